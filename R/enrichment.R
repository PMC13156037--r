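#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene list and a gene set within a background universe, with the
#' enrichment ratio observed/expected overlap.
#'
#' @param query,gene_set Character vectors, subsets of `background`.
#' @param background Background gene universe (non-empty).
#' @return List with `overlap`, `enrichment_ratio`, `expected`, `p`.
#' @examples
#' hypergeom_ora(letters[1:5], letters[1:5], letters[1:20])
#' @export
hypergeom_ora <- function(query, gene_set, background) {
  if (length(background) == 0) stop("`background` is empty", call. = FALSE)
  background <- unique(background)
  query <- intersect(unique(query), background)
  gene_set <- intersect(unique(gene_set), background)
  ov <- length(intersect(query, gene_set))
  expected <- length(query) * length(gene_set) / length(background)
  p <- stats::phyper(ov - 1, length(gene_set),
                     length(background) - length(gene_set),
                     length(query), lower.tail = FALSE)
  list(overlap = ov,
       enrichment_ratio = if (expected > 0) ov / expected else NA_real_,
       expected = expected, p = p)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on an ordered
# hit indicator. Returns the signed extremum, its position, and the walk.
.gsea_walk <- function(hits, scores, weight_p) {
  n <- length(hits)
  w <- abs(scores)^weight_p
  w_hit <- ifelse(hits, w, 0)
  nr <- sum(w_hit)
  n_miss <- n - sum(hits)
  if (nr == 0 || n_miss == 0) return(list(es = 0, pos = 0, walk = numeric(n)))
  step_hit <- w_hit / nr
  step_miss <- ifelse(hits, 0, 1 / n_miss)
  walk <- cumsum(step_hit - step_miss)
  pos <- which.max(abs(walk))
  list(es = walk[pos], pos = pos, walk = walk)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum GSEA on a signed gene ranking.
#' The enrichment score (ES) is the signed extremum of the running sum;
#' the leading edge contains the set members up to the extremum (from the
#' top for positive ES, from the extremum to the bottom for negative ES).
#' Significance is assessed by gene-label permutation; the normalized score
#' (NES) divides ES by the mean absolute ES of same-sign permutations.
#'
#' @param ranked Named numeric vector: gene -> signed score (ranked
#'   internally, most positive first).
#' @param gene_set Character vector; at least 3 members must intersect the
#'   ranking.
#' @param weight_p Weighting exponent on |score| (1 = weighted, 0 = classic
#'   KS; default 1).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return List with `es`, `nes`, `p`, `leading_edge`, `n_members`; `NULL`
#'   components (with a warning) when fewer than 3 members intersect.
#' @export
gsea_preranked <- function(ranked, gene_set, weight_p = 1, n_perm = 1000L,
                           seed = 1L) {
  if (is.null(names(ranked))) stop("`ranked` must be named by gene", call. = FALSE)
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  scores <- ranked[ord]
  hits <- genes %in% gene_set
  n_hit <- sum(hits)
  if (n_hit < 3) {
    warning("fewer than 3 gene-set members in the ranking; skipped",
            call. = FALSE)
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                leading_edge = character(0), n_members = n_hit,
                reason = "fewer than 3 members"))
  }
  obs <- .gsea_walk(hits, scores, weight_p)
  leading <- if (obs$es >= 0) {
    genes[seq_len(obs$pos)][hits[seq_len(obs$pos)]]
  } else {
    genes[obs$pos:length(genes)][hits[obs$pos:length(genes)]]
  }
  n_perm <- .check_count(n_perm, "n_perm")
  perm_es <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ph <- rep(FALSE, length(genes))
      ph[sample.int(length(genes), n_hit)] <- TRUE
      .gsea_walk(ph, scores, weight_p)$es
    }, numeric(1))
  })
  same_sign <- perm_es[sign(perm_es) == sign(obs$es)]
  if (length(same_sign) == 0) {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
  } else {
    nes <- obs$es / mean(abs(same_sign))
    p <- (sum(abs(same_sign) >= abs(obs$es)) + 1) / (length(same_sign) + 1)
  }
  list(es = obs$es, nes = nes, p = p, leading_edge = leading,
       n_members = n_hit)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement; output order matches
#' input order and the adjusted values are invariant to input permutation.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  .check_prob(pvalues[!is.na(pvalues)], "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Down-sampling robustness of over-representation results
#'
#' Repeatedly down-samples each gene set to fixed sizes and re-runs the
#' hypergeometric test, summarizing the stability of the enrichment call
#' across subsamples. Sets smaller than a requested size are skipped for
#' that size (with a message).
#'
#' @param query Character vector of query genes.
#' @param gene_sets Named list of gene sets.
#' @param background Background universe.
#' @param sizes Down-sampled set sizes (default `c(100, 250, 500, 750,
#'   1000)`).
#' @param reps Subsamples per (set, size) (default 10).
#' @param seed Seed for the subsampling.
#' @return Data frame with one row per (set, size, rep): `set`, `size`,
#'   `rep`, `overlap`, `enrichment_ratio`, `p`.
#' @export
downsample_enrichment <- function(query, gene_sets, background,
                                  sizes = c(100, 250, 500, 750, 1000),
                                  reps = 10L, seed = 1L) {
  reps <- .check_count(reps, "reps")
  rows <- list()
  .with_seed(seed, {
    for (set_name in names(gene_sets)) {
      gs <- intersect(gene_sets[[set_name]], background)
      for (size in sizes) {
        if (length(gs) < size) {
          message(sprintf("set '%s' smaller than %d; skipped", set_name, size))
          next
        }
        for (r in seq_len(reps)) {
          sub <- sample(gs, size)
          res <- hypergeom_ora(query, sub, background)
          rows[[length(rows) + 1L]] <- data.frame(
            set = set_name, size = size, rep = r, overlap = res$overlap,
            enrichment_ratio = res$enrichment_ratio, p = res$p,
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  if (length(rows) == 0) {
    return(data.frame(set = character(0), size = numeric(0),
                      rep = integer(0), overlap = integer(0),
                      enrichment_ratio = numeric(0), p = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
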