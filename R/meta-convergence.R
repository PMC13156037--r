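#' Meta-analyze differential-expression tables across KO perturbations
#'
#' Combines per-perturbation differential-expression summaries (one table per
#' knockout) into per-gene meta-analytic statistics. The default
#' `"sample_size"` method is the signed Stouffer combination used by
#' P-value-based meta-analysis tools: each study contributes a signed Z
#' derived from its two-sided p-value and the sign of its log2 fold change,
#' weighted by the square root of its sample size,
#' \deqn{Z = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2}, \quad w_i = \sqrt{n_i}.}
#' The `"inverse_variance"` method instead pools the log2 fold changes with
#' weights \eqn{1/se_i^2}. In both cases Cochran's Q heterogeneity statistic
#' is computed on the effect scale with inverse-variance weights
#' (\eqn{Q = \sum_i (\beta_i - \hat\beta)^2 / se_i^2}, df = k - 1), and
#' Benjamini-Hochberg FDR is applied to the meta p-values within the tested
#' gene set.
#'
#' @param tables A list of DEG tables (data frames) over one gene universe.
#'   Each must have columns `gene_id`, `log2fc`, `se`, `pvalue`, `n`.
#' @param method `"sample_size"` (signed Stouffer, the default) or
#'   `"inverse_variance"`.
#' @param allow_single Permit the degenerate single-table call, which returns
#'   the input statistics unchanged (identity meta-analysis). Off by default.
#' @return A data frame of class `meta_result`, one row per gene, with
#'   columns `gene_id`, `z_meta`, `p_meta`, `q_value`, `beta_meta` (pooled
#'   effect, inverse-variance scale), `cochran_q`, `p_het`, `n_studies`,
#'   `direction_consistent` and `sign` (+1/-1 shared direction, 0 otherwise).
#'   The per-study log2 fold-change sign matrix is attached as attribute
#'   `"study_signs"` (genes x studies).
#' @examples
#' t1 <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1, -1),
#'                  se = 0.2, pvalue = c(0.01, 0.5), n = 10)
#' t2 <- data.frame(gene_id = c("g1", "g2"), log2fc = c(0.8, 1),
#'                  se = 0.2, pvalue = c(0.02, 0.4), n = 10)
#' meta_analyze(list(ko_a = t1, ko_b = t2))
#' @export
meta_analyze <- function(tables, method = c("sample_size", "inverse_variance"),
                         allow_single = FALSE) {
  method <- match.arg(method)
  if (!is.list(tables) || length(tables) == 0) {
    stop("`tables` must be a non-empty list of DEG tables", call. = FALSE)
  }
  if (length(tables) < 2 && !allow_single) {
    stop("meta-analysis needs >= 2 tables (set `allow_single` to override)",
         call. = FALSE)
  }
  req <- c("gene_id", "log2fc", "se", "pvalue", "n")
  for (tab in tables) {
    miss <- setdiff(req, names(tab))
    if (length(miss)) {
      stop("DEG table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (any(tab$se <= 0)) stop("se must be > 0 for every gene", call. = FALSE)
    .check_prob(tab$pvalue, "pvalue")
    if (anyDuplicated(tab$gene_id)) {
      stop("DEG table has duplicated gene ids", call. = FALSE)
    }
  }
  k <- length(tables)
  all_genes <- unique(unlist(lapply(tables, `[[`, "gene_id")))
  presence <- vapply(tables, function(tab) all_genes %in% tab$gene_id,
                     logical(length(all_genes)))
  presence <- matrix(presence, nrow = length(all_genes))
  n_present <- rowSums(presence)
  min_needed <- if (allow_single && k == 1) 1L else 2L
  keep <- n_present >= min_needed
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) present in fewer than 2 tables were dropped",
            call. = FALSE)
  }
  genes <- all_genes[keep]
  if (length(genes) == 0) stop("no gene shared by >= 2 tables", call. = FALSE)

  # Align per-study statistics into genes x studies matrices (NA = absent).
  grab <- function(col) {
    m <- vapply(tables, function(tab) {
      col_v <- tab[[col]][match(genes, tab$gene_id)]
      as.numeric(col_v)
    }, numeric(length(genes)))
    matrix(m, nrow = length(genes), dimnames = list(genes, names(tables)))
  }
  b <- grab("log2fc"); se <- grab("se"); p <- grab("pvalue"); n <- grab("n")

  sgn <- sign(b)
  z_study <- .z_from_p(p, ifelse(sgn == 0, 1, sgn))

  n_studies <- rowSums(!is.na(b))
  if (method == "sample_size") {
    w <- sqrt(n)
    z_meta <- rowSums(w * z_study, na.rm = TRUE) /
      sqrt(rowSums(w^2, na.rm = TRUE))
  } else {
    wiv <- 1 / se^2
    beta_hat <- rowSums(b * wiv, na.rm = TRUE) / rowSums(wiv, na.rm = TRUE)
    z_meta <- beta_hat * sqrt(rowSums(wiv, na.rm = TRUE))
  }
  p_meta <- .p_from_z(z_meta)

  # Cochran's Q on the effect scale regardless of the combination method.
  wiv <- 1 / se^2
  beta_iv <- rowSums(b * wiv, na.rm = TRUE) / rowSums(wiv, na.rm = TRUE)
  q_stat <- rowSums((b - beta_iv)^2 * wiv, na.rm = TRUE)
  df <- n_studies - 1L
  p_het <- ifelse(df >= 1, stats::pchisq(q_stat, df, lower.tail = FALSE), NA_real_)
  p_het[df >= 1 & q_stat == 0] <- 1

  dir_cons <- apply(sgn, 1L, function(s) {
    s <- s[!is.na(s)]
    length(s) > 0 && all(s != 0) && length(unique(s)) == 1L
  })
  shared_sign <- ifelse(dir_cons, sgn[, 1L], 0)
  # First study might be NA for genes missing there; take first non-NA sign.
  first_sign <- apply(sgn, 1L, function(s) s[!is.na(s)][1L])
  shared_sign <- ifelse(dir_cons, first_sign, 0)

  out <- data.frame(
    gene_id = genes,
    z_meta = z_meta,
    p_meta = p_meta,
    q_value = stats::p.adjust(p_meta, method = "BH"),
    beta_meta = beta_iv,
    cochran_q = q_stat,
    p_het = p_het,
    n_studies = n_studies,
    direction_consistent = dir_cons,
    sign = shared_sign,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "study_signs") <- sgn
  attr(out, "method") <- method
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Call convergent genes from a meta-analysis result
#'
#' A gene is convergent when it is meta-significant after FDR correction
#' (`q_value < fdr_max`), shows no detectable effect heterogeneity
#' (`p_het > phet_min`, Cochran's Q), and has the identical nonzero direction
#' of effect in every perturbation. A zero log2 fold change counts as "no
#' direction" and blocks the call.
#'
#' @param meta A `meta_result` from [meta_analyze()].
#' @param per_study_signs Optional genes x studies sign matrix; defaults to
#'   the matrix recorded by [meta_analyze()].
#' @param fdr_max FDR threshold on the meta p-value (default 0.05).
#' @param phet_min Heterogeneity p-value floor: genes at or below it are
#'   considered heterogeneous and excluded (default 0.05).
#' @return Data frame of convergent genes with columns `gene_id`, `sign`,
#'   `z_meta`, `q_value`, `p_het`.
#' @export
call_convergent <- function(meta, per_study_signs = NULL,
                            fdr_max = 0.05, phet_min = 0.05) {
  if (is.null(per_study_signs)) per_study_signs <- attr(meta, "study_signs")
  if (!is.null(per_study_signs)) {
    if (!identical(rownames(per_study_signs), meta$gene_id)) {
      per_study_signs <- per_study_signs[match(meta$gene_id,
                                               rownames(per_study_signs)), ,
                                         drop = FALSE]
    }
    dir_cons <- apply(sign(per_study_signs), 1L, function(s) {
      s <- s[!is.na(s)]
      length(s) > 0 && all(s != 0) && length(unique(s)) == 1L
    })
  } else {
    dir_cons <- meta$direction_consistent
  }
  hit <- !is.na(meta$q_value) & meta$q_value < fdr_max &
    !is.na(meta$p_het) & meta$p_het > phet_min & dir_cons
  out <- meta[hit, c("gene_id", "sign", "z_meta", "q_value", "p_het")]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Gene-level convergence ratio
#'
#' Strength of convergence for a KO set: the number of convergent genes
#' divided by the arithmetic mean of the per-KO DEG counts.
#'
#' @param n_convergent Count of convergent genes.
#' @param deg_counts Vector of per-KO DEG counts.
#' @return A single ratio; `NA` (with a warning) when the mean DEG count is 0.
#' @examples
#' convergence_ratio(5, c(10, 20, 30))  # 0.25
#' @export
convergence_ratio <- function(n_convergent, deg_counts) {
  if (length(deg_counts) == 0) stop("`deg_counts` must be non-empty", call. = FALSE)
  m <- mean(deg_counts)
  if (m == 0) {
    warning("mean DEG count is 0; convergence ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  n_convergent / m
}

#' Enumerate KO subsets
#'
#' All subsets of the KO identifiers with sizes in `[min_size, max_size]`,
#' in deterministic lexicographic order, optionally down-sampled to a
#' requested number of subsets under a seed.
#'
#' @param ko_ids Character vector of perturbation ids.
#' @param min_size Smallest subset size (default 2).
#' @param max_size Largest subset size; `NULL` means `length(ko_ids)`.
#' @param sample_n Optional number of subsets to retain by seeded sampling.
#' @param seed Seed for the optional down-sampling.
#' @return A list of character vectors.
#' @examples
#' length(enumerate_ko_subsets(letters[1:9]))            # 502
#' length(enumerate_ko_subsets(letters[1:9], max_size = 5))  # 372
#' @export
enumerate_ko_subsets <- function(ko_ids, min_size = 2L, max_size = NULL,
                                 sample_n = NULL, seed = NULL) {
  min_size <- .check_count(min_size, "min_size", min = 2L)
  n <- length(ko_ids)
  if (is.null(max_size)) max_size <- n
  max_size <- .check_count(max_size, "max_size", min = 1L)
  if (max_size > n) stop("`max_size` exceeds the number of KOs", call. = FALSE)
  if (min_size > n) return(list())
  ko_sorted <- sort(ko_ids)
  subsets <- list()
  for (k in seq(min_size, max_size)) {
    subsets <- c(subsets, utils::combn(ko_sorted, k, simplify = FALSE))
  }
  if (!is.null(sample_n) && sample_n < length(subsets)) {
    idx <- .with_seed(seed, sample.int(length(subsets), sample_n))
    subsets <- subsets[sort(idx)]
  }
  subsets
}

#' Rank-rank hypergeometric overlap map
#'
#' Threshold-grid comparison of two ranked gene lists. Both lists carry a
#' signed per-gene score (e.g., signed -log10 p); genes are ranked from most
#' positive to most negative. For every threshold pair (i, j) on the step
#' grid, the overlap between the top-i genes of list A and the top-j genes of
#' list B is tested against the hypergeometric expectation; the map entry is
#' `-log10 p` signed positive when the observed overlap exceeds expectation
#' (enrichment, upper tail) and negative when it falls short (depletion,
#' lower tail).
#'
#' @param ranked_a,ranked_b Named numeric vectors of signed scores over the
#'   same gene universe.
#' @param step Grid step in ranks; default `ceiling(N / 100)`.
#' @return A numeric matrix of signed -log10 p values, thresholds of A in
#'   rows, of B in columns (dimnames give the rank thresholds).
#' @export
rrho_map <- function(ranked_a, ranked_b, step = NULL) {
  if (is.null(names(ranked_a)) || is.null(names(ranked_b))) {
    stop("ranked lists must be named by gene", call. = FALSE)
  }
  if (!setequal(names(ranked_a), names(ranked_b))) {
    stop("ranked lists must cover the same gene universe", call. = FALSE)
  }
  n <- length(ranked_a)
  if (is.null(step)) step <- ceiling(n / 100)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  ord_a <- names(sort(ranked_a, decreasing = TRUE))
  ord_b <- names(sort(ranked_b, decreasing = TRUE))
  thr <- seq(step, n, by = step)
  # Overlap counting by cumulative membership: rank of each gene in B's order.
  rank_b <- match(ord_a, ord_b)
  out <- matrix(NA_real_, length(thr), length(thr),
                dimnames = list(a = thr, b = thr))
  for (ii in seq_along(thr)) {
    i <- thr[ii]
    rb <- rank_b[seq_len(i)]
    for (jj in seq_along(thr)) {
      j <- thr[jj]
      k <- sum(rb <= j)
      expected <- i * j / n
      if (k >= expected) {
        p <- stats::phyper(k - 1, i, n - i, j, lower.tail = FALSE)
        out[ii, jj] <- -log10(max(p, .P_FLOOR))
      } else {
        p <- stats::phyper(k, i, n - i, j, lower.tail = TRUE)
        out[ii, jj] <- log10(max(p, .P_FLOOR))
      }
    }
  }
  out
}

#' Cross-perturbation correlation of DEG profiles
#'
#' Pearson correlation between every pair of perturbation log2FC profiles,
#' computed over the union of genes nominally significant (p < `p_max`) in
#' either member of the pair.
#'
#' @param logfc_matrix Genes x perturbations matrix of log2 fold changes.
#' @param p_matrix Matching matrix of p-values.
#' @param p_max Nominal significance threshold selecting genes (default 0.01).
#' @return Symmetric perturbation x perturbation correlation matrix with unit
#'   diagonal; entries with fewer than 3 qualifying genes are `NA`.
#' @export
correlate_profiles <- function(logfc_matrix, p_matrix, p_max = 0.01) {
  if (!all(dim(logfc_matrix) == dim(p_matrix))) {
    stop("matrix dimensions must match", call. = FALSE)
  }
  m <- ncol(logfc_matrix)
  out <- diag(1, m)
  dimnames(out) <- list(colnames(logfc_matrix), colnames(logfc_matrix))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      sel <- which(p_matrix[, i] < p_max | p_matrix[, j] < p_max)
      if (length(sel) < 3) {
        out[i, j] <- out[j, i] <- NA_real_
      } else {
        out[i, j] <- out[j, i] <- stats::cor(logfc_matrix[sel, i],
                                             logfc_matrix[sel, j])
      }
    }
  }
  out
}
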