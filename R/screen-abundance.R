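#' Normalize gRNA counts to scramble controls
#'
#' Divides each gRNA's raw count by the summed scramble-control counts of
#' its sample, making downstream fold changes exactly invariant to
#' per-sample sequencing depth.
#'
#' @param counts Data frame with columns `grna_id`, `sample_id`, `count`
#'   and a logical `scramble` column.
#' @return The input with an added `norm_abundance` column.
#' @export
normalize_to_scramble <- function(counts) {
  stopifnot(all(c("grna_id", "sample_id", "count", "scramble") %in%
                  names(counts)))
  scr_tot <- tapply(counts$count[counts$scramble],
                    counts$sample_id[counts$scramble], sum)
  samples <- unique(counts$sample_id)
  missing_scr <- setdiff(samples, names(scr_tot))
  zero_scr <- names(scr_tot)[scr_tot == 0]
  bad <- c(missing_scr, zero_scr)
  if (length(bad)) {
    stop("zero scramble total in sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts$norm_abundance <- counts$count / as.numeric(scr_tot[counts$sample_id])
  counts
}

#' Gene-level abundance from normalized gRNA abundances
#'
#' Sums the normalized abundances of all gRNAs targeting each gene,
#' excluding guides with editing efficiency below `efficiency_min` when
#' efficiencies are provided (strict `<`: a guide at exactly the threshold
#' is retained).
#'
#' @param normalized Output of [normalize_to_scramble()] (one sample, or
#'   pass per-sample subsets).
#' @param map Data frame `grna_id`, `gene_id` covering all non-scramble
#'   guides; optional `efficiency` column in `[0, 1]`.
#' @param efficiency_min Exclusion threshold (default 0.05).
#' @return Named numeric vector of per-gene summed abundance per sample when
#'   a single sample is present; otherwise a genes x samples matrix. Genes
#'   with zero retained guides are `NA` with a warning.
#' @export
gene_abundance <- function(normalized, map, efficiency_min = 0.05) {
  dat <- normalized[!normalized$scramble, , drop = FALSE]
  idx <- match(dat$grna_id, map$grna_id)
  if (anyNA(idx)) {
    stop("gRNA map does not cover all non-scramble guides", call. = FALSE)
  }
  dat$gene_id <- map$gene_id[idx]
  if (!is.null(map$efficiency)) {
    eff <- map$efficiency[idx]
    dat <- dat[is.na(eff) | eff >= efficiency_min, , drop = FALSE]
  }
  genes <- unique(map$gene_id[!is.na(map$gene_id)])
  samples <- unique(normalized$sample_id)
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  agg <- tapply(dat$norm_abundance, list(dat$gene_id, dat$sample_id), sum)
  out[rownames(agg), colnames(agg)] <- agg
  if (anyNA(out)) {
    warning("gene(s) with zero retained gRNAs: ",
            paste(rownames(out)[apply(is.na(out), 1, any)], collapse = ", "),
            call. = FALSE)
  }
  if (length(samples) == 1) out[, 1] else out
}

#' Per-gene log2 fold change between sorted fractions
#'
#' `log2((high + pseudo) / (low + pseudo))` on normalized gene abundances,
#' with replicate samples averaged on the log scale.
#'
#' @param abund_high,abund_low Named vectors (or genes x replicates
#'   matrices) of normalized gene abundances over matched gene sets.
#' @param pseudo Pseudo-abundance guarding the ratio (default 1e-9).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
fraction_log2fc <- function(abund_high, abund_low, pseudo = 1e-9) {
  as_mat <- function(x) if (is.null(dim(x))) cbind(x) else x
  h <- as_mat(abund_high); l <- as_mat(abund_low)
  if (!identical(rownames(h), rownames(l))) {
    l <- l[rownames(h), , drop = FALSE]
  }
  lh <- rowMeans(log2(h + pseudo))
  ll <- rowMeans(log2(l + pseudo))
  lh - ll
}

#' Averaged per-gene log2 fold change between two conditions
#'
#' Mean over replicate pairs of `log2(a / b)` on normalized gene
#' abundances (replicate i of condition a paired with replicate i of b).
#'
#' @param abund_a,abund_b Genes x replicates matrices (or named vectors) of
#'   normalized abundances; equal replicate counts are paired positionally.
#' @param pseudo Pseudo-abundance (default 1e-9).
#' @return Named numeric vector of averaged log2 fold changes.
#' @export
condition_log2fc <- function(abund_a, abund_b, pseudo = 1e-9) {
  as_mat <- function(x) if (is.null(dim(x))) cbind(x) else x
  a <- as_mat(abund_a); b <- as_mat(abund_b)
  if (!identical(rownames(a), rownames(b))) b <- b[rownames(a), , drop = FALSE]
  if (ncol(a) != ncol(b)) {
    stop("conditions must have equal replicate counts for pairing",
         call. = FALSE)
  }
  rowMeans(log2((a + pseudo) / (b + pseudo)))
}
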