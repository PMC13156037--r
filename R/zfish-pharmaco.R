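#' Fit the effect of a genotype/treatment contrast on one behavioral
#' parameter
#'
#' Linear mixed model `value ~ group + (1 | batch_date)` with a Wald normal
#' p-value for the group coefficient. When only one batch is present (or the
#' random effect is degenerate) the fit falls back to ordinary least squares
#' (flagged in the result). The `"mutant_vs_control"` contrast compares
#' mutant+vehicle with control+vehicle larvae; `"mutantdrug_vs_control"`
#' compares mutant+drug with control+vehicle.
#'
#' @param table Long behavior data frame (see [simulate_behavior_table()]).
#' @param parameter Behavioral parameter to fit.
#' @param contrast `"mutant_vs_control"` (default) or
#'   `"mutantdrug_vs_control"`.
#' @return List with `beta`, `p`, `n_per_group`, `method` (`"lmm"` or
#'   `"ols"`), `degenerate` flag.
#' @export
fit_behavior_effect <- function(table, parameter,
                                contrast = c("mutant_vs_control",
                                             "mutantdrug_vs_control")) {
  contrast <- match.arg(contrast)
  dat <- table[table$parameter == parameter, , drop = FALSE]
  base <- dat[dat$genotype == "control" & dat$treatment == "vehicle", ]
  test <- if (contrast == "mutant_vs_control") {
    dat[dat$genotype == "mutant" & dat$treatment == "vehicle", ]
  } else {
    dat[dat$genotype == "mutant" & dat$treatment == "drug", ]
  }
  if (nrow(base) < 3 || nrow(test) < 3) {
    stop("need >= 3 larvae per contrasted group", call. = FALSE)
  }
  if (stats::sd(base$value) == 0 && stats::sd(test$value) == 0) {
    return(list(beta = mean(test$value) - mean(base$value), p = 1,
                n_per_group = c(nrow(base), nrow(test)), method = "none",
                degenerate = TRUE))
  }
  d <- rbind(base, test)
  d$group <- factor(rep(c(0L, 1L), c(nrow(base), nrow(test))))
  n_batch <- length(unique(d$batch_date))
  if (n_batch > 1) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ group + (1 | batch_date), data = d)))
    cf <- summary(fit)$coefficients
    beta <- cf["group1", "Estimate"]
    tval <- cf["group1", "t value"]
    p <- .p_from_z(tval)
    method <- "lmm"
  } else {
    fit <- stats::lm(value ~ group, data = d)
    cf <- summary(fit)$coefficients
    beta <- cf["group1", "Estimate"]
    p <- cf["group1", "Pr(>|t|)"]
    method <- "ols"
  }
  list(beta = beta, p = p, n_per_group = c(nrow(base), nrow(test)),
       method = method, degenerate = FALSE)
}

#' Behavioral fingerprint of a mutant (or a drug condition)
#'
#' Per-parameter mixed-model effect of the requested contrast, summarized as
#' the signed score `sign(beta) * -log10(p)` (p floored at 1e-300).
#'
#' @param table Long behavior data frame.
#' @param contrast Passed to [fit_behavior_effect()].
#' @param parameters Parameters to fit (default: all present in `table`;
#'   missing standard parameters are simply absent from the result).
#' @return Data frame with columns `parameter`, `beta`, `p`, `signed_score`.
#' @export
behavioral_fingerprint <- function(table, contrast = "mutant_vs_control",
                                   parameters = NULL) {
  if (is.null(parameters)) parameters <- unique(table$parameter)
  rows <- lapply(parameters, function(pp) {
    fit <- fit_behavior_effect(table, pp, contrast)
    data.frame(parameter = pp, beta = fit$beta, p = fit$p,
               signed_score = .signed_log10p(fit$p, sign(fit$beta)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster mutants by behavioral fingerprint
#'
#' Pearson correlation between mutants over their signed fingerprint scores,
#' then average-linkage hierarchical clustering on the `1 - r` distance with
#' an optional cut into `k` groups.
#'
#' @param fingerprints Mutants x parameters numeric matrix of signed scores
#'   (rownames are mutant ids).
#' @param k Optional number of groups to cut the dendrogram into.
#' @return List with `correlation` (mutant x mutant), `hclust`, and
#'   `groups` (named membership vector, when `k` given). Constant
#'   fingerprints yield `NA` correlations and are dropped from clustering
#'   with a warning.
#' @export
cluster_mutants <- function(fingerprints, k = NULL) {
  if (nrow(fingerprints) < 2) stop("need >= 2 mutants", call. = FALSE)
  const <- apply(fingerprints, 1, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("constant fingerprint(s) dropped from clustering: ",
            paste(rownames(fingerprints)[const], collapse = ", "),
            call. = FALSE)
  }
  cm <- suppressWarnings(stats::cor(t(fingerprints)))
  usable <- fingerprints[!const, , drop = FALSE]
  hc <- NULL; groups <- NULL
  if (nrow(usable) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(usable)))
    hc <- stats::hclust(d, method = "average")
    if (!is.null(k)) groups <- stats::cutree(hc, k = k)
  }
  list(correlation = cm, hclust = hc, groups = groups)
}

#' Match drugs to a mutant fingerprint
#'
#' Pearson correlation (t-test p) between the mutant's signed scores and
#' each drug's signed scores over the shared behavioral parameters; a drug
#' is a `correlate` when `r > r_abs_min` with `p < p_max`, an
#' `anti-correlate` when `r < -r_abs_min` with `p < p_max`.
#'
#' @param mutant_fp Fingerprint data frame (from
#'   [behavioral_fingerprint()]) or named numeric vector of signed scores.
#' @param drug_fps Named list of drug fingerprints (same forms).
#' @param r_abs_min Absolute-correlation threshold (default 0.5).
#' @param p_max p-value threshold (default 0.05).
#' @return Data frame per drug: `drug`, `r`, `p`, `match`
#'   (`"correlate"` / `"anti-correlate"` / `"none"`); drugs sharing < 3
#'   parameters get `NA` statistics.
#' @export
match_drugs <- function(mutant_fp, drug_fps, r_abs_min = 0.5, p_max = 0.05) {
  as_vec <- function(fp) {
    if (is.data.frame(fp)) stats::setNames(fp$signed_score, fp$parameter)
    else fp
  }
  mv <- as_vec(mutant_fp)
  rows <- lapply(names(drug_fps), function(dn) {
    dv <- as_vec(drug_fps[[dn]])
    shared <- intersect(names(mv), names(dv))
    if (length(shared) < 3) {
      return(data.frame(drug = dn, r = NA_real_, p = NA_real_,
                        match = NA_character_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(mv[shared], dv[shared])
    r <- unname(ct$estimate); p <- ct$p.value
    match_lab <- if (!is.na(r) && r > r_abs_min && p < p_max) "correlate"
    else if (!is.na(r) && r < -r_abs_min && p < p_max) "anti-correlate"
    else "none"
    data.frame(drug = dn, r = r, p = p, match = match_lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Connectivity-map style signature-reversal query
#'
#' Scores disjoint up/down query gene sets against a collection of ranked
#' expression signatures. Per signature, weighted KS enrichment scores are
#' computed for the up and the down set on the signature's ranking; the
#' weighted two-sided connectivity score is
#' `wtcs = (ES_up - ES_down) / 2` when the two scores have opposite signs
#' and 0 otherwise. NCS normalizes wtcs by the mean of same-sign wtcs within
#' the signature's perturbation group. FDR for a reference signature is the
#' fraction of null (vehicle) signatures whose |NCS| reaches that
#' signature's |NCS|. Signatures with `ncs <= -1` and `fdr <= 0.05` are
#' flagged as reversers.
#'
#' @param query_up,query_down Disjoint character vectors of query genes.
#' @param signatures Data frame with columns `signature_id`, `group_id`,
#'   `gene`, `score` (the per-gene differential-expression statistic; the
#'   ranking), `null_flag` (logical, vehicle signatures).
#' @param weight_p GSEA weight exponent (default 1).
#' @return Data frame per signature: `signature_id`, `group_id`,
#'   `null_flag`, `wtcs`, `ncs`, `fdr`, `reverser`.
#' @export
cmap_query <- function(query_up, query_down, signatures, weight_p = 1) {
  if (length(intersect(query_up, query_down)) > 0) {
    stop("query sets must be disjoint", call. = FALSE)
  }
  sig_ids <- unique(signatures$signature_id)
  rows <- lapply(sig_ids, function(sid) {
    sig <- signatures[signatures$signature_id == sid, ]
    ranked <- stats::setNames(sig$score, sig$gene)
    ord <- order(ranked, decreasing = TRUE)
    genes <- names(ranked)[ord]; scores <- ranked[ord]
    es_for <- function(qs) {
      hits <- genes %in% qs
      if (sum(hits) == 0) return(NA_real_)
      .gsea_walk(hits, scores, weight_p)$es
    }
    es_up <- es_for(query_up); es_dn <- es_for(query_down)
    wtcs <- if (is.na(es_up) || is.na(es_dn)) NA_real_
    else if (sign(es_up) != sign(es_dn)) (es_up - es_dn) / 2 else 0
    data.frame(signature_id = sid, group_id = sig$group_id[1],
               null_flag = isTRUE(sig$null_flag[1]), wtcs = wtcs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # NCS: divide by the signed mean of same-sign wtcs within the group.
  out$ncs <- NA_real_
  for (grp in unique(out$group_id)) {
    in_grp <- out$group_id == grp
    for (s in c(-1, 1)) {
      sel <- in_grp & !is.na(out$wtcs) & sign(out$wtcs) == s
      if (any(sel)) out$ncs[sel] <- out$wtcs[sel] / mean(abs(out$wtcs[sel]))
    }
    zero <- in_grp & !is.na(out$wtcs) & out$wtcs == 0
    out$ncs[zero] <- 0
  }
  null_ncs <- abs(out$ncs[out$null_flag & !is.na(out$ncs)])
  out$fdr <- vapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$ncs[i]) || length(null_ncs) == 0) return(NA_real_)
    mean(null_ncs >= abs(out$ncs[i]))
  }, numeric(1))
  out$reverser <- !is.na(out$ncs) & !is.na(out$fdr) &
    out$ncs <= -1.00 & out$fdr <= 0.05
  rownames(out) <- NULL
  out
}

#' Classify the rescue effect of a drug on one behavioral parameter
#'
#' Five-category comparison of the mutant-vs-control effect (`mut`) with the
#' mutant+drug-vs-control effect (`drug`), gated on a nominally significant
#' mutant effect (`mut$p < alpha`, default alpha 0.06):
#' \itemize{
#'   \item `rescued` - the drug abolishes significance (`drug_p >= alpha`);
#'   \item `over_corrected` - still significant but direction flipped;
#'   \item `partial_rescue` - significant, same direction, smaller |beta|;
#'   \item `exacerbated` - p at least as strong as the mutant's and larger
#'     |beta|, same direction;
#'   \item `unchanged` - any remaining classified case.
#' }
#' Categories are assigned in that precedence order.
#'
#' @param mut List/vector with `beta` and `p` for mutant+vehicle vs
#'   control+vehicle.
#' @param drug Same for mutant+drug vs control+vehicle.
#' @param alpha Significance gate (default 0.06).
#' @return List with `category` (`NA` when the mutant effect fails the
#'   gate), `mut_beta`, `mut_p`, `drug_beta`, `drug_p`.
#' @export
classify_rescue <- function(mut, drug, alpha = 0.06) {
  mb <- mut[["beta"]]; mp <- mut[["p"]]
  db <- drug[["beta"]]; dp <- drug[["p"]]
  out <- list(category = NA_character_, mut_beta = mb, mut_p = mp,
              drug_beta = db, drug_p = dp)
  if (is.na(mp) || mp >= alpha) return(out)   # gate: mutant effect required
  if (is.na(dp) || is.na(db)) return(out)     # missing drug fit: uncalled
  out$category <-
    if (dp >= alpha) "rescued"
    else if (sign(db) != sign(mb)) "over_corrected"
    else if (abs(db) < abs(mb)) "partial_rescue"
    else if (dp <= mp && abs(db) > abs(mb)) "exacerbated"
    else "unchanged"
  out
}
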