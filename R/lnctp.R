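#' Assemble a GRN-masked Gaussian energy model over bulk + cell-type
#' expression
#'
#' Builds the joint Gaussian over the concatenated expression vector
#' (bulk context followed by `C` cell-type contexts, each over the gene
#' panel). Each context contributes a precision block whose off-diagonal
#' support is exactly the context's gene regulatory network (GRN); a
#' deconvolution penalty of weight `lambda` couples every bulk gene to the
#' cell-fraction-weighted combination of its cell-type copies,
#' \eqn{\lambda \sum_g (x_{0g} - f^T x_{1..C,g})^2}. The quadratic-form
#' matrices are interpreted directly as precision blocks (the conventional
#' factor between energy and precision is absorbed), so the model is the
#' Gaussian with precision
#' \eqn{\Omega = \mathrm{blockdiag}(J_0, J_1, \ldots, J_C) + 2\lambda \sum_g v_g v_g^T}
#' where \eqn{v_g} has entry 1 at (bulk, g) and \eqn{-f_c} at (c, g).
#' Indefinite assemblies are repaired by diagonal loading (logged via a
#' message); irreparable ones are an error naming the offending eigenvalue.
#'
#' @param panel Character vector of gene ids (the panel G).
#' @param grn Named list of per-context edge data frames (`gene_a`,
#'   `gene_b`, optional `weight`, default -0.25). A context named `"bulk"`
#'   populates the bulk block; all other names become cell-type contexts.
#' @param lambda Deconvolution weight (>= 0, default 0).
#' @param fractions Named (or unnamed, recycled in context order) cell-type
#'   proportions summing to 1; default equal.
#' @param diag_value Diagonal precision per coordinate before loading
#'   (default 1).
#' @param genotype Optional list `list(z = , beta = )` with `z` an
#'   individuals x variants dosage matrix and `beta` a variants x G
#'   coefficient matrix; the product shifts bulk means per individual.
#' @param mu Optional mean vector over all coordinates (default 0).
#' @return An `lnctp_model`: `panel`, `contexts` (bulk first), `precision`,
#'   `mu`, `lambda`, `fractions`, `support` (logical matrix of permitted
#'   off-diagonals), `loading` (diagonal loading applied), `vars` (coordinate
#'   names `<context>.<gene>`), optional `indiv_shift`.
#' @export
assemble_lnctp <- function(panel, grn, lambda = 0, fractions = NULL,
                           diag_value = 1, genotype = NULL, mu = NULL) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  G <- length(panel)
  cell_types <- setdiff(names(grn), "bulk")
  if (is.null(names(grn))) stop("`grn` must be a named list", call. = FALSE)
  contexts <- c("bulk", cell_types)
  C <- length(cell_types)
  if (is.null(fractions)) {
    fractions <- if (C > 0) rep(1 / C, C) else numeric(0)
  }
  if (C > 0) {
    if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
      stop("`fractions` must be nonnegative and sum to 1", call. = FALSE)
    }
    if (is.null(names(fractions))) names(fractions) <- cell_types
  }
  vars <- as.vector(t(outer(contexts, panel, paste, sep = ".")))
  n_tot <- length(vars)
  coord <- function(ctx, gene) match(paste(ctx, gene, sep = "."), vars)

  omega <- diag(diag_value, n_tot)
  support <- matrix(FALSE, n_tot, n_tot)
  for (ctx in names(grn)) {
    ed <- grn[[ctx]]
    if (is.null(ed) || nrow(ed) == 0) next
    w <- if (is.null(ed$weight)) rep(-0.25, nrow(ed)) else ed$weight
    for (r in seq_len(nrow(ed))) {
      if (!(ed$gene_a[r] %in% panel) || !(ed$gene_b[r] %in% panel)) {
        stop("GRN edge references a gene outside the panel", call. = FALSE)
      }
      i <- coord(ctx, ed$gene_a[r]); j <- coord(ctx, ed$gene_b[r])
      omega[i, j] <- omega[i, j] + w[r]
      omega[j, i] <- omega[i, j]
      support[i, j] <- support[j, i] <- TRUE
    }
  }
  if (lambda > 0 && C > 0) {
    for (g in panel) {
      v <- numeric(n_tot)
      v[coord("bulk", g)] <- 1
      for (ct in cell_types) v[coord(ct, g)] <- -fractions[[ct]]
      omega <- omega + 2 * lambda * tcrossprod(v)
      nz <- which(v != 0)
      support[nz, nz] <- TRUE
    }
  }
  diag(support) <- FALSE
  dimnames(omega) <- list(vars, vars)

  # Positive-definiteness repair by diagonal loading.
  loading <- 0
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  attempts <- 0L
  while (ev_min <= 1e-10 && attempts < 30L) {
    attempts <- attempts + 1L
    step <- max(abs(ev_min) * 2, 1e-6) * 2^attempts
    loading <- loading + step
    omega <- omega + diag(step, n_tot)
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  }
  if (ev_min <= 1e-10) {
    stop(sprintf("precision irreparably indefinite (min eigenvalue %.3g)",
                 ev_min), call. = FALSE)
  }
  if (loading > 0) {
    message(sprintf("diagonal loading %.3g applied to reach positive definiteness",
                    loading))
  }
  if (is.null(mu)) mu <- stats::setNames(numeric(n_tot), vars)
  indiv_shift <- NULL
  if (!is.null(genotype)) {
    stopifnot(is.matrix(genotype$z), is.matrix(genotype$beta),
              ncol(genotype$beta) == G)
    shift_bulk <- genotype$z %*% genotype$beta
    indiv_shift <- matrix(0, nrow(shift_bulk), n_tot,
                          dimnames = list(rownames(genotype$z), vars))
    indiv_shift[, coord("bulk", panel)] <- shift_bulk
  }
  structure(list(panel = panel, contexts = contexts, precision = omega,
                 mu = mu, lambda = lambda, fractions = fractions,
                 support = support, loading = loading, vars = vars,
                 indiv_shift = indiv_shift),
            class = "lnctp_model")
}

#' Draw samples from an energy model
#'
#' Exact multivariate-normal sampling via the Cholesky factor of the
#' precision matrix; per-individual genotype mean shifts are added when the
#' model carries them.
#'
#' @param model An `lnctp_model`.
#' @param n Number of individuals to draw.
#' @return An `n` x coordinates matrix (column names `<context>.<gene>`).
#' @export
sample_lnctp <- function(model, n) {
  n <- .check_count(n, "n")
  u <- chol(model$precision)
  z <- matrix(stats::rnorm(n * length(model$vars)), nrow = length(model$vars))
  x <- t(backsolve(u, z)) + matrix(model$mu, n, length(model$vars),
                                   byrow = TRUE)
  colnames(x) <- model$vars
  rownames(x) <- sprintf("ind%04d", seq_len(n))
  if (!is.null(model$indiv_shift)) {
    idx <- rep_len(seq_len(nrow(model$indiv_shift)), n)
    x <- x + model$indiv_shift[idx, , drop = FALSE]
  }
  x
}

#' Fit a reduced energy model from population expression
#'
#' Node-wise ridge pseudolikelihood restricted to the GRN support: each
#' coordinate is regressed (centered, ridge-penalized) on its GRN neighbors
#' within its context; regression coefficients and residual variances are
#' mapped to precision entries (\eqn{\Omega_{jj} = 1/\sigma_j^2},
#' \eqn{\Omega_{jk} = -\beta_{jk}/\sigma_j^2}) and symmetrized by averaging
#' the (j,k)/(k,j) estimates. Entries outside the GRN support are exactly 0.
#' Means are the sample column means. Deterministic given the data.
#'
#' @param values Individuals x coordinates matrix with `<context>.<gene>`
#'   column names (e.g. from [simulate_lnctp_population()]).
#' @param grn Named list of per-context GRN edge data frames (as in
#'   [assemble_lnctp()]).
#' @param ridge Ridge penalty (default 1e-3).
#' @return An `lnctp_model` with the fitted precision.
#' @export
fit_reduced_model <- function(values, grn, ridge = 1e-3) {
  if (ridge < 0) stop("`ridge` must be >= 0", call. = FALSE)
  vars <- colnames(values)
  if (is.null(vars)) stop("`values` must have coordinate column names",
                          call. = FALSE)
  sds <- apply(values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(vars[sds == 0], collapse = ", "), call. = FALSE)
  }
  split_vars <- strsplit(vars, ".", fixed = TRUE)
  ctxs <- vapply(split_vars, `[`, "", 1)
  genes <- vapply(split_vars, function(v) paste(v[-1], collapse = "."), "")
  panel <- unique(genes)
  if (nrow(values) < 2 * length(panel)) {
    warning("fewer than 2 x panel-size individuals; fit may be unstable",
            call. = FALSE)
  }
  n_tot <- length(vars)
  nbr <- vector("list", n_tot)
  for (ctx in names(grn)) {
    ed <- grn[[ctx]]
    if (is.null(ed) || nrow(ed) == 0) next
    for (r in seq_len(nrow(ed))) {
      i <- match(paste(ctx, ed$gene_a[r], sep = "."), vars)
      j <- match(paste(ctx, ed$gene_b[r], sep = "."), vars)
      if (is.na(i) || is.na(j)) next
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  mu <- colMeans(values)
  xc <- sweep(values, 2, mu)
  omega_hat <- matrix(0, n_tot, n_tot, dimnames = list(vars, vars))
  contrib <- matrix(0L, n_tot, n_tot)
  for (j in seq_len(n_tot)) {
    nb <- unique(nbr[[j]])
    y <- xc[, j]
    if (length(nb) == 0) {
      s2 <- mean(y^2)
      omega_hat[j, j] <- omega_hat[j, j] + 1 / s2
      contrib[j, j] <- contrib[j, j] + 1L
      next
    }
    X <- xc[, nb, drop = FALSE]
    beta <- solve(crossprod(X) + diag(ridge, length(nb)), crossprod(X, y))
    res <- y - X %*% beta
    s2 <- mean(res^2)
    omega_hat[j, j] <- omega_hat[j, j] + 1 / s2
    contrib[j, j] <- contrib[j, j] + 1L
    omega_hat[j, nb] <- omega_hat[j, nb] - as.vector(beta) / s2
    contrib[j, nb] <- contrib[j, nb] + 1L
  }
  # Symmetrize by averaging the two node-wise estimates of each entry.
  denom <- contrib + t(contrib)
  omega_sym <- (omega_hat + t(omega_hat)) / pmax(denom, 1L)
  omega_sym[denom == 0] <- 0
  support <- matrix(FALSE, n_tot, n_tot)
  for (j in seq_len(n_tot)) support[j, unique(nbr[[j]])] <- TRUE
  support <- support | t(support)
  off <- !diag(TRUE, n_tot)
  omega_sym[off & !support] <- 0

  cell_types <- setdiff(unique(ctxs), "bulk")
  structure(list(panel = panel, contexts = c("bulk", cell_types),
                 precision = omega_sym, mu = mu, lambda = 0,
                 fractions = NULL, support = support, loading = 0,
                 vars = vars, indiv_shift = NULL, fitted = TRUE),
            class = "lnctp_model")
}

#' In silico perturbation by clamping one coordinate
#'
#' Fixes the expression of one (context, gene) coordinate at `sign * k` and
#' computes the predicted log fold change of every coordinate as expected
#' value before minus after perturbation,
#' \eqn{\Delta = E[x] - E[x \mid x_{c^*,g^*} = \mathrm{sign}\,k]}. The
#' `"closed_form"` estimator conditions the Gaussian exactly (partitioned
#' precision); `"sampling"` runs a Gibbs sampler over the unclamped
#' coordinates and reports a batch-means standard error. When the model
#' carries per-individual genotype shifts, deltas are averaged across
#' individuals.
#'
#' @param model An `lnctp_model`.
#' @param target Coordinate to clamp: either a `"<context>.<gene>"` string
#'   or `c(context, gene)`.
#' @param k Clamp magnitude (> 0, default 2).
#' @param sign Clamp direction, +1 or -1 (default -1, mimicking a knockout
#'   on the Z-scored expression scale).
#' @param estimator `"closed_form"` (default) or `"sampling"`.
#' @param n_samples Gibbs sweeps retained (sampling only, default 2000).
#' @param burn_in Gibbs warm-up sweeps (default 200).
#' @param seed Seed for the sampler.
#' @return A `delta_result`: `delta` (named vector over all coordinates,
#'   before-minus-after), `target`, `clamp_value`, and for the sampling
#'   estimator `se` (batch-means standard errors).
#' @export
lnctp_perturb <- function(model, target, k = 2, sign = -1,
                          estimator = c("closed_form", "sampling"),
                          n_samples = 2000L, burn_in = 200L, seed = 1L) {
  estimator <- match.arg(estimator)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  tgt <- if (length(target) == 2) paste(target, collapse = ".") else target
  j <- match(tgt, model$vars)
  if (is.na(j)) stop("target coordinate not in the model panel", call. = FALSE)
  omega <- model$precision
  if (omega[j, j] <= 0) {
    stop("clamped coordinate has nonpositive marginal precision", call. = FALSE)
  }
  v <- sign * k
  mus <- if (!is.null(model$indiv_shift)) {
    lapply(seq_len(nrow(model$indiv_shift)), function(i) {
      model$mu + model$indiv_shift[i, ]
    })
  } else {
    list(model$mu)
  }
  rest <- setdiff(seq_along(model$vars), j)
  if (estimator == "closed_form") {
    # E[x_rest | x_j = v] = mu_rest - Omega_rr^{-1} Omega_rj (v - mu_j)
    a_vec <- solve(omega[rest, rest, drop = FALSE], omega[rest, j])
    deltas <- vapply(mus, function(mu) {
      d <- numeric(length(model$vars))
      d[rest] <- a_vec * (v - mu[j])
      d[j] <- mu[j] - v
      d
    }, numeric(length(model$vars)))
    delta <- rowMeans(deltas)
    names(delta) <- model$vars
    structure(list(delta = delta, target = tgt, clamp_value = v,
                   estimator = "closed_form"),
              class = "delta_result")
  } else {
    n_samples <- .check_count(n_samples, "n_samples")
    acc <- matrix(0, n_samples, length(model$vars))
    .with_seed(seed, {
      for (mi in seq_along(mus)) {
        mu <- mus[[mi]]
        x <- mu; x[j] <- v
        sd_j <- 1 / sqrt(diag(omega))
        for (sweep_i in seq_len(burn_in + n_samples)) {
          for (jj in rest) {
            cond_mu <- mu[jj] -
              (omega[jj, ] %*% (x - mu) - omega[jj, jj] * (x[jj] - mu[jj])) /
              omega[jj, jj]
            x[jj] <- stats::rnorm(1, cond_mu, sd_j[jj])
          }
          if (sweep_i > burn_in) {
            acc[sweep_i - burn_in, ] <- acc[sweep_i - burn_in, ] +
              x / length(mus)
          }
        }
      }
    })
    mu_bar <- Reduce(`+`, mus) / length(mus)
    post_mean <- colMeans(acc)
    delta <- mu_bar - post_mean
    delta[j] <- mu_bar[j] - v
    names(delta) <- model$vars
    # Batch-means SE over 20 batches to absorb Gibbs autocorrelation.
    n_batch <- 20L
    bsize <- floor(n_samples / n_batch)
    bm <- sapply(seq_len(n_batch), function(b) {
      colMeans(acc[((b - 1) * bsize + 1):(b * bsize), , drop = FALSE])
    })
    se <- apply(bm, 1, stats::sd) / sqrt(n_batch)
    names(se) <- model$vars
    se[j] <- 0
    structure(list(delta = delta, target = tgt, clamp_value = v, se = se,
                   estimator = "sampling"),
              class = "delta_result")
  }
}

#' Apply a set of perturbations and collect the delta matrix
#'
#' @param model An `lnctp_model`.
#' @param targets Character vector of `"<context>.<gene>"` coordinates to
#'   clamp in turn.
#' @param ... Passed to [lnctp_perturb()].
#' @return Perturbations x coordinates matrix of deltas (before minus
#'   after).
#' @export
lnctp_perturb_set <- function(model, targets, ...) {
  rows <- lapply(targets, function(tg) lnctp_perturb(model, tg, ...)$delta)
  out <- do.call(rbind, rows)
  rownames(out) <- targets
  out
}

#' Call in silico convergent genes by sign test
#'
#' For each (context, gene) coordinate, deltas from the perturbation set are
#' restricted to entries with `|delta| >= tau` (small predicted fold changes
#' are noise-suppressed); the retained signs are tested against a fair coin
#' with a two-tailed one-sample sign test,
#' `p = min(1, 2 * pbinom(min(n+, n-), n, 1/2))`. A coordinate is convergent
#' when `p < alpha`. Coordinates whose qualifying count cannot reach `alpha`
#' even with perfect sign agreement (n such that `2 * 0.5^n >= alpha`; fewer
#' than 5 at the default `alpha = 0.1`) are flagged untestable, not
#' non-convergent.
#'
#' @param deltas Perturbations x coordinates delta matrix (from
#'   [lnctp_perturb_set()]); at least 2 perturbations.
#' @param tau Absolute-delta qualification threshold (default 0.3).
#' @param alpha Sign-test significance level (default 0.1).
#' @return Data frame per coordinate: `coordinate`, `n_qualifying`,
#'   `n_positive`, `p_sign`, `testable`, `convergent`, `sign` (majority
#'   sign; 0 on ties).
#' @export
call_insilico_convergent <- function(deltas, tau = 0.3, alpha = 0.1) {
  if (nrow(deltas) < 2) stop("need >= 2 perturbations", call. = FALSE)
  min_n <- ceiling(log2(2 / alpha))
  res <- lapply(colnames(deltas), function(cn) {
    d <- deltas[, cn]
    q <- d[abs(d) >= tau]
    n <- length(q)
    npos <- sum(q > 0)
    p <- if (n > 0) min(1, 2 * stats::pbinom(min(npos, n - npos), n, 0.5)) else NA_real_
    testable <- n >= min_n
    data.frame(coordinate = cn, n_qualifying = n, n_positive = npos,
               p_sign = p, testable = testable,
               convergent = testable && !is.na(p) && p < alpha,
               sign = sign(npos - (n - npos)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overlap statistics between two convergent gene sets
#'
#' Overlap count, two-sided hypergeometric (Fisher) p-value against the
#' model's background universe, and Jaccard index.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Background gene set (e.g. the full model panel).
#' @return List with `overlap`, `p_hyper`, `jaccard`, `n_a`, `n_b`,
#'   `n_universe`.
#' @export
compare_convergent_sets <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("`universe` is empty", call. = FALSE)
  set_a <- intersect(unique(set_a), universe)
  set_b <- intersect(unique(set_b), universe)
  ov <- length(intersect(set_a, set_b))
  un <- length(union(set_a, set_b))
  tab <- matrix(c(ov, length(set_a) - ov, length(set_b) - ov,
                  length(universe) - un), 2, 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(overlap = ov, p_hyper = p,
       jaccard = if (un > 0) ov / un else 0,
       n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe))
}

#' Semantic distance between two sets of enriched terms
#'
#' Term-to-term similarity is the Jaccard index of the terms' leading-edge
#' gene sets, \eqn{s(t_1,t_2) = |G(t_1) \cap G(t_2)| / |G(t_1) \cup G(t_2)|}.
#' All between-set pairwise similarities are compared with the pooled
#' within-set similarities by a one-sided Mann-Whitney rank-sum test for
#' smaller between-set similarity (i.e. larger semantic distance).
#'
#' @param terms_a,terms_b Named lists: term id -> leading-edge gene vector
#'   (each nonempty; typically terms at GSEA BH FDR <= 0.2).
#' @return List with `p` (one-sided rank-sum), `between` and `within`
#'   similarity vectors; `p` is `NA` when either list has < 2 terms.
#' @export
semantic_distance_test <- function(terms_a, terms_b) {
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0) return(0)
    length(intersect(x, y)) / u
  }
  if (any(lengths(terms_a) == 0) || any(lengths(terms_b) == 0)) {
    stop("every term must carry a nonempty leading-edge set", call. = FALSE)
  }
  pair_vals <- function(lst1, lst2, same) {
    vals <- c()
    n1 <- length(lst1); n2 <- length(lst2)
    for (i in seq_len(n1)) {
      jj <- if (same) seq_len(i - 1L) else seq_len(n2)
      for (j in jj) vals <- c(vals, jac(lst1[[i]], lst2[[j]]))
    }
    vals
  }
  between <- pair_vals(terms_a, terms_b, same = FALSE)
  within <- c(pair_vals(terms_a, terms_a, same = TRUE),
              pair_vals(terms_b, terms_b, same = TRUE))
  p <- if (length(terms_a) < 2 || length(terms_b) < 2 || length(within) == 0) {
    NA_real_
  } else {
    stats::wilcox.test(between, within, alternative = "less",
                       exact = FALSE)$p.value
  }
  list(p = p, between = between, within = within)
}
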