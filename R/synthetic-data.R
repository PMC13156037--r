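#' Configuration for a simulated perturbation screen
#'
#' Bundles the knobs of [simulate_perturbation_screen()]: the number of KO
#' perturbations and genes, the cell-type contexts, how many truly convergent
#' genes to plant, the effect-size distribution (log2FC units) of the planted
#' signal, residual noise, and the pseudobulk replicate count per KO from
#' which standard errors derive.
#'
#' @param n_kos Number of KO perturbations.
#' @param n_genes Genes in the universe.
#' @param cell_types Character vector of cell-type labels; the convergent
#'   signal is planted in the FIRST listed cell type (default order puts
#'   mature glutamatergic neurons first, the context where convergence is
#'   strongest in this class of screens).
#' @param n_convergent_true Number of planted convergent genes (<= n_genes).
#' @param effect_size_mean,effect_size_sd Normal distribution of the planted
#'   shared-direction effects, in log2FC units.
#' @param noise_sd Residual noise sd of per-KO log2FC estimates.
#' @param per_ko_n Pseudobulk replicates per KO (>= 2); standard errors are
#'   `noise_sd / sqrt(per_ko_n)` with a mild per-gene lognormal jitter so that
#'   inverse-variance and sample-size weighting are distinguishable.
#' @param seed Integer seed; generators are pure functions of (config, seed).
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_kos = 9L, n_genes = 2000L,
                              cell_types = c("iGLUT_mature", "iNPC",
                                             "iGLUT_immature", "iGABA"),
                              n_convergent_true = 100L,
                              effect_size_mean = 1.0, effect_size_sd = 0.25,
                              noise_sd = 0.5, per_ko_n = 4L, seed = 1L) {
  n_kos <- .check_count(n_kos, "n_kos")
  n_genes <- .check_count(n_genes, "n_genes")
  n_convergent_true <- .check_count(n_convergent_true, "n_convergent_true",
                                    min = 0L)
  per_ko_n <- .check_count(per_ko_n, "per_ko_n", min = 2L)
  if (n_convergent_true > n_genes) {
    stop("n_convergent_true must not exceed n_genes", call. = FALSE)
  }
  if (effect_size_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(n_kos = n_kos, n_genes = n_genes, cell_types = cell_types,
                 n_convergent_true = n_convergent_true,
                 effect_size_mean = effect_size_mean,
                 effect_size_sd = effect_size_sd, noise_sd = noise_sd,
                 per_ko_n = per_ko_n, seed = seed),
            class = "screen_sim_config")
}

#' Simulate a pooled KO perturbation screen with planted convergent genes
#'
#' Emits one DEG summary table per (KO, cell type). In the designated cell
#' type (the first in `config$cell_types`) each planted convergent gene
#' carries one true effect shared by every KO: a random direction times a
#' magnitude drawn once from Normal(`effect_size_mean`, `effect_size_sd`).
#' All other (gene, KO) true effects are zero, so their observed log2 fold
#' changes are independent estimation noise with random signs (a global
#' null). Standard errors are `noise_sd / sqrt(per_ko_n)` jittered by a
#' per-gene lognormal factor (sdlog 0.2); observed log2FC = true effect +
#' Normal(0, se); p-values come from the two-sided normal test of
#' `log2fc / se`.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `tables` (named list of DEG data frames, names
#'   `<ko>.<cell_type>`), and `truth` (data frame `gene_id`, `convergent`,
#'   `sign` for the designated cell type).
#' @export
simulate_perturbation_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  .with_seed(config$seed, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    kos <- sprintf("KO%02d", seq_len(config$n_kos))
    conv_idx <- if (config$n_convergent_true > 0) {
      sample.int(config$n_genes, config$n_convergent_true)
    } else integer(0)
    conv_sign <- integer(config$n_genes)
    conv_sign[conv_idx] <- sample(c(-1L, 1L), length(conv_idx), replace = TRUE)
    truth <- data.frame(gene_id = genes,
                        convergent = seq_len(config$n_genes) %in% conv_idx,
                        sign = conv_sign, stringsAsFactors = FALSE)
    # One shared true effect per planted gene; zero elsewhere (global null).
    true_eff <- numeric(config$n_genes)
    if (length(conv_idx)) {
      true_eff[conv_idx] <- conv_sign[conv_idx] *
        abs(stats::rnorm(length(conv_idx), config$effect_size_mean,
                         config$effect_size_sd))
    }
    tables <- list()
    for (ct_i in seq_along(config$cell_types)) {
      ct <- config$cell_types[ct_i]
      eff <- if (ct_i == 1L) true_eff else numeric(config$n_genes)
      for (ko in kos) {
        se <- config$noise_sd / sqrt(config$per_ko_n) *
          stats::rlnorm(config$n_genes, 0, 0.2)
        se <- pmax(se, 1e-9)
        noisy <- eff + stats::rnorm(config$n_genes, 0, se)
        pv <- .p_from_z(noisy / se)
        tab <- data.frame(ko_id = ko, cell_type = ct, gene_id = genes,
                          log2fc = noisy, se = se, pvalue = pv,
                          n = config$per_ko_n, stringsAsFactors = FALSE)
        tables[[paste(ko, ct, sep = ".")]] <- tab
      }
    }
    list(tables = tables, truth = truth, kos = kos,
         cell_types = config$cell_types)
  })
}

#' Simulate a population expression panel from a GRN-structured Gaussian
#'
#' Draws per-individual expression for a bulk context and `C` cell-type
#' contexts from the multivariate Gaussian defined by a GRN-masked energy
#' model (see [assemble_lnctp()]): cell-type precision blocks carry the GRN
#' edge weights, and a deconvolution penalty of weight `lambda` couples each
#' bulk gene to the cell-fraction-weighted average of its cell-type copies.
#' The generating model is returned alongside the samples for recovery tests.
#'
#' @param panel Character vector of gene ids.
#' @param grn Named list (one element per cell-type context) of edge data
#'   frames with columns `gene_a`, `gene_b` and optional `weight` (precision
#'   off-diagonal; default -0.25).
#' @param n_individuals Number of individuals to draw.
#' @param lambda Deconvolution coupling weight (>= 0).
#' @param fractions Cell-type proportions, summing to 1.
#' @param seed Integer seed.
#' @return List with `values` (individuals x (context, gene) matrix; column
#'   names `<context>.<gene>`), `individuals`, `panel`, `contexts`, and
#'   `model` (the generating `lnctp_model`).
#' @export
simulate_lnctp_population <- function(panel, grn, n_individuals, lambda = 0,
                                      fractions = NULL, seed = 1L) {
  n_individuals <- .check_count(n_individuals, "n_individuals")
  model <- assemble_lnctp(panel, grn, lambda = lambda, fractions = fractions)
  .with_seed(seed, {
    x <- sample_lnctp(model, n_individuals)
    list(values = x,
         individuals = rownames(x),
         panel = panel,
         contexts = model$contexts,
         model = model)
  })
}

#' Simulate a toy rooted ontology with propagated annotations
#'
#' Builds a random rooted DAG of `n_terms` terms (each non-root term gets
#' 1-2 parents among shallower terms, capped at `max_depth`), annotates each
#' gene to a random leaf-ward term, and propagates all annotations to
#' ancestors (true-path rule) so every gene is annotated to the root.
#'
#' @param n_terms Number of terms including the root (>= 1).
#' @param max_depth Maximum term depth (root = 0).
#' @param n_genes Number of genes to annotate.
#' @param namespace Namespace label stored on the ontology (default "BP").
#' @param seed Integer seed.
#' @return An `ontology` object (see [build_ontology()]).
#' @export
simulate_ontology <- function(n_terms, max_depth = 4L, n_genes = 50L,
                              namespace = "BP", seed = 1L) {
  n_terms <- .check_count(n_terms, "n_terms")
  n_genes <- .check_count(n_genes, "n_genes")
  .with_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    depth <- integer(n_terms); depth[1] <- 0L
    parents <- stats::setNames(vector("list", n_terms), terms)
    if (n_terms > 1) {
      for (i in 2:n_terms) {
        elig <- which(depth[seq_len(i - 1)] < max_depth)
        if (length(elig) == 0) elig <- 1L
        np <- min(sample(1:2, 1), length(elig))
        pa <- if (length(elig) == 1) elig else sample(elig, np)
        parents[[i]] <- terms[pa]
        depth[i] <- max(depth[pa]) + 1L
      }
    }
    genes <- sprintf("gene%03d", seq_len(n_genes))
    ann <- stats::setNames(vector("list", n_genes), genes)
    for (g in seq_len(n_genes)) {
      ann[[g]] <- terms[sample.int(n_terms, 1)]
    }
    build_ontology(parents, ann, namespace = namespace)
  })
}

#' Simulate a long-format larval behavior table
#'
#' Generates per-larva measurements of behavioral parameters under a
#' two-factor design (genotype x treatment) with a batch-date random
#' intercept: value = baseline + genotype shift + drug shift + batch
#' intercept + Gaussian residual. Batch intercepts are Normal(0, `batch_sd`);
#' residuals are Normal(0, `resid_sd`).
#'
#' @param n_per_group Larvae per (genotype, treatment) group (>= 3).
#' @param parameters Character vector of behavioral parameter labels
#'   (default: the 24 standard arousal/startle parameters from
#'   [behavior_parameters()]).
#' @param genotype_effects Named per-parameter shifts applied to mutants
#'   (unnamed scalar recycles to all parameters; default 0).
#' @param drug_effects Per-parameter shifts applied under drug treatment of
#'   mutants (same conventions; default 0).
#' @param n_batches Number of experiment dates (default 3).
#' @param batch_sd Sd of the batch random intercept (default 0.5).
#' @param resid_sd Residual sd (default 1).
#' @param seed Integer seed.
#' @return Long data frame with columns `larva_id`, `genotype`
#'   (`control`/`mutant`), `treatment` (`vehicle`/`drug`), `batch_date`,
#'   `parameter`, `value`.
#' @export
simulate_behavior_table <- function(n_per_group = 30L,
                                    parameters = behavior_parameters(),
                                    genotype_effects = 0, drug_effects = 0,
                                    n_batches = 3L, batch_sd = 0.5,
                                    resid_sd = 1, seed = 1L) {
  n_per_group <- .check_count(n_per_group, "n_per_group", min = 3L)
  n_batches <- .check_count(n_batches, "n_batches")
  expand_fx <- function(fx) {
    if (is.null(names(fx))) {
      stats::setNames(rep_len(fx, length(parameters)), parameters)
    } else {
      out <- stats::setNames(rep(0, length(parameters)), parameters)
      out[intersect(names(fx), parameters)] <- fx[intersect(names(fx), parameters)]
      out
    }
  }
  g_fx <- expand_fx(genotype_effects)
  d_fx <- expand_fx(drug_effects)
  .with_seed(seed, {
    groups <- expand.grid(genotype = c("control", "mutant"),
                          treatment = c("vehicle", "drug"),
                          stringsAsFactors = FALSE)
    batch_int <- stats::rnorm(n_batches, 0, batch_sd)
    rows <- list()
    larva <- 0L
    for (gi in seq_len(nrow(groups))) {
      for (rep_i in seq_len(n_per_group)) {
        larva <- larva + 1L
        b <- sample.int(n_batches, 1)
        mu <- rep(0, length(parameters))
        if (groups$genotype[gi] == "mutant") mu <- mu + g_fx
        if (groups$genotype[gi] == "mutant" &&
            groups$treatment[gi] == "drug") mu <- mu + d_fx
        vals <- mu + batch_int[b] + stats::rnorm(length(parameters), 0, resid_sd)
        rows[[larva]] <- data.frame(
          larva_id = sprintf("larva%04d", larva),
          genotype = groups$genotype[gi], treatment = groups$treatment[gi],
          batch_date = sprintf("batch%02d", b),
          parameter = parameters, value = vals, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' The 24 standard larval behavioral parameters
#'
#' Six visual-startle parameters for lights-off and lights-on stimuli plus
#' six sleep/wake parameters for day and night.
#'
#' @return Character vector of 24 labels.
#' @export
behavior_parameters <- function() {
  vsr <- c("startle_intensity", "post_stim_activity", "activity_after_first",
           "stim_vs_post_activity", "first_stim_response", "final_stim_response")
  sw <- c("total_activity", "total_sleep", "waking_activity",
          "rest_bouts", "sleep_length", "sleep_latency")
  c(paste0("vsr_off_", vsr), paste0("vsr_on_", vsr),
    paste0("day_", sw), paste0("night_", sw))
}

#' Simulate gRNA counts across sorted fractions
#'
#' Multinomial sequencing counts for a gRNA library (several guides per gene
#' plus scramble controls) across sample fractions, with optional planted
#' log2 abundance shifts of specific genes in specific fractions.
#'
#' @param genes Character vector of target gene ids.
#' @param grnas_per_gene Guides per gene (default 4).
#' @param scramble_frac Fraction of the library that is scramble controls
#'   (> 0; default 0.1).
#' @param fractions Sample labels (e.g. `c("PE_high", "FITC_high")`).
#' @param depth Reads per sample (default 1e6).
#' @param planted_gene_shifts Named list `fraction -> named numeric vector of
#'   per-gene log2 shifts` applied to that fraction's relative abundances.
#' @param seed Integer seed.
#' @return List with `counts` (data frame `grna_id`, `gene_id`, `scramble`,
#'   `sample_id`, `count`) and `map` (`grna_id`, `gene_id`, `scramble`).
#' @export
simulate_grna_counts <- function(genes, grnas_per_gene = 4L,
                                 scramble_frac = 0.1,
                                 fractions = c("PE_high", "FITC_high"),
                                 depth = 1e6, planted_gene_shifts = list(),
                                 seed = 1L) {
  if (scramble_frac <= 0) stop("`scramble_frac` must be > 0", call. = FALSE)
  grnas_per_gene <- .check_count(grnas_per_gene, "grnas_per_gene")
  .with_seed(seed, {
    g_ids <- unlist(lapply(genes, function(g) {
      sprintf("%s_g%d", g, seq_len(grnas_per_gene))
    }))
    g_gene <- rep(genes, each = grnas_per_gene)
    n_scr <- max(1L, round(scramble_frac * length(g_ids) / (1 - scramble_frac)))
    s_ids <- sprintf("scramble_g%d", seq_len(n_scr))
    map <- data.frame(grna_id = c(g_ids, s_ids),
                      gene_id = c(g_gene, rep(NA_character_, n_scr)),
                      scramble = c(rep(FALSE, length(g_ids)),
                                   rep(TRUE, n_scr)),
                      stringsAsFactors = FALSE)
    base_prop <- stats::rlnorm(nrow(map), 0, 0.3)
    rows <- list()
    for (fr in fractions) {
      prop <- base_prop
      shifts <- planted_gene_shifts[[fr]]
      if (!is.null(shifts)) {
        for (g in names(shifts)) {
          prop[map$gene_id %in% g] <- prop[map$gene_id %in% g] * 2^shifts[[g]]
        }
      }
      prop <- prop / sum(prop)
      cnt <- stats::rmultinom(1, size = depth, prob = prop)[, 1]
      rows[[fr]] <- data.frame(grna_id = map$grna_id, gene_id = map$gene_id,
                               scramble = map$scramble, sample_id = fr,
                               count = cnt, stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         map = map)
  })
}

#' Remove lowly expressed genes from a count matrix
#'
#' A gene is removed when it has fewer than `min_count` reads in at least
#' `min_frac_samples` of the samples, i.e. removal iff
#' `mean(counts < min_count) >= min_frac_samples`. Ties at the threshold
#' fraction remove. Surviving gene order is preserved.
#'
#' @param counts Genes x samples matrix of nonnegative counts (rownames are
#'   gene ids).
#' @param min_count Minimum read count (default 2).
#' @param min_frac_samples Failing-sample fraction at which a gene is dropped
#'   (default 0.90).
#' @return The filtered count matrix; a warning is raised if nothing
#'   survives.
#' @export
filter_low_expression <- function(counts, min_count = 2,
                                  min_frac_samples = 0.90) {
  if (is.null(dim(counts))) stop("`counts` must be a matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  frac_low <- rowMeans(counts < min_count)
  keep <- frac_low < min_frac_samples
  if (!any(keep)) warning("no gene passes the expression filter", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Expression-bin-matched module score
#'
#' Per-sample score of a gene set against expression-matched controls, in the
#' style of cell-cycle scoring: background genes are cut into `n_bins`
#' equal-frequency bins of average expression; for each set gene, `n_ctrl`
#' control genes are drawn (with replacement) from its bin; the score is the
#' mean expression of the set genes minus the mean expression of the pooled
#' control draw, per sample.
#'
#' @param expr Genes x samples expression matrix (rownames are gene ids).
#' @param gene_set Character vector of set genes (must be rows of `expr`).
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @param avg_ref Optional named reference average-expression vector used
#'   for bin matching; defaults to the row means of `expr`. Pass averages
#'   derived from unperturbed control samples to score a perturbation
#'   against its baseline.
#' @return Numeric vector of per-sample scores.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L, avg_ref = NULL) {
  if (length(gene_set) == 0) stop("`gene_set` is empty", call. = FALSE)
  gene_set <- intersect(gene_set, rownames(expr))
  if (length(gene_set) == 0) {
    stop("no gene of `gene_set` is present in `expr`", call. = FALSE)
  }
  avg <- if (is.null(avg_ref)) rowMeans(expr) else avg_ref[rownames(expr)]
  n_bins <- min(n_bins, length(avg))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(expr)
  .with_seed(seed, {
    ctrl <- unlist(lapply(gene_set, function(g) {
      pool <- names(bin)[bin == bin[[g]]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
    set_mean <- colMeans(expr[gene_set, , drop = FALSE])
    ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
    set_mean - ctrl_mean
  })
}
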