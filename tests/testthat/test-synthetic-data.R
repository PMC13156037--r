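test_that("screen generator is deterministic and respects its config", {
  cfg <- screen_sim_config(n_kos = 3, n_genes = 50, n_convergent_true = 5,
                           seed = 12)
  s1 <- simulate_perturbation_screen(cfg)
  s2 <- simulate_perturbation_screen(cfg)
  expect_identical(s1, s2)
  expect_length(s1$tables, 3 * length(cfg$cell_types))
  expect_equal(sum(s1$truth$convergent), 5)
  # planted genes share one effect direction across all KOs in the first
  # cell type
  ct <- cfg$cell_types[1]
  planted <- s1$truth$gene_id[s1$truth$convergent]
  tabs <- s1$tables[grepl(paste0("\\.", ct, "$"), names(s1$tables))]
  signs <- sapply(tabs, function(tb) sign(tb$log2fc[match(planted, tb$gene_id)]))
  truth_sign <- s1$truth$sign[s1$truth$convergent]
  expect_gt(mean(signs == truth_sign), 0.9)
  expect_error(screen_sim_config(n_genes = 10, n_convergent_true = 20),
               "exceed")
})

test_that("null screen config produces near-zero convergent calls", {
  cfg <- screen_sim_config(n_kos = 5, n_genes = 500, n_convergent_true = 0,
                           effect_size_mean = 0, cell_types = "iNPC",
                           seed = 21)
  sim <- simulate_perturbation_screen(cfg)
  called <- call_convergent(meta_analyze(sim$tables))
  expect_lte(nrow(called), 0.01 * cfg$n_genes)
})

test_that("population generator matches its generating Gaussian", {
  panel <- sprintf("g%02d", 1:10)
  # edgeless, lambda 0: independent unit-variance columns
  pop0 <- simulate_lnctp_population(panel, list(bulk = chain_grn(panel)[0, ]),
                                    n_individuals = 500, seed = 4)
  cm <- cor(pop0$values); diag(cm) <- 0
  expect_lt(max(abs(cm)), 3 / sqrt(500))
  expect_equal(unname(apply(pop0$values, 2, sd)), rep(1, 10), tolerance = 0.15)
  # determinism
  pop0b <- simulate_lnctp_population(panel, list(bulk = chain_grn(panel)[0, ]),
                                     n_individuals = 500, seed = 4)
  expect_identical(pop0$values, pop0b$values)
  # chain GRN: sample partial correlations of adjacent genes match the
  # generating precision (brute-force partial correlation via inversion)
  grn <- list(bulk = chain_grn(panel))
  pop <- simulate_lnctp_population(panel, grn, n_individuals = 500, seed = 5)
  omega_emp <- solve(cov(pop$values))
  pc_emp <- -omega_emp / sqrt(tcrossprod(diag(omega_emp)))
  om <- pop$model$precision
  pc_true <- -om / sqrt(tcrossprod(diag(om)))
  adj <- cbind(seq_len(9), seq_len(9) + 1)
  expect_lt(max(abs(pc_emp[adj] - pc_true[adj])), 0.1)
  # sample covariance converges entrywise
  expect_lt(max(abs(cov(pop$values) - solve(om))), 5 / sqrt(500))
})

test_that("ontology generator yields a rooted acyclic DAG with true-path annotations", {
  ont <- simulate_ontology(n_terms = 20, n_genes = 40, seed = 9)
  # topological order exists (no cycle): ancestors never include a term's
  # own descendants; build_ontology would have errored on a cycle
  expect_s3_class(ont, "ontology")
  expect_equal(unname(ont$ic[ont$root]), 0)
  # every gene annotated to the root
  expect_true(all(vapply(ont$annotations, function(ts) ont$root %in% ts,
                         logical(1))))
  # IC monotone along every parent -> child edge
  for (t in ont$terms) {
    for (p in ont$parents[[t]]) {
      if (!is.na(ont$ic[t]) && !is.na(ont$ic[p])) {
        expect_gte(ont$ic[[t]], ont$ic[[p]] - 1e-12)
      }
    }
  }
  # hand-built: root with 2 children each holding half the genes
  ont2 <- build_ontology(list(root = NULL, L = "root", R = "root"),
                         c(setNames(rep(list("L"), 5), paste0("g", 1:5)),
                           setNames(rep(list("R"), 5), paste0("g", 6:10))))
  expect_equal(unname(ont2$ic["L"]), -log(0.5), tolerance = 1e-12)
  # single-term ontology: root annotates everything, IC 0
  ont1 <- build_ontology(list(root = NULL), list(g1 = "root", g2 = "root"))
  expect_equal(unname(ont1$ic["root"]), 0)
})

test_that("behavior generator plants recoverable genotype shifts", {
  tb <- simulate_behavior_table(n_per_group = 10, seed = 3)
  expect_identical(tb, simulate_behavior_table(n_per_group = 10, seed = 3))
  expect_setequal(unique(tb$parameter), behavior_parameters())
  expect_length(behavior_parameters(), 24)
  # null effects: signed scores stay small
  fp <- behavioral_fingerprint(simulate_behavior_table(n_per_group = 30,
                                                       seed = 14))
  expect_lt(median(abs(fp$signed_score)), 1)
  # planted 2-sd shift is detected in most seeds
  hits <- vapply(1:10, function(s) {
    tb2 <- simulate_behavior_table(n_per_group = 30,
                                   genotype_effects = c(day_total_sleep = 2),
                                   seed = s)
    fit_behavior_effect(tb2, "day_total_sleep")$p <= 0.06
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gRNA count generator supports null and planted-shift recovery", {
  genes <- paste0("gene", 1:50)
  sim0 <- simulate_grna_counts(genes, depth = 1e6, seed = 2)
  expect_identical(sim0, simulate_grna_counts(genes, depth = 1e6, seed = 2))
  nn <- normalize_to_scramble(sim0$counts)
  ab <- gene_abundance(nn, sim0$map)
  fc <- fraction_log2fc(ab[, "PE_high"], ab[, "FITC_high"])
  expect_lt(abs(median(fc)), 0.1)
  simp <- simulate_grna_counts(genes, depth = 1e6,
                               planted_gene_shifts = list(PE_high = c(gene1 = 1)),
                               seed = 6)
  abp <- gene_abundance(normalize_to_scramble(simp$counts), simp$map)
  fcp <- fraction_log2fc(abp[, "PE_high"], abp[, "FITC_high"])
  expect_lt(abs(fcp[["gene1"]] - 1), 0.2)
})

test_that("low-expression filter applies the documented boundary rule", {
  cm <- rbind(
    dropme  = c(0, 1, 1, 0, 1, 0, 0, 0, 0, 0),  # <2 in 9/10 = 90% -> removed
    keeper  = rep(5, 10),
    border  = c(2, 2, rep(0, 8))                # <2 in 80% -> retained
  )
  out <- filter_low_expression(cm)
  expect_identical(rownames(out), c("keeper", "border"))
  # ties at exactly 90% remove; order of survivors preserved
  cm2 <- rbind(a = c(rep(0, 9), 5), b = rep(3, 10), c = rep(1, 10))
  expect_identical(rownames(filter_low_expression(cm2)), "b")
  expect_warning(filter_low_expression(rbind(x = rep(0, 10))), "no gene")
})

test_that("module score is centered under the null and recovers a planted shift", {
  set.seed(4)
  em <- matrix(rnorm(2000 * 20, mean = rep(seq(0, 3, length.out = 2000), 20)),
               2000, 20, dimnames = list(paste0("g", 1:2000), NULL))
  gs <- sample(rownames(em), 20)
  s0 <- module_score(em, gs, seed = 2)
  expect_lt(abs(mean(s0)), 0.05)
  expect_identical(s0, module_score(em, gs, seed = 2))
  base_avg <- rowMeans(em)
  em2 <- em; em2[gs, ] <- em2[gs, ] + 1
  s1 <- module_score(em2, gs, seed = 2, avg_ref = base_avg)
  expect_lt(abs(mean(s1) - 1), 0.1)
  expect_error(module_score(em, character(0)), "empty")
})

test_that("TSV round trips preserve the exchange formats", {
  cfg <- screen_sim_config(n_kos = 2, n_genes = 10, n_convergent_true = 2,
                           cell_types = "iGLUT", seed = 1)
  sim <- simulate_perturbation_screen(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_deg_tables(sim$tables, f)
  back <- read_deg_tables(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$log2fc, sim$tables[[1]]$log2fc, tolerance = 1e-12)
  g <- withr::local_tempfile(fileext = ".tsv")
  grn <- list(bulk = chain_grn())
  write_grn(grn, g)
  expect_equal(read_grn(g)$bulk$weight, grn$bulk$weight)
  gmt <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(s1 = c("a", "b"), s2 = c("c", "d", "e"))
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)
})
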