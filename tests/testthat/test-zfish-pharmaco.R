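test_that("behavior effect fitting detects planted shifts and stays calibrated", {
  # planted 2-sd genotype shift
  tb <- simulate_behavior_table(n_per_group = 30,
                                genotype_effects = c(day_total_sleep = 2),
                                seed = 8)
  fit <- fit_behavior_effect(tb, "day_total_sleep")
  expect_equal(fit$beta, 2, tolerance = 0.8)
  expect_lte(fit$p, 0.06)
  expect_equal(fit$method, "lmm")
  # single batch falls back to OLS
  tb1 <- simulate_behavior_table(n_per_group = 10, n_batches = 1, seed = 2)
  expect_equal(fit_behavior_effect(tb1, "day_total_sleep")$method, "ols")
  # balanced large batches leave beta unbiased
  tbb <- simulate_behavior_table(n_per_group = 40, batch_sd = 3,
                                 genotype_effects = c(day_total_sleep = 1),
                                 seed = 5)
  expect_equal(fit_behavior_effect(tbb, "day_total_sleep")$beta, 1,
               tolerance = 0.8)
  expect_error(fit_behavior_effect(tb[tb$genotype == "control", ],
                                   "day_total_sleep"), ">= 3 larvae")
})

test_that("fingerprints flip sign exactly when group labels swap", {
  tb <- simulate_behavior_table(n_per_group = 12,
                                genotype_effects = c(day_total_sleep = 1.5),
                                seed = 4)
  fp <- behavioral_fingerprint(tb)
  swapped <- tb
  swapped$genotype <- ifelse(tb$genotype == "control", "mutant", "control")
  fp_sw <- behavioral_fingerprint(swapped)
  expect_equal(fp$signed_score, -fp_sw$signed_score, tolerance = 1e-8)
  expect_equal(nrow(fp), 24)
})

test_that("mutant clustering recovers planted fingerprint groups", {
  set.seed(9)
  protos <- matrix(rnorm(4 * 24, sd = 3), 4, 24)
  fps <- do.call(rbind, lapply(1:4, function(g) {
    t(sapply(1:5, function(i) protos[g, ] + rnorm(24, sd = 0.5)))
  }))
  rownames(fps) <- paste0("mut", 1:20)
  colnames(fps) <- behavior_parameters()
  cl <- cluster_mutants(fps, k = 4)
  truth <- rep(1:4, each = 5)
  # adjusted Rand of the cut against the planted grouping
  tab <- table(cl$groups, truth)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2)); n <- sum(tab)
  ari <- (a - b * cc / choose(n, 2)) /
    ((b + cc) / 2 - b * cc / choose(n, 2))
  expect_gte(ari, 0.9)
  expect_equal(diag(cl$correlation), setNames(rep(1, 20), rownames(fps)))
  # negated fingerprints correlate at -1
  two <- rbind(m1 = protos[1, ], m2 = -protos[1, ])
  expect_equal(cluster_mutants(two)$correlation["m1", "m2"], -1,
               tolerance = 1e-12)
})

test_that("drug matching applies the stated correlation and p thresholds", {
  set.seed(3)
  mut <- setNames(rnorm(24, sd = 2), behavior_parameters())
  drugs <- list(anti = -mut,
                corr = mut + rnorm(24, sd = 0.5),
                null = rnorm(24))
  names(drugs$anti) <- names(drugs$corr) <- names(drugs$null) <-
    behavior_parameters()
  res <- match_drugs(mut, drugs)
  expect_equal(res$match[res$drug == "anti"], "anti-correlate")
  expect_equal(res$r[res$drug == "anti"], -1, tolerance = 1e-12)
  expect_equal(res$match[res$drug == "corr"], "correlate")
  expect_equal(res$match[res$drug == "null"], "none")
  # r above threshold but p large, and r below threshold with small p: no
  # match either way
  few <- setNames(mut[1:4], behavior_parameters()[1:4])
  mixed <- match_drugs(few, list(d = setNames(c(few[1:2], -few[3:4]),
                                              names(few))))
  expect_equal(mixed$match, "none")
  # < 3 shared parameters: missing
  short <- match_drugs(setNames(1:2, c("p1", "p2")),
                       list(d = setNames(1:2, c("p1", "p2"))))
  expect_true(is.na(short$r))
})

test_that("CMap query scores reversers by the WTCS/NCS/FDR rules", {
  set.seed(13)
  genes <- paste0("g", 1:100)
  up <- genes[1:10]; dn <- genes[91:100]
  mk_sig <- function(id, grp, null_flag, reverse = FALSE, match = FALSE,
                     flat = FALSE) {
    sc <- rnorm(100)
    if (reverse) { sc[1:10] <- -10 - runif(10); sc[91:100] <- 10 + runif(10) }
    if (match) { sc[1:10] <- 10 + runif(10); sc[91:100] <- -10 - runif(10) }
    # both query sets at the top of the ranking: wtcs forced to 0
    if (flat) { sc[c(1:10, 91:100)] <- 10 + runif(20) }
    data.frame(signature_id = id, group_id = grp, gene = genes, score = sc,
               null_flag = null_flag)
  }
  nulls <- do.call(rbind, lapply(1:10, function(i) {
    mk_sig(paste0("n", i), "vehicle", TRUE, flat = TRUE)
  }))
  sigs <- rbind(mk_sig("rev", "drugA", FALSE, reverse = TRUE),
                mk_sig("fwd", "drugA", FALSE, match = TRUE),
                mk_sig("bland", "drugA", FALSE),
                nulls)
  res <- cmap_query(up, dn, sigs)
  rev_row <- res[res$signature_id == "rev", ]
  fwd_row <- res[res$signature_id == "fwd", ]
  expect_lt(rev_row$wtcs, -0.9)     # near-maximal reversal
  expect_gt(fwd_row$wtcs, 0.9)      # near-maximal match
  expect_true(rev_row$reverser)
  expect_false(fwd_row$reverser)
  expect_lte(rev_row$fdr, 0.05)
  # NCS invariant to positive rescaling of wtcs within a group: scaling all
  # scores cannot change the sign pattern, check the normalization directly
  neg <- res$wtcs[res$group_id == "drugA" & res$wtcs < 0]
  expect_equal(rev_row$ncs, rev_row$wtcs / mean(abs(neg)), tolerance = 1e-12)
})

test_that("wtcs is zero when both enrichment scores share a sign", {
  genes <- paste0("g", 1:50)
  # both query sets at the top: ES_up and ES_down both positive
  sigs <- data.frame(signature_id = "s", group_id = "g", gene = genes,
                     score = 50:1, null_flag = FALSE)
  res <- cmap_query(genes[1:5], genes[6:10], sigs)
  expect_equal(res$wtcs, 0)
})

test_that("rescue classification matches the truth-table oracle on the full grid", {
  ps <- c(0.001, 0.05, 0.059, 0.06, 0.5)
  betas <- c(-2, -1, -0.5, 0.5, 1, 2)
  for (mp in ps) for (dp in ps) for (mb in betas) for (db in betas) {
    got <- classify_rescue(list(beta = mb, p = mp),
                           list(beta = db, p = dp))$category
    expect_identical(got, rescue_oracle(mb, mp, db, dp),
                     info = sprintf("mp=%g dp=%g mb=%g db=%g", mp, dp, mb, db))
  }
  # spec'd canonical cases
  expect_equal(classify_rescue(list(beta = 2, p = 0.01),
                               list(beta = 0.5, p = 0.5))$category, "rescued")
  expect_equal(classify_rescue(list(beta = 2, p = 0.01),
                               list(beta = -2, p = 0.01))$category,
               "over_corrected")
  expect_equal(classify_rescue(list(beta = 2, p = 0.01),
                               list(beta = 1, p = 0.03))$category,
               "partial_rescue")
  # missing drug fit leaves the parameter uncalled
  expect_true(is.na(classify_rescue(list(beta = 2, p = 0.01),
                                    list(beta = NA, p = NA))$category))
})
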