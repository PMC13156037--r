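test_that("model assembly honors the GRN mask and deconvolution coupling", {
  panel <- c("gA", "gB", "gC")
  empty <- data.frame(gene_a = character(0), gene_b = character(0))
  # lambda 0, empty GRNs: diagonal precision, conditionals equal marginals
  m0 <- assemble_lnctp(panel, list(bulk = empty))
  expect_equal(m0$precision, diag(1, 3, 3), ignore_attr = TRUE)
  d0 <- lnctp_perturb(m0, "bulk.gA", k = 2, sign = -1)
  expect_equal(unname(d0$delta[c("bulk.gB", "bulk.gC")]), c(0, 0))
  # off-support entries are exactly zero
  grn <- list(bulk = data.frame(gene_a = "gA", gene_b = "gB", weight = -0.3))
  m1 <- assemble_lnctp(panel, grn)
  expect_identical(m1$precision["bulk.gA", "bulk.gC"], 0)
  expect_identical(m1$precision["bulk.gB", "bulk.gC"], 0)
  expect_equal(m1$precision["bulk.gA", "bulk.gB"], -0.3)
  # strong lambda couples bulk and cell-type copies in samples
  m2 <- assemble_lnctp(c("gA", "gB"),
                       list(bulk = empty, neuron = empty),
                       lambda = 10, fractions = c(neuron = 1))
  set.seed(2)
  s <- sample_lnctp(m2, 500)
  expect_gt(cor(s[, "bulk.gA"], s[, "neuron.gA"]), 0.9)
  # invalid fractions rejected
  expect_error(assemble_lnctp(panel, list(bulk = empty, neuron = empty),
                              fractions = c(neuron = 0.5)), "sum to 1")
})

test_that("clamped conditioning matches the hand-derived Gaussian conditional", {
  # 2-gene model with precision [[2,-1],[-1,2]], clamp gene2 at -2
  mod <- assemble_lnctp(c("gA", "gB"),
                        list(bulk = data.frame(gene_a = "gA", gene_b = "gB",
                                               weight = -1)),
                        diag_value = 2)
  d <- lnctp_perturb(mod, "bulk.gB", k = 2, sign = -1)
  expect_equal(unname(d$delta["bulk.gA"]), 1, tolerance = 1e-12)
  # clamped coordinate: delta = baseline mean - sign*k exactly
  expect_equal(unname(d$delta["bulk.gB"]), 2, tolerance = 1e-15)
  dpos <- lnctp_perturb(mod, "bulk.gB", k = 2, sign = 1)
  expect_equal(unname(dpos$delta["bulk.gB"]), -2, tolerance = 1e-15)
  expect_error(lnctp_perturb(mod, "bulk.zz"), "not in the model")
})

test_that("Gibbs sampling estimator agrees with the closed form within 3 SE", {
  panel <- sprintf("g%02d", 1:10)
  grn <- list(bulk = chain_grn(panel))
  mod <- assemble_lnctp(panel, grn)
  cf <- lnctp_perturb(mod, "bulk.g05", k = 2, sign = -1)
  mc <- lnctp_perturb(mod, "bulk.g05", k = 2, sign = -1,
                      estimator = "sampling", n_samples = 2000, seed = 7)
  rest <- setdiff(mod$vars, "bulk.g05")
  z <- abs(mc$delta[rest] - cf$delta[rest]) / pmax(mc$se[rest], 1e-12)
  expect_lt(max(z), 3)
  expect_equal(unname(mc$delta["bulk.g05"]), 2, tolerance = 1e-12)
})

test_that("stronger deconvolution weight ties bulk to cell-type expression monotonely", {
  empty <- data.frame(gene_a = character(0), gene_b = character(0))
  disc <- vapply(c(0.1, 1, 10, 100), function(lam) {
    m <- assemble_lnctp("gA", list(bulk = empty, neuron = empty),
                        lambda = lam, fractions = c(neuron = 1))
    set.seed(5)
    s <- sample_lnctp(m, 400)
    mean((s[, "bulk.gA"] - s[, "neuron.gA"])^2)
  }, numeric(1))
  expect_true(all(diff(disc) < 0))
})

test_that("reduced-model fitting recovers a known chain precision on GRN support", {
  panel <- sprintf("g%02d", 1:10)
  grn <- list(bulk = chain_grn(panel))
  rs <- vapply(1:5, function(s) {
    pop <- simulate_lnctp_population(panel, grn, n_individuals = 500, seed = s)
    fit <- fit_reduced_model(pop$values, grn)
    om <- pop$model$precision
    od <- which(upper.tri(om) & pop$model$support)
    cor(om[od], fit$precision[od])
  }, numeric(1))
  expect_gte(mean(rs), 0.9)
  # support exactness and self-consistency
  pop <- simulate_lnctp_population(panel, grn, n_individuals = 600, seed = 31)
  fit <- fit_reduced_model(pop$values, grn)
  off_support <- upper.tri(fit$precision) & !pop$model$support
  expect_true(all(fit$precision[off_support] == 0))
  # data regenerated from the fit reproduces it within 10% (scaled)
  set.seed(1)
  x2 <- sample_lnctp(fit, 4000)
  fit2 <- fit_reduced_model(x2, grn)
  od <- which(upper.tri(fit$precision) & pop$model$support)
  expect_lt(max(abs(fit2$precision[od] - fit$precision[od]) /
                  pmax(abs(fit$precision[od]), 0.3)), 0.1)
  expect_error(fit_reduced_model(cbind(bulk.gA = rep(1, 10)), grn),
               "zero-variance")
})

test_that("sign-test convergence calling matches binomial enumeration for n <= 12", {
  for (n in 2:12) {
    for (npos in 0:n) {
      deltas <- matrix(0, nrow = max(n, 2), ncol = 1,
                       dimnames = list(NULL, "bulk.g1"))
      deltas[seq_len(n), 1] <- c(rep(1, npos), rep(-1, n - npos))
      if (n < nrow(deltas)) deltas[(n + 1):nrow(deltas), 1] <- 0  # below tau
      res <- call_insilico_convergent(deltas, tau = 0.3, alpha = 0.1)
      expect_equal(res$p_sign, sign_test_oracle(npos, n), tolerance = 1e-12)
      expect_equal(res$n_qualifying, n)
    }
  }
  # alpha = 0.1 consequence: >= 5 consistent perturbations required
  d4 <- matrix(rep(1, 4), 4, 1, dimnames = list(NULL, "c.g"))
  expect_false(call_insilico_convergent(d4)$convergent)
  expect_false(call_insilico_convergent(d4)$testable)
  d5 <- matrix(rep(1, 5), 5, 1, dimnames = list(NULL, "c.g"))
  r5 <- call_insilico_convergent(d5)
  expect_true(r5$convergent)
  expect_equal(r5$p_sign, 0.0625, tolerance = 1e-12)
  # 3 up / 3 down: capped two-tailed p of 1, not convergent
  d6 <- matrix(c(1, 1, 1, -1, -1, -1), 6, 1, dimnames = list(NULL, "c.g"))
  r6 <- call_insilico_convergent(d6)
  expect_equal(r6$p_sign, 1)
  expect_false(r6$convergent)
  # tau filter drops sub-threshold deltas
  dm <- matrix(c(rep(0.5, 5), rep(0.29, 5)), 5, 2,
               dimnames = list(NULL, c("c.a", "c.b")))
  rr <- call_insilico_convergent(dm, tau = 0.3)
  expect_equal(rr$n_qualifying, c(5, 0))
})

test_that("convergent-set comparison reports overlap, Fisher p and Jaccard", {
  uni <- paste0("g", 1:20)
  a <- uni[1:5]; b <- uni[4:8]
  res <- compare_convergent_sets(a, b, uni)
  expect_equal(res$overlap, 2)
  expect_equal(res$jaccard, 2 / 8)
  expect_equal(res$p_hyper,
               fisher.test(matrix(c(2, 3, 3, 12), 2, 2))$p.value,
               tolerance = 1e-12)
  expect_equal(compare_convergent_sets(a, a, uni)$jaccard, 1)
  e <- compare_convergent_sets(character(0), a, uni)
  expect_equal(e$overlap, 0)
  expect_equal(e$jaccard, 0)
  expect_error(compare_convergent_sets(a, b, character(0)), "empty")
})

test_that("semantic distance test separates constructed term geometries", {
  # identical leading edges everywhere: no separation, p near 1
  same <- list(t1 = letters[1:5], t2 = letters[1:5])
  r0 <- semantic_distance_test(same, same)
  expect_gt(r0$p, 0.5)
  # within-set similar (sharing 4/5), between-set disjoint
  ta <- list(a1 = letters[1:5], a2 = letters[2:6], a3 = letters[1:4])
  tb <- list(b1 = LETTERS[1:5], b2 = LETTERS[2:6], b3 = LETTERS[1:4])
  r1 <- semantic_distance_test(ta, tb)
  expect_lt(r1$p, 0.01)
  expect_true(all(r1$between == 0))
  # Jaccard hand value via the between vector
  r2 <- semantic_distance_test(list(x = c("a", "b", "c")),
                               list(y = c("b", "c", "d")))
  expect_equal(r2$between, 0.5)
  expect_true(is.na(r2$p))   # < 2 terms per list
  expect_error(semantic_distance_test(list(x = character(0)), ta), "nonempty")
})
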