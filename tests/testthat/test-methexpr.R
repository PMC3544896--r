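test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_pairs(1:8, (1:8)^3)$spearman_r, 1)
  expect_equal(spearman_pairs(1:8, -(1:8))$spearman_r, -1)
  # ties: midrank oracle computed by hand-ranking
  x <- c(1, 2, 2, 3, 5, 6, 7, 8)
  y <- c(1, 1, 2, 3, 4, 6, 5, 8)
  rx <- c(1, 2.5, 2.5, 4, 5, 6, 7, 8)
  ry <- c(1.5, 1.5, 3, 4, 5, 7, 6, 8)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_pairs(x, y)$spearman_r, oracle, tolerance = 1e-12)
  # identity: Spearman is Pearson on midranks
  set.seed(83)
  a <- sample(20); b <- rnorm(20)
  expect_equal(spearman_pairs(a, b)$spearman_r, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_equal(spearman_pairs(a, b)$spearman_r,
               cor(a, b, method = "spearman"), tolerance = 1e-12)
})

test_that("small-sample Spearman p-values are exact and deterministic", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  out <- spearman_pairs(x, y)
  expect_equal(out$method, "exact_permutation")
  expect_identical(out$p_value, spearman_pairs(x, y)$p_value)
  # oracle: enumerate all 6! rank permutations directly
  perms <- hapmeth:::permutations_of(6)
  rs_all <- apply(perms, 1, function(pp) cor(x, y[pp]))
  p_oracle <- mean(abs(rs_all) >= abs(out$spearman_r) - 1e-12)
  expect_equal(out$p_value, p_oracle, tolerance = 1e-12)
  # degenerate ranks are reported, not guessed
  expect_equal(spearman_pairs(c(1, 1, 1, 1), c(1, 2, 3, 4))$method,
               "undefined")
})

test_that("integration table covers every requested pair", {
  set.seed(89)
  e <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("E1", "E2", "E3"), sprintf("s%02d", 1:10)))
  pr <- list(meth = setNames(runif(10), colnames(e)),
             dosage = setNames(sample(0:2, 10, TRUE), colnames(e)))
  out <- integration_correlations(e, pr)
  expect_equal(nrow(out), 6)
  expect_setequal(out$predictor, c("meth", "dosage"))
})

test_that("expression models match the oracle and respect orthogonality", {
  d <- c(a = 0, b = 1, c = 2, d = 0, e = 1, f = 2, g = 1, h = 2)
  e <- matrix(c(5, 4, 3, 5.2, 4.1, 2.9, 4.0, 3.1), 1,
              dimnames = list("E1", names(d)))
  cov <- data.frame(sample = names(d),
                    u_as = c(100, 120, 90, 105, 111, 95, 130, 88),
                    rin = c(8, 8.5, 9, 8.2, 8.8, 9.1, 8.4, 8.9))
  out <- expression_models(e, "E1", d, cov)
  X <- cbind(1, d, log(cov$u_as), cov$rin)
  beta_or <- solve(crossprod(X), crossprod(X, e[1, ]))
  expect_equal(out$beta1, beta_or[2], tolerance = 1e-10)
  # covariates projected orthogonal to the dose: slope equals the simple
  # regression slope
  set.seed(101)
  z1 <- resid(lm(rnorm(8) ~ d))
  z2 <- resid(lm(rnorm(8) ~ d + z1))
  covo <- data.frame(sample = names(d), u_as = exp(z1), rin = z2)
  simple <- cov(e[1, ], d) / var(d)
  outo <- expression_models(e, "E1", d, covo)
  expect_equal(outo$beta1, unname(simple), tolerance = 1e-10)
  # rank deficiency flagged
  covr <- data.frame(sample = names(d), u_as = exp(d), rin = 1)
  expect_equal(expression_models(e, "E1", d, covr)$status, "rank_deficient")
})

test_that("relative expression scales the reference group median to one", {
  d <- setNames(c(2, 2, 2, 1, 0), sprintf("s%d", 1:5))
  e <- matrix(c(2, 4, 6, 8, 10), 1, dimnames = list("E1", names(d)))
  out <- relative_expression(e, d)
  expect_equal(unname(out[1, ]), c(2, 4, 6, 8, 10) / 4)
  expect_equal(median(out[1, 1:5][d == 2]), 1)
  # idempotence
  out2 <- relative_expression(out, d)
  expect_equal(unclass(out2), unclass(out), ignore_attr = TRUE)
  # identical reference values collapse to exactly 1
  e2 <- matrix(rep(3, 5), 1, dimnames = list("E1", names(d)))
  expect_equal(unname(relative_expression(e2, d)[1, d == 2]), c(1, 1, 1))
  expect_error(relative_expression(e, setNames(rep(0, 5), names(d))),
               "empty")
  e3 <- matrix(c(0, 0, 0, 1, 2), 1, dimnames = list("E1", names(d)))
  expect_error(relative_expression(e3, d), "median is 0")
})

test_that("specific-gravity adjustment follows the dilution formula", {
  expect_equal(adjust_specific_gravity(150, 1.020, 1.020), 150)
  expect_equal(adjust_specific_gravity(100, 1.010, 1.020), 200)
  expect_error(adjust_specific_gravity(100, 1.000, 1.020), "undefined")
  expect_error(adjust_specific_gravity(100, 1.010, 0.9), "sg_ref")
  # monotone decreasing in measured specific gravity
  sg <- seq(1.005, 1.035, by = 0.005)
  adj <- adjust_specific_gravity(100, sg, 1.020)
  expect_true(all(diff(adj) < 0))
})

test_that("metabolite percentages always conserve 100%", {
  out <- metabolite_percentages(10, 10, 80)
  expect_equal(c(out$pct_ias, out$pct_mma, out$pct_dma), c(10, 10, 80))
  out0 <- metabolite_percentages(0, 0, 5)
  expect_equal(c(out0$pct_ias, out0$pct_mma, out0$pct_dma), c(0, 0, 100))
  set.seed(97)
  x <- matrix(rexp(300), ncol = 3)
  outr <- metabolite_percentages(x[, 1], x[, 2], x[, 3])
  expect_true(all(abs(outr$pct_ias + outr$pct_mma + outr$pct_dma - 100) <
                    1e-12))
  zero <- metabolite_percentages(0, 0, 0)
  expect_false(zero$valid)
  expect_true(is.na(zero$pct_dma))
  expect_error(metabolite_percentages(-1, 0, 1), "non-negative")
})

test_that("heterozygous CpG assays read half the homozygous signal", {
  expect_equal(het_cpg_signal_ratio(1.0, "CA"), 0.5)
  expect_equal(het_cpg_signal_ratio(1.0, "CC"), 1.0)
  expect_equal(het_cpg_signal_ratio(0, "CA"), 0)
  expect_equal(het_cpg_signal_ratio(0.03, "CC"), 0.03)
  m <- runif(5)
  expect_equal(het_cpg_signal_ratio(m, "CA") / het_cpg_signal_ratio(m, "CC"),
               rep(0.5, 5))
  expect_error(het_cpg_signal_ratio(1.2, "CC"), "\\[0,1\\]")
})

test_that("constructed signals propagate sign through the integration", {
  # dosage -> methylation positive, methylation -> expression negative,
  # hence dosage -> expression negative
  signs <- vapply(1:10, function(s) {
    cfg <- sim_config("argentina", n_null_probes = 5L, missing_rate = 0,
                      effect_table = c(cgS = 0.08),
                      baseline_beta = c(cgS = 0.35),
                      expr_coupling = data.frame(probe_id = "cgS",
                                                 expr_id = "E1",
                                                 rho = -0.5),
                      seed = 2000L + s)
    ch <- generate_cohort(cfg)
    dos <- setNames(ch$truth$copies, ch$truth$sample)
    meth <- generate_methylation(dos, cfg)
    e <- generate_expression(meth$beta, cfg)
    sign(spearman_pairs(dos[colnames(e)], e["E1", ])$spearman_r)
  }, numeric(1))
  expect_lte(mean(signs), -0.8)
})
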