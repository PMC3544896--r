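test_that("dose scan correlations match the closed-form oracle", {
  d <- c(s1 = 0, s2 = 1, s3 = 2, s4 = 0, s5 = 2)
  y <- c(0.10, 0.20, 0.30, 0.10, 0.35)
  m <- tiny_beta(matrix(y, 1), probes = "p1", samples = names(d))
  sc <- dose_scan(m, d)
  r_oracle <- sum((d - mean(d)) * (y - mean(y))) /
    sqrt(sum((d - mean(d))^2) * sum((y - mean(y))^2))
  expect_equal(sc$pearson_r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(sc$p_value, 2 * pt(abs(t_oracle), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(sc$n_used, 5)
  # cross-check against the standard test
  ct <- cor.test(d, y)
  expect_equal(sc$pearson_r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(sc$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("degenerate probes get statuses instead of statistics", {
  d <- c(s1 = 0, s2 = 1, s3 = 2, s4 = 1)
  v <- rbind(p_lin = c(0.1, 0.2, 0.3, 0.2),     # exactly linear
             p_const = c(0.4, 0.4, 0.4, 0.4),
             p_sparse = c(0.1, NA, NA, NA))
  m <- tiny_beta(v, samples = names(d))
  sc <- dose_scan(m, d)
  expect_equal(sc$pearson_r[1], 1, tolerance = 1e-12)
  expect_lt(sc$p_value[1], 1e-12)
  expect_equal(sc$status[2], "zero_variance")
  expect_true(is.na(sc$pearson_r[2]))
  expect_equal(sc$status[3], "insufficient_n")
  expect_error(dose_scan(m, c(zz = 1)), ">= 3 samples")
})

test_that("pairwise-complete handling matches cor on masked data", {
  set.seed(31)
  v <- matrix(runif(60, 0.2, 0.8), 6, 10)
  v[cbind(sample(6, 4, TRUE), sample(10, 4, TRUE))] <- NA
  d <- setNames(sample(0:2, 10, TRUE), sprintf("s%02d", 1:10))
  m <- tiny_beta(v, samples = names(d))
  sc <- dose_scan(m, d)
  for (i in 1:6) {
    ok <- !is.na(v[i, ])
    if (sd(v[i, ok]) > 0 && sd(d[ok]) > 0)
      expect_equal(sc$pearson_r[i], cor(v[i, ok], d[ok]), tolerance = 1e-10)
  }
})

test_that("BH adjustment with explicit m matches the step-up oracle", {
  expect_equal(bh_fdr(0.03, m = 1), 0.03)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))  # step-up fixed point
  p <- c(1e-8, 0.02, 0.03)
  got <- bh_fdr(p, m = 450000)
  # oracle: direct step-up computation
  oracle <- rev(cummin(rev(p * 450000 / 1:3)))
  expect_equal(got, pmin(oracle, 1), tolerance = 1e-15)
  expect_lt(got[1], 0.05)
  expect_equal(got[2:3], c(1, 1))
  # with m = n the procedure is exactly p.adjust's BH
  set.seed(7)
  p2 <- runif(50)
  expect_equal(bh_fdr(p2), p.adjust(p2, "BH"), tolerance = 1e-15)
  # permutation equivariance
  perm <- sample(50)
  expect_equal(bh_fdr(p2[perm]), bh_fdr(p2)[perm], tolerance = 1e-15)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0,1\\]")
  expect_error(bh_fdr(runif(10), m = 5), "m must be")
})

test_that("dose scan on rank-transformed data reproduces Spearman", {
  set.seed(37)
  d <- setNames(sample(0:2, 12, TRUE), sprintf("s%02d", 1:12))
  y <- runif(12)
  m <- tiny_beta(matrix(rank(y) / 12, 1), samples = names(d))
  sc <- dose_scan(m, setNames(rank(d), names(d)))
  expect_equal(sc$pearson_r, cor(y, d, method = "spearman"),
               tolerance = 1e-10)
})

test_that("scan p-values agree with a permutation null on a small fixture", {
  set.seed(41)
  n <- 20
  d <- setNames(sample(0:2, n, TRUE), sprintf("s%02d", 1:n))
  y <- 0.4 + 0.05 * d + rnorm(n, 0, 0.08)
  m <- tiny_beta(matrix(pmin(pmax(y, 0), 1), 1), samples = names(d))
  sc <- dose_scan(m, d)
  r_obs <- abs(sc$pearson_r)
  B <- 20000
  exceed <- 0L
  for (b in seq_len(B))
    if (abs(cor(y, sample(d))) >= r_obs - 1e-12) exceed <- exceed + 1L
  p_perm <- exceed / B
  expect_lt(abs(sc$p_value - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / B) +
              0.005)
})

test_that("uni- and multivariable slopes match the normal-equations oracle", {
  d <- c(a = 0, b = 1, c = 2, d = 0, e = 1, f = 2)
  y <- c(0.30, 0.38, 0.47, 0.28, 0.40, 0.45)
  m <- tiny_beta(matrix(y, 1), samples = names(d))
  cov <- data.frame(sample = names(d), u_as = c(50, 80, 120, 60, 90, 200),
                    age = c(30, 40, 35, 28, 50, 44))
  fm <- fit_dose_models(m, d, cov, covariates = c("ln_u_as", "age"))
  X <- cbind(1, d, log(cov$u_as), cov$age)
  beta_or <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fm$beta_multi, beta_or[2], tolerance = 1e-10)
  Xu <- cbind(1, d)
  expect_equal(fm$beta_uni, solve(crossprod(Xu), crossprod(Xu, y))[2],
               tolerance = 1e-10)
  # p-values agree with lm
  fit <- lm(y ~ d + log(cov$u_as) + cov$age)
  expect_equal(fm$p_multi, summary(fit)$coefficients["d", 4],
               tolerance = 1e-10)
})

test_that("orthogonal covariates leave the dose slope unchanged", {
  d <- c(s1 = 0, s2 = 0, s3 = 1, s4 = 1, s5 = 2, s6 = 2)
  z <- c(1, -1, 1, -1, 1, -1)            # orthogonal to d and to 1? centre it
  z <- z - mean(z)
  y <- 0.3 + 0.05 * d + 0.01 * z
  m <- tiny_beta(matrix(y, 1), samples = names(d))
  cov <- data.frame(sample = names(d), z = z)
  fm <- fit_dose_models(m, d, cov, covariates = "z")
  expect_equal(fm$beta_multi, fm$beta_uni, tolerance = 1e-10)
})

test_that("collinear designs are flagged, not estimated", {
  d <- c(s1 = 0, s2 = 1, s3 = 2, s4 = 0, s5 = 1, s6 = 2)
  cov <- data.frame(sample = names(d), dup = 2 * d)
  m <- tiny_beta(matrix(c(0.2, 0.3, 0.4, 0.25, 0.33, 0.41), 1),
                 samples = names(d))
  fm <- fit_dose_models(m, d, cov, covariates = "dup")
  expect_equal(fm$status, "rank_deficient")
  expect_true(is.na(fm$beta_multi))
})

test_that("Kruskal-Wallis screen matches the direct-formula oracle", {
  cov <- data.frame(sample = sprintf("s%d", 1:6),
                    x = c(1, 2, 3, 4, 5, 6))
  g <- setNames(c(0, 0, 1, 1, 2, 2), cov$sample)
  out <- kw_screen(cov, g)
  # rank sums 3, 7, 11; H = 12/(n(n+1)) * sum(R^2/n_i) - 3(n+1)
  H_oracle <- 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7
  expect_equal(out$H, H_oracle, tolerance = 1e-12)
  expect_equal(out$p_value, pchisq(H_oracle, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # all-tied variable: H = 0, p = 1
  cov$x <- rep(5, 6)
  out2 <- kw_screen(cov, g)
  expect_equal(out2$H, 0)
  expect_equal(out2$p_value, 1)
})

test_that("two-group Kruskal-Wallis agrees with the rank-sum test", {
  set.seed(43)
  cov <- data.frame(sample = sprintf("s%d", 1:14), x = rnorm(14))
  g <- setNames(rep(c(0, 1), 7), cov$sample)
  out <- kw_screen(cov, g)
  wt <- wilcox.test(cov$x[g[cov$sample] == 0], cov$x[g[cov$sample] == 1],
                    exact = FALSE, correct = FALSE)
  expect_equal(out$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("metabolite efficiency regression recovers group gradients", {
  set.seed(47)
  n <- 90
  d <- setNames(sample(0:2, n, TRUE, c(0.09, 0.44, 0.47)),
                sprintf("s%02d", 1:n))
  cov <- data.frame(sample = names(d), u_as = exp(rnorm(n, 5, 1)))
  # null: slope near 0, p not small
  pd0 <- setNames(73 + rnorm(n, 0, 6), names(d))
  g0 <- glm_metabolites(pd0, d, cov)
  expect_lt(abs(g0$slope), 3)
  # monotone medians rising with copies: positive slope
  pd1 <- setNames(73 + 5.2 * d + rnorm(n, 0, 6), names(d))
  g1 <- glm_metabolites(pd1, d, cov)
  expect_gt(g1$slope, 0)
  expect_lt(g1$p_value, 0.01)
  # constant %DMA: slope exactly 0
  g2 <- glm_metabolites(setNames(rep(80, n), names(d)), d, cov)
  expect_identical(g2$slope, 0)
})
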