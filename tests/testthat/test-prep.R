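test_that("imputation leaves complete matrices and observed cells alone", {
  m <- tiny_beta(matrix(runif(20), 5, 4))
  expect_identical(unclass(impute_knn(m, 2)), unclass(m))
  v <- unclass(m); v[2, 3] <- NA
  out <- impute_knn(tiny_beta(v), 2)
  expect_identical(unclass(out)[-2, ], v[-2, ])
  expect_identical(unclass(out)[2, -3], v[2, -3])
  expect_false(anyNA(out))
})

test_that("one missing cell is imputed as the k-nearest-probe mean", {
  # all donor probes identical at the target sample -> imputed value v
  v <- matrix(c(0.90, 0.91, 0.89, 0.32,
                0.30, 0.31, 0.29, 0.70,
                0.30, 0.31, 0.29, 0.70,
                0.30, 0.31, 0.29, NA), 4, 4, byrow = TRUE)
  out <- impute_knn(tiny_beta(v), 2)
  expect_equal(unclass(out)[4, 4], 0.70)
})

test_that("imputed values match a brute-force nearest-probe oracle", {
  set.seed(8)
  v <- matrix(runif(20), 5, 4)
  v[2, 3] <- NA
  out <- impute_knn(tiny_beta(v), k = 2)
  # oracle: exhaustive distances over co-observed samples, fraction-rescaled
  n <- ncol(v)
  d <- sapply(seq_len(5), function(j) {
    if (j == 2) return(Inf)
    co <- which(!is.na(v[2, ]) & !is.na(v[j, ]))
    sqrt(sum((v[2, co] - v[j, co])^2) / (length(co) / n))
  })
  donors <- order(d)[1:2]
  expect_equal(unclass(out)[2, 3], mean(v[donors, 3]))
  # imputed value lies within the donor range
  expect_true(unclass(out)[2, 3] >= min(v[donors, 3]) &&
                unclass(out)[2, 3] <= max(v[donors, 3]))
})

test_that("fully missing probes abort and scarce donors warn", {
  v <- matrix(c(0.1, 0.2, NA, NA), 2, 2, byrow = TRUE)
  expect_error(impute_knn(tiny_beta(v), 2), "fully missing.*p02")
  v2 <- matrix(c(0.1, 0.2, 0.3, NA), 2, 2, byrow = TRUE)
  expect_warning(out <- impute_knn(tiny_beta(v2), k = 5), "only 1 donors")
  expect_equal(unclass(out)[2, 2], 0.2)
})

test_that("SVD screen flags a constructed plate shift on component 1", {
  set.seed(11)
  n <- 20; p <- 60
  plate <- rep(c("P1", "P2"), each = n / 2)
  v <- matrix(runif(p * n, 0.3, 0.7), p, n) +
    0.15 * matrix(plate == "P2", p, n, byrow = TRUE)
  m <- tiny_beta(pmin(v, 1))
  vars <- data.frame(sample = colnames(m), plate = plate,
                     noise = rnorm(n))
  rep_ <- screen_components(m, vars, n_components = 3, alpha = 0.01)
  expect_true(rep_$flagged[rep_$component == 1 & rep_$variable == "plate"])
  # variance fractions are non-increasing and sum to <= 1
  vf <- unique(rep_[, c("component", "variance_fraction")])$variance_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-8)
})

test_that("SVD screen is calibrated on pure noise", {
  # expected flag rate at alpha is alpha; average over seeds
  flags <- 0; total <- 0
  for (s in 1:15) {
    set.seed(400 + s)
    m <- tiny_beta(matrix(runif(40 * 20), 40, 20))
    vars <- data.frame(sample = colnames(m), x = rnorm(20),
                       g = sample(c("a", "b"), 20, TRUE))
    rep_ <- screen_components(m, vars, n_components = 4, alpha = 0.01)
    flags <- flags + sum(rep_$flagged)
    total <- total + nrow(rep_)
  }
  expect_lt(flags / total, 0.05)
})

test_that("degenerate inputs do not break the component screen", {
  one <- runif(30)
  m <- tiny_beta(matrix(one, 30, 6))  # identical samples: zero variance
  vars <- data.frame(sample = colnames(m),
                     plate = rep(c("P1", "P2"), 3), const = 1)
  rep_ <- screen_components(m, vars, n_components = 3)
  expect_true(all(is.na(rep_$p_value)))
  expect_true(all(!rep_$flagged))
})

test_that("screen variance fractions match an eigendecomposition oracle", {
  set.seed(13)
  m <- tiny_beta(matrix(runif(15 * 8), 15, 8))
  rep_ <- screen_components(m, data.frame(sample = colnames(m),
                                          x = rnorm(8)),
                            n_components = 5)
  vf <- rep_$variance_fraction[!duplicated(rep_$component)]
  xc <- unclass(m) - rowMeans(m)
  ev <- eigen(crossprod(xc), symmetric = TRUE)$values
  expect_equal(vf, (ev / sum(ev))[1:5], tolerance = 1e-8)
})

test_that("plate residualization removes the batch signal exactly", {
  set.seed(17)
  p <- 25; n <- 12
  plate <- rep(c("P1", "P2"), each = n / 2)
  v <- matrix(runif(p * n, 0.2, 0.7), p, n) +
    0.1 * matrix(plate == "P2", p, n, byrow = TRUE)
  m <- tiny_beta(pmin(v, 1))
  out <- residualize_batch(m, plate)
  expect_true(isTRUE(attr(out, "adjusted")))
  ind <- as.numeric(plate == "P2")
  r <- apply(unclass(out), 1, function(y) abs(cor(y, ind)))
  expect_true(all(r < 1e-10))
  # per-plate means equal for every probe
  m1 <- rowMeans(unclass(out)[, plate == "P1"])
  m2 <- rowMeans(unclass(out)[, plate == "P2"])
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("single-batch residualization with recentring is the identity", {
  m <- tiny_beta(matrix(runif(12, 0.2, 0.8), 3, 4))
  out <- residualize_batch(m, rep("P1", 4), recentre = TRUE)
  expect_equal(unclass(out), unclass(m), tolerance = 1e-12,
               ignore_attr = "adjusted")
  out2 <- residualize_batch(m, rep("P1", 4), recentre = FALSE)
  expect_equal(rowMeans(out2), rep(0, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("residuals equal the closed-form normal-equations oracle", {
  v <- matrix(c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8,
                0.5, 0.5, 0.6, 0.4, 0.3, 0.4,
                0.1, 0.2, 0.1, 0.9, 0.8, 0.9), 3, 6, byrow = TRUE)
  batch <- rep(c("A", "B"), each = 3)
  m <- tiny_beta(v)
  out <- residualize_batch(m, batch, recentre = FALSE)
  # oracle: residuals of lm(y ~ batch) per probe
  oracle <- t(apply(v, 1, function(y) resid(lm(y ~ factor(batch)))))
  expect_equal(unclass(out), oracle, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a singleton batch level warns and zeroes its residual", {
  v <- matrix(runif(8, 0.2, 0.8), 2, 4)
  batch <- c("A", "A", "A", "B")
  expect_warning(out <- residualize_batch(tiny_beta(v), batch,
                                          recentre = FALSE), "single sample")
  expect_equal(unname(unclass(out)[, 4]), c(0, 0))
})
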