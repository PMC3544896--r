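#' Epigenome-scale allele-dose association scan
#'
#' For every probe, the Pearson correlation between methylation and the
#' haplotype copy number (0-2, continuous) over the samples where both are
#' present, with a two-sided p-value from the t-distribution on
#' `n_used - 2` degrees of freedom. Probes with zero variance (or fewer
#' than 3 usable samples) get a status and are excluded from FDR
#' adjustment.
#'
#' @param m A [beta_matrix()] (missing cells allowed: pairwise-complete).
#' @param d Haplotype dosage: a named numeric vector (see
#'   [dosage_values()]) or a `dosage_vector` data frame.
#' @param fdr_m If non-`NULL`, append an `fdr` column from [bh_fdr()] with
#'   this total-comparison denominator (e.g. 450000 for a 450K array-wide
#'   scan; use `nrow(m)` for the standard procedure).
#' @return Data frame with columns `probe_id`, `n_used`, `pearson_r`,
#'   `p_value`, `status` (`ok`, `zero_variance`, `insufficient_n`) and,
#'   when requested, `fdr`.
#' @export
dose_scan <- function(m, d, fdr_m = NULL) {
  if (inherits(d, "dosage_vector")) d <- dosage_values(d)
  x <- unclass(m)
  shared <- intersect(colnames(x), names(d)[!is.na(d)])
  if (length(shared) < 3)
    stop("need >= 3 samples shared between matrix and dosage")
  x <- x[, shared, drop = FALSE]
  dd <- d[shared]

  obs <- !is.na(x)
  n_used <- rowSums(obs)
  # pairwise-complete moments via masked matrix products
  x0 <- x; x0[!obs] <- 0
  sx <- x0 %*% rep(1, length(dd))
  sxx <- (x0 * x0) %*% rep(1, length(dd))
  sd_ <- obs %*% dd
  sdd <- obs %*% dd^2
  sxd <- x0 %*% dd
  cov_xd <- sxd - sx * sd_ / n_used
  var_x <- sxx - sx^2 / n_used
  var_d <- sdd - sd_^2 / n_used

  status <- rep("ok", nrow(x))
  status[n_used < 3] <- "insufficient_n"
  eps <- 1e-24
  status[status == "ok" & (var_x <= eps | var_d <= eps)] <- "zero_variance"
  ok <- status == "ok"
  r <- rep(NA_real_, nrow(x))
  r[ok] <- pmin(pmax(cov_xd[ok] / sqrt(var_x[ok] * var_d[ok]), -1), 1)
  p <- rep(NA_real_, nrow(x))
  df <- n_used - 2
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tt[ok], df[ok], lower.tail = FALSE)
  p[ok & abs(r) == 1] <- 0

  out <- data.frame(probe_id = rownames(x), n_used = n_used,
                    pearson_r = r, p_value = p, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fdr_m)) {
    out$fdr <- NA_real_
    out$fdr[ok] <- bh_fdr(out$p_value[ok], m = fdr_m)
  }
  out
}

#' Benjamini-Hochberg FDR with an explicit comparison count
#'
#' Step-up adjustment `p_(i) * m / i` with monotonicity enforced by a
#' cumulative minimum from the largest rank, capped at 1, returned in the
#' input order. Unlike `p.adjust(..., "BH")` the denominator `m` may exceed
#' the number of p-values supplied, the convention for an array-wide scan
#' where a fixed total (450,000) is adjusted for regardless of how many
#' probes reached the scan.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @param m Total number of comparisons; must be at least
#'   `length(p_values)`.
#' @return Adjusted values (FDR), same length and order as the input.
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0,1] and non-missing")
  n <- length(p_values)
  if (m < n) stop("m must be >= number of p-values")
  o <- order(p_values)
  ranks <- seq_len(n)
  adj_sorted <- rev(cummin(rev(p_values[o] * m / ranks)))
  pmin(adj_sorted, 1)[order(o)]
}

#' Per-probe univariable and multivariable dose-response models
#'
#' Ordinary least squares of methylation on haplotype copies, probe by
#' probe. The univariable model is `methylation ~ copies`. When
#' `covariates` are named, a multivariable model adds them; the covariate
#' `ln_u_as` is derived as `log(u_as)` when absent (urinary arsenic always
#' enters natural-log transformed). Samples missing any model variable are
#' dropped per probe (complete case); rank-deficient designs flag the
#' probe instead of estimating.
#'
#' @param m A [beta_matrix()].
#' @param d Dosage (named vector or `dosage_vector`).
#' @param cov Covariate data frame with a `sample` column (required when
#'   `covariates` is non-empty).
#' @param covariates Character vector of covariate column names for the
#'   multivariable model; empty for univariable only.
#' @return Data frame with `probe_id`, `n_used`, `beta_uni`, `se_uni`,
#'   `p_uni` and (when covariates are given) `n_multi`, `beta_multi`,
#'   `se_multi`, `p_multi`, plus `status`.
#' @export
fit_dose_models <- function(m, d, cov = NULL, covariates = character()) {
  if (inherits(d, "dosage_vector")) d <- dosage_values(d)
  x <- unclass(m)
  shared <- intersect(colnames(x), names(d)[!is.na(d)])
  if (length(shared) < 3) stop("need >= 3 shared samples")
  x <- x[, shared, drop = FALSE]
  dd <- d[shared]

  # univariable slope, vectorized over probes (pairwise-complete)
  obs <- !is.na(x)
  n_used <- rowSums(obs)
  x0 <- x; x0[!obs] <- 0
  sx <- drop(x0 %*% rep(1, length(dd)))
  sxx <- drop((x0 * x0) %*% rep(1, length(dd)))
  sd_ <- drop(obs %*% dd)
  sdd <- drop(obs %*% dd^2)
  sxd <- drop(x0 %*% dd)
  sxx_c <- sxx - sx^2 / n_used
  sdd_c <- sdd - sd_^2 / n_used
  sxd_c <- sxd - sx * sd_ / n_used
  beta_uni <- sxd_c / sdd_c
  rss <- pmax(sxx_c - beta_uni * sxd_c, 0)
  se_uni <- sqrt(rss / (n_used - 2) / sdd_c)
  t_uni <- beta_uni / se_uni
  p_uni <- 2 * stats::pt(abs(t_uni), n_used - 2, lower.tail = FALSE)
  status <- rep("ok", nrow(x))
  status[n_used < 3] <- "insufficient_n"
  status[status == "ok" & sdd_c <= 1e-24] <- "zero_variance"
  bad <- status != "ok"
  beta_uni[bad] <- se_uni[bad] <- p_uni[bad] <- NA_real_

  out <- data.frame(probe_id = rownames(x), n_used = n_used,
                    beta_uni = beta_uni, se_uni = se_uni, p_uni = p_uni,
                    status = status, stringsAsFactors = FALSE,
                    row.names = NULL)

  if (length(covariates)) {
    if (is.null(cov) || !"sample" %in% names(cov))
      stop("multivariable model needs a covariate table with a sample column")
    cidx <- match(shared, cov$sample)
    if (anyNA(cidx)) stop("covariates missing for sample(s): ",
                          paste(shared[is.na(cidx)], collapse = ", "))
    cv <- cov[cidx, , drop = FALSE]
    if ("ln_u_as" %in% covariates && !"ln_u_as" %in% names(cv)) {
      if (!"u_as" %in% names(cv)) stop("ln_u_as requested but u_as absent")
      if (any(cv$u_as <= 0, na.rm = TRUE))
        stop("u_as must be positive for log transform")
      cv$ln_u_as <- log(cv$u_as)
    }
    missing_cov <- setdiff(covariates, names(cv))
    if (length(missing_cov)) stop("covariate(s) not found: ",
                                  paste(missing_cov, collapse = ", "))
    df <- data.frame(copies = dd, cv[covariates], check.names = FALSE)
    fml <- stats::as.formula(paste("~ copies +",
                                   paste(sprintf("`%s`", covariates),
                                         collapse = " + ")))
    out$n_multi <- NA_integer_
    out$beta_multi <- out$se_multi <- out$p_multi <- NA_real_
    for (i in seq_len(nrow(x))) {
      if (out$status[i] != "ok") next
      y <- x[i, ]
      use <- stats::complete.cases(df) & !is.na(y)
      if (sum(use) < length(covariates) + 3) {
        out$status[i] <- "insufficient_n"
        next
      }
      X <- stats::model.matrix(fml, df[use, , drop = FALSE])
      qr_ <- qr(X)
      if (qr_$rank < ncol(X)) {
        out$status[i] <- "rank_deficient"
        next
      }
      fit <- stats::lm.fit(X, y[use])
      sigma2 <- sum(fit$residuals^2) / fit$df.residual
      xtxi <- chol2inv(qr.R(qr_))
      se <- sqrt(sigma2 * diag(xtxi))
      j <- match("copies", colnames(X))
      out$n_multi[i] <- sum(use)
      out$beta_multi[i] <- fit$coefficients[j]
      out$se_multi[i] <- se[j]
      out$p_multi[i] <- 2 * stats::pt(abs(fit$coefficients[j] / se[j]),
                                      fit$df.residual, lower.tail = FALSE)
    }
  }
  out
}

#' Kruskal-Wallis screen of covariates across copy-number groups
#'
#' Tests every covariate for distributional differences across the
#' haplotype copy-number groups (hard calls 0/1/2) with the Kruskal-Wallis
#' rank test (midrank ties correction); binary and categorical covariates
#' are rank-tested identically after integer coding. A covariate with all
#' values tied yields H = 0, p = 1.
#'
#' @param cov Covariate data frame with a `sample` column.
#' @param d Dosage data frame (`dosage_vector`) or named hard-call vector.
#' @param variables Covariate columns to screen (default: all but
#'   `sample`).
#' @return Data frame with `variable`, `H`, `df`, `p_value`, `n`.
#' @export
kw_screen <- function(cov, d,
                      variables = setdiff(names(cov), "sample")) {
  g <- if (inherits(d, "dosage_vector")) dosage_values(d, hard = TRUE) else d
  idx <- match(cov$sample, names(g))
  grp <- factor(g[idx])
  out <- lapply(variables, function(v) {
    val <- cov[[v]]
    if (!is.numeric(val)) val <- as.integer(factor(val))
    use <- !is.na(val) & !is.na(grp)
    if (length(unique(val[use])) <= 1 || nlevels(droplevels(grp[use])) < 2)
      return(data.frame(variable = v, H = 0, df = NA_integer_, p_value = 1,
                        n = sum(use)))
    kt <- stats::kruskal.test(val[use], droplevels(grp[use]))
    data.frame(variable = v, H = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value,
               n = sum(use))
  })
  do.call(rbind, out)
}

#' Dose-response model for arsenic methylation efficiency
#'
#' OLS of the %DMA urinary metabolite fraction (the standard index of
#' methylation efficiency) on haplotype copies, adjusted for total urinary
#' arsenic (natural-log transformed).
#'
#' @param pct_dma Named numeric vector of per-sample %DMA.
#' @param d Dosage (named vector or `dosage_vector`).
#' @param cov Covariate data frame with `sample` and `u_as` columns.
#' @return One-row data frame: `slope`, `se`, `p_value`, `n`.
#' @export
glm_metabolites <- function(pct_dma, d, cov) {
  if (inherits(d, "dosage_vector")) d <- dosage_values(d)
  shared <- Reduce(intersect, list(names(pct_dma), names(d), cov$sample))
  cv <- cov[match(shared, cov$sample), ]
  df <- data.frame(y = pct_dma[shared], copies = d[shared],
                   ln_u_as = log(cv$u_as))
  df <- df[stats::complete.cases(df), ]
  if (stats::var(df$y) == 0)
    return(data.frame(slope = 0, se = NA_real_, p_value = 1, n = nrow(df)))
  fit <- stats::lm(y ~ copies + ln_u_as, data = df)
  sm <- summary(fit)$coefficients
  data.frame(slope = sm["copies", 1], se = sm["copies", 2],
             p_value = sm["copies", 4], n = nrow(df))
}
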