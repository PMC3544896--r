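#' Spearman rank correlation with deterministic small-sample p-values
#'
#' Midrank Spearman correlation over pairwise-complete observations. The
#' two-sided p-value uses the t-approximation on `n - 2` degrees of
#' freedom; for very small samples (n <= 7) it is computed by exhaustive
#' permutation enumeration instead, which is exact and deterministic even
#' with ties.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row data frame: `spearman_r`, `p_value`, `n`, `method`.
#'   Zero rank variance gives `NA` correlation with `method = "undefined"`.
#' @export
spearman_pairs <- function(x, y) {
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(data.frame(spearman_r = NA_real_, p_value = NA_real_, n = n,
                      method = "undefined", stringsAsFactors = FALSE))
  rs <- stats::cor(rx, ry)
  if (n <= 7) {
    perms <- permutations_of(n)
    obs <- abs(rs)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12)
        cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact_permutation"
  } else {
    tt <- rs * sqrt((n - 2) / pmax(1 - rs^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    if (abs(rs) == 1) p <- 0
    method <- "t_approximation"
  }
  data.frame(spearman_r = rs, p_value = min(p, 1), n = n, method = method,
             stringsAsFactors = FALSE)
}

# all permutations of 1..n as a matrix (n! rows); n is small (<= 7)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(if (pos > 1) sub[, seq_len(pos - 1L), drop = FALSE],
                 n, if (pos < n) sub[, pos:(n - 1L), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman correlations between methylation/dosage and expression
#'
#' Computes [spearman_pairs()] for every requested (predictor, assay)
#' pair, the layout of a methylation-expression integration table.
#'
#' @param e Expression matrix (assays x samples).
#' @param predictors Named list of numeric per-sample vectors (methylation
#'   probe values or a dosage vector), each named by sample.
#' @param assays Assay ids to correlate (default: all rows of `e`).
#' @return Data frame with `predictor`, `assay`, `spearman_r`, `p_value`,
#'   `n`.
#' @export
integration_correlations <- function(e, predictors,
                                     assays = rownames(e)) {
  out <- list()
  for (pn in names(predictors)) {
    p <- predictors[[pn]]
    shared <- intersect(colnames(e), names(p))
    for (a in assays) {
      sp <- spearman_pairs(p[shared], e[a, shared])
      out[[length(out) + 1L]] <- data.frame(
        predictor = pn, assay = a, spearman_r = sp$spearman_r,
        p_value = sp$p_value, n = sp$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Expression regression on dosage or methylation with quality covariates
#'
#' OLS of an expression assay on a predictor (haplotype copies or a
#' methylation level), adjusted for total urinary arsenic (natural-log
#' transformed) and RNA integrity (RIN):
#' `expression ~ predictor + ln(u_as) + rin`. Complete cases only.
#'
#' @param e Expression matrix (assays x samples).
#' @param assay Assay id (row of `e`).
#' @param predictor Named numeric per-sample vector.
#' @param cov Covariate data frame with `sample`, `u_as`, `rin` columns.
#' @return One-row data frame: `beta1`, `se`, `p_value`, `n`, or `status =
#'   "rank_deficient"` with `NA` estimates when the design is collinear.
#' @export
expression_models <- function(e, assay, predictor, cov) {
  shared <- Reduce(intersect,
                   list(colnames(e), names(predictor), cov$sample))
  cv <- cov[match(shared, cov$sample), ]
  if (any(cv$u_as <= 0, na.rm = TRUE)) stop("u_as must be positive")
  df <- data.frame(y = e[assay, shared], pred = predictor[shared],
                   ln_u_as = log(cv$u_as), rin = cv$rin)
  df <- df[stats::complete.cases(df), ]
  X <- stats::model.matrix(~ pred + ln_u_as + rin, df)
  if (qr(X)$rank < ncol(X))
    return(data.frame(beta1 = NA_real_, se = NA_real_, p_value = NA_real_,
                      n = nrow(df), status = "rank_deficient",
                      stringsAsFactors = FALSE))
  fit <- stats::lm(y ~ pred + ln_u_as + rin, data = df)
  sm <- summary(fit)$coefficients
  data.frame(beta1 = sm["pred", 1], se = sm["pred", 2],
             p_value = sm["pred", 4], n = nrow(df), status = "ok",
             stringsAsFactors = FALSE)
}

#' Scale expression relative to a reference copy-number group
#'
#' Divides each assay by the median expression of the samples carrying
#' `reference_copies` of the haplotype, so the reference group's median is
#' exactly 1 (the convention for reporting relative expression against
#' 2-copy carriers). Idempotent: scaling an already-relative matrix leaves
#' it unchanged.
#'
#' @param e Expression matrix (assays x samples).
#' @param d Dosage (`dosage_vector` or named hard-call vector).
#' @param reference_copies Copy-number group defining the reference
#'   (default 2).
#' @return The scaled matrix with attribute `relative = TRUE`.
#' @export
relative_expression <- function(e, d, reference_copies = 2L) {
  g <- if (inherits(d, "dosage_vector")) dosage_values(d, hard = TRUE) else d
  ref <- intersect(colnames(e), names(g)[!is.na(g) & g == reference_copies])
  if (length(ref) == 0) stop("reference copy-number group is empty")
  med <- apply(e[, ref, drop = FALSE], 1, stats::median, na.rm = TRUE)
  if (any(med == 0, na.rm = TRUE))
    stop("reference group median is 0 for assay(s): ",
         paste(rownames(e)[which(med == 0)], collapse = ", "))
  out <- e / med
  attr(out, "relative") <- TRUE
  out
}

#' Adjust a urinary analyte concentration for dilution by specific gravity
#'
#' The standard urinary-dilution correction: concentrations are scaled to
#' a cohort reference specific gravity,
#' `adjusted = u_as * (sg_ref - 1) / (sg - 1)`. Monotone decreasing in the
#' measured specific gravity and the identity when `sg == sg_ref`.
#'
#' @param u_as Concentration(s), e.g. total urinary arsenic in ug/L.
#' @param sg Measured urine specific gravity in g/mL (> 1).
#' @param sg_ref Cohort reference specific gravity in g/mL (> 1), e.g.
#'   1.020 (Andean adults) or 1.012 (Bangladeshi cohort).
#' @return Adjusted concentration(s).
#' @export
adjust_specific_gravity <- function(u_as, sg, sg_ref) {
  if (any(sg_ref <= 1)) stop("sg_ref must exceed 1")
  if (any(sg <= 1, na.rm = TRUE))
    stop("specific gravity <= 1: dilution adjustment undefined")
  u_as * (sg_ref - 1) / (sg - 1)
}

#' Urinary arsenic metabolite percentages
#'
#' Converts inorganic arsenic, MMA and DMA concentrations to percentages
#' of their sum (the total-arsenic exposure marker). The last percentage
#' is taken as the complement so the three sum to exactly 100.
#'
#' @param i_as,mma,dma Non-negative concentrations (ug/L), vectorized.
#' @return Data frame with `total`, `pct_ias`, `pct_mma`, `pct_dma`;
#'   samples with zero total get `NA` percentages and a `valid = FALSE`
#'   flag.
#' @export
metabolite_percentages <- function(i_as, mma, dma) {
  if (any(c(i_as, mma, dma) < 0, na.rm = TRUE))
    stop("metabolite concentrations must be non-negative")
  total <- i_as + mma + dma
  valid <- !is.na(total) & total > 0
  pct_ias <- ifelse(valid, 100 * i_as / total, NA_real_)
  pct_mma <- ifelse(valid, 100 * mma / total, NA_real_)
  pct_dma <- ifelse(valid, 100 - pct_ias - pct_mma, NA_real_)
  data.frame(total = total, pct_ias = pct_ias, pct_mma = pct_mma,
             pct_dma = pct_dma, valid = valid)
}

#' Expected assay signal at a polymorphic CpG site
#'
#' A CpG created by one allele of a SNP is present on both chromosomes of
#' a homozygote (CC) but only one chromosome of a heterozygote (CA), so a
#' population-of-alleles methylation assay reads half the homozygous
#' signal in heterozygotes at equal per-allele methylation:
#' `signal = per_allele_methylation * n_cpg_alleles / 2`.
#'
#' @param per_allele_methylation Methylation fraction of the CpG-bearing
#'   allele(s), in \[0,1\].
#' @param genotype `"CC"` (two CpG-bearing alleles) or `"CA"` (one).
#' @return Expected assay signal (fraction).
#' @export
het_cpg_signal_ratio <- function(per_allele_methylation,
                                 genotype = c("CC", "CA")) {
  genotype <- match.arg(genotype)
  if (any(per_allele_methylation < 0 | per_allele_methylation > 1))
    stop("per-allele methylation must be in [0,1]")
  n_alleles <- if (genotype == "CC") 2 else 1
  per_allele_methylation * n_alleles / 2
}
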