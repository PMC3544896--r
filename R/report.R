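#' Cohort characteristics stratified by haplotype copy number
#'
#' For each covariate: overall median and 5th/95th percentiles (linear
#' interpolation between order statistics), per-copy-group medians (hard
#' calls 0/1/2), and the Kruskal-Wallis p-value across groups. Binary and
#' categorical covariates are summarized as the fraction in the
#' non-reference level.
#'
#' @param cov Covariate data frame with a `sample` column.
#' @param d Dosage (`dosage_vector` or named hard-call vector).
#' @param variables Covariate columns to summarize (default: all but
#'   `sample`).
#' @return Data frame with `variable`, `median`, `p5`, `p95`,
#'   `median_0`, `median_1`, `median_2` (`NA` for an empty group),
#'   `kw_p`.
#' @export
summarize_cohort <- function(cov, d,
                             variables = setdiff(names(cov), "sample")) {
  g <- if (inherits(d, "dosage_vector")) dosage_values(d, hard = TRUE) else d
  grp <- g[match(cov$sample, names(g))]
  kw <- kw_screen(cov, d, variables)
  out <- lapply(variables, function(v) {
    val <- cov[[v]]
    if (!is.numeric(val)) val <- as.numeric(factor(val)) - 1
    q <- stats::quantile(val, c(0.05, 0.5, 0.95), na.rm = TRUE,
                         names = FALSE, type = 7)
    gm <- vapply(0:2, function(cc) {
      vv <- val[!is.na(grp) & grp == cc]
      if (length(vv) == 0) NA_real_ else stats::median(vv, na.rm = TRUE)
    }, numeric(1))
    data.frame(variable = v, median = q[2], p5 = q[1], p95 = q[3],
               median_0 = gm[1], median_1 = gm[2], median_2 = gm[3],
               kw_p = kw$p_value[kw$variable == v],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Table of probes significantly associated with haplotype dosage
#'
#' Joins scan records passing `fdr < alpha` in *either* of the supplied
#' cohorts to the probe annotation and per-probe beta summaries, sorted by
#' decreasing `|r|` in the first cohort. The row count equals the number
#' of qualifying records; nothing is silently dropped.
#'
#' @param records Scan data frame from [dose_scan()] with an `fdr` column
#'   (the first cohort).
#' @param ann A [probe_annotation()] table.
#' @param alpha FDR significance cut-off (default 0.05).
#' @param m Optional [beta_matrix()] for per-probe beta mean/min/max.
#' @param records2 Optional second cohort's scan records; a probe
#'   qualifies when significant in either cohort.
#' @return Data frame with scan statistics, annotation columns and (when
#'   `m` is given) `beta_mean`, `beta_min`, `beta_max`, sorted by `|r|`
#'   descending.
#' @export
top_table <- function(records, ann, alpha = 0.05, m = NULL,
                      records2 = NULL) {
  if (!"fdr" %in% names(records))
    stop("records need an fdr column (run dose_scan with fdr_m)")
  sig <- !is.na(records$fdr) & records$fdr < alpha
  if (!is.null(records2)) {
    sig2 <- records2$probe_id[!is.na(records2$fdr) & records2$fdr < alpha]
    sig <- sig | records$probe_id %in% sig2
  }
  out <- records[sig, , drop = FALSE]
  aidx <- match(out$probe_id, ann$probe_id)
  out <- cbind(out, ann[aidx, c("chromosome", "position", "gene",
                                "island_relation", "enhancer",
                                "snp_distance")])
  if (!is.null(m)) {
    x <- unclass(m)
    midx <- match(out$probe_id, rownames(x))
    out$beta_mean <- rowMeans(x[midx, , drop = FALSE], na.rm = TRUE)
    out$beta_min <- apply(x[midx, , drop = FALSE], 1, min, na.rm = TRUE)
    out$beta_max <- apply(x[midx, , drop = FALSE], 1, max, na.rm = TRUE)
  }
  out <- out[order(-abs(out$pearson_r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
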