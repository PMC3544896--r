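#' Impute missing beta values by k-nearest probes
#'
#' Each missing cell is replaced by the unweighted mean, at that sample, of
#' the `k` nearest probes. Probe-probe distance is Euclidean over the
#' samples observed in both probes, rescaled by the fraction of samples
#' co-observed (so probes with different missingness are comparable):
#' `d = sqrt(sum(diff^2) / frac_co_observed)`. Only probes observed at the
#' target sample can donate; ties in distance are broken by probe order so
#' the result is deterministic. Observed cells are never altered.
#'
#' @param m A [beta_matrix()] (may contain `NA`).
#' @param k Number of donor probes (default 10).
#' @return A [beta_matrix()] with no missing cells.
#' @export
impute_knn <- function(m, k = 10L) {
  stopifnot(k >= 1)
  x <- unclass(m)
  fully_missing <- rownames(x)[rowSums(!is.na(x)) == 0]
  if (length(fully_missing))
    stop("probe(s) fully missing, cannot impute: ",
         paste(fully_missing, collapse = ", "))
  miss_rows <- which(rowSums(is.na(x)) > 0)
  if (length(miss_rows) == 0) return(m)
  n <- ncol(x)
  obs <- !is.na(x)
  for (i in miss_rows) {
    diff2 <- sweep(x, 2, x[i, ])^2           # NA where either is missing
    co <- obs & matrix(obs[i, ], nrow = nrow(x), ncol = n, byrow = TRUE)
    n_co <- rowSums(co)
    ss <- rowSums(diff2, na.rm = TRUE)
    d <- sqrt(ss / (n_co / n))
    d[i] <- Inf
    d[n_co == 0] <- Inf
    ord <- order(d, seq_along(d))
    for (j in which(is.na(x[i, ]))) {
      donors <- ord[obs[ord, j] & is.finite(d[ord])]
      if (length(donors) == 0)
        stop("no donor probe observed at sample ", colnames(x)[j],
             " for probe ", rownames(x)[i])
      if (length(donors) < k)
        warning(sprintf(
          "probe %s sample %s: only %d donors available (k = %d)",
          rownames(x)[i], colnames(x)[j], length(donors), k))
      x[i, j] <- mean(x[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  beta_matrix(x, adjusted = isTRUE(attr(m, "adjusted")))
}

#' Screen principal components against technical and biological variables
#'
#' Singular value decomposition of the probe-centered beta matrix, the
#' standard technical screen for array data: per component, the fraction of
#' variance explained and its association with each supplied variable
#' (Pearson correlation test for quantitative variables, Kruskal-Wallis for
#' categorical/logical ones). Variables associated at `p < alpha` are
#' flagged; a flagged plate/batch variable is the cue to residualize.
#'
#' @param m A [beta_matrix()] without missing values (impute first).
#' @param variables Data frame of per-sample variables; if it has a
#'   `sample` column it is matched to the matrix columns, otherwise rows
#'   must already align with them.
#' @param n_components Number of leading components to screen (default 5).
#' @param alpha Flagging threshold (default 0.01).
#' @return Data frame with columns `component`, `variance_fraction`,
#'   `variable`, `statistic`, `p_value`, `flagged`. Constant variables and
#'   zero-variance components yield `NA` statistics, never an error.
#' @export
screen_components <- function(m, variables, n_components = 5L, alpha = 0.01) {
  x <- unclass(m)
  if (anyNA(x)) stop("matrix has missing values; run impute_knn first")
  if (ncol(x) < 2) stop("need at least 2 samples")
  if ("sample" %in% names(variables)) {
    idx <- match(colnames(x), variables$sample)
    if (anyNA(idx)) stop("variables missing for sample(s): ",
                         paste(colnames(x)[is.na(idx)], collapse = ", "))
    variables <- variables[idx, setdiff(names(variables), "sample"),
                           drop = FALSE]
  }
  xc <- x - rowMeans(x)
  sv <- svd(xc, nu = 0)
  tot <- sum(sv$d^2)
  n_components <- min(n_components, length(sv$d))
  out <- list()
  for (j in seq_len(n_components)) {
    score <- sv$v[, j]
    vf <- if (tot > 0) sv$d[j]^2 / tot else NA_real_
    degenerate <- sv$d[j]^2 <= tot * 1e-12
    for (v in names(variables)) {
      val <- variables[[v]]
      stat <- p <- NA_real_
      if (!degenerate && length(unique(stats::na.omit(val))) > 1) {
        if (is.numeric(val)) {
          ct <- suppressWarnings(stats::cor.test(score, val))
          stat <- unname(ct$estimate); p <- ct$p.value
        } else {
          grp <- factor(val)
          kt <- suppressWarnings(stats::kruskal.test(score, grp))
          stat <- unname(kt$statistic); p <- kt$p.value
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        component = j, variance_fraction = vf, variable = v,
        statistic = stat, p_value = p,
        flagged = !is.na(p) && p < alpha)
    }
  }
  do.call(rbind, out)
}

#' Remove a batch (plate) effect by per-probe residualization
#'
#' For each probe a least-squares fit on the batch indicator (one-way
#' layout) is taken and the residuals become the new values, so every
#' probe's per-batch means are equal afterward and the values are exactly
#' orthogonal to the batch indicator. With `recentre = TRUE` (default) the
#' per-probe grand mean is added back so values stay near the beta scale;
#' `recentre = FALSE` returns raw residuals (the literal procedure).
#' The output carries `adjusted = TRUE` and is exempt from the \[0,1\]
#' range check.
#'
#' @param m A [beta_matrix()].
#' @param batch Per-sample batch labels (length `ncol(m)`).
#' @param recentre Add back the per-probe grand mean (default `TRUE`).
#' @return An adjusted [beta_matrix()].
#' @export
residualize_batch <- function(m, batch, recentre = TRUE) {
  x <- unclass(m)
  if (length(batch) != ncol(x))
    stop("batch must have one label per sample")
  b <- factor(batch)
  singletons <- names(which(table(b) == 1))
  if (length(singletons))
    warning("batch level(s) with a single sample (residual forced to 0): ",
            paste(singletons, collapse = ", "))
  out <- x
  for (lev in levels(b)) {
    cols <- which(b == lev)
    bm <- rowMeans(x[, cols, drop = FALSE], na.rm = TRUE)
    out[, cols] <- x[, cols, drop = FALSE] - bm
  }
  if (recentre) out <- out + rowMeans(x, na.rm = TRUE)
  beta_matrix(out, adjusted = TRUE)
}
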