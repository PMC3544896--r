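#' @title Regional co-methylation profiling
#' @description
#' Sliding windows of consecutive genes are scored by the fraction of
#' between-gene CpG probe pairs whose methylation Pearson correlation
#' exceeds a threshold in absolute value (within-gene pairs are excluded:
#' they are trivially co-methylated). The null distribution of this
#' fraction is obtained by permuting the order of genes along the
#' chromosome while keeping each gene's probes together, which preserves
#' the within-gene correlation structure the statistic deliberately
#' ignores.
#' @name regioncor
NULL

# shared setup: probe correlations collapsed to per-gene-pair hit and
# valid-pair counts, so permutations reuse one correlation matrix
region_setup <- function(m, ann, threshold) {
  x <- unclass(m)
  probes <- intersect(rownames(x), ann$probe_id)
  if (length(probes) == 0) stop("no annotated probes in matrix")
  a <- ann[match(probes, ann$probe_id), ]
  empty_genes <- setdiff(unique(ann$gene[nzchar(ann$gene)]), a$gene)
  if (length(empty_genes))
    message(length(empty_genes), " gene(s) with no probes in the matrix; ",
            "skipped from the ordering")
  gene_pos <- tapply(a$position, a$gene, min)
  gene_order <- names(sort(gene_pos))
  gf <- factor(a$gene, levels = gene_order)
  C <- suppressWarnings(stats::cor(t(x[probes, , drop = FALSE]),
                                   use = "pairwise.complete.obs"))
  hit <- (abs(C) > threshold)      # strict inequality
  valid <- !is.na(C)
  hit[!valid] <- FALSE
  P <- stats::model.matrix(~ gf - 1)
  HIT <- crossprod(P, (hit * 1) %*% P)
  VALID <- crossprod(P, (valid * 1) %*% P)
  list(genes = gene_order, HIT = HIT, VALID = VALID,
       n_probes = as.integer(table(gf)))
}

window_fractions <- function(setup, ord, window) {
  G <- length(setup$genes)
  nw <- G - window + 1L
  dH <- diag(setup$HIT); dV <- diag(setup$VALID)
  frac <- numeric(nw)
  pairs <- numeric(nw)
  for (i in seq_len(nw)) {
    idx <- ord[i:(i + window - 1L)]
    h <- (sum(setup$HIT[idx, idx]) - sum(dH[idx])) / 2
    v <- (sum(setup$VALID[idx, idx]) - sum(dV[idx])) / 2
    pairs[i] <- v
    frac[i] <- if (v > 0) h / v else NA_real_
  }
  list(fraction = frac, n_pairs = pairs)
}

#' Windowed between-gene co-methylation profile
#'
#' Genes are ordered by genomic position and scanned in windows of
#' `window` consecutive genes advancing one gene at a time. Within each
#' window, all probe pairs whose genes differ are evaluated and the
#' fraction with `|r| > threshold` reported.
#'
#' @param m A [beta_matrix()] (preprocessed: imputed and, where indicated,
#'   residualized).
#' @param ann A [probe_annotation()] assigning probes to genes with
#'   positions.
#' @param window Number of consecutive genes per window (default 20).
#' @param threshold Absolute-correlation cut-off (default 0.5, strict).
#' @return Data frame with `window`, `start_gene`, `end_gene`,
#'   `n_between_pairs`, `fraction`. Fewer genes than `window` yields an
#'   empty profile with a warning.
#' @export
window_profile <- function(m, ann, window = 20L, threshold = 0.5) {
  setup <- region_setup(m, ann, threshold)
  G <- length(setup$genes)
  if (G < window) {
    warning("only ", G, " gene(s) present; window is ", window)
    return(data.frame(window = integer(0), start_gene = character(0),
                      end_gene = character(0), n_between_pairs = numeric(0),
                      fraction = numeric(0)))
  }
  wf <- window_fractions(setup, seq_len(G), window)
  nw <- G - window + 1L
  data.frame(window = seq_len(nw),
             start_gene = setup$genes[seq_len(nw)],
             end_gene = setup$genes[seq_len(nw) + window - 1L],
             n_between_pairs = wf$n_pairs,
             fraction = wf$fraction,
             stringsAsFactors = FALSE)
}

#' Permutation null band for the co-methylation profile
#'
#' Each permutation shuffles the order of genes (probes travel with their
#' gene), recomputes every window fraction, and the window fractions from
#' all permutations are pooled into one null distribution whose 2.5th,
#' 50th and 97.5th percentiles form the band. Observed windows above the
#' 97.5th percentile are flagged.
#'
#' @param m,ann,window,threshold As in [window_profile()].
#' @param n_perm Number of permutations (>= 20; quantiles are unstable
#'   below that).
#' @param seed Integer seed for the permutations.
#' @return List with `profile` (the observed [window_profile()] plus
#'   columns `null_q025`, `null_q50`, `null_q975`, `exceeds_null`),
#'   `null_quantiles` (the pooled 2.5/50/97.5 percentiles) and
#'   `null_fractions` (all pooled permuted window fractions).
#' @export
permutation_null <- function(m, ann, window = 20L, threshold = 0.5,
                             n_perm = 100L, seed = 1L) {
  if (n_perm < 20) stop("n_perm must be >= 20 (quantiles unstable)")
  setup <- region_setup(m, ann, threshold)
  G <- length(setup$genes)
  if (G < window) stop("fewer genes (", G, ") than window (", window, ")")
  obs <- window_fractions(setup, seq_len(G), window)
  set.seed(seed)
  pooled <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(G)
    pooled[[b]] <- window_fractions(setup, ord, window)$fraction
  }
  null_frac <- unlist(pooled)
  q <- stats::quantile(null_frac, c(0.025, 0.5, 0.975), na.rm = TRUE,
                       names = FALSE)
  nw <- G - window + 1L
  profile <- data.frame(window = seq_len(nw),
                        start_gene = setup$genes[seq_len(nw)],
                        end_gene = setup$genes[seq_len(nw) + window - 1L],
                        n_between_pairs = obs$n_pairs,
                        fraction = obs$fraction,
                        null_q025 = q[1], null_q50 = q[2], null_q975 = q[3],
                        exceeds_null = obs$fraction > q[3],
                        stringsAsFactors = FALSE)
  list(profile = profile,
       null_quantiles = stats::setNames(q, c("q025", "q50", "q975")),
       null_fractions = null_frac)
}
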