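#' Default haplotype panel
#'
#' The eight-SNP panel (5' to 3') tagging the efficient arsenic-metabolism
#' haplotype on 10q24, with its target alleles: rs7085104 G, rs3740400 C,
#' rs3740393 C, rs3740390 A, rs11191439 T, rs11191453 C, rs10748835 A,
#' rs1046778 C.
#'
#' @param snp_ids SNP identifiers, 5' to 3'.
#' @param target_alleles One target allele per SNP.
#' @param other_alleles The alternative allele per SNP (used by the
#'   generator for non-target haplotypes).
#' @return A list of class `"haplotype_panel"`.
#' @export
haplotype_panel <- function(
    snp_ids = c("rs7085104", "rs3740400", "rs3740393", "rs3740390",
                "rs11191439", "rs11191453", "rs10748835", "rs1046778"),
    target_alleles = c("G", "C", "C", "A", "T", "C", "A", "C"),
    other_alleles = c("A", "A", "G", "G", "C", "T", "G", "T")) {
  n <- length(snp_ids)
  if (n < 1 || n > 12) stop("panel must hold 1-12 SNPs")
  if (length(target_alleles) != n || length(other_alleles) != n)
    stop("one target and one other allele per SNP required")
  if (any(target_alleles == other_alleles))
    stop("target and other allele must differ at every SNP")
  structure(list(snp_ids = snp_ids,
                 target_alleles = stats::setNames(target_alleles, snp_ids),
                 other_alleles = stats::setNames(other_alleles, snp_ids)),
            class = "haplotype_panel")
}

# Table of per-copy methylation shifts used as the default signal set:
# twelve CpG probes in the 10q24 region with their observed per-copy slopes
# and cohort-mean beta levels. Baselines are the zero-copy means implied by
# the slope and the overall mean at haplotype frequency 0.69 (mean dosage
# 1.38), clamped to [0.02, 0.98].
default_effect_probes <- function() {
  slopes <- c(cg03493300 = 0.080, cg09803321 = 0.070, cg11667387 = -0.33,
              cg00035347 = -0.066, cg23093090 = -0.036, cg18534077 = 0.035,
              cg18367433 = -0.042, cg07119830 = -0.061, cg15744005 = -0.050,
              cg23175074 = -0.021, cg00894378 = 0.027, cg08772003 = -0.032)
  means <- c(cg03493300 = 0.46, cg09803321 = 0.65, cg11667387 = 0.71,
             cg00035347 = 0.58, cg23093090 = 0.82, cg18534077 = 0.79,
             cg18367433 = 0.79, cg07119830 = 0.31, cg15744005 = 0.31,
             cg23175074 = 0.15, cg00894378 = 0.64, cg08772003 = 0.45)
  baseline <- pmin(pmax(means - slopes * 1.38, 0.02), 0.98)
  list(effect = slopes, baseline = baseline)
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-cohort generator. The defaults emulate
#' the Andean adult cohort: n = 94 individuals, target haplotype frequency
#' 0.69 under Hardy-Weinberg equilibrium, twelve signal probes carrying the
#' observed per-copy beta shifts (magnitudes 0.021-0.33) on top of null
#' probes, beta-scale Gaussian noise (SD 0.05), 0.1% missing cells, a
#' single analysis plate, and urinary-arsenic/age/BMI/coca-use covariates
#' matching the published medians. `cohort = "bangladesh"` switches to the
#' cord-blood structure: n = 127, frequency 0.17, two plates with a batch
#' shift, sex of child instead of coca use.
#'
#' @param cohort `"argentina"` or `"bangladesh"` preset, or `"custom"`.
#' @param n_individuals Cohort size.
#' @param hap_freq Target haplotype frequency in \[0,1\].
#' @param panel A [haplotype_panel()].
#' @param effect_table Named numeric: per-copy beta shift per signal probe.
#' @param baseline_beta Named numeric: zero-copy mean beta per signal probe.
#' @param noise_sd Beta-scale Gaussian noise SD.
#' @param n_null_probes Number of no-effect probes.
#' @param missing_rate Fraction of beta cells set missing, in \[0,1).
#' @param n_plates Number of analysis plates.
#' @param plate_shift Additive beta shift applied to plates 2..n_plates.
#' @param off_target_freq Per-SNP probability that a non-target haplotype
#'   carries the target allele (imperfect off-haplotype LD).
#' @param expr_coupling Data frame (`probe_id`, `expr_id`, `rho`) of target
#'   Spearman correlations between methylation probes and expression assays;
#'   `abs(rho) < 1`.
#' @param n_genes Number of ordered genes on the simulated chromosome.
#' @param pct_dma_base Median %DMA at 0 copies; `pct_dma_per_copy` the
#'   per-copy increase (the metabolite-efficiency gradient).
#' @param pct_dma_per_copy See `pct_dma_base`.
#' @param seed Integer seed; all generator draws flow from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(cohort = c("argentina", "bangladesh", "custom"),
                       n_individuals = NULL,
                       hap_freq = NULL,
                       panel = haplotype_panel(),
                       effect_table = NULL,
                       baseline_beta = NULL,
                       noise_sd = 0.05,
                       n_null_probes = 5000L,
                       missing_rate = 0.001,
                       n_plates = NULL,
                       plate_shift = 0.02,
                       off_target_freq = 0.10,
                       expr_coupling = NULL,
                       n_genes = 200L,
                       pct_dma_base = 73,
                       pct_dma_per_copy = 5.2,
                       seed = 1L) {
  cohort <- match.arg(cohort)
  if (is.null(n_individuals))
    n_individuals <- switch(cohort, argentina = 94L, bangladesh = 127L, 100L)
  if (is.null(hap_freq))
    hap_freq <- switch(cohort, argentina = 0.69, bangladesh = 0.17, 0.5)
  if (is.null(n_plates))
    n_plates <- switch(cohort, argentina = 1L, bangladesh = 2L, 1L)
  if (is.null(effect_table) || is.null(baseline_beta)) {
    d <- default_effect_probes()
    if (is.null(effect_table)) effect_table <- d$effect
    if (is.null(baseline_beta)) baseline_beta <- d$baseline[names(effect_table)]
  }
  if (is.null(expr_coupling))
    expr_coupling <- data.frame(
      probe_id = c("cg03493300", "cg03493300", "cg18534077", "cg18367433"),
      expr_id = c("AS3MT_3UTR", "USMG5_1773313", "AS3MT_3UTR",
                  "USMG5_1773313"),
      rho = c(-0.54, 0.58, -0.32, -0.67),
      stringsAsFactors = FALSE)
  if (hap_freq < 0 || hap_freq > 1) stop("hap_freq must be in [0,1]")
  stopifnot(all(baseline_beta >= 0 & baseline_beta <= 1),
            missing_rate >= 0, missing_rate < 1,
            all(abs(expr_coupling$rho) < 1),
            all(names(effect_table) %in% names(baseline_beta)))
  structure(list(cohort = cohort, n_individuals = as.integer(n_individuals),
                 hap_freq = hap_freq, panel = panel,
                 effect_table = effect_table, baseline_beta = baseline_beta,
                 noise_sd = noise_sd, n_null_probes = as.integer(n_null_probes),
                 missing_rate = missing_rate, n_plates = as.integer(n_plates),
                 plate_shift = plate_shift, off_target_freq = off_target_freq,
                 expr_coupling = expr_coupling, n_genes = as.integer(n_genes),
                 pct_dma_base = pct_dma_base,
                 pct_dma_per_copy = pct_dma_per_copy,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate genotypes, covariates and true haplotype dosages
#'
#' Each individual receives two haplotypes drawn independently: with
#' probability `hap_freq` a haplotype is the target (carrying the target
#' allele at every panel SNP), otherwise each SNP allele is drawn
#' independently with probability `off_target_freq` of being the target
#' allele, so off-haplotype linkage is imperfect and phasing is non-trivial.
#' Genotypes are reported as unordered allele pairs (unphased). Covariates
#' follow the cohort preset: log-normal urinary arsenic, specific gravity
#' around the cohort reference, age, BMI, a binary covariate (coca use or
#' child sex), plate assignment, RNA integrity, and urinary arsenic
#' metabolite fractions whose %DMA median rises with copy number.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (genotype table), `covariates`
#'   (data frame keyed by `sample`), and `truth` (data frame `sample`,
#'   `copies` with the true target-haplotype count).
#' @export
generate_cohort <- function(config) {
  if (config$hap_freq < 0 || config$hap_freq > 1)
    stop("hap_freq must be in [0,1]")
  set.seed(config$seed)
  n <- config$n_individuals
  panel <- config$panel
  L <- length(panel$snp_ids)
  samples <- sprintf("S%04d", seq_len(n))

  is_target <- matrix(stats::runif(2 * n) < config$hap_freq, nrow = n)
  copies <- rowSums(is_target)

  # one n x L allele matrix per chromosome: target haplotypes carry the
  # target allele at every SNP; non-target haplotypes draw each SNP
  # independently (imperfect off-haplotype LD)
  hap_matrix <- function(target) {
    tgt <- matrix(stats::runif(n * L) < config$off_target_freq,
                  nrow = n, ncol = L)
    tgt[target, ] <- TRUE
    tm <- matrix(panel$target_alleles, nrow = n, ncol = L, byrow = TRUE)
    om <- matrix(panel$other_alleles, nrow = n, ncol = L, byrow = TRUE)
    ifelse(tgt, tm, om)
  }
  h1 <- hap_matrix(is_target[, 1])
  h2 <- hap_matrix(is_target[, 2])
  gt <- data.frame(sample = rep(samples, each = L),
                   snp = rep(panel$snp_ids, times = n),
                   allele1 = as.vector(t(h1)),
                   allele2 = as.vector(t(h2)),
                   phased = FALSE, stringsAsFactors = FALSE)
  class(gt) <- c("genotype_table", "data.frame")

  sg_ref <- if (config$cohort == "bangladesh") 1.012 else 1.020
  ln_uas <- stats::rnorm(n,
                         mean = log(if (config$cohort == "bangladesh") 68 else 188),
                         sd = 1.1)
  pct_dma <- pmin(95, pmax(40, config$pct_dma_base +
                             config$pct_dma_per_copy * copies +
                             stats::rnorm(n, 0, 6)))
  pct_mma <- pmin(0.6 * (100 - pct_dma),
                  pmax(1, stats::rnorm(n, 10, 3)))
  u_as <- exp(ln_uas)
  covariates <- data.frame(
    sample = samples,
    u_as = u_as,
    sg = pmax(1.001, stats::rnorm(n, sg_ref, 0.004)),
    age = round(pmin(65, pmax(17, stats::rnorm(
      n, if (config$cohort == "bangladesh") 25 else 32, 9)))),
    bmi = round(pmin(40, pmax(16, stats::rnorm(
      n, if (config$cohort == "bangladesh") 20 else 24, 3.5))), 1),
    coca = stats::runif(n) < 0.42,
    sex = sample(c("F", "M"), n, replace = TRUE),
    plate = paste0("P", 1L + (seq_len(n) %% config$n_plates)),
    rin = round(pmax(7.5, stats::rnorm(n, 8.5, 0.5)), 1),
    i_as = u_as * (100 - pct_dma - pct_mma) / 100,
    mma = u_as * pct_mma / 100,
    dma = u_as * pct_dma / 100,
    stringsAsFactors = FALSE)

  list(genotypes = gt, covariates = covariates,
       truth = data.frame(sample = samples, copies = copies))
}

#' Generate a methylation beta matrix with annotation
#'
#' Signal probes get `baseline + effect x copies`; null probes have zero
#' effect. A constant plate shift is added for samples on plates other than
#' the first, Gaussian noise (SD `noise_sd`) is added everywhere, values are
#' clamped to \[0,1\], and `missing_rate` of cells are blanked uniformly at
#' random. Probes are assigned sequentially to `n_genes` ordered genes of
#' 3-12 probes each along one simulated chromosome (signal probes occupy
#' the first genes, emulating a clustered regulatory region).
#'
#' @param dosage Numeric vector of haplotype copies, named by sample.
#' @param config A [sim_config()].
#' @param plate Optional per-sample plate labels (same order as `dosage`);
#'   default: no plate structure.
#' @return List with `beta` (a [beta_matrix()]) and `annotation`
#'   (a [probe_annotation()]).
#' @export
generate_methylation <- function(dosage, config, plate = NULL) {
  set.seed(config$seed + 1L)
  n <- length(dosage)
  samples <- names(dosage)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(n))
  eff <- config$effect_table
  base <- config$baseline_beta[names(eff)]
  over <- abs(base + 2 * eff - pmin(pmax(base + 2 * eff, 0), 1)) > 0.02
  if (any(over))
    warning("baseline + 2*effect leaves [0,1] by >0.02 at: ",
            paste(names(eff)[over], collapse = ", "))

  null_ids <- sprintf("cgN%06d", seq_len(config$n_null_probes))
  probe_ids <- c(names(eff), null_ids)
  p <- length(probe_ids)
  baseline <- c(unname(base), stats::runif(config$n_null_probes, 0.1, 0.9))
  delta <- c(unname(eff), rep(0, config$n_null_probes))

  m <- outer(baseline, rep(1, n)) + outer(delta, dosage)
  if (!is.null(plate)) {
    shifted <- as.integer(factor(plate)) > 1L
    m <- m + config$plate_shift * matrix(shifted, nrow = p, ncol = n,
                                         byrow = TRUE)
  }
  m <- m + matrix(stats::rnorm(p * n, 0, config$noise_sd), nrow = p)
  m <- pmin(pmax(m, 0), 1)
  if (config$missing_rate > 0) {
    miss <- stats::runif(p * n) < config$missing_rate
    # never blank a full probe
    full <- rowSums(matrix(!miss, nrow = p)) == 0
    miss[which(full)] <- FALSE
    m[miss] <- NA_real_
  }
  dimnames(m) <- list(probe_ids, samples)

  # gene sizes 3-12 probes, recycled over n_genes genes, sequential layout
  sizes <- 3L + (seq_len(config$n_genes) * 7L) %% 10L
  gene_of <- rep(seq_len(config$n_genes), times = sizes)[seq_len(p)]
  if (anyNA(gene_of))  # more probes than gene slots: overflow into last gene
    gene_of[is.na(gene_of)] <- config$n_genes
  ann <- probe_annotation(data.frame(
    probe_id = probe_ids,
    chromosome = "chrS",
    position = 10000L + seq_len(p) * 500L + gene_of * 2000L,
    gene = sprintf("g%04d", gene_of),
    island_relation = "unknown",
    enhancer = FALSE,
    snp_distance = NA_integer_,
    stringsAsFactors = FALSE))
  list(beta = beta_matrix(m), annotation = ann)
}

#' Generate expression data coupled to methylation
#'
#' Expression for each assay named in `expr_coupling` is generated by a
#' Gaussian copula against the ranks of the named methylation probe: the
#' latent Pearson correlation is set to `2*sin(pi*rho/6)` so the *Spearman*
#' correlation is `rho` in expectation. Values are mapped to a log-normal
#' scale (median 1-ish relative units). Assays not named in the coupling are
#' independent log-normals.
#'
#' @param meth A [beta_matrix()] (missing cells allowed; their latent values
#'   are drawn independently).
#' @param config A [sim_config()].
#' @param extra_assays Character vector of additional uncoupled assay ids.
#' @return Numeric matrix, assays x samples.
#' @export
generate_expression <- function(meth, config, extra_assays = character()) {
  set.seed(config$seed + 2L)
  cp <- config$expr_coupling
  missing_probes <- setdiff(cp$probe_id, rownames(meth))
  if (length(missing_probes))
    stop("expression coupling references unknown probe(s): ",
         paste(missing_probes, collapse = ", "))
  n <- ncol(meth)
  assays <- unique(c(cp$expr_id, extra_assays))
  out <- matrix(NA_real_, nrow = length(assays), ncol = n,
                dimnames = list(assays, colnames(meth)))
  for (a in assays) {
    rows <- cp[cp$expr_id == a, , drop = FALSE]
    if (nrow(rows) == 0) {
      z <- stats::rnorm(n)
    } else {
      # couple to the first named probe for this assay
      x <- unclass(meth)[rows$probe_id[1], ]
      r <- rank(x, na.last = "keep")
      zx <- stats::qnorm((r - 0.5) / sum(!is.na(x)))
      zx[is.na(zx)] <- stats::rnorm(sum(is.na(zx)))
      rho_l <- 2 * sin(pi * rows$rho[1] / 6)
      z <- rho_l * zx + sqrt(1 - rho_l^2) * stats::rnorm(n)
    }
    out[a, ] <- exp(0.6 * z)
  }
  out
}

#' Run the full generator and write all pipeline input files
#'
#' Convenience wrapper: generates genotypes, covariates, methylation,
#' annotation and expression for one cohort and writes them in the formats
#' the readers consume, plus truth tables (true dosage and per-probe effect)
#' for test harnesses.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_simulated_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  dosage <- stats::setNames(cohort$truth$copies, cohort$truth$sample)
  meth <- generate_methylation(dosage, config,
                               plate = cohort$covariates$plate)
  expr <- generate_expression(meth$beta, config)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    beta = file.path(dir, "beta.tsv"),
    annotation = file.path(dir, "annotation.csv"),
    expression = file.path(dir, "expression.tsv"),
    truth_dosage = file.path(dir, "truth_dosage.tsv"),
    truth_effects = file.path(dir, "truth_effects.tsv"))
  write_genotypes(cohort$genotypes, paths["genotypes"])
  utils::write.table(cohort$covariates, paths["covariates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_beta_matrix(meth$beta, paths["beta"])
  write_probe_annotation(meth$annotation, paths["annotation"])
  write_expression_matrix(expr, paths["expression"])
  utils::write.table(cohort$truth, paths["truth_dosage"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(config$effect_table),
               effect = unname(config$effect_table)),
    paths["truth_effects"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
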