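# small fixture builders shared across test files

tiny_beta <- function(values, probes = NULL, samples = NULL,
                      adjusted = FALSE) {
  m <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  beta_matrix(m, adjusted = adjusted)
}

# long-format genotype table from a per-sample list of allele-pair strings,
# e.g. list(i1 = c(snpA = "AA", snpB = "BB"))
make_genotypes <- function(geno, phased = FALSE) {
  rows <- lapply(names(geno), function(s) {
    g <- geno[[s]]
    data.frame(sample = s, snp = names(g),
               allele1 = substr(g, 1, 1), allele2 = substr(g, 2, 2),
               phased = phased, stringsAsFactors = FALSE)
  })
  gt <- do.call(rbind, rows)
  gt$allele1[gt$allele1 == "."] <- NA_character_
  gt$allele2[gt$allele2 == "."] <- NA_character_
  class(gt) <- c("genotype_table", "data.frame")
  gt
}

# two-SNP panel used throughout the EM tests: target haplotype "AB"
panel2 <- function() haplotype_panel(snp_ids = c("snp1", "snp2"),
                                     target_alleles = c("A", "C"),
                                     other_alleles = c("G", "T"))

# independent likelihood maximization oracle for small panels: optimizes
# haplotype frequencies over the simplex by multi-start Nelder-Mead on a
# softmax parameterization, never calling the EM code path
em_oracle_loglik <- function(gt, panel, n_starts = 30, seed = 99) {
  ind <- hapmeth:::split_genotypes(gt, panel)
  uni <- hapmeth:::allele_universe(gt, panel)
  pairs <- lapply(ind, function(x) hapmeth:::enumerate_pairs(x$alleles, uni))
  haps <- sort(unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2)))))
  ll_of <- function(theta) {
    f <- exp(theta - max(theta)); f <- f / sum(f)
    sum(vapply(pairs, function(p) {
      w <- f[match(p$h1, haps)] * f[match(p$h2, haps)] *
        ifelse(p$h1 == p$h2, 1, 2)
      log(max(sum(w), 1e-300))
    }, numeric(1)))
  }
  set.seed(seed)
  best <- -Inf
  for (i in seq_len(n_starts)) {
    fit <- optim(rnorm(length(haps)), function(th) -ll_of(th),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    best <- max(best, -fit$value)
  }
  best
}
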