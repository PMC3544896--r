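#' @title Haplotype frequency estimation and copy-number calling
#' @description
#' An expectation-maximization estimator of haplotype frequencies from
#' unphased multi-SNP genotypes (the classic gene-counting scheme of
#' Excoffier & Slatkin), plus posterior-mean and modal copy numbers of a
#' designated target haplotype. This is the in-package replacement for an
#' external MCMC phasing step: deterministic given the seed, and exact for
#' the short (<= 12 SNP) panels it is meant for.
#' @name haplo
NULL

# genotype table -> list: per sample, a 2 x L character matrix of alleles
# (columns = panel SNPs, NA for missing), plus phased flags per SNP
split_genotypes <- function(gt, panel) {
  extra <- setdiff(unique(gt$snp), panel$snp_ids)
  if (length(extra))
    warning("ignoring non-panel SNP(s): ", paste(extra, collapse = ", "))
  gt <- gt[gt$snp %in% panel$snp_ids, , drop = FALSE]
  if (nrow(gt) == 0) stop("no individuals with panel genotypes")
  samples <- unique(gt$sample)
  L <- length(panel$snp_ids)
  lapply(stats::setNames(samples, samples), function(s) {
    g <- gt[gt$sample == s, , drop = FALSE]
    a <- matrix(NA_character_, nrow = 2, ncol = L,
                dimnames = list(NULL, panel$snp_ids))
    ph <- logical(L)
    idx <- match(g$snp, panel$snp_ids)
    a[1, idx] <- g$allele1
    a[2, idx] <- g$allele2
    ph[idx] <- g$phased
    list(alleles = a, phased = ph)
  })
}

# biallelic allele universe per SNP: the panel's target (and, when known,
# other) allele plus whatever is observed in the data
allele_universe <- function(gt, panel) {
  lapply(stats::setNames(panel$snp_ids, panel$snp_ids), function(s) {
    seen <- unique(stats::na.omit(c(gt$allele1[gt$snp == s],
                                    gt$allele2[gt$snp == s])))
    u <- unique(c(panel$target_alleles[[s]], seen))
    if (length(u) == 1 && !is.null(panel$other_alleles))
      u <- unique(c(u, panel$other_alleles[[s]]))
    if (length(u) > 2)
      stop("SNP ", s, " is not biallelic: alleles ",
           paste(u, collapse = ","))
    if (length(u) == 1) u <- c(u, setdiff(c("A", "C", "G", "T"), u)[1])
    u
  })
}

# enumerate the unordered haplotype pairs consistent with one individual's
# genotypes; missing SNPs are summed over the allele universe
enumerate_pairs <- function(alleles, universe) {
  L <- ncol(alleles)
  per_snp <- vector("list", L)
  for (j in seq_len(L)) {
    a <- alleles[1, j]; b <- alleles[2, j]
    if (is.na(a) || is.na(b)) {
      u <- universe[[j]]
      per_snp[[j]] <- expand.grid(u, u, stringsAsFactors = FALSE)
    } else if (a == b) {
      per_snp[[j]] <- data.frame(Var1 = a, Var2 = b,
                                 stringsAsFactors = FALSE)
    } else {
      per_snp[[j]] <- data.frame(Var1 = c(a, b), Var2 = c(b, a),
                                 stringsAsFactors = FALSE)
    }
  }
  h1 <- ""; h2 <- ""
  for (j in seq_len(L)) {
    k <- nrow(per_snp[[j]])
    h1 <- paste0(rep(h1, each = k), per_snp[[j]]$Var1)
    h2 <- paste0(rep(h2, each = k), per_snp[[j]]$Var2)
  }
  key <- ifelse(h1 <= h2, paste(h1, h2), paste(h2, h1))
  keep <- !duplicated(key)
  data.frame(h1 = pmin(h1, h2)[keep], h2 = pmax(h1, h2)[keep],
             stringsAsFactors = FALSE)
}

#' Estimate haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies from unphased genotypes by
#' expectation-maximization over all phase resolutions compatible with each
#' individual. Missing genotypes are summed over in the E-step rather than
#' dropping the individual. Initialization is uniform over the haplotypes
#' compatible with the data, with a small seeded jitter (1e-3) to escape
#' symmetric saddle points; `n_restarts` independent starts are run and the
#' best-likelihood solution kept.
#'
#' @param gt Genotype table ([read_genotypes()] format).
#' @param panel A [haplotype_panel()].
#' @param tol Convergence threshold on the largest frequency change.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed for the initialization jitter.
#' @param n_restarts Number of jittered restarts.
#' @return List with `frequencies` (named, sums to 1, names are
#'   concatenated alleles 5' to 3'), `loglik`, `loglik_trace` (per-iteration,
#'   non-decreasing), `n_iter`, `converged`, and `target` (the target
#'   haplotype string).
#' @export
em_haplotype_frequencies <- function(gt, panel, tol = 1e-8, max_iter = 500L,
                                     seed = 1L, n_restarts = 10L) {
  ind <- split_genotypes(gt, panel)
  if (length(ind) == 0) stop("no individuals")
  uni <- allele_universe(gt, panel)
  pairs <- lapply(ind, function(x) enumerate_pairs(x$alleles, uni))
  haps <- sort(unique(unlist(lapply(pairs, function(p) c(p$h1, p$h2)))))
  H <- length(haps)
  # index pairs once
  idx <- lapply(pairs, function(p)
    cbind(match(p$h1, haps), match(p$h2, haps)))

  run_em <- function(f0) {
    f <- f0
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      new_counts <- numeric(H)
      ll <- 0
      for (p in idx) {
        w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] == p[, 2], 1, 2)
        tot <- sum(w)
        if (tot <= 0) { w <- rep(1 / length(w), length(w)); tot <- 1 }
        post <- w / tot
        ll <- ll + log(tot)
        for (k in seq_along(post)) {
          new_counts[p[k, 1]] <- new_counts[p[k, 1]] + post[k]
          new_counts[p[k, 2]] <- new_counts[p[k, 2]] + post[k]
        }
      }
      trace <- c(trace, ll)
      f_new <- new_counts / (2 * length(idx))
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    list(f = f, loglik = trace[length(trace)], trace = trace,
         n_iter = length(trace), converged = delta < tol)
  }

  set.seed(seed)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    f0 <- rep(1 / H, H) + stats::runif(H, 0, 1e-3)
    f0 <- f0 / sum(f0)
    fits[[r]] <- run_em(f0)
  }
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(lls)]]
  # tie rule: restarts reaching the same likelihood but different
  # frequency vectors are symmetric global maxima (unresolvable phase
  # couplings); keep all distinct tied solutions so copy-number posteriors
  # can average over them
  tied <- fits[lls >= best$loglik - 1e-9]
  tied_f <- lapply(tied, function(x) stats::setNames(x$f, haps))
  distinct <- tied_f[!duplicated(vapply(
    tied_f, function(f) paste(round(f, 6), collapse = ","), character(1)))]
  list(frequencies = stats::setNames(best$f, haps),
       tied_frequencies = distinct,
       loglik = best$loglik,
       loglik_trace = best$trace,
       n_iter = best$n_iter,
       converged = best$converged,
       target = paste(panel$target_alleles, collapse = ""))
}

#' Per-individual target-haplotype copy numbers
#'
#' Computes, for every individual, the posterior distribution of the number
#' of copies (0-2) of the panel's target haplotype given the genotypes and
#' the haplotype frequencies, and reports the posterior mean
#' (`expected_copies`, the continuous dosage used downstream), the modal
#' count (`hard_call`) and its posterior probability. Fully phased
#' individuals bypass the posterior: their counts are exact with
#' probability 1. Individuals with all panel genotypes missing get `NA`
#' dosage (excluded downstream).
#'
#' When the EM likelihood surface has symmetric tied maxima (the classic
#' single-double-heterozygote ambiguity), the posterior is averaged over
#' the distinct tied frequency solutions, so an unresolvable coupling
#' yields the symmetric expected dosage rather than an arbitrary pick.
#'
#' @param gt Genotype table.
#' @param panel A [haplotype_panel()].
#' @param freqs Haplotype frequencies: a named vector, a fit from
#'   [em_haplotype_frequencies()] (its tied solutions are used), a list of
#'   named vectors (tied solutions), or `NULL` to run EM first.
#' @param ... Passed to [em_haplotype_frequencies()] when `freqs` is `NULL`.
#' @return Data frame of class `"dosage_vector"` with columns `sample`,
#'   `expected_copies`, `hard_call`, `call_probability`.
#' @export
count_copies <- function(gt, panel, freqs = NULL, ...) {
  ind <- split_genotypes(gt, panel)
  uni <- allele_universe(gt, panel)
  target <- paste(panel$target_alleles, collapse = "")
  if (is.null(freqs))
    freqs <- em_haplotype_frequencies(gt, panel, ...)
  freq_set <- if (is.list(freqs) && !is.null(freqs$tied_frequencies))
    freqs$tied_frequencies
  else if (is.list(freqs) && !is.data.frame(freqs)) freqs
  else list(freqs)

  res <- lapply(names(ind), function(s) {
    x <- ind[[s]]
    if (all(is.na(x$alleles))) {
      message("sample ", s, ": all panel genotypes missing; dosage NA")
      return(data.frame(sample = s, expected_copies = NA_real_,
                        hard_call = NA_integer_,
                        call_probability = NA_real_))
    }
    if (all(x$phased) && !anyNA(x$alleles)) {
      h1 <- paste(x$alleles[1, ], collapse = "")
      h2 <- paste(x$alleles[2, ], collapse = "")
      copies <- (h1 == target) + (h2 == target)
      return(data.frame(sample = s, expected_copies = as.numeric(copies),
                        hard_call = as.integer(copies),
                        call_probability = 1))
    }
    p <- enumerate_pairs(x$alleles, uni)
    copies_k <- (p$h1 == target) + (p$h2 == target)
    pc_one <- function(f) {
      f1 <- f[p$h1]; f2 <- f[p$h2]
      f1[is.na(f1)] <- 0; f2[is.na(f2)] <- 0
      w <- f1 * f2 * ifelse(p$h1 == p$h2, 1, 2)
      if (sum(w) <= 0) w <- rep(1, length(w))  # flat over compatible pairs
      w / sum(w)
    }
    # average the posterior over tied frequency solutions
    post <- Reduce(`+`, lapply(freq_set, pc_one)) / length(freq_set)
    pc <- vapply(0:2, function(cc) sum(post[copies_k == cc]), numeric(1))
    data.frame(sample = s,
               expected_copies = sum(post * copies_k),
               hard_call = as.integer(which.max(pc) - 1L),
               call_probability = max(pc))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("dosage_vector", "data.frame")
  out
}

#' Extract the numeric dosage vector
#'
#' @param d A `dosage_vector` data frame from [count_copies()].
#' @param hard Use the modal hard call instead of the posterior mean.
#' @return Named numeric vector (sample -> copies).
#' @export
dosage_values <- function(d, hard = FALSE) {
  stats::setNames(if (hard) as.numeric(d$hard_call) else d$expected_copies,
                  d$sample)
}

#' Write a dosage table to TSV
#' @param d A `dosage_vector` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
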