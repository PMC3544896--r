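#' Classify a SNP allele substitution as CpG-creating or CpG-removing
#'
#' Looks at the two dinucleotides the variant base participates in (last
#' flank base + allele, allele + first flank base) under the reference and
#' the alternate allele, and compares the number of CG dinucleotides formed.
#' More CGs with the alternate allele is `"creates"`, fewer is `"removes"`,
#' otherwise `"neutral"`. An `N` at either adjacent flank base makes the
#' context undecidable and returns `"unknown_context"`. Because CG is its
#' own reverse complement, a single-strand check suffices.
#'
#' @param flank5 Sequence 5' of the variant (at least 1 base, ACGTN).
#' @param ref_allele,alt_allele Single distinct bases in ACGT.
#' @param flank3 Sequence 3' of the variant (at least 1 base, ACGTN).
#' @return One of `"creates"`, `"removes"`, `"neutral"`,
#'   `"unknown_context"`.
#' @export
classify_allele_cpg_effect <- function(flank5, ref_allele, alt_allele,
                                       flank3) {
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (nchar(flank5) < 1 || nchar(flank3) < 1)
    stop("need at least 1 bp of flank on each side")
  if (!ref_allele %in% c("A", "C", "G", "T") ||
      !alt_allele %in% c("A", "C", "G", "T"))
    stop("alleles must be single ACGT bases")
  if (ref_allele == alt_allele) stop("alleles must differ")
  left <- substr(flank5, nchar(flank5), nchar(flank5))
  right <- substr(flank3, 1, 1)
  if (left == "N" || right == "N") return("unknown_context")
  n_cg <- function(a)
    (paste0(left, a) == "CG") + (paste0(a, right) == "CG")
  d <- n_cg(alt_allele) - n_cg(ref_allele)
  if (d > 0) "creates" else if (d < 0) "removes" else "neutral"
}

#' Detect CpG islands by sliding-window scan
#'
#' CpGPlot-style detector: every 1-bp-step window of `window` bases is
#' scored for GC fraction and observed/expected CpG ratio
#' (`count(CG) * len / (count(C) * count(G))`); windows passing both
#' thresholds are merged (union of their spans) and merged runs shorter
#' than `min_length` are discarded. Coordinates are 1-based inclusive.
#'
#' @param seq Nucleotide string (ACGT; other letters never match).
#' @param window Window width in bp (default 200).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_obs_exp Minimum observed/expected CpG ratio (default 0.6).
#' @param min_length Minimum merged island length in bp (default 200).
#' @return Data frame with columns `start`, `end`, `length`, `gc_fraction`,
#'   `obs_exp_cpg` (per reported interval), sorted and non-overlapping;
#'   zero rows when nothing passes. A sequence shorter than `window` gives
#'   an empty result with a warning.
#' @export
find_cpg_islands <- function(seq, window = 200L, min_gc = 0.5,
                             min_obs_exp = 0.6, min_length = 200L) {
  seq <- toupper(seq)
  len <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_fraction = numeric(0),
                      obs_exp_cpg = numeric(0))
  if (len < window) {
    warning("sequence shorter than window (", len, " < ", window, ")")
    return(empty)
  }
  base <- strsplit(seq, "")[[1]]
  is_c <- as.integer(base == "C")
  is_g <- as.integer(base == "G")
  is_cg <- as.integer(base == "C" & c(base[-1], "") == "G")  # CG starting here

  csum <- function(v) cumsum(c(0L, v))
  cc <- csum(is_c); cg_ <- csum(is_g); ccg <- csum(is_cg)
  starts <- seq_len(len - window + 1L)
  ends <- starts + window - 1L
  n_c <- cc[ends + 1L] - cc[starts]
  n_g <- cg_[ends + 1L] - cg_[starts]
  # CG dinucleotides fully inside the window start at positions start..end-1
  n_cg <- ccg[ends] - ccg[starts]
  gc <- (n_c + n_g) / window
  oe <- ifelse(n_c * n_g > 0, n_cg * window / (n_c * n_g), 0)
  pass <- gc >= min_gc & oe >= min_obs_exp
  if (!any(pass)) return(empty)

  # merge overlapping/adjacent passing windows
  ps <- starts[pass]; pe <- ends[pass]
  brk <- which(ps[-1] > pe[-length(pe)] + 1L)
  grp_start <- c(1L, brk + 1L)
  grp_end <- c(brk, length(ps))
  ivs <- data.frame(start = ps[grp_start], end = pe[grp_end])
  ivs$length <- ivs$end - ivs$start + 1L
  ivs <- ivs[ivs$length >= min_length, , drop = FALSE]
  if (nrow(ivs) == 0) return(empty)
  stat <- function(s, e) {
    w <- e - s + 1L
    nc <- cc[e + 1L] - cc[s]; ng <- cg_[e + 1L] - cg_[s]
    ncg <- ccg[e] - ccg[s]
    c(gc = (nc + ng) / w,
      oe = if (nc * ng > 0) ncg * w / (nc * ng) else 0)
  }
  st <- t(mapply(stat, ivs$start, ivs$end))
  ivs$gc_fraction <- st[, "gc"]
  ivs$obs_exp_cpg <- st[, "oe"]
  rownames(ivs) <- NULL
  ivs
}

#' Classify a position relative to CpG islands
#'
#' Standard 450K annotation convention: inside an island interval is
#' `"island"`; within `shore_bp` (default 2000) of the nearest island edge
#' is `"shore"`; within (`shore_bp`, `shelf_bp`\] (default 4000) is
#' `"shelf"`; anything farther (or an empty island set) is `"open_sea"`.
#'
#' @param position 1-based position(s), vectorized.
#' @param islands Data frame with 1-based inclusive `start`, `end`
#'   (sorted, non-overlapping), e.g. from [find_cpg_islands()].
#' @param shore_bp,shelf_bp Distance cut-offs in bp.
#' @return Character vector of classifications.
#' @export
classify_relation <- function(position, islands, shore_bp = 2000L,
                              shelf_bp = 4000L) {
  vapply(position, function(pos) {
    if (is.null(islands) || nrow(islands) == 0) return("open_sea")
    d <- pmax(islands$start - pos, pos - islands$end, 0)
    dmin <- min(d)
    if (dmin == 0) "island"
    else if (dmin <= shore_bp) "shore"
    else if (dmin <= shelf_bp) "shelf"
    else "open_sea"
  }, character(1))
}

#' Flag probes with SNPs at or near the interrogated CpG
#'
#' Probes whose annotated SNP lies closer than `flag_distance` bp (default
#' 10) to the CpG site are flagged `high_interference_risk` (base-extension
#' interference is strongest there); every probe with any annotated SNP
#' distance is additionally marked `snp_containing`.
#'
#' @param ann A [probe_annotation()] table (`snp_distance` column; `NA`
#'   where no SNP is annotated).
#' @param flag_distance Distance cut-off in bp (strict `<`).
#' @return `ann` with logical columns `snp_containing` and
#'   `high_interference_risk` appended.
#' @export
flag_probe_snps <- function(ann, flag_distance = 10L) {
  if (any(!is.na(ann$snp_distance) & ann$snp_distance < 0))
    stop("snp_distance must be non-negative")
  ann$snp_containing <- !is.na(ann$snp_distance)
  ann$high_interference_risk <- !is.na(ann$snp_distance) &
    ann$snp_distance < flag_distance
  ann
}

#' Classify CpG effects for a panel of SNPs from flanking sequences
#'
#' Convenience wrapper over [classify_allele_cpg_effect()] for a FASTA of
#' flanking sequences. Each record must be named `<snp_id>` and contain the
#' variant base at position `flank_width + 1`, i.e. `flank_width` bases of
#' 5' flank, the reference base, then the 3' flank.
#'
#' @param fasta_path FASTA of flank records.
#' @param panel A [haplotype_panel()]; the effect reported is that of
#'   substituting the panel's target allele for its other allele in the
#'   flanking context (the embedded variant base itself is ignored).
#' @param flank_width Number of 5' flank bases before the variant base.
#' @return Data frame with columns `snp_id`, `other_allele`,
#'   `target_allele`, `effect`.
#' @export
classify_panel_cpg_effects <- function(fasta_path, panel, flank_width = 10L) {
  seqs <- read_fasta(fasta_path)
  missing <- setdiff(panel$snp_ids, names(seqs))
  if (length(missing))
    stop("no flank sequence for: ", paste(missing, collapse = ", "))
  out <- lapply(panel$snp_ids, function(s) {
    sq <- seqs[[s]]
    tgt <- panel$target_alleles[[s]]
    oth <- panel$other_alleles[[s]]
    eff <- classify_allele_cpg_effect(substr(sq, 1, flank_width), oth, tgt,
                                      substr(sq, flank_width + 2L, nchar(sq)))
    data.frame(snp_id = s, other_allele = oth, target_allele = tgt,
               effect = eff, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
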