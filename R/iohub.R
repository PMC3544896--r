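#' Run configuration for the haplotype-dose pipeline
#'
#' Collects the tunable parameters of the analysis in one validated list.
#' The defaults reproduce the conventions of a 450K-array epigenome scan:
#' false discovery rates computed against a fixed total of 450,000
#' comparisons, k = 10 nearest-neighbour imputation, 20-gene co-methylation
#' windows at a |r| > 0.5 cut-off, and cohort-specific urine specific-gravity
#' references (1.020 g/mL for an Andean adult cohort, 1.012 g/mL for a
#' Bangladeshi cord-blood cohort).
#'
#' @param cohort_name Label for the cohort the run describes.
#' @param fdr_m Total number of comparisons used as the Benjamini-Hochberg
#'   denominator. Defaults to 450000 even when fewer probes are analysed
#'   (the conservative array-wide convention); set to the number of tests
#'   for the standard procedure.
#' @param fdr_alpha Significance cut-off on the FDR scale, in (0,1).
#' @param knn_k Number of nearest probes used to impute a missing beta value.
#' @param window_genes Number of consecutive genes per co-methylation window.
#' @param corr_threshold Absolute Pearson correlation above which a
#'   between-gene CpG pair counts as co-methylated, in (0,1).
#' @param n_permutations Gene-order permutations for the regional null band.
#' @param seed Integer seed recorded with, and used by, stochastic stages.
#' @param sg_reference Specific-gravity reference (g/mL) for urinary arsenic
#'   dilution adjustment; must exceed 1.
#'
#' @return A list of class `"hapmeth_config"`.
#' @export
run_config <- function(cohort_name = "cohort",
                       fdr_m = 450000L,
                       fdr_alpha = 0.05,
                       knn_k = 10L,
                       window_genes = 20L,
                       corr_threshold = 0.5,
                       n_permutations = 100L,
                       seed = 1L,
                       sg_reference = 1.020) {
  stopifnot(
    is.numeric(fdr_m), fdr_m >= 1,
    fdr_alpha > 0, fdr_alpha < 1,
    knn_k >= 1,
    window_genes >= 1,
    corr_threshold > 0, corr_threshold < 1,
    n_permutations >= 1,
    sg_reference > 1
  )
  structure(list(
    cohort_name = cohort_name,
    fdr_m = as.integer(fdr_m),
    fdr_alpha = fdr_alpha,
    knn_k = as.integer(knn_k),
    window_genes = as.integer(window_genes),
    corr_threshold = corr_threshold,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    sg_reference = sg_reference
  ), class = "hapmeth_config")
}

#' Construct a beta-value matrix
#'
#' A beta matrix is a numeric probes x samples matrix of methylation
#' fractions in \[0,1\] with `NA` marking missing cells. After plate
#' residualization values may leave \[0,1\]; such matrices carry
#' `adjusted = TRUE` and are exempt from the range check.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   unique row and column names.
#' @param adjusted Logical; `TRUE` for residualized (no longer raw-scale)
#'   matrices.
#' @return The matrix with class `"beta_matrix"` and an `adjusted` attribute.
#' @export
beta_matrix <- function(values, adjusted = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         rownames(values)[anyDuplicated(rownames(values))])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[anyDuplicated(colnames(values))])
  if (!adjusted) {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s'",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  structure(values, adjusted = adjusted, class = c("beta_matrix", "matrix"))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d missing%s)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              if (isTRUE(attr(x, "adjusted"))) ", adjusted" else ""))
  invisible(x)
}

#' Read a beta-value matrix from TSV
#'
#' Expects a tab-separated file whose header row holds sample ids and whose
#' first column holds probe ids; empty cells or `NA` mark missing values.
#' All present values must lie in \[0,1\].
#'
#' @param path Path to the TSV file.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 2) stop("beta matrix file needs a probe column and samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate probe id: ", ids[anyDuplicated(ids)])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  beta_matrix(m)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with 6 decimal places (the package's fixed text
#' precision); missing cells are written empty. A residualized matrix gets a
#' `# adjusted=TRUE` comment header line recording its state.
#'
#' @param m A [beta_matrix()].
#' @param path Output file path.
#' @param digits Decimal places to keep (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  if (isTRUE(attr(m, "adjusted")))
    writeLines("# adjusted=TRUE (plate-residualized; values not raw betas)", con)
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  txt <- formatC(round(unclass(m), digits), format = "f", digits = digits)
  txt[is.na(m)] <- ""
  utils::write.table(cbind(probe_id = rownames(m), txt), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from TSV or minimal VCF
#'
#' Two layouts are accepted. A four-column TSV (`sample`, `snp`, `allele1`,
#' `allele2`) with `.` or empty for missing alleles; or a minimal VCF v4.x
#' with biallelic records and a `GT` field, where `|` separators mark phased
#' genotypes. The result is a long-format genotype table.
#'
#' @param path Path to the genotype file; files whose first non-empty line
#'   starts with `##fileformat=VCF` are parsed as VCF.
#' @return A `data.frame` of class `"genotype_table"` with columns
#'   `sample`, `snp`, `allele1`, `allele2`, `phased` (logical). Missing
#'   genotypes have `NA` alleles. For phased rows the allele order is the
#'   chromosomal order; otherwise it is arbitrary.
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    gt <- read_genotypes_vcf(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("", ".", "NA"))
    need <- c("sample", "snp", "allele1", "allele2")
    if (!all(need %in% names(df)))
      stop("genotype TSV must have columns: ", paste(need, collapse = ", "))
    gt <- data.frame(sample = as.character(df$sample),
                     snp = as.character(df$snp),
                     allele1 = toupper(as.character(df$allele1)),
                     allele2 = toupper(as.character(df$allele2)),
                     phased = if ("phased" %in% names(df))
                       as.logical(df$phased) else FALSE,
                     stringsAsFactors = FALSE)
  }
  ok <- is.na(gt$allele1) | gt$allele1 %in% c("A", "C", "G", "T")
  ok <- ok & (is.na(gt$allele2) | gt$allele2 %in% c("A", "C", "G", "T"))
  if (any(!ok))
    stop("unknown allele code at row ", which(!ok)[1], ": ",
         gt$allele1[which(!ok)[1]], "/", gt$allele2[which(!ok)[1]])
  class(gt) <- c("genotype_table", "data.frame")
  gt
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) stop("VCF without #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (length(samples) == 0) stop("VCF has no sample columns")
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    ref <- toupper(f[4]); alt <- toupper(f[5])
    if (grepl(",", alt))
      stop("multiallelic record at ", f[3], " (ALT = ", alt, ")")
    alleles <- c(ref, alt)
    fmt <- strsplit(f[9], ":")[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("record ", f[3], " has no GT field")
    gts <- vapply(strsplit(f[-(1:9)], ":"), `[`, character(1), gt_idx)
    phased <- grepl("\\|", gts)
    parts <- strsplit(gts, "[/|]")
    a1 <- vapply(parts, `[`, character(1), 1)
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                 character(1))
    decode <- function(a) {
      idx <- suppressWarnings(as.integer(a))  # "." -> NA by design
      ifelse(is.na(idx), NA_character_, alleles[idx + 1L])
    }
    out[[i]] <- data.frame(sample = samples, snp = f[3],
                           allele1 = decode(a1), allele2 = decode(a2),
                           phased = phased, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a genotype table to TSV
#'
#' @param gt A genotype table as returned by [read_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  df <- as.data.frame(gt)
  df$allele1[is.na(df$allele1)] <- "."
  df$allele2[is.na(df$allele2)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' CSV in the style of an Illumina array manifest extract: columns
#' `probe_id`, `chromosome`, `position` (1-based), `gene`, `island_relation`
#' (one of island/shore/shelf/open_sea/unknown), `enhancer` (logical) and
#' `snp_distance` (bp to nearest SNP; empty when no SNP is annotated).
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `"probe_annotation"`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  probe_annotation(df)
}

#' Validate a probe annotation data frame
#'
#' @param df Data frame with the columns documented in
#'   [read_probe_annotation()].
#' @return `df` with class `"probe_annotation"` prepended.
#' @export
probe_annotation <- function(df) {
  need <- c("probe_id", "chromosome", "position", "gene",
            "island_relation", "enhancer", "snp_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id: ", df$probe_id[anyDuplicated(df$probe_id)])
  if (any(df$position < 1)) stop("positions must be >= 1 (1-based)")
  rel <- c("island", "shore", "shelf", "open_sea", "unknown")
  if (!all(df$island_relation %in% rel))
    stop("island_relation outside {", paste(rel, collapse = ", "), "}")
  if (any(!is.na(df$snp_distance) & df$snp_distance < 0))
    stop("snp_distance must be non-negative")
  class(df) <- unique(c("probe_annotation", class(df)))
  df
}

#' Write a probe annotation table as CSV
#' @param ann A probe annotation table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Same TSV dialect as [read_beta_matrix()] (assays x samples, first column
#' assay ids) but without the \[0,1\] range constraint.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with assay rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate assay id: ",
                               ids[anyDuplicated(ids)])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#' @param m Numeric matrix, assays x samples.
#' @param path Output path.
#' @param digits Decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, digits = 6) {
  txt <- formatC(round(m, digits), format = "f", digits = digits)
  txt[is.na(m)] <- ""
  df <- cbind(assay_id = rownames(m), as.data.frame(txt, optional = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sequence set from FASTA
#'
#' Minimal single-purpose FASTA reader for flanking-sequence and island
#' inputs: returns uppercase sequences named by the first word of each
#' header.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  names_ <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  stats::setNames(seqs, names_[as.integer(names(seqs))])
}

#' Write CpG island intervals as BED
#'
#' Intervals are stored 1-based inclusive and written 0-based half-open,
#' the BED convention; the conversion happens only here.
#'
#' @param islands Data frame from [find_cpg_islands()].
#' @param path Output path.
#' @param chrom Chromosome name for the BED records.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path, chrom = "chr1") {
  df <- data.frame(chrom = chrom,
                   start = islands$start - 1L,   # 1-based -> 0-based
                   end = islands$end,            # inclusive -> half-open
                   name = sprintf("island_%d", seq_len(nrow(islands))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a provenance record for a run
#'
#' Emits a small JSON-like record (plain text, one `key\tvalue` per line)
#' with the configuration, seed, package version, and R version, sufficient
#' to re-run the stage identically.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path, extra = list()) {
  fields <- c(unclass(config),
              list(package = "hapmeth",
                   package_version = as.character(
                     utils::packageVersion("hapmeth")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = ".")),
              extra)
  writeLines(paste(names(fields),
                   vapply(fields, function(x) paste(x, collapse = ","),
                          character(1)),
                   sep = "\t"), path)
  invisible(path)
}
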