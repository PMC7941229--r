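# Readers/writers for the on-disk formats: TSV matrices (leading "id"
# column), GMT gene-set collections, minimal MAF mutation tables, clinical
# tables and JSON manifests. All matrices use one dialect so write -> read
# round-trips are bit-exact on valid data.

#' Read a numeric matrix from TSV with a leading `id` column
#' @param path TSV file path.
#' @param what Label used in error messages.
#' @return Numeric matrix with the `id` column as rownames.
#' @export
read_matrix_tsv <- function(path, what = "matrix") {
  if (!file.exists(path)) tme_format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "id")
    tme_format_error(sprintf("%s: expected a leading 'id' column", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    tme_format_error(sprintf("%s: duplicate row identifier '%s'", what,
                             ids[duplicated(ids)][1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    tme_format_error(sprintf("%s: non-numeric cell at row '%s', column '%s'",
                             what, ids[badrow], names(df)[bad + 1]))
  }
  rownames(m) <- ids
  m
}

#' Write a numeric matrix as TSV with a leading `id` column
#' @param m Matrix with rownames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix from TSV
#'
#' Expects gene rows, sample columns and a leading `id` column. Optionally
#' drops genes with too many zeros (noise filter on linear-scale input).
#'
#' @param path TSV file path.
#' @param scale `"linear"` or `"log2"` (the on-disk scale).
#' @param min_expressed_frac If non-NULL, keep only genes expressed (> 0) in
#'   at least this fraction of samples (linear scale only).
#' @return An [expression_cohort()].
#' @export
read_expression <- function(path, scale = c("linear", "log2"),
                            min_expressed_frac = NULL) {
  scale <- match.arg(scale)
  m <- read_matrix_tsv(path, "expression matrix")
  cohort <- expression_cohort(m, scale = scale)
  if (!is.null(min_expressed_frac) && scale == "linear")
    cohort <- filter_low_expression(cohort, min_expressed_frac)
  cohort
}

#' Write an expression cohort to TSV
#' @param cohort An [expression_cohort()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(cohort, path) write_matrix_tsv(cohort$values, path)

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) tme_format_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short))
    tme_format_error(sprintf("GMT line %d has fewer than 3 fields",
                             which(short)[1]))
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm))
    tme_format_error(sprintf("duplicate gene-set name '%s'",
                             nm[duplicated(nm)][1]))
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicated members removed", f[[1]]))
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  names(desc) <- nm
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection to GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set descriptions (recycled if length 1).
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (!length(sets)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  desc <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

maf_required_cols <- c("Tumor_Sample_Barcode", "Hugo_Symbol",
                       "Variant_Classification", "Reference_Allele",
                       "Tumor_Seq_Allele2", "context_96")

#' Read a minimal MAF mutation table
#'
#' Required columns: `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `context_96` (trinucleotide-context channel index in 0..95).
#'
#' @param path TSV path.
#' @return A data.frame of mutations.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) tme_format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(maf_required_cols, names(df))
  if (length(missing))
    tme_format_error(sprintf("MAF missing required column(s): %s",
                             paste(missing, collapse = ", ")))
  if (nrow(df) && any(df$context_96 < 0 | df$context_96 > 95, na.rm = TRUE))
    tme_format_error("context_96 values must be in [0, 95]")
  df
}

#' Write a minimal MAF mutation table
#' @param mutations Data.frame with the minimal MAF columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_maf <- function(mutations, path) {
  utils::write.table(mutations[, maf_required_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe x sample methylation beta matrix
#'
#' Values outside \[-0.001, 1.001\] are rejected (naming the probe and
#' sample); values inside that band are clamped into \[0, 1\].
#'
#' @param path TSV path with leading `id` probe column.
#' @return A probe x sample numeric matrix of beta values in \[0, 1\].
#' @export
read_methylation <- function(path) {
  m <- read_matrix_tsv(path, "methylation matrix")
  bad <- which(m < -0.001 | m > 1.001, arr.ind = TRUE)
  if (nrow(bad))
    tme_format_error(sprintf(
      "beta value %.4g out of range at probe '%s', sample '%s'",
      m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  pmin(pmax(m, 0), 1)
}

#' Read a broad arm-level copy-number table (arms x samples)
#' @param path TSV path with leading `id` arm column.
#' @return An arms x samples numeric matrix.
#' @export
read_broad_cna <- function(path) read_matrix_tsv(path, "broad CNA table")

#' Read a clinical table (one row per sample)
#' @param path TSV path; must contain a `sample` column.
#' @return A data.frame, `""` treated as missing.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) tme_format_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (is.null(df$sample))
    tme_format_error("clinical table missing required column: sample")
  if (anyDuplicated(df$sample))
    tme_format_error("clinical table has duplicated sample identifiers")
  df
}

#' Read and validate a pipeline configuration (YAML or JSON)
#'
#' Recognized fields include input paths, the rank search range
#' (`k_min`/`k_max`, within \[2, 12\]), `n_restarts` (>= 2), the ssGSEA
#' exponent, differential-expression thresholds, the NTP resample count,
#' seeds and the output directory; unknown fields are kept as-is.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return A named list of configuration values with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) tme_config_error(sprintf("config not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(k_min = 2L, k_max = 8L, n_restarts = 10L,
                   ssgsea_alpha = 0.25, fc_threshold = 0.4,
                   q_threshold = 0.05, ntp_resamples = 1000L, seed = 1L,
                   out_dir = "results")
  cfg <- utils::modifyList(defaults, as.list(cfg))
  if (cfg$k_min < 2 || cfg$k_max > 12 || cfg$k_min > cfg$k_max)
    tme_config_error("rank range must lie within [2, 12] with k_min <= k_max")
  if (cfg$n_restarts < 2) tme_config_error("n_restarts must be >= 2")
  cfg
}

#' Write a data.frame as TSV
#' @param df Data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
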