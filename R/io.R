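#' Read a probes-by-samples matrix from TSV
#'
#' The expected dialect has a first column `probe_id` (or `gene_id` for count
#' matrices) and one column per sample. Missing values are empty cells; `.` is
#' not a missing marker.
#'
#' @param path Path to a tab-separated file.
#' @param id_col Name of the identifier column (default `"probe_id"`).
#' @return Numeric matrix with row names from `id_col` and sample column names.
#' @export
read_matrix_tsv <- function(path, id_col = "probe_id") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  if (!id_col %in% names(dt)) {
    stop("expected identifier column '", id_col, "' in ", path)
  }
  ids <- as.character(dt[[id_col]])
  dt[[id_col]] <- NULL
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a probes-by-samples matrix to TSV
#'
#' Values are written with full round-trip precision so that
#' read -> write -> read reproduces the matrix bit-exactly.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name used for the identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  # 17 significant digits guarantee an exact double round trip
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  ch[is.na(m)] <- ""
  dt <- data.table::as.data.table(ch, keep.rownames = id_col)
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `subject_id`, `session`, `timepoint`,
#' `batch`, `group`, `monocyte_proportion`.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  req <- c("sample_id", "subject_id", "session", "timepoint", "batch",
           "group", "monocyte_proportion")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  validate_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path, sep = ",", quote = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  mono <- sheet$monocyte_proportion
  if (any(mono < 0 | mono > 1, na.rm = TRUE)) {
    stop("monocyte_proportion must lie in [0, 1]")
  }
  n_per_subject <- table(sheet$subject_id)
  if (any(n_per_subject > 8)) stop("a subject has more than 8 samples")
  invisible(sheet)
}

#' Read a probe annotation table
#'
#' CSV with columns `probe_id`, `chromosome` (\"chr1\"..\"chr22\", \"chrX\",
#' \"chrY\"), `position` (1-based bp), `feature_class` (TSS, 5UTR, Body, 3UTR,
#' undefined), `gene_symbol`, plus logical flag columns `mQTL` and
#' `circadian_TSS`.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  req <- c("probe_id", "chromosome", "position", "feature_class", "gene_symbol")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in annotation")
  df
}

#' @rdname read_probe_annotation
#' @param ann Probe annotation `data.frame`.
#' @export
write_probe_annotation <- function(ann, path) {
  data.table::fwrite(ann, path, sep = ",", quote = FALSE)
  invisible(path)
}
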