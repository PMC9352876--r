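# Delimited-text and sparse-matrix I/O for the pipeline's tables.

#' Write / read an experiment as a pair of TSV files
#'
#' The abundance matrix is written genes x samples with a `gene_id` first
#' column; sample metadata goes to a sidecar TSV with a `sample_id` column
#' matching the matrix column names.
#'
#' @param x An [experiment_matrix()].
#' @param matrix_path,meta_path Output / input file paths.
#' @return `write_experiment` returns the paths invisibly;
#'   `read_experiment` returns an [experiment_matrix()].
#' @export
write_experiment <- function(x, matrix_path, meta_path) {
  stopifnot(inherits(x, "experiment_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- cbind(sample_id = colnames(x$abundance), x$sample_meta)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' @rdname write_experiment
#' @export
read_experiment <- function(matrix_path, meta_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  ord <- match(colnames(m), meta$sample_id)
  if (anyNA(ord))
    stop("sample metadata does not cover all matrix columns", call. = FALSE)
  experiment_matrix(m, meta[ord, setdiff(names(meta), "sample_id"),
                            drop = FALSE])
}

#' Write / read a tidy result table as TSV
#'
#' Generic plain-TSV writers for the pipeline's result data.frames
#' (`de_result`, `convergence_table`, `twas_scan`, `enrichment_result`,
#' `constraint_report`).
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `write_result_tsv` returns `path` invisibly; `read_result_tsv`
#'   a data.frame.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_tsv
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then gene ids,
#'   tab-separated).
#' @return Named list of character gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param genesets Named list of character gene-id vectors.
#' @param path Output path.
#' @param description Description field (second GMT column); recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path, description = "na") {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  lines <- vapply(names(genesets), function(nm) {
    paste(c(nm, description, genesets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a cell-type profile
#'
#' A profile (genes x cell types) round-trips either as a dense TSV (with a
#' `gene_id` first column) or, when `path` ends in `.mtx`, as a
#' MatrixMarket coordinate file with plain-text row / column label sidecars
#' (`<path>.rows`, `<path>.cols`).
#'
#' @param profile Numeric matrix with dimnames.
#' @param path Output / input path (`.tsv` or `.mtx`).
#' @return `write_profile` returns `path` invisibly; `read_profile` the
#'   dense numeric matrix.
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(profile, sparse = TRUE), path)
    writeLines(rownames(profile), paste0(path, ".rows"))
    writeLines(colnames(profile), paste0(path, ".cols"))
  } else {
    df <- data.frame(gene_id = rownames(profile), profile,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(path, ".rows"))
    colnames(m) <- readLines(paste0(path, ".cols"))
    m
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    m
  }
}
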