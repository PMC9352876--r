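#' Gene-by-sample expression container
#'
#' Bundles a nonnegative gene-by-sample abundance matrix with the per-sample
#' design factors the differential-expression model uses: `cell_type`,
#' `treatment`, `buffer` and `plate`.
#'
#' @param abundance Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns. No missing values, all entries >= 0.
#' @param sample_meta `data.frame` with one row per sample column and at
#'   least the columns `cell_type`, `treatment`, `buffer`, `plate`.
#'
#' @return An object of class `experiment_matrix`: a list with elements
#'   `abundance`, `sample_meta` and `gene_ids`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(cell_type = "daoy",
#'                    treatment = rep(c("h2o", "propranolol"), each = 2),
#'                    buffer = "h2o", plate = rep(c("p1", "p2"), 2))
#' experiment_matrix(m, meta)
experiment_matrix <- function(abundance, sample_meta) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("'abundance' must be a numeric matrix", call. = FALSE)
  if (anyNA(abundance))
    stop("'abundance' must not contain missing values", call. = FALSE)
  if (any(abundance < 0))
    stop("'abundance' must be nonnegative", call. = FALSE)
  if (is.null(rownames(abundance)))
    stop("'abundance' must have gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(abundance)))
    stop("gene ids must be unique", call. = FALSE)
  if (!is.data.frame(sample_meta))
    stop("'sample_meta' must be a data.frame", call. = FALSE)
  if (nrow(sample_meta) != ncol(abundance))
    stop("'sample_meta' rows must align one-to-one with sample columns",
         call. = FALSE)
  needed <- c("cell_type", "treatment", "buffer", "plate")
  missing_cols <- setdiff(needed, names(sample_meta))
  if (length(missing_cols))
    stop("'sample_meta' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (f in needed) {
    sample_meta[[f]] <- as.character(sample_meta[[f]])
    if (any(!nzchar(sample_meta[[f]])) || anyNA(sample_meta[[f]]))
      stop(sprintf("'sample_meta$%s' has empty or missing levels", f),
           call. = FALSE)
  }
  structure(
    list(abundance = abundance, sample_meta = sample_meta,
         gene_ids = rownames(abundance)),
    class = "experiment_matrix"
  )
}

#' @export
print.experiment_matrix <- function(x, ...) {
  cat(sprintf("experiment_matrix: %d genes x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  for (f in c("cell_type", "treatment", "buffer", "plate")) {
    tab <- table(x$sample_meta[[f]])
    cat(sprintf("  %-9s %s\n", f,
                paste(sprintf("%s(%d)", names(tab), tab), collapse = " ")))
  }
  invisible(x)
}

#' @export
dim.experiment_matrix <- function(x) dim(x$abundance)

# Subset samples (and optionally genes) keeping metadata aligned.
subset_experiment <- function(x, samples = NULL, genes = NULL) {
  ab <- x$abundance
  meta <- x$sample_meta
  if (!is.null(samples)) {
    ab <- ab[, samples, drop = FALSE]
    meta <- meta[samples, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(genes)) ab <- ab[genes, , drop = FALSE]
  experiment_matrix(ab, meta)
}
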