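#' Stouffer's Z-score combination
#'
#' Combines k independent Z-scores as `sum(z) / sqrt(k)` (the calibrated
#' form: the combination of k i.i.d. standard normals is again standard
#' normal). `normalize = FALSE` gives the raw sum, for comparison with
#' conventions that report unnormalized sums.
#'
#' @param z Numeric vector of finite Z-scores, length >= 1.
#' @param normalize Divide by `sqrt(k)` (default TRUE).
#' @return List with `z` (combined statistic) and `p` (two-sided normal
#'   p-value of the combined statistic).
#' @export
#' @examples
#' stouffer_combine(c(1, 2, 3, 4))$z  # 10 / sqrt(4) = 5
stouffer_combine <- function(z, normalize = TRUE) {
  if (length(z) < 1) stop("empty Z-score vector", call. = FALSE)
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("Z-scores must be finite numbers", call. = FALSE)
  zc <- if (normalize) sum(z) / sqrt(length(z)) else sum(z)
  list(z = zc, p = 2 * pnorm(abs(zc), lower.tail = FALSE))
}

#' Assemble a gene-by-condition Z-score panel
#'
#' Intersects the gene sets of several per-condition differential-expression
#' results (each condition applies its own low-abundance filter, so the
#' retained genes differ) and collects their Z-scores into one matrix.
#'
#' @param de_list List of [run_de()] results. Names are taken from each
#'   result's condition attribute unless the list is named.
#' @return Numeric matrix, genes x conditions, dimnames set.
#' @export
z_panel <- function(de_list) {
  stopifnot(is.list(de_list), length(de_list) >= 1)
  labels <- names(de_list)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(de_list, function(d) attr(d, "condition") %||% NA_character_,
                     character(1))
    if (anyNA(labels)) stop("unlabeled de_result in panel", call. = FALSE)
  }
  common <- Reduce(intersect, lapply(de_list, function(d) d$gene_id))
  if (length(common) == 0)
    stop("no genes shared across all conditions", call. = FALSE)
  common <- sort(common)
  panel <- vapply(de_list, function(d) {
    stats::setNames(d$z, d$gene_id)[common]
  }, numeric(length(common)))
  dimnames(panel) <- list(common, labels)
  panel
}

# canonical condition-set definitions over the four condition columns
condition_sets <- function(conditions) {
  short <- conditions
  list(
    prop = grep("_prop$", short, value = TRUE),
    prim = grep("_prim$", short, value = TRUE),
    daoy = grep("^daoy_", short, value = TRUE),
    npc = grep("^npc_", short, value = TRUE),
    all = short
  )
}

#' Convergence meta-analysis across condition sets
#'
#' Combines per-condition gene Z-scores by Stouffer's method within each of
#' the five canonical condition sets — `prop` (one drug across both cell
#' types), `prim`, `daoy` (both drugs within one cell type), `npc`, and
#' `all` (every condition) — and BH-adjusts each set's p-values across genes
#' (five separate FDR families).
#'
#' @param panel Genes-by-conditions Z matrix from [z_panel()], with the
#'   column names `daoy_prop`, `daoy_prim`, `npc_prop`, `npc_prim`; or a
#'   list of `de_result`s, which is passed through [z_panel()] first.
#' @param sets Optional named list of condition-set definitions (character
#'   vectors of column names); defaults to the five canonical sets.
#' @param normalize Passed to [stouffer_combine()].
#'
#' @return A `convergence_table`: `data.frame` with `gene_id` and, per set
#'   `s`, columns `z_s`, `p_s`, `q_s`.
#' @export
#' @examples
#' pan <- matrix(2, 1, 4, dimnames = list("g1",
#'   c("daoy_prop", "daoy_prim", "npc_prop", "npc_prim")))
#' run_convergence(pan)$z_all  # 8 / sqrt(4) = 4
run_convergence <- function(panel, sets = NULL, normalize = TRUE) {
  if (is.list(panel) && !is.matrix(panel)) panel <- z_panel(panel)
  stopifnot(is.matrix(panel), is.numeric(panel))
  if (any(!is.finite(panel)))
    stop("panel contains non-finite Z-scores", call. = FALSE)
  conds <- colnames(panel)
  if (is.null(sets)) {
    canonical <- c("daoy_prop", "daoy_prim", "npc_prop", "npc_prim")
    absent <- setdiff(canonical, conds)
    if (length(absent))
      stop("condition column(s) missing from the panel: ",
           paste(absent, collapse = ", "),
           "; supply `sets` explicitly for non-canonical panels",
           call. = FALSE)
    sets <- condition_sets(canonical)
  }
  for (nm in names(sets)) {
    missing_cols <- setdiff(sets[[nm]], conds)
    if (length(missing_cols))
      stop("condition column(s) missing for set '", nm, "': ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (length(sets[[nm]]) == 0)
      stop("condition set '", nm, "' is empty", call. = FALSE)
  }
  out <- data.frame(gene_id = rownames(panel), stringsAsFactors = FALSE)
  for (nm in names(sets)) {
    cols <- sets[[nm]]
    k <- length(cols)
    zc <- rowSums(panel[, cols, drop = FALSE])
    if (normalize) zc <- zc / sqrt(k)
    p <- 2 * pnorm(abs(zc), lower.tail = FALSE)
    out[[paste0("z_", nm)]] <- unname(zc)
    out[[paste0("p_", nm)]] <- unname(p)
    out[[paste0("q_", nm)]] <- bh_adjust(unname(p))
  }
  rownames(out) <- NULL
  structure(out, class = c("convergence_table", "data.frame"),
            sets = sets, normalize = normalize)
}

#' @export
print.convergence_table <- function(x, n = 6, ...) {
  sets <- names(attr(x, "sets"))
  cat(sprintf("convergence_table: %d genes, sets: %s\n", nrow(x),
              paste(sets, collapse = ", ")))
  print.data.frame(utils::head(x, n), digits = 3)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' @export
summary.convergence_table <- function(object, q_threshold = 0.05, ...) {
  sets <- names(attr(object, "sets"))
  counts <- vapply(sets, function(s) sum(object[[paste0("q_", s)]] <
                                           q_threshold), integer(1))
  cat(sprintf("convergent DEGs at q < %g:\n", q_threshold))
  for (s in sets) cat(sprintf("  %-5s %d\n", s, counts[[s]]))
  invisible(counts)
}

#' Extract convergent DEG lists from a convergence table
#'
#' @param conv A `convergence_table`.
#' @param set Condition-set name (default `"all"`).
#' @param q_threshold FDR threshold (default 0.05).
#' @param direction `"both"`, `"up"` (combined Z > 0) or `"down"`.
#' @return Character vector of gene ids.
#' @export
convergent_degs <- function(conv, set = "all", q_threshold = 0.05,
                            direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  qcol <- paste0("q_", set); zcol <- paste0("z_", set)
  if (!qcol %in% names(conv))
    stop("no such condition set: '", set, "'", call. = FALSE)
  keep <- conv[[qcol]] < q_threshold
  if (direction == "up") keep <- keep & conv[[zcol]] > 0
  if (direction == "down") keep <- keep & conv[[zcol]] < 0
  conv$gene_id[keep]
}

#' Significance weighting of a Z-score
#'
#' The sign-preserving weighting used by the weighted correlation and
#' weighted TWAS regression: `z * |z|` (magnitude squared, direction
#' retained). Weighting by significance de-emphasises small Z-scores while
#' keeping up/down information, in place of hard thresholding at an FDR
#' cutoff.
#'
#' @param z Numeric vector of finite Z-scores.
#' @return `z * abs(z)`.
#' @export
#' @examples
#' weighted_z(1)   # 1
#' weighted_z(4)   # 16
#' weighted_z(-2)  # -4
weighted_z <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("Z-scores must be finite numbers", call. = FALSE)
  z * abs(z)
}

#' Correlation between two conditions' Z-score vectors
#'
#' Pearson correlation between per-gene Z-scores of two conditions over
#' their common gene set, optionally after significance weighting
#' ([weighted_z()]) of both vectors. The p-value is two-sided from the t
#' reference, as in [stats::cor.test()].
#'
#' @param z1,z2 Numeric vectors of equal length >= 3.
#' @param weighted Apply `z * |z|` to both vectors first.
#' @return List with `r` and `p`.
#' @export
correlate_conditions <- function(z1, z2, weighted = FALSE) {
  stopifnot(is.numeric(z1), is.numeric(z2))
  if (length(z1) != length(z2) || length(z1) < 3)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (weighted) {
    z1 <- weighted_z(z1)
    z2 <- weighted_z(z2)
  }
  if (stats::sd(z1) == 0 || stats::sd(z2) == 0)
    stop("zero variance in a Z-score vector", call. = FALSE)
  ct <- stats::cor.test(z1, z2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise condition correlation matrix
#'
#' All pairwise [correlate_conditions()] values over a Z panel, as plotted
#' in cross-condition correlation heatmaps.
#'
#' @param panel Genes-by-conditions Z matrix from [z_panel()].
#' @param weighted Apply significance weighting first.
#' @return List of two matrices, `r` and `p`.
#' @export
condition_cor_matrix <- function(panel, weighted = FALSE) {
  stopifnot(is.matrix(panel))
  k <- ncol(panel)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(panel), colnames(panel))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    cc <- correlate_conditions(panel[, i], panel[, j], weighted)
    r[i, j] <- r[j, i] <- cc$r
    p[i, j] <- p[j, i] <- cc$p
  }
  list(r = r, p = p)
}
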