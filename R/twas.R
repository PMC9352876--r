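#' Regress TWAS Z-scores on drug-effect Z-scores with gene covariates
#'
#' Ordinary least squares of per-gene TWAS Z-scores on drug-effect Z-scores,
#' controlling for gene length and GC fraction:
#' `twas_z ~ drug_z + gene_length + gc_fraction`. In weighted mode both Z
#' vectors are significance-weighted first; the default weighting is the
#' sign-preserving `z * |z|` (see [weighted_z()]), with a literal
#' sign-discarding `z^2` available via `weight_mode = "squared"`.
#'
#' @param twas_z,drug_z Named numeric vectors of Z-scores (names are gene
#'   ids). Only the intersection of their names and the annotation's genes
#'   is used; unnamed vectors must align with `ann` row-for-row.
#' @param ann Gene annotation `data.frame` with columns `gene_id`,
#'   `gene_length`, `gc_fraction` (as produced by
#'   [generate_gene_annotation()]).
#' @param weighted Apply significance weighting to both Z vectors.
#' @param weight_mode `"signed"` (`z * |z|`, default) or `"squared"`
#'   (`z^2`, discards direction).
#' @param log_length Regress on `log10(gene_length)` instead of raw bp.
#'
#' @return List with `coef` (drug-term coefficient), `se`, `p` (two-sided),
#'   `n` (genes used), and `fit` (the underlying [stats::lm()] object).
#' @export
fit_twas_model <- function(twas_z, drug_z, ann, weighted = FALSE,
                           weight_mode = c("signed", "squared"),
                           log_length = FALSE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "gene_length", "gc_fraction") %in% names(ann)))
  if (!is.null(names(twas_z)) && !is.null(names(drug_z))) {
    genes <- intersect(intersect(names(twas_z), names(drug_z)), ann$gene_id)
    twas_z <- twas_z[genes]
    drug_z <- drug_z[genes]
    ann <- ann[match(genes, ann$gene_id), , drop = FALSE]
  } else if (length(twas_z) != nrow(ann) || length(drug_z) != nrow(ann)) {
    stop("unnamed Z vectors must align with the annotation rows",
         call. = FALSE)
  }
  n <- length(twas_z)
  if (n < 10) stop("fewer than 10 genes in common", call. = FALSE)
  if (weighted) {
    if (weight_mode == "signed") {
      twas_z <- weighted_z(twas_z)
      drug_z <- weighted_z(drug_z)
    } else {
      twas_z <- twas_z^2
      drug_z <- drug_z^2
    }
  }
  len <- if (log_length) log10(ann$gene_length) else ann$gene_length
  dat <- data.frame(twas = as.numeric(twas_z), drug = as.numeric(drug_z),
                    len = len, gc = ann$gc_fraction)
  if (any(vapply(dat[-1], function(v) stats::sd(v) == 0, logical(1))))
    stop("constant predictor or covariate", call. = FALSE)
  fit <- stats::lm(twas ~ drug + len + gc, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("collinear covariates in the TWAS model", call. = FALSE)
  sm <- summary(fit)$coefficients
  list(coef = unname(sm["drug", "Estimate"]),
       se = unname(sm["drug", "Std. Error"]),
       p = unname(sm["drug", "Pr(>|t|)"]),
       n = n, fit = fit)
}

#' TWAS regression scan over tissues, condition sets and weighting modes
#'
#' Fits [fit_twas_model()] for every combination of tissue (from the TWAS
#' table), condition set (from the convergence table's combined Z columns)
#' and weighting mode, then BH-adjusts the drug-term p-values across the
#' whole scan (one FDR family covering every fitted cell).
#'
#' @param twas `data.frame` with columns `gene_id`, `tissue`, `z`.
#' @param conv A [run_convergence()] table (its combined `z_<set>` columns
#'   supply the drug-effect Z-scores).
#' @param ann Gene annotation; see [fit_twas_model()].
#' @param sets Condition sets to scan; default: all sets in `conv`.
#' @param weighted Logical vector of weighting modes to scan
#'   (default `c(FALSE, TRUE)`).
#' @param ... Passed to [fit_twas_model()] (`weight_mode`, `log_length`).
#'
#' @return A `twas_scan`: `data.frame` with columns `tissue`,
#'   `condition_set`, `weighted`, `n`, `coef`, `se`, `p`, `q`. Combinations
#'   with an empty gene intersection are reported with `NA` statistics
#'   rather than failing.
#' @export
run_twas_scan <- function(twas, conv, ann, sets = NULL,
                          weighted = c(FALSE, TRUE), ...) {
  stopifnot(is.data.frame(twas),
            all(c("gene_id", "tissue", "z") %in% names(twas)))
  if (is.null(sets)) {
    sets <- sub("^z_", "", grep("^z_", names(conv), value = TRUE))
  }
  tissues <- unique(twas$tissue)
  if (length(tissues) < 1 || length(sets) < 1)
    stop("need at least one tissue and one condition set", call. = FALSE)
  grid <- expand.grid(tissue = tissues, condition_set = sets,
                      weighted = weighted, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ti <- grid$tissue[i]; se_t <- grid$condition_set[i]
    wt <- grid$weighted[i]
    tz <- twas[twas$tissue == ti, ]
    twas_z <- stats::setNames(tz$z, tz$gene_id)
    drug_z <- stats::setNames(conv[[paste0("z_", se_t)]], conv$gene_id)
    fit <- tryCatch(
      fit_twas_model(twas_z, drug_z, ann, weighted = wt, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      data.frame(tissue = ti, condition_set = se_t, weighted = wt,
                 n = 0L, coef = NA_real_, se = NA_real_, p = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(tissue = ti, condition_set = se_t, weighted = wt,
                 n = fit$n, coef = fit$coef, se = fit$se, p = fit$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  structure(out, class = c("twas_scan", "data.frame"))
}

#' @export
print.twas_scan <- function(x, ...) {
  cat(sprintf("twas_scan: %d tissue x set x weighting cells\n", nrow(x)))
  print.data.frame(x, digits = 3)
  invisible(x)
}
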