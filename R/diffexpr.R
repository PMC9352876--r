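#' Remove low-abundance genes
#'
#' Keeps exactly the genes whose abundance is at least `min_abundance` in at
#' least `ceiling(min_fraction * n_samples)` samples (by default 10 units of
#' abundance in 90% of samples). Sample metadata is untouched.
#'
#' @param matrix An [experiment_matrix()].
#' @param min_abundance Abundance threshold (>= 0).
#' @param min_fraction Required fraction of samples, in (0, 1].
#'
#' @return A filtered [experiment_matrix()].
#' @export
filter_low_expression <- function(matrix, min_abundance = 10,
                                  min_fraction = 0.9) {
  stopifnot(inherits(matrix, "experiment_matrix"))
  stop_field(min_abundance < 0, "min_abundance", "must be >= 0")
  stop_field(min_fraction <= 0 || min_fraction > 1, "min_fraction",
             "must lie in (0, 1]")
  n <- ncol(matrix$abundance)
  need <- ceiling(min_fraction * n)
  keep <- rowSums(matrix$abundance >= min_abundance) >= need
  if (!any(keep))
    stop("no genes retained by the low-expression filter", call. = FALSE)
  subset_experiment(matrix, genes = which(keep))
}

# Build the per-condition design matrix ~ plate + buffer + treatment from a
# metadata subset. Factors that are constant within the subset carry no
# information and are dropped (e.g. buffer, which is shared between a drug
# and its matched vehicle control). The treatment factor is releveled so the
# control arm is the reference and the drug coefficient is drug-vs-control.
build_design <- function(meta, drug, control) {
  meta$treatment <- factor(meta$treatment, levels = c(control, drug))
  terms <- c("plate", "buffer", "treatment")
  used <- terms[vapply(terms, function(f) length(unique(meta[[f]])) > 1,
                       logical(1))]
  if (!"treatment" %in% used)
    stop("treatment arm and control are indistinguishable in this subset",
         call. = FALSE)
  X <- stats::model.matrix(
    stats::reformulate(used),
    data = meta[, used, drop = FALSE]
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; confounded term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X
}

# Vectorised OLS of log2(abundance + 0.5) on a fixed design for a whole
# gene-by-sample block. Returns per-gene treatment coefficient, its standard
# error, the Wald statistic and a two-sided p-value from the chosen
# reference. `y_mat` is genes x samples on the log2 scale already.
ols_wald <- function(y_mat, X, coef_name, wald_reference = c("t", "normal")) {
  wald_reference <- match.arg(wald_reference)
  qrX <- qr(X)
  cf <- qr.coef(qrX, t(y_mat))
  if (is.null(dim(cf))) cf <- matrix(cf, ncol = 1)
  res <- t(y_mat) - X %*% cf
  df <- nrow(X) - ncol(X)
  if (df < 1)
    stop("no residual degrees of freedom in the design", call. = FALSE)
  s2 <- colSums(res^2) / df
  ci <- chol2inv(chol(crossprod(X)))[match(coef_name, colnames(X)),
                                     match(coef_name, colnames(X))]
  beta <- cf[coef_name, ]
  se <- sqrt(pmax(s2, 0) * ci)
  se[s2 < .Machine$double.eps * 100] <- 0  # exact-fit sentinel
  stat <- ifelse(se > 0, beta / se, 0)
  if (wald_reference == "t") {
    logp <- pt(abs(stat), df = df, lower.tail = FALSE, log.p = TRUE) + log(2)
  } else {
    logp <- pnorm(abs(stat), lower.tail = FALSE, log.p = TRUE) + log(2)
  }
  p <- pmin(exp(logp), 1)
  # calibrated z: signed normal quantile of the two-sided p, so that the
  # null distribution is N(0,1) whichever reference produced p; identical
  # to beta/se under the normal reference
  z <- signed_z_from_logp(logp, sign(beta))
  z[beta == 0] <- 0
  # degenerate (zero residual variance) genes: exact fit; coefficients at
  # solver noise level count as exactly zero
  if (any(se == 0)) {
    idx <- which(se == 0)
    null_beta <- abs(beta[idx]) < 1e-8
    beta[idx][null_beta] <- 0
    z[idx] <- ifelse(beta[idx] == 0, 0, sign(beta[idx]) * Inf)
    p[idx] <- ifelse(beta[idx] == 0, 1, 0)
  }
  list(beta = unname(beta), se = unname(se), z = unname(z), p = unname(p),
       df = df)
}

#' Fit the per-gene differential-expression model for one gene
#'
#' Ordinary least squares of log2-transformed abundance (`log2(x + 0.5)`) on
#' an intercept plus plate, buffer and treatment dummies, returning the
#' treatment coefficient (log2 fold change), its standard error, the Wald
#' statistic and a two-sided p-value.
#'
#' With `wald_reference = "t"` (the default) the p-value uses the Student-t
#' reference with the fit's residual degrees of freedom — the calibrated
#' choice at the small replicate numbers typical of cell-line screens — and
#' the reported `z` is the signed standard-normal quantile of that p-value,
#' so `z` is N(0,1) under the null and ready for Stouffer combination. With
#' `wald_reference = "normal"`, `z = beta/se` exactly and p comes from the
#' normal reference.
#'
#' @param y Per-sample abundance vector (raw scale; log2(x+0.5) is applied).
#' @param design `data.frame` with columns `plate`, `buffer`, `treatment`;
#'   `treatment` must have exactly two levels, control listed first or given
#'   via `control`.
#' @param control,drug Treatment levels defining the contrast. Defaults:
#'   first and second level of `design$treatment`.
#' @param wald_reference `"t"` (default) or `"normal"`.
#'
#' @return List with `beta` (log2 fold change), `se`, `z`, `p`, `df`.
#' @export
fit_gene_model <- function(y, design, control = NULL, drug = NULL,
                           wald_reference = c("t", "normal")) {
  wald_reference <- match.arg(wald_reference)
  stopifnot(is.numeric(y), nrow(design) == length(y))
  lev <- unique(as.character(design$treatment))
  if (is.null(control)) control <- lev[1]
  if (is.null(drug)) drug <- setdiff(lev, control)[1]
  X <- build_design(design, drug = drug, control = control)
  coef_name <- paste0("treatment", drug)
  out <- ols_wald(matrix(log2(y + 0.5), nrow = 1), X, coef_name,
                  wald_reference)
  list(beta = out$beta, se = out$se, z = out$z, p = out$p, df = out$df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`, preserving input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, elementwise >= `p` and <= 1.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Differential expression for one (cell type, drug) condition
#'
#' Subsets the experiment to the requested cell type, the drug arm and its
#' matched vehicle control, applies the low-abundance filter, fits every
#' retained gene with [fit_gene_model()]'s design, and BH-adjusts the
#' p-values across retained genes.
#'
#' @param matrix An [experiment_matrix()].
#' @param cell_type Cell-type label to analyse.
#' @param drug Drug arm label.
#' @param control Matched control arm; by default looked up from the
#'   conventional pairing (`h2o` for propranolol, `dmso` for primidone).
#' @param min_abundance,min_fraction Passed to [filter_low_expression()].
#' @param wald_reference Passed to the per-gene fit; see [fit_gene_model()].
#'
#' @return A `de_result`: a `data.frame` with columns `gene_id`, `log2fc`,
#'   `se`, `z`, `p`, `q`, sorted by `q` ascending (ties broken by gene id),
#'   with the condition recorded in attributes `cell_type`, `drug`,
#'   `control` and `condition`.
#' @export
#' @examples
#' sim <- generate_experiment(sim_config(n_genes = 300, seed = 2))
#' de <- run_de(sim$matrix, "daoy", "propranolol")
#' summary(de)
run_de <- function(matrix, cell_type, drug, control = NULL,
                   min_abundance = 10, min_fraction = 0.9,
                   wald_reference = c("t", "normal")) {
  wald_reference <- match.arg(wald_reference)
  stopifnot(inherits(matrix, "experiment_matrix"))
  meta <- matrix$sample_meta
  if (!cell_type %in% meta$cell_type)
    stop("cell type '", cell_type, "' absent from the experiment",
         call. = FALSE)
  if (is.null(control)) {
    default_controls <- c(propranolol = "h2o", primidone = "dmso")
    if (!drug %in% names(default_controls))
      stop("no default control known for drug '", drug,
           "'; supply `control`", call. = FALSE)
    control <- default_controls[[drug]]
  }
  for (arm in c(drug, control)) {
    if (!any(meta$cell_type == cell_type & meta$treatment == arm))
      stop("arm '", arm, "' absent for cell type '", cell_type, "'",
           call. = FALSE)
  }
  sel <- which(meta$cell_type == cell_type &
                 meta$treatment %in% c(drug, control))
  sub <- subset_experiment(matrix, samples = sel)
  sub <- filter_low_expression(sub, min_abundance, min_fraction)

  X <- build_design(sub$sample_meta, drug = drug, control = control)
  fit <- ols_wald(log2(sub$abundance + 0.5), X, paste0("treatment", drug),
                  wald_reference)
  res <- data.frame(gene_id = sub$gene_ids,
                    log2fc = fit$beta, se = fit$se, z = fit$z, p = fit$p,
                    stringsAsFactors = FALSE)
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("de_result", "data.frame"),
            cell_type = cell_type, drug = drug, control = control,
            condition = condition_label(cell_type, drug),
            wald_reference = wald_reference, df = fit$df)
}

#' @export
print.de_result <- function(x, n = 6, ...) {
  cat(sprintf("de_result: %s vs %s in %s (%d genes, %s reference)\n",
              attr(x, "drug"), attr(x, "control"), attr(x, "cell_type"),
              nrow(x), attr(x, "wald_reference")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' @export
summary.de_result <- function(object, q_threshold = 0.05, ...) {
  sig <- object$q < q_threshold
  out <- list(condition = attr(object, "condition"),
              n_genes = nrow(object),
              n_deg = sum(sig),
              n_up = sum(sig & object$log2fc > 0),
              n_down = sum(sig & object$log2fc < 0),
              q_threshold = q_threshold)
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("condition %s: %d genes tested, %d DEGs at q < %g (%d up, %d down)\n",
              x$condition, x$n_genes, x$n_deg, x$q_threshold, x$n_up,
              x$n_down))
  invisible(x)
}

#' @export
coef.de_result <- function(object, ...) {
  stats::setNames(object$log2fc, object$gene_id)
}

#' Volcano plot of a differential-expression result
#'
#' @param x A `de_result`.
#' @param q_threshold Significance threshold drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.de_result <- function(x, q_threshold = 0.05, ...) {
  sig <- x$q < q_threshold
  graphics::plot(x$log2fc, -log10(pmax(x$p, 1e-300)),
                 col = ifelse(sig, "firebrick", "grey50"), pch = 16,
                 cex = 0.5, xlab = "log2 fold change",
                 ylab = "-log10 p",
                 main = paste("volcano:", attr(x, "condition")), ...)
  graphics::abline(v = c(-0.5, 0.5), col = "steelblue", lty = 2)
  invisible(x)
}
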