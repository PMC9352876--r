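#' Transform an o/e constraint score to a percentage
#'
#' Loss-of-function observed/expected scores are displayed as percentages:
#' a score is multiplied by 100 (0.25 becomes 25%), and scores over 10 are
#' counted as 100%. The cap affects only display histograms; statistical
#' comparisons run on the raw o/e scale.
#'
#' @param score Numeric vector of o/e scores (>= 0).
#' @return Percentages.
#' @export
#' @examples
#' oe_to_percent(c(0.25, 12))  # 25, 100
oe_to_percent <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0))
    stop("o/e scores must be nonnegative numbers", call. = FALSE)
  ifelse(score > 10, 100, score * 100)
}

#' Propensity scores for DEG membership given gene covariates
#'
#' Logistic regression of the DEG indicator on coding-sequence length and
#' GC fraction (maximum likelihood via [stats::glm()]); the fitted
#' probabilities are the propensity scores used to match comparable
#' background genes.
#'
#' @param ann Gene annotation `data.frame` with the covariate columns.
#' @param deg_flags Logical (or 0/1) vector, one per annotation row.
#' @param covariates Covariate column names (default `cds_length`,
#'   `gc_fraction`). Constant covariates are dropped; with no informative
#'   covariate left the fit is intercept-only and every score equals the
#'   DEG prevalence.
#' @return Numeric vector of fitted probabilities in (0, 1), one per gene;
#'   the fitted [stats::glm()] object is attached as attribute `"fit"`.
#' @export
propensity_scores <- function(ann, deg_flags,
                              covariates = c("cds_length", "gc_fraction")) {
  stopifnot(is.data.frame(ann), length(deg_flags) == nrow(ann))
  missing_cov <- setdiff(covariates, names(ann))
  if (length(missing_cov))
    stop("covariate(s) absent from annotation: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  flags <- as.logical(deg_flags)
  if (all(flags) || !any(flags))
    stop("both DEG and background classes must be non-empty", call. = FALSE)
  # constant covariates carry no information; with none left the model is
  # intercept-only and every score equals the DEG prevalence
  informative <- covariates[vapply(covariates,
                                   function(cv) stats::sd(ann[[cv]]) > 0,
                                   logical(1))]
  dat <- ann[, informative, drop = FALSE]
  dat$.deg <- flags
  rhs <- if (length(informative)) informative else "1"
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(rhs, response = ".deg"),
               data = dat, family = stats::binomial())
  )
  pr <- stats::fitted(fit)
  if (any(pr < 1e-12) || any(pr > 1 - 1e-12)) {
    # fitted probabilities pinned at 0/1 indicate (quasi-)separation
    if (!fit$converged || max(abs(stats::coef(fit))) > 1e3)
      stop("perfect separation in the propensity model; inspect covariates",
           call. = FALSE)
  }
  structure(unname(pr), fit = fit)
}

#' Nearest-neighbour matching with replacement on propensity scores
#'
#' For each treated unit, selects the `ratio` control units with the
#' smallest absolute propensity-score difference. Controls may be reused
#' across treated units (matching with replacement) but appear at most once
#' within one treated unit's match set. Ties in distance are broken by the
#' smallest control index, so the matching is deterministic.
#'
#' @param treated_scores Numeric vector of treated-unit scores.
#' @param control_scores Numeric vector of control-unit scores (>= `ratio`
#'   units).
#' @param ratio Matches per treated unit (>= 1).
#' @return Integer matrix (`length(treated_scores)` x `ratio`) of control
#'   indices; `as.vector()` of it is the matched multiset.
#' @export
#' @examples
#' nn_match_with_replacement(0.5, c(0.48, 0.3, 0.9), 2)  # indices 1, 2
nn_match_with_replacement <- function(treated_scores, control_scores,
                                      ratio) {
  stopifnot(is.numeric(treated_scores), is.numeric(control_scores))
  if (length(control_scores) == 0)
    stop("no control units to match against", call. = FALSE)
  stop_field(ratio < 1 || ratio != trunc(ratio), "ratio",
             "must be a positive integer")
  stop_field(ratio > length(control_scores), "ratio",
             "cannot exceed the number of controls")
  idx <- vapply(treated_scores, function(s) {
    d <- abs(control_scores - s)
    order(d, seq_along(control_scores))[seq_len(ratio)]
  }, integer(ratio))
  m <- if (ratio == 1) matrix(idx, ncol = 1) else t(idx)
  dimnames(m) <- NULL
  m
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` for the first sample (midranks for ties) with a
#' two-sided p-value: exact by complete enumeration of all
#' `choose(n_x + n_y, n_x)` group assignments when `n_x + n_y <= exact_max`,
#' otherwise the normal approximation with tie and continuity correction
#' (via [stats::wilcox.test()]).
#'
#' Note `W` here is the rank sum, not the Mann-Whitney U that
#' [stats::wilcox.test()] reports; the two differ by `n_x (n_x + 1) / 2`.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_max Largest combined sample size for exact enumeration
#'   (default 12).
#' @return List with `W` (rank sum of `x`) and `p` (two-sided).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))$p  # exact: 1/3
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max) {
    # exact two-sided p: P(|W* - mu| >= |W - mu|) over all assignments
    combs <- utils::combn(n, nx)
    Wstar <- colSums(matrix(r[combs], nrow = nx))
    p <- mean(abs(Wstar - mu) >= abs(W - mu) - 1e-9)
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
  list(W = W, p = p)
}

# absolute standardized mean difference of a covariate between two groups
smd <- function(a, b) {
  sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (sp == 0) return(0)
  abs(mean(a) - mean(b)) / sp
}

#' Constraint comparison of DEG sets against matched background genes
#'
#' For each DEG set (typically `all`, `up`, `down` convergent genes),
#' compares loss-of-function o/e scores against background genes matched on
#' coding-sequence length and GC fraction: a logistic propensity model
#' ([propensity_scores()]), nearest-neighbour matching with replacement at
#' `ratio` matches per DEG ([nn_match_with_replacement()]), then a
#' two-sample Wilcoxon rank-sum test ([wilcoxon_rank_sum()]) of DEG o/e
#' versus matched-background o/e.
#'
#' The default ratio is the maximum number of matches,
#' `floor(n_background / n_deg)`, per set.
#'
#' @param ann Gene annotation with `gene_id`, `oe_score` and the matching
#'   covariates.
#' @param deg_sets Named list of character gene-id vectors.
#' @param ratio Matches per DEG; a single number, a named vector per set,
#'   or `NULL` (default) for `floor(n_background / n_deg)`.
#' @param covariates Matching covariates (default `cds_length`,
#'   `gc_fraction`).
#'
#' @return A `constraint_report`: `data.frame` with one row per set:
#'   `set`, `n_deg`, `n_background`, `ratio`, `median_deg_oe`,
#'   `median_bg_oe`, `W`, `p`, and pre-/post-matching standardized mean
#'   differences per covariate (`smd_pre_*`, `smd_post_*`). The matched
#'   index multisets are attached as attribute `"matches"`, and the
#'   percentage-scale o/e distributions ([oe_to_percent()]) as attribute
#'   `"percent"`.
#' @export
run_constraint_analysis <- function(ann, deg_sets, ratio = NULL,
                                    covariates = c("cds_length",
                                                   "gc_fraction")) {
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "oe_score") %in% names(ann)))
  if (!is.list(deg_sets) || is.null(names(deg_sets)))
    stop("'deg_sets' must be a named list of gene-id vectors", call. = FALSE)
  matches <- list(); percent <- list()
  rows <- lapply(names(deg_sets), function(nm) {
    genes <- unique(deg_sets[[nm]])
    unknown <- setdiff(genes, ann$gene_id)
    if (length(unknown))
      stop("DEG set '", nm, "' contains genes absent from the annotation",
           call. = FALSE)
    if (length(genes) < 5)
      stop("DEG set '", nm, "' has fewer than 5 annotated genes",
           call. = FALSE)
    flags <- ann$gene_id %in% genes
    n_deg <- sum(flags); n_bg <- sum(!flags)
    rt <- if (is.null(ratio)) {
      max(1L, n_bg %/% n_deg)
    } else if (!is.null(names(ratio))) {
      as.integer(ratio[[nm]])
    } else {
      as.integer(ratio[1])
    }
    scores <- propensity_scores(ann, flags, covariates)
    m <- nn_match_with_replacement(scores[flags], scores[!flags], rt)
    bg_rows <- which(!flags)[as.vector(m)]
    w <- wilcoxon_rank_sum(ann$oe_score[flags], ann$oe_score[bg_rows])
    matches[[nm]] <<- matrix(which(!flags)[m], nrow = nrow(m))
    percent[[nm]] <<- list(deg = oe_to_percent(ann$oe_score[flags]),
                           background = oe_to_percent(ann$oe_score[bg_rows]))
    out <- data.frame(set = nm, n_deg = n_deg, n_background = n_bg,
                      ratio = rt,
                      median_deg_oe = stats::median(ann$oe_score[flags]),
                      median_bg_oe = stats::median(ann$oe_score[bg_rows]),
                      W = w$W, p = w$p, stringsAsFactors = FALSE)
    for (cv in covariates) {
      out[[paste0("smd_pre_", cv)]] <- smd(ann[[cv]][flags],
                                           ann[[cv]][!flags])
      out[[paste0("smd_post_", cv)]] <- smd(ann[[cv]][flags],
                                            ann[[cv]][bg_rows])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("constraint_report", "data.frame"),
            matches = matches, percent = percent, covariates = covariates)
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("constraint_report (o/e of DEG sets vs matched background):\n")
  show <- x[, c("set", "n_deg", "ratio", "median_deg_oe", "median_bg_oe",
                "W", "p")]
  print.data.frame(show, digits = 4)
  invisible(x)
}

#' @export
summary.constraint_report <- function(object, ...) {
  print(object)
  cvs <- attr(object, "covariates")
  cat("covariate balance (absolute standardized mean difference):\n")
  for (cv in cvs) {
    cat(sprintf("  %-12s pre %s  post %s\n", cv,
                paste(sprintf("%.3f", object[[paste0("smd_pre_", cv)]]),
                      collapse = "/"),
                paste(sprintf("%.3f", object[[paste0("smd_post_", cv)]]),
                      collapse = "/")))
  }
  invisible(object)
}
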