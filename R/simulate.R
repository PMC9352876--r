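#' Simulation settings for a synthetic drug-treatment experiment
#'
#' Describes a two-cell-line, two-drug treatment screen: each cell line is
#' exposed to each drug arm and its matched vehicle control (water for
#' propranolol, DMSO for primidone), with replicates split across two culture
#' plates. Counts are drawn from a negative-binomial model on a log-linear
#' mean (gene baseline + plate effect + buffer effect + treatment effect).
#'
#' A configured fraction of genes carries a shared ("convergent") treatment
#' effect of identical sign and magnitude in every (cell type, drug)
#' condition; a second fraction carries an effect in exactly one condition.
#' All effect magnitudes equal `effect_size_log2`, so recovery statements
#' against the returned truth table are exact.
#'
#' @param n_genes Number of genes (> 0).
#' @param n_replicates Samples per (cell type, arm) combination.
#' @param cell_types Character vector of cell-line labels.
#' @param arms Character vector of the four arms, in the order drug 1, its
#'   control, drug 2, its control. Odd positions are treated as drugs, each
#'   followed by its matched vehicle; buffer is shared within each pair.
#' @param frac_convergent Fraction of genes with a shared drug effect in all
#'   conditions, in \[0, 1\].
#' @param frac_condition_specific Fraction with an effect in exactly one
#'   condition, in \[0, 1\]. `frac_convergent + frac_condition_specific`
#'   must not exceed 1.
#' @param effect_size_log2 Magnitude of every true log2 fold change (> 0
#'   whenever either fraction is positive).
#' @param dispersion Negative-binomial dispersion (> 0); the NB size
#'   parameter is `1/dispersion`.
#' @param plate_sd,buffer_sd Standard deviations (log2 scale, >= 0) of
#'   gene-specific plate and buffer nuisance effects.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-gene
#'   baseline log2 abundance.
#' @param twas_rho Target correlation carried by [generate_twas()] when
#'   driven from this configuration, in \[-1, 1\].
#' @param seed Integer master seed; all generator randomness flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_experiment()]
#' @export
sim_config <- function(n_genes = 5000,
                       n_replicates = 3,
                       cell_types = c("daoy", "npc"),
                       arms = c("propranolol", "h2o", "primidone", "dmso"),
                       frac_convergent = 0.025,
                       frac_condition_specific = 0.10,
                       effect_size_log2 = 1,
                       dispersion = 0.05,
                       plate_sd = 0.15,
                       buffer_sd = 0.15,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       twas_rho = 0,
                       seed = 1L) {
  stop_field(!is.numeric(n_genes) || n_genes < 1, "n_genes",
             "must be a positive integer")
  stop_field(!is.numeric(n_replicates) || n_replicates < 2, "n_replicates",
             "need at least 2 replicates per arm")
  stop_field(length(cell_types) < 1 || anyDuplicated(cell_types) > 0,
             "cell_types", "must be non-empty unique labels")
  stop_field(length(arms) != 4 || anyDuplicated(arms) > 0, "arms",
             "must be four unique labels (drug1, control1, drug2, control2)")
  stop_field(frac_convergent < 0 || frac_convergent > 1, "frac_convergent",
             "must lie in [0, 1]")
  stop_field(frac_condition_specific < 0 || frac_condition_specific > 1,
             "frac_condition_specific", "must lie in [0, 1]")
  stop_field(frac_convergent + frac_condition_specific > 1,
             "frac_convergent", paste("frac_convergent +",
             "frac_condition_specific must not exceed 1"))
  stop_field(dispersion <= 0, "dispersion", "must be > 0")
  stop_field(plate_sd < 0, "plate_sd", "must be >= 0")
  stop_field(buffer_sd < 0, "buffer_sd", "must be >= 0")
  stop_field(abs(twas_rho) > 1, "twas_rho", "must lie in [-1, 1]")
  stop_field((frac_convergent + frac_condition_specific) > 0 &&
               effect_size_log2 <= 0,
             "effect_size_log2", "must be > 0 when true effects are present")
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         cell_types = as.character(cell_types),
         arms = as.character(arms),
         frac_convergent = frac_convergent,
         frac_condition_specific = frac_condition_specific,
         effect_size_log2 = effect_size_log2,
         dispersion = dispersion,
         plate_sd = plate_sd, buffer_sd = buffer_sd,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         twas_rho = twas_rho,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  %d genes; %d replicates per arm; cell types: %s\n",
              x$n_genes, x$n_replicates, paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  arms: %s\n", paste(x$arms, collapse = ", ")))
  cat(sprintf("  convergent %.1f%%, condition-specific %.1f%%, |log2FC| = %g\n",
              100 * x$frac_convergent, 100 * x$frac_condition_specific,
              x$effect_size_log2))
  cat(sprintf("  dispersion %g; plate sd %g; buffer sd %g; seed %d\n",
              x$dispersion, x$plate_sd, x$buffer_sd, x$seed))
  invisible(x)
}

# Short label for a (cell type, drug) condition, e.g. "daoy_prop".
condition_label <- function(cell_type, drug) {
  short <- c(propranolol = "prop", primidone = "prim")
  d <- ifelse(drug %in% names(short), unname(short[drug]), drug)
  paste0(cell_type, "_", d)
}

# drug arm -> matched vehicle-control arm, from the arms vector layout
control_map <- function(arms) {
  stats::setNames(arms[c(2, 4)], arms[c(1, 3)])
}

#' Generate a synthetic treatment experiment with ground truth
#'
#' Draws a gene-by-sample count matrix under the design described in
#' [sim_config()]: negative-binomial counts whose log2 mean is the sum of a
#' gene baseline, a gene-specific plate effect, a gene-specific buffer
#' effect, and — for truth-flagged genes in their flagged conditions — a
#' treatment effect. Replicates within each (cell type, arm) are assigned
#' alternately to two plates so that plate crosses treatment.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `convergex_sim` with elements:
#' \describe{
#'   \item{matrix}{An [experiment_matrix()] of counts plus sample metadata
#'     (`cell_type`, `treatment`, `buffer`, `plate`).}
#'   \item{truth}{`data.frame` with one row per gene: `gene_id`,
#'     `convergent` and `specific` flags, and one `effect_<condition>`
#'     column of true log2 fold changes per (cell type, drug) condition.}
#' }
#' Identical configs (including seed) give byte-identical output.
#' @export
#' @examples
#' sim <- generate_experiment(sim_config(n_genes = 200, seed = 7))
#' sim$matrix
#' table(sim$truth$convergent)
generate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  cfg <- config
  drugs <- cfg$arms[c(1, 3)]
  buffers <- stats::setNames(rep(cfg$arms[c(2, 4)], each = 2),
                             cfg$arms[c(1, 2, 3, 4)])
  conds <- as.vector(outer(cfg$cell_types, drugs, condition_label))
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))

  with_seed(cfg$seed, {
    n_conv <- round(cfg$frac_convergent * cfg$n_genes)
    n_spec <- round(cfg$frac_condition_specific * cfg$n_genes)
    flagged <- sample.int(cfg$n_genes, n_conv + n_spec)
    conv_idx <- flagged[seq_len(n_conv)]
    spec_idx <- flagged[n_conv + seq_len(n_spec)]

    effects <- matrix(0, cfg$n_genes, length(conds),
                      dimnames = list(gene_ids, conds))
    if (n_conv > 0) {
      s <- sample(c(-1, 1), n_conv, replace = TRUE)
      effects[conv_idx, ] <- s * cfg$effect_size_log2
    }
    if (n_spec > 0) {
      which_cond <- sample.int(length(conds), n_spec, replace = TRUE)
      s <- sample(c(-1, 1), n_spec, replace = TRUE)
      effects[cbind(spec_idx, which_cond)] <- s * cfg$effect_size_log2
    }

    baseline <- rnorm(cfg$n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    plate_eff <- matrix(rnorm(cfg$n_genes * 2, 0, cfg$plate_sd),
                        cfg$n_genes, 2, dimnames = list(NULL, c("p1", "p2")))
    buf_levels <- unique(unname(buffers))
    buffer_eff <- matrix(rnorm(cfg$n_genes * length(buf_levels), 0,
                               cfg$buffer_sd),
                         cfg$n_genes, length(buf_levels),
                         dimnames = list(NULL, buf_levels))

    meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                        treatment = cfg$arms, cell_type = cfg$cell_types,
                        stringsAsFactors = FALSE)
    meta$buffer <- buffers[meta$treatment]
    meta$plate <- ifelse(meta$replicate %% 2L == 1L, "p1", "p2")
    meta$sample_id <- sprintf("%s_%s_%d", meta$cell_type, meta$treatment,
                              meta$replicate)

    mu_log2 <- matrix(baseline, cfg$n_genes, nrow(meta))
    for (j in seq_len(nrow(meta))) {
      mu_log2[, j] <- mu_log2[, j] +
        plate_eff[, meta$plate[j]] + buffer_eff[, meta$buffer[j]]
      if (meta$treatment[j] %in% drugs) {
        mu_log2[, j] <- mu_log2[, j] +
          effects[, condition_label(meta$cell_type[j], meta$treatment[j])]
      }
    }
    counts <- matrix(rnbinom(length(mu_log2), mu = 2^mu_log2,
                             size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes,
                     dimnames = list(gene_ids, meta$sample_id))

    truth <- data.frame(gene_id = gene_ids,
                        convergent = seq_len(cfg$n_genes) %in% conv_idx,
                        specific = seq_len(cfg$n_genes) %in% spec_idx,
                        stringsAsFactors = FALSE)
    for (cond in conds) truth[[paste0("effect_", cond)]] <- effects[, cond]

    structure(
      list(matrix = experiment_matrix(
             counts,
             meta[, c("cell_type", "treatment", "buffer", "plate")]),
           truth = truth, config = cfg),
      class = "convergex_sim"
    )
  })
}

#' @export
print.convergex_sim <- function(x, ...) {
  cat("convergex_sim (synthetic treatment experiment)\n")
  print(x$matrix)
  cat(sprintf("  truth: %d convergent, %d condition-specific genes\n",
              sum(x$truth$convergent), sum(x$truth$specific)))
  invisible(x)
}

#' Generate synthetic per-gene annotation with a constrained subpopulation
#'
#' Emulates the per-gene annotation the constraint and TWAS analyses consume:
#' gene length (bp), GC fraction, coding-sequence length (bp) and a
#' loss-of-function observed/expected (o/e) score in the style of gnomAD
#' LOEUF. A configurable fraction of genes forms a mutationally constrained
#' subpopulation centred at a low o/e; constrained genes are also given
#' longer coding sequences and slightly higher GC, so that constraint status
#' is confounded with the matching covariates (as it is in real data).
#'
#' @param n_genes Number of genes (> 0).
#' @param frac_constrained Fraction of genes in the constrained
#'   subpopulation, in \[0, 1\].
#' @param seed Integer seed.
#'
#' @return `data.frame` with columns `gene_id`, `gene_length`,
#'   `gc_fraction`, `cds_length`, `oe_score`, and the truth flag
#'   `constrained`. `cds_length <= gene_length` always holds.
#' @export
generate_gene_annotation <- function(n_genes, frac_constrained = 0.15,
                                     seed = 1L) {
  stop_field(!is.numeric(n_genes) || n_genes < 1, "n_genes",
             "must be a positive integer")
  stop_field(frac_constrained < 0 || frac_constrained > 1,
             "frac_constrained", "must lie in [0, 1]")
  n_genes <- as.integer(n_genes)
  with_seed(seed, {
    n_con <- round(frac_constrained * n_genes)
    constrained <- seq_len(n_genes) %in% sample.int(n_genes, n_con)
    gene_length <- pmax(round(rlnorm(n_genes, log(2e4), 0.9)), 300)
    cds <- rlnorm(n_genes, log(1300), 0.45) * ifelse(constrained, 2, 1)
    cds_length <- pmin(round(cds), gene_length)
    gc <- rbeta(n_genes, 60, 90) + ifelse(constrained, 0.05, 0)
    gc_fraction <- pmin(pmax(gc, 0.01), 0.99)
    oe <- ifelse(constrained,
                 rlnorm(n_genes, log(0.15), 0.35),
                 rlnorm(n_genes, log(0.40), 0.55))
    data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
               gene_length = gene_length, gc_fraction = gc_fraction,
               cds_length = cds_length, oe_score = oe,
               constrained = constrained, stringsAsFactors = FALSE)
  })
}

#' Generate TWAS Z-scores correlated with drug-effect Z-scores
#'
#' Builds a per-gene TWAS Z-score vector whose Pearson correlation with the
#' supplied drug-effect Z-scores converges to `rho`. The construction is a
#' Gaussian copula: the drug scores are mapped to normal scores through
#' their ranks, mixed with independent Gaussian noise, so the output is
#' standard-normal marginally whatever the input's shape. At `|rho| = 1`
#' the degenerate limit is returned: the standardized (affine-transformed)
#' input itself, giving sample correlation exactly +/-1.
#'
#' @param drug_z Named or unnamed numeric vector of finite Z-scores.
#' @param rho Target correlation in \[-1, 1\].
#' @param seed Integer seed.
#'
#' @return Numeric vector of TWAS Z-scores, same length and names as
#'   `drug_z`.
#' @export
generate_twas <- function(drug_z, rho, seed = 1L) {
  stop_field(!is.numeric(drug_z) || length(drug_z) < 2, "drug_z",
             "must be a numeric vector of length >= 2")
  stop_field(any(!is.finite(drug_z)), "drug_z", "must be finite")
  stop_field(!is.numeric(rho) || length(rho) != 1 || is.na(rho) ||
               abs(rho) > 1, "rho", "must lie in [-1, 1]")
  n <- length(drug_z)
  out <- if (abs(rho) == 1) {
    s <- stats::sd(drug_z)
    stop_field(s == 0, "drug_z", "has zero variance; cannot target |rho| = 1")
    sign(rho) * (drug_z - mean(drug_z)) / s
  } else {
    with_seed(seed, {
      z1 <- qnorm(rank(drug_z, ties.method = "average") / (n + 1))
      rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    })
  }
  names(out) <- names(drug_z)
  out
}

#' Generate a synthetic cell-type average-expression profile
#'
#' Emulates a genes-by-cell-types matrix of average expression counts (the
#' derived form of single-cell/single-nucleus data the enrichment analysis
#' consumes): log-normal per-gene baselines, multiplicative gamma noise per
#' (gene, cell type), and a multiplicative `fold` bump for each enriched
#' gene set in its target cell type.
#'
#' @param n_genes Number of genes (> 0).
#' @param cell_types Character vector of cell-type labels (default: ten
#'   cerebellar populations).
#' @param enriched_sets Named list; each element is a list with components
#'   `genes` (character gene ids) and `cell_type` (a label from
#'   `cell_types`). May be empty (no enrichment; exchangeable columns).
#' @param fold Enrichment fold-change (> 1).
#' @param seed Integer seed.
#' @param gene_ids Gene identifiers; default `sprintf("g%05d", 1:n_genes)`,
#'   matching the other generators.
#'
#' @return Numeric matrix (genes x cell types, dimnames set), entries >= 0,
#'   with the enrichment ground truth attached as attribute
#'   `"enriched_truth"` (a data.frame geneset/cell_type).
#' @export
generate_sc_profiles <- function(n_genes,
                                 cell_types = c("Purk1", "Purk2", "Ast",
                                                "OPC", "Oli", "Mic", "End",
                                                "Gran", "Per", "Epend"),
                                 enriched_sets = list(),
                                 fold = 2,
                                 seed = 1L,
                                 gene_ids = sprintf("g%05d", seq_len(n_genes))) {
  stop_field(!is.numeric(n_genes) || n_genes < 1, "n_genes",
             "must be a positive integer")
  stop_field(length(cell_types) < 2 || anyDuplicated(cell_types) > 0,
             "cell_types", "must be >= 2 unique labels")
  stop_field(fold <= 1, "fold",
             "must be > 1 (no enrichment expressible otherwise)")
  n_genes <- as.integer(n_genes)
  stopifnot(length(gene_ids) == n_genes)
  for (nm in names(enriched_sets)) {
    s <- enriched_sets[[nm]]
    stop_field(!all(s$genes %in% gene_ids), "enriched_sets",
               sprintf("gene set '%s' names genes absent from the profile", nm))
    stop_field(!(s$cell_type %in% cell_types), "enriched_sets",
               sprintf("gene set '%s' targets unknown cell type '%s'",
                       nm, s$cell_type))
  }
  with_seed(seed, {
    lambda <- rlnorm(n_genes, meanlog = 1, sdlog = 0.5)
    noise <- matrix(rgamma(n_genes * length(cell_types), shape = 10,
                           rate = 10),
                    n_genes, length(cell_types))
    prof <- lambda * noise
    dimnames(prof) <- list(gene_ids, cell_types)
    for (s in enriched_sets) {
      prof[s$genes, s$cell_type] <- prof[s$genes, s$cell_type] * fold
    }
    truth <- data.frame(
      geneset = names(enriched_sets) %||% character(),
      cell_type = vapply(enriched_sets, function(s) s$cell_type,
                         character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
    attr(prof, "enriched_truth") <- truth
    prof
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
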