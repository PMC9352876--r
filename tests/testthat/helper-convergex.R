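# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as direct transcriptions of the definitions (brute
# force), independent of the package's implementation paths.

# brute-force BH step-up: q_i = min_{j: p_(j) >= p_(i)} min(1, m p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[i] - 1e-15)
    q[i] <- min(1, min(m * p[o][js] / js))
  }
  q
}

# brute-force exact two-sided Wilcoxon by complete enumeration of group
# assignments over the pooled sample (midranks)
wilcox_brute <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  Wall <- apply(utils::combn(n, nx), 2, function(ix) sum(r[ix]))
  list(W = W, p = mean(abs(Wall - mu) >= abs(W - mu) - 1e-9))
}

# four per-condition DE fits over one simulated experiment
run_four_de <- function(mat, ...) {
  conds <- list(c("daoy", "propranolol"), c("daoy", "primidone"),
                c("npc", "propranolol"), c("npc", "primidone"))
  lapply(conds, function(cd) run_de(mat, cd[1], cd[2], ...))
}

# tiny hand-built experiment: 2 genes x 6 samples, one cell type
tiny_experiment <- function(abundance = NULL) {
  if (is.null(abundance)) {
    abundance <- matrix(c(100, 110, 90, 200, 210, 190,
                          50, 55, 45, 52, 48, 50),
                        nrow = 2, byrow = TRUE,
                        dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  }
  meta <- data.frame(
    cell_type = "daoy",
    treatment = rep(c("h2o", "propranolol"), each = 3),
    buffer = "h2o",
    plate = c("p1", "p2", "p1", "p1", "p2", "p1")
  )
  experiment_matrix(abundance, meta)
}
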