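# Shared fixtures for the test suite.

# The two calibration/training circuit designs.
genes_train1 <- c("GFPmCherry", "GFP", "STOP", "GFP")
genes_train2 <- c("GFPmCherry", "STOP", "mCherry", "mCherry")

# Printed observed/ideal vector pairs used as metric golden data.
golden_vectors <- list(
  c1 = list(obs = c(42, 53, 34, 46, 44, 59, 55, 69), ideal = rep(100, 8), n = 8),
  c2 = list(obs = c(0, 0, 0, 2, 0, 0, 0, 89), ideal = c(0, 0, 0, 0, 0, 0, 0, 100), n = 1),
  c3 = list(obs = c(67, 76, 60, 2, 6, 13, 77, 0), ideal = c(100, 100, 100, 0, 0, 0, 100, 0), n = 4),
  c4 = list(obs = c(63, 73, 1, 7, 4, 88, 0, 92), ideal = c(100, 100, 0, 0, 0, 100, 0, 100), n = 4)
)

# Short SSA runs for structural tests where the full 10000-event budget is
# not needed.
quick_ssa <- function(n = 1500) ssa_config(max_reactions = n)

circuit_genes <- getFromNamespace("circuit_genes", "bladesim")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Log-uniform random parameter set within the calibration search bounds.
random_params <- function(lo = 1e-5, hi = 1e5) {
  vals <- 10^runif(12, log10(lo), log10(hi))
  validate <- getFromNamespace("validate_params", "bladesim")
  validate(setNames(as.list(vals), getFromNamespace("blade_param_names", "bladesim")()))
}
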