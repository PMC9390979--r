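# shared builders for the default operating points used across the tests

default_modules <- function(d_m = 1, d_p = 0.1) {
  list(gene_module(d_m = d_m, d_p = d_p), gene_module(d_m = d_m, d_p = d_p))
}

rc_context <- function(J_p = 10, J_g = 20) {
  resource_context("competitive", J_p = J_p, J_g = J_g)
}

calibrated_modules <- function(mode = "competitive", J_p = 10, J_g = 20,
                               target_m = c(10, 10), target_p = c(100, 100),
                               d_m = 1, d_p = 0.1) {
  ctx <- if (mode == "frozen_cross") {
    resource_context(mode, J_p = J_p, J_g = J_g, frozen_means = target_m)
  } else {
    resource_context(mode, J_p = J_p, J_g = J_g)
  }
  list(modules = match_means(default_modules(d_m, d_p), ctx,
                             target_m = target_m, target_p = target_p),
       context = ctx)
}

# LNA CV^2 of P1 straight from the Lyapunov solution (independent of the
# decomposition formulas it is used to check)
lna_cv2_p1 <- function(network) {
  C <- lna_covariance(network)
  x <- attr(C, "fixed_point")
  C["P1", "P1"] / x[["P1"]]^2
}

random_states <- function(n, n_species = 4L, max_copies = 60, seed = 42) {
  set.seed(seed)
  matrix(sample(0:max_copies, n * n_species, replace = TRUE), n, n_species)
}

all_controller_configs <- function() {
  expand.grid(ctype = c("ncr", "local", "global"),
              placement = c("MIX", "PIX", "MIL", "PIL"),
              stringsAsFactors = FALSE)
}
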