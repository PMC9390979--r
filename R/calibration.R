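#' Rescale rate constants to hit target stationary means
#'
#' Fair noise comparisons across resource modes require identical operating
#' points, so the transcription and translation rate constants are rescaled
#' until the mean-field fixed point reproduces the requested mRNA and protein
#' means. The fixed-point equations are linear in `k_m` and `k_p` at fixed
#' means, so the inversion is closed-form: `k_m = d_m m* / (g phi)` with
#' `phi` the transcriptional sharing factor, and `k_p = d_p P* / f(m*)` with
#' `f` the translation law evaluated at unit rate constant.
#'
#' @param modules List of two [gene_module()] objects supplying gene doses
#'   and degradation rates (the fixed parameters).
#' @param context A [resource_context()].
#' @param target_m,target_p Length-2 positive vectors of target mRNA and
#'   protein means (copies); a scalar is recycled to both modules.
#' @return The modules list with `k_m` and `k_p` replaced.
#' @examples
#' mods <- match_means(list(gene_module(), gene_module()),
#'                     resource_context("competitive", J_p = 10, J_g = 20))
#' deterministic_steady_state(build_network(mods,
#'   resource_context("competitive", J_p = 10, J_g = 20)))
#' @export
match_means <- function(modules, context, target_m = c(10, 10),
                        target_p = c(100, 100)) {
  target_m <- rep_len(target_m, 2L)
  target_p <- rep_len(target_p, 2L)
  stopifnot("targets must be positive" =
              all(target_m > 0) && all(target_p > 0))
  out <- modules
  for (i in 1:2) {
    mod <- modules[[i]]
    if (mod$g <= 0) {
      stop(sprintf("module %d has zero gene dose; target mRNA mean %g is unreachable",
                   i, target_m[i]), call. = FALSE)
    }
    probe <- modules
    probe[[i]]$k_m <- 1
    phi <- transcription_propensity(i, c(0, 0, 0, 0), context, probe)
    out[[i]]$k_m <- mod$d_m * target_m[i] / phi
  }
  for (i in 1:2) {
    probe <- out
    probe[[i]]$k_p <- 1
    f_unit <- translation_law(i, context, probe)$f(target_m[1], target_m[2])
    if (!is.finite(f_unit) || f_unit <= 0) {
      stop(sprintf("translation target for module %d is unreachable (unit-rate flux %g)",
                   i, f_unit), call. = FALSE)
    }
    out[[i]]$k_p <- out[[i]]$d_p * target_p[i] / f_unit
  }
  out
}

#' Mean-field copy-number sweep of the RFP module
#'
#' Varies the effective RFP gene dose `g2` with the module-1 constants held
#' fixed (a single calibration up-front; re-calibrating at every dose would
#' erase the competition effect being measured) and records the mean-field
#' means at each grid point.
#'
#' @param modules Calibrated list of two [gene_module()] objects.
#' @param context A [resource_context()].
#' @param g2_grid Non-negative numeric vector of RFP gene doses.
#' @return A tibble with columns `g2`, `m1`, `m2`, `P1`, `P2` and an
#'   attribute `rfp_mean_asymptote`, the RFP protein mean in the
#'   infinite-dose limit.
#' @export
sweep_copy_number <- function(modules, context, g2_grid) {
  stopifnot("g2 grid must be non-negative" =
              is.numeric(g2_grid) && all(g2_grid >= 0))
  one <- function(g2) {
    mods <- modules
    mods[[2]]$g <- g2
    ss <- deterministic_steady_state(build_network(mods, context))
    tibble::tibble(g2 = g2, m1 = ss[["m1"]], m2 = ss[["m2"]],
                   P1 = ss[["P1"]], P2 = ss[["P2"]])
  }
  out <- purrr::map_dfr(g2_grid, one)
  attr(out, "rfp_mean_asymptote") <- one(1e9)$P2
  out
}
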