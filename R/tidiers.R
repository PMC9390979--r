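#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang %||%
NULL

#' Tidy a noise decomposition
#'
#' @param x A [decompose_noise()] result.
#' @param ... Unused.
#' @return A tibble with one row per noise component (`eta2` is the
#'   variance contribution, `eta` the coefficient of variation, `share`
#'   the variance fraction of the total).
#' @export
tidy.noise_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("protein_birth_death", "own_mrna", "resource_competition"),
    eta2 = c(x$eta_p2, x$eta_m2, x$eta_rc2),
    eta = sqrt(c(x$eta_p2, x$eta_m2, x$eta_rc2)),
    share = c(x$eta_p2, x$eta_m2, x$eta_rc2) / x$eta_total2
  )
}

#' One-row summary of a noise decomposition
#'
#' @inheritParams tidy.noise_decomposition
#' @return A one-row tibble with every decomposition field.
#' @export
glance.noise_decomposition <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c(
    "eta_p2", "eta_m2", "eta_rc2", "eta_total2", "H21", "H23",
    "tau1", "tau2", "tau3", "sigma_m1_2", "sigma_m2_2",
    "M1", "M2", "P1", "mode")])
}

#' Tidy stationary summary statistics
#'
#' @param x A [stationary_statistics()] result.
#' @param ... Unused.
#' @return The per-species tibble of time-weighted moments.
#' @export
tidy.stationary_summary <- function(x, ...) {
  x$species_stats
}

#' One-row summary of stationary statistics
#'
#' @inheritParams tidy.stationary_summary
#' @return A one-row tibble: seed, per-species means and squared CVs, and
#'   the protein-pair correlation when defined.
#' @export
glance.stationary_summary <- function(x, ...) {
  s <- x$species_stats
  wide <- c(stats::setNames(s$mean, paste0("mean_", s$species)),
            stats::setNames(s$cv2, paste0("cv2_", s$species)))
  out <- dplyr::bind_cols(tibble::tibble(seed = x$seed, span = x$span),
                          tibble::as_tibble(as.list(wide)))
  if (!is.null(x$correlation)) {
    out$corr <- x$correlation$r
    out$corr_se <- x$correlation$se
  }
  out
}

#' Plot a stochastic trajectory
#'
#' Step traces of the two reporter proteins (all species for non-circuit
#' networks), with dashed horizontal lines at the time-weighted means.
#'
#' @param object An [simulate_ssa()] trajectory.
#' @param species Species to draw; defaults to the protein pair when
#'   present.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssa_trajectory <- function(object, species = NULL, ...) {
  species <- species %||%
    (if (all(c("P1", "P2") %in% object$species)) c("P1", "P2")
     else object$species)
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "copies")
  w <- holding_times(object)
  means <- vapply(species, function(s) {
    sum(object$states[, match(s, object$species)] * w) / sum(w)
  }, 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$copies,
                                     colour = .data$species)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = means, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::scale_colour_manual(values = c(P1 = "#2E8B57", P2 = "#B22222",
                                            m1 = "#74c476", m2 = "#fb6a4a",
                                            x = "#444444")[species],
                                 na.value = "grey40") +
    ggplot2::labs(x = "time", y = "copy number", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a joint copy-number distribution
#'
#' @param object A [cme_joint2d()] table.
#' @param ... Unused.
#' @return A ggplot tile map of the stationary joint probability.
#' @export
autoplot.cme_joint <- function(object, ...) {
  sp <- attr(object, "species_pair")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sp[1], y = sp[2], fill = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a normalized-noise grid
#'
#' Heatmap of the GFP noise fold change over the plane of achieved RFP
#' mean and controller strength; blue regions mark noise reduction, red
#' regions noise increase relative to the uncontrolled base.
#'
#' @param object A [noise_heatmap()] result.
#' @param value Column to map to fill (`"norm_gfp"` or `"norm_total"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noise_grid <- function(object, value = "norm_gfp", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rfp_mean, y = .data$S_c,
                                       fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#08306B",
                                  mid = "white", high = "#99000D") +
    ggplot2::facet_wrap(~ paste(.data$ctype, .data$placement, sep = "-")) +
    ggplot2::labs(x = "RFP mean", y = expression(S[c]),
                  fill = "fold change") +
    ggplot2::theme_minimal()
}

#' Plot a translational-capacity noise sweep
#'
#' @param sweep A [sweep_jp()] table.
#' @return A ggplot of the three noise components and their total against
#'   `J_p` (log scale).
#' @export
plot_jp_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep[, c("J_p", "eta_p2", "eta_m2", "eta_rc2", "eta_total2")],
    -"J_p", names_to = "component", values_to = "eta2")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$J_p, y = sqrt(.data$eta2),
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(J[p]), y = "noise (CV)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot GFP noise against achieved RFP mean
#'
#' @param tbl A [noise_vs_rfp_mean()] table.
#' @return A ggplot comparing the competitive and orthogonal systems.
#' @export
plot_noise_vs_rfp <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rfp_mean,
                                    y = sqrt(.data$eta_total2),
                                    colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(tbl, .data$rfp_mean == min(.data$rfp_mean))) +
    ggplot2::labs(x = "RFP mean", y = "GFP total noise (CV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
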