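#' Total system noise of the two reporters
#'
#' Pythagorean sum of the GFP and RFP noise (coefficients of variation):
#' `sqrt(eta_GFP^2 + eta_RFP^2)`.
#'
#' @param eta_gfp,eta_rfp Non-negative noise levels (CV), vectorised.
#' @return Total system noise.
#' @examples
#' total_system_noise(0.3, 0.4) # 0.5
#' @export
total_system_noise <- function(eta_gfp, eta_rfp) {
  if (any(eta_gfp < 0, na.rm = TRUE) || any(eta_rfp < 0, na.rm = TRUE)) {
    stop("noise levels must be non-negative", call. = FALSE)
  }
  sqrt(eta_gfp^2 + eta_rfp^2)
}

#' Average noise reduction coefficient of a controller grid
#'
#' The grid-averaged `1 - fold change` of the total system noise across all
#' cells with a controller active (the `S_c = 0` baseline row is the
#' reference, not a sample). Positive values mean a net noise reduction
#' over the operating plane, negative values net amplification.
#'
#' @param grid A [noise_heatmap()] result (or several row-bound together).
#' @return A tibble with one row per controller identity and base system:
#'   `coefficient` and the number of grid cells averaged.
#' @export
noise_reduction_coefficient <- function(grid) {
  active <- dplyr::filter(grid, .data$S_c > 0, .data$ok)
  if (nrow(active) == 0L) {
    stop("grid has no active-controller cells to average", call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(active, .data$ctype, .data$placement, .data$base),
    coefficient = mean(1 - .data$norm_total),
    n_cells = dplyr::n(),
    .groups = "drop")
}

experiment_registry <- function() {
  list(
    trajectories = experiment_trajectories,
    cme_joint = experiment_cme_joint,
    jp_sweep = experiment_jp_sweep,
    orthogonal_comparison = experiment_orthogonal_comparison,
    ncr_grid = experiment_ncr_grid,
    controller_comparison = experiment_controller_comparison,
    or_combinations = experiment_or_combinations
  )
}

merge_params <- function(defaults, params, experiment) {
  if (is.null(params)) return(defaults)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad)) {
    stop(sprintf("unknown parameter(s) for experiment '%s': %s (valid: %s)",
                 experiment, paste(bad, collapse = ", "),
                 paste(names(defaults), collapse = ", ")), call. = FALSE)
  }
  utils::modifyList(defaults, params)
}

experiment_trajectories <- function(params, seed) {
  p <- merge_params(list(t_end = 2500, burn_in = 500, thin_points = 2000),
                    params, "trajectories")
  nets <- list(
    competitive = strong_competition_network(),
    frozen_cross = {
      net <- strong_competition_network()
      ss <- deterministic_steady_state(net)
      ctx <- resource_context("frozen_cross", J_p = net$context$J_p,
                              J_g = net$context$J_g,
                              frozen_means = ss[c("m1", "m2")])
      build_network(net$modules, ctx)
    })
  traces <- purrr::imap_dfr(nets, function(net, nm) {
    tr <- simulate_ssa(net, t_end = p$t_end, burn_in = p$burn_in,
                       seed = seed)
    grid <- seq(tr$burn_in, tr$t_end, length.out = p$thin_points)
    idx <- findInterval(grid, tr$time)
    tibble::tibble(system = nm, time = grid,
                   P1 = tr$states[idx, 3], P2 = tr$states[idx, 4])
  })
  summaries <- purrr::imap_dfr(nets, function(net, nm) {
    tr <- simulate_ssa(net, t_end = p$t_end, burn_in = p$burn_in,
                       seed = seed)
    dplyr::mutate(glance(stationary_statistics(tr)), system = nm,
                  .before = 1)
  })
  list(trajectories = traces, summaries = summaries)
}

experiment_cme_joint <- function(params, seed) {
  p <- merge_params(list(target_m = 3, target_p = 6, J_p = 3), params,
                    "cme_joint")
  out <- purrr::map(c(competitive = "competitive",
                      frozen_cross = "frozen_cross"), function(mode) {
    net <- cme_regime_network(mode, target_m = p$target_m,
                              target_p = p$target_p, J_p = p$J_p)
    stationary_distribution(build_generator(net))
  })
  joints <- purrr::imap_dfr(out, function(d, nm) {
    dplyr::mutate(cme_joint2d(d, c("P1", "P2")), system = nm)
  })
  marginals <- purrr::imap_dfr(out, function(d, nm) {
    dplyr::mutate(cme_marginal(d, "P1"), system = nm)
  })
  widths <- purrr::imap_dfr(out, function(d, nm) {
    tibble::tibble(system = nm, fwhm_P1 = as.numeric(fwhm(cme_marginal(d, "P1"))))
  })
  list(joint_p1_p2 = joints, marginal_p1 = marginals, fwhm = widths)
}

experiment_jp_sweep <- function(params, seed) {
  p <- merge_params(list(jp_min = 0.1, jp_max = 1e4, n = 40), params,
                    "jp_sweep")
  net <- calibrated_network("competitive")
  grid <- 10^seq(log10(p$jp_min), log10(p$jp_max), length.out = p$n)
  list(jp_sweep = sweep_jp(net$modules, net$context, grid))
}

experiment_orthogonal_comparison <- function(params, seed) {
  p <- merge_params(list(g2_max = 40, n = 15), params,
                    "orthogonal_comparison")
  g2 <- c(0, 10^seq(-1, log10(p$g2_max), length.out = p$n - 1))
  list(noise_vs_rfp = noise_vs_rfp_mean(g2))
}

default_controller_grids <- function() {
  list(g2_grid = c(0, 0.5, 1, 2, 4, 8, 16, 32),
       sc_grid = c(0, 0.5, 1, 2, 4, 8, 14, 20))
}

experiment_ncr_grid <- function(params, seed) {
  g <- default_controller_grids()
  p <- merge_params(c(g, list(S_c_fixed = 14)), params, "ncr_grid")
  net <- strong_competition_network()
  grids <- purrr::map_dfr(controller_placements, function(pl) {
    noise_heatmap(net$modules, net$context, "ncr", pl,
                  p$g2_grid, p$sc_grid)
  })
  fixed <- dplyr::filter(grids, .data$S_c == p$S_c_fixed)
  out <- list(grids = grids, fixed_strength = fixed)
  if (any(grids$S_c > 0)) {
    out$coefficients <- noise_reduction_coefficient(grids)
  }
  out
}

experiment_controller_comparison <- function(params, seed) {
  g <- default_controller_grids()
  p <- merge_params(g, params, "controller_comparison")
  net <- strong_competition_network()
  grids <- purrr::map_dfr(controller_types, function(ct) {
    purrr::map_dfr(controller_placements, function(pl) {
      noise_heatmap(net$modules, net$context, ct, pl,
                    p$g2_grid, p$sc_grid)
    })
  })
  co <- noise_reduction_coefficient(grids)
  by_type <- dplyr::summarise(dplyr::group_by(co, .data$ctype),
                              coefficient = mean(.data$coefficient),
                              .groups = "drop")
  by_placement <- dplyr::summarise(dplyr::group_by(co, .data$placement),
                                   coefficient = mean(.data$coefficient),
                                   .groups = "drop")
  list(grids = grids, coefficients = co, by_type = by_type,
       by_placement = by_placement)
}

experiment_or_combinations <- function(params, seed) {
  g <- default_controller_grids()
  p <- merge_params(g, params, "or_combinations")
  net <- strong_competition_network(mode = "orthogonal")
  grids <- purrr::map_dfr(controller_types, function(ct) {
    purrr::map_dfr(controller_placements, function(pl) {
      noise_heatmap(net$modules, net$context, ct, pl,
                    p$g2_grid, p$sc_grid)
    })
  })
  co <- noise_reduction_coefficient(grids)
  by_placement <- dplyr::summarise(dplyr::group_by(co, .data$placement),
                                   coefficient = mean(.data$coefficient),
                                   .groups = "drop")
  list(grids = grids, coefficients = co, by_placement = by_placement)
}

#' Run a registered figure-level experiment
#'
#' Orchestrates one of the package's canned analyses end-to-end and
#' (optionally) writes its tables as CSV files plus a JSON metadata sidecar
#' (experiment name, parameters, seed, package version, wall-clock) into an
#' output directory. Re-running with identical configuration and seed
#' reproduces the CSVs byte for byte.
#'
#' @param config Either the experiment name, a list with elements
#'   `experiment` (name) and optional `params` (overrides for that
#'   experiment's defaults), or a path to a YAML/JSON file holding such a
#'   list.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Integer seed for any stochastic step.
#' @return Invisibly, a named list of result tibbles.
#' @examples
#' res <- run_experiment(list(experiment = "jp_sweep",
#'                            params = list(n = 5)))
#' names(res)
#' @export
run_experiment <- function(config, out_dir = NULL, seed = 1L) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    config <- read_config(config)
  }
  if (is.character(config)) config <- list(experiment = config)
  if (!is.list(config) || is.null(config$experiment)) {
    stop("config must name an 'experiment'", call. = FALSE)
  }
  bad <- setdiff(names(config), c("experiment", "params", "seed"))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s (valid: experiment, params, seed)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  registry <- experiment_registry()
  name <- config$experiment
  if (!name %in% names(registry)) {
    stop(sprintf("unknown experiment '%s'; registered experiments: %s",
                 name, paste(names(registry), collapse = ", ")),
         call. = FALSE)
  }
  seed <- as.integer(config$seed %||% seed)
  t0 <- proc.time()[["elapsed"]]
  results <- registry[[name]](config$params, seed)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      utils::write.csv(results[[nm]],
                       file.path(out_dir, paste0(name, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(experiment = name, params = config$params, seed = seed,
           package = "rcnoise",
           version = as.character(utils::packageVersion("rcnoise")),
           elapsed_seconds = round(elapsed, 3)),
      file.path(out_dir, paste0(name, "_metadata.json")),
      auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(results)
}
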