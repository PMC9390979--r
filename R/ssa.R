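#' Minimal one-species birth-death network
#'
#' Constant birth at rate `k`, first-order death at rate `d`. The stationary
#' law is Poisson(`k/d`), which makes this the standard closed-form oracle
#' for validating the simulator, the master-equation solver and the
#' linear-noise machinery.
#'
#' @param k Birth rate (copies per time).
#' @param d Death rate (per time).
#' @return A `reaction_network` with a single species `x`.
#' @export
birth_death_network <- function(k = 5, d = 1) {
  stopifnot(k >= 0, d > 0)
  stoich <- rbind(birth = 1, death = -1)
  colnames(stoich) <- "x"
  structure(list(
    species = "x",
    stoich = stoich,
    propensity = function(x) c(k, d * x[1L]),
    propensity_grid = function(X) cbind(rep_len(k, nrow(X)), d * X[, 1L]),
    modules = NULL, context = NULL, controller = NULL,
    provenance = list(mode = "birth_death", k = k, d = d)
  ), class = "reaction_network")
}

default_horizons <- function(network) {
  d_slow <- if (!is.null(network$modules)) {
    min(network$modules[[1]]$d_p, network$modules[[2]]$d_p)
  } else {
    1
  }
  list(burn_in = 50 / d_slow, t_end = 2050 / d_slow)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Generates one statistically exact sample path of the jump process defined
#' by a network's propensities. The burn-in segment is simulated but not
#' recorded; the trajectory starts at time `burn_in` with the state reached
#' there, so all recorded mass is (approximately) stationary. Identical
#' `seed` and inputs give identical trajectories.
#'
#' @param network A `reaction_network`.
#' @param t_end End time (time units); must exceed `burn_in`. Default
#'   2000 protein lifetimes after the default burn-in.
#' @param burn_in Discarded initial horizon; default 50 protein lifetimes.
#' @param seed Integer random seed (required: no silent nondeterminism).
#' @param x0 Initial state; defaults to the rounded deterministic steady
#'   state, which keeps the burn-in needed for stationarity short.
#' @return An `ssa_trajectory`: fields `time` (strictly increasing, first
#'   entry `burn_in`), `states` (integer matrix, one row per entry of
#'   `time`), `species`, `t_end`, `burn_in`, `seed`, `absorbed` (`TRUE` if
#'   all propensities vanished before `t_end`) and the network `provenance`.
#' @examples
#' tr <- simulate_ssa(birth_death_network(5, 1), t_end = 100, burn_in = 5,
#'                    seed = 1)
#' stationary_statistics(tr)
#' @export
simulate_ssa <- function(network, t_end = NULL, burn_in = NULL, seed,
                         x0 = NULL) {
  if (missing(seed)) stop("simulate_ssa() requires an explicit seed",
                          call. = FALSE)
  hz <- default_horizons(network)
  if (is.null(burn_in)) burn_in <- hz$burn_in
  if (is.null(t_end)) t_end <- hz$t_end
  stopifnot("need t_end > burn_in >= 0" = t_end > burn_in && burn_in >= 0)
  if (is.null(x0)) x0 <- round(deterministic_steady_state(network))
  ns <- length(network$species)
  stopifnot(length(x0) == ns, all(x0 >= 0))

  set.seed(as.integer(seed))
  prop <- network$propensity
  srows <- lapply(seq_len(nrow(network$stoich)),
                  function(r) network$stoich[r, ])
  x <- as.numeric(x0)
  t <- 0
  cap <- 65536L
  times <- numeric(cap)
  states <- matrix(0L, cap, ns)
  n <- 0L
  recording <- FALSE
  absorbed <- FALSE

  repeat {
    a <- prop(x)
    A <- sum(a)
    if (A <= 0) {
      absorbed <- TRUE
      break
    }
    t_next <- t - log(stats::runif(1L)) / A
    if (!recording && t_next > burn_in) {
      # state x holds at the burn-in boundary: first recorded sample
      recording <- TRUE
      n <- 1L
      times[1L] <- burn_in
      states[1L, ] <- as.integer(x)
    }
    if (t_next > t_end) break
    t <- t_next
    u <- stats::runif(1L) * A
    r <- 1L
    acc <- a[1L]
    while (acc < u && r < length(a)) {
      r <- r + 1L
      acc <- acc + a[r]
    }
    x <- x + srows[[r]]
    if (recording) {
      n <- n + 1L
      if (n > cap) {
        cap <- cap * 2L
        times <- c(times, numeric(cap / 2L))
        states <- rbind(states, matrix(0L, cap / 2L, ns))
      }
      times[n] <- t
      states[n, ] <- as.integer(x)
    }
  }
  if (n == 0L) {
    # absorbed during burn-in: flag and report the final state
    n <- 1L
    times[1L] <- min(burn_in, t)
    states[1L, ] <- as.integer(x)
  }
  structure(list(
    time = times[seq_len(n)],
    states = states[seq_len(n), , drop = FALSE],
    species = network$species,
    t_end = t_end, burn_in = burn_in, seed = as.integer(seed),
    absorbed = absorbed,
    provenance = network$provenance
  ), class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ssa_trajectory> %d events on [%g, %g], species: %s, seed %d%s\n",
    length(x$time) - 1L, x$burn_in, x$t_end,
    paste(x$species, collapse = ", "), x$seed,
    if (x$absorbed) " [absorbed]" else ""))
  invisible(x)
}

#' Convert a trajectory to a tibble
#'
#' @param x An `ssa_trajectory`.
#' @param ... Unused.
#' @return A tibble with `time` and one column per species.
#' @export
as_tibble.ssa_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$states))
  names(out) <- x$species
  dplyr::bind_cols(tibble::tibble(time = x$time), out)
}

# holding times of each recorded state (last state held until t_end)
holding_times <- function(traj) {
  diff(c(traj$time, max(traj$t_end, traj$time[length(traj$time)])))
}

weighted_moments <- function(X, w) {
  Tt <- sum(w)
  mu <- colSums(X * w) / Tt
  Xc <- sweep(X, 2, mu)
  v <- colSums(Xc^2 * w) / Tt
  list(mean = mu, var = v, Tt = Tt)
}

#' Time-weighted stationary statistics of a trajectory
#'
#' Trajectory values are step functions, so all moments are time-weighted
#' (event-weighted averaging would bias toward fast-firing regions). Monte
#' Carlo standard errors come from non-overlapping batch means; the Pearson
#' correlation of the protein pair uses the time-weighted covariance.
#'
#' @param traj An [simulate_ssa()] trajectory.
#' @param n_batches Number of batches for standard errors (>= 2).
#' @param min_lifetimes Required horizon, in units of the slowest lifetime
#'   present in the trajectory's provenance (protein lifetime for circuit
#'   networks). Shorter trajectories are rejected with the required minimum.
#' @return A `stationary_summary` with a per-species tibble (`mean`, `var`,
#'   `cv2`, `fano`, `se_mean`) and, when the species `P1`/`P2` are present,
#'   their time-weighted correlation with its batch standard error. Use
#'   [tidy()] / [glance()] to extract tibbles.
#' @export
stationary_statistics <- function(traj, n_batches = 20L,
                                  min_lifetimes = 100) {
  stopifnot(inherits(traj, "ssa_trajectory"), n_batches >= 2L)
  span <- traj$t_end - traj$burn_in
  d_slow <- if (!is.null(traj$provenance$modules)) {
    min(vapply(traj$provenance$modules, `[[`, 0, "d_p"))
  } else if (identical(traj$provenance$mode, "birth_death")) {
    traj$provenance$d
  } else {
    NA_real_
  }
  if (is.finite(d_slow) && span < min_lifetimes / d_slow) {
    stop(sprintf(
      "trajectory spans %.3g time units after burn-in; need at least %.3g (%g slowest lifetimes)",
      span, min_lifetimes / d_slow, min_lifetimes), call. = FALSE)
  }
  w <- holding_times(traj)
  X <- traj$states
  mom <- weighted_moments(X, w)

  # batch assignment by interval start time (holding times are short
  # relative to a batch, so boundary smearing is negligible)
  edges <- seq(traj$burn_in, traj$t_end, length.out = n_batches + 1L)
  bi <- findInterval(traj$time, edges, rightmost.closed = TRUE)
  bi[bi < 1L] <- 1L
  bi[bi > n_batches] <- n_batches
  batch_mean <- function(col) {
    vapply(seq_len(n_batches), function(b) {
      sel <- bi == b
      if (!any(sel)) return(NA_real_)
      sum(X[sel, col] * w[sel]) / sum(w[sel])
    }, 0)
  }
  bm <- vapply(seq_along(traj$species), batch_mean,
               numeric(n_batches))
  se_mean <- apply(bm, 2, stats::sd, na.rm = TRUE) / sqrt(n_batches)

  species_stats <- tibble::tibble(
    species = traj$species,
    mean = mom$mean,
    var = mom$var,
    cv2 = mom$var / mom$mean^2,
    fano = mom$var / mom$mean,
    se_mean = se_mean
  )

  correlation <- NULL
  if (all(c("P1", "P2") %in% traj$species)) {
    i1 <- match("P1", traj$species)
    i2 <- match("P2", traj$species)
    wcor <- function(sel) {
      ws <- w[sel]
      Tt <- sum(ws)
      m1 <- sum(X[sel, i1] * ws) / Tt
      m2 <- sum(X[sel, i2] * ws) / Tt
      cv <- sum((X[sel, i1] - m1) * (X[sel, i2] - m2) * ws) / Tt
      v1 <- sum((X[sel, i1] - m1)^2 * ws) / Tt
      v2 <- sum((X[sel, i2] - m2)^2 * ws) / Tt
      cv / sqrt(v1 * v2)
    }
    r_full <- wcor(rep_len(TRUE, nrow(X)))
    r_batch <- vapply(seq_len(n_batches), function(b) {
      sel <- bi == b
      if (sum(sel) < 3L) return(NA_real_)
      wcor(sel)
    }, 0)
    correlation <- tibble::tibble(
      pair = "P1:P2",
      r = r_full,
      se = stats::sd(r_batch, na.rm = TRUE) / sqrt(sum(!is.na(r_batch)))
    )
  }
  structure(list(species_stats = species_stats, correlation = correlation,
                 span = span, n_batches = n_batches,
                 absorbed = traj$absorbed, seed = traj$seed),
            class = "stationary_summary")
}

#' @export
print.stationary_summary <- function(x, ...) {
  cat(sprintf("<stationary_summary> span %g, %d batches%s\n", x$span,
              x$n_batches, if (x$absorbed) " [absorbed]" else ""))
  print(x$species_stats)
  if (!is.null(x$correlation)) {
    cat(sprintf("corr(P1, P2) = %.3f (batch se %.3f)\n",
                x$correlation$r, x$correlation$se))
  }
  invisible(x)
}

#' Replicate ensemble of stationary summaries
#'
#' Runs `n_reps` independent trajectories with seeds
#' `seed_base, ..., seed_base + n_reps - 1` and collects one summary row per
#' replicate.
#'
#' @param network A `reaction_network`.
#' @param n_reps Number of replicates (>= 1).
#' @param seed_base First seed.
#' @param ... Passed to [simulate_ssa()] (e.g. `t_end`, `burn_in`).
#' @return A tibble with one row per replicate (seed, per-species means and
#'   cv2, protein correlation when defined).
#' @export
ssa_ensemble <- function(network, n_reps, seed_base = 1L, ...) {
  stopifnot(n_reps >= 1L)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    tr <- simulate_ssa(network, seed = seed_base + i - 1L, ...)
    glance(stationary_statistics(tr))
  })
}

#' Time-weighted copy-number histogram of one species
#'
#' @param traj An [simulate_ssa()] trajectory.
#' @param species Species name.
#' @return A tibble with integer `copies` and stationary probability `p`
#'   (summing to 1).
#' @export
ssa_histogram <- function(traj, species) {
  i <- match(species, traj$species)
  stopifnot(!is.na(i))
  w <- holding_times(traj)
  v <- traj$states[, i]
  tab <- tapply(w, factor(v, levels = 0:max(v)), sum, default = 0)
  tibble::tibble(copies = 0:max(v), p = as.numeric(tab) / sum(w))
}
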