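controller_types <- c("ncr", "local", "global")
controller_placements <- c("MIX", "PIX", "MIL", "PIL")

#' Specify a negative-feedback noise controller
#'
#' Three controller types, each available in four placements along the
#' protein biosynthesis pathway. The placement letter pair encodes the
#' inhibitory moiety (M: mRNA-mediated, P: protein-mediated) and the target
#' (X: transcription, L: translation). The targeted propensity of module `i`
#' is multiplied by the non-cooperative repression factor
#' `1/(1 + S_c E_i / K_e)` with effector:
#' \describe{
#'   \item{local}{`E_i = X_i`, the module's own moiety level — one
#'     independent feedback loop per module;}
#'   \item{global}{`E_i = X_1 + X_2` — a single shared loop repressing both
#'     modules;}
#'   \item{ncr}{negatively competitive regulation. Each module expresses a
#'     sensor RNA `s_i` tracking its moiety (production rate
#'     `alpha_s X_i`, degradation `d_s s_i`); the sensors compete for a
#'     fixed pool of inhibitory CRISPR machinery, and the
#'     quasi-steady-state self-inhibiting complex
#'     `c_i = dcas_total (s_i/K_b) / (1 + s_1/K_b + s_2/K_b)` is the
#'     effector. A rise in the opposing module pulls machinery away from
#'     the module's own complex and releases it — a built-in
#'     anti-compensation of resource stealing — while the sensor's own
#'     birth/death shot noise is injected into the loop.}
#' }
#'
#' @param ctype `"ncr"`, `"local"` or `"global"`.
#' @param placement `"MIX"`, `"PIX"`, `"MIL"` or `"PIL"`.
#' @param S_c Controller strength (dimensionless, >= 0; 0 is the identity).
#' @param K_e Effector half-inhibition scale (copies).
#' @param K_b Sensor-machinery binding scale (copies; NCR only).
#' @param dcas_total Conserved pool of inhibitory machinery (copies; NCR
#'   only).
#' @param alpha_s Sensor production coupling (per moiety copy per time; NCR
#'   only). The default `NA` auto-scales the coupling when the controller
#'   is attached, placing the module-1 sensor mean at the binding scale
#'   `K_b` — the half-occupancy point where the machinery partition is most
#'   sensitive — so that mRNA- and protein-mediated sensors operate at
#'   comparable copy numbers.
#' @param d_s Sensor degradation rate (per time; NCR only).
#' @return A `controller_spec`.
#' @examples
#' controller_spec("ncr", "MIX", S_c = 14)
#' @export
controller_spec <- function(ctype, placement, S_c, K_e = 10, K_b = 10,
                            dcas_total = 50, alpha_s = NA, d_s = 1) {
  ctype <- match.arg(tolower(ctype), controller_types)
  placement <- match.arg(toupper(placement), controller_placements)
  stopifnot(
    "S_c must be a single non-negative number" =
      is.numeric(S_c) && length(S_c) == 1L && is.finite(S_c) && S_c >= 0,
    "K_e must be > 0" = K_e > 0,
    "K_b must be > 0" = K_b > 0,
    "dcas_total must be > 0" = dcas_total > 0,
    "alpha_s must be NA (auto) or > 0" = is.na(alpha_s) || alpha_s > 0,
    "d_s must be > 0" = d_s > 0
  )
  structure(list(ctype = ctype, placement = placement, S_c = S_c,
                 K_e = K_e, K_b = K_b, dcas_total = dcas_total,
                 alpha_s = alpha_s, d_s = d_s),
            class = "controller_spec")
}

#' @export
print.controller_spec <- function(x, ...) {
  cat(sprintf("<controller_spec> %s-%s  S_c=%g  K_e=%g\n",
              x$ctype, x$placement, x$S_c, x$K_e))
  invisible(x)
}

moiety_indices <- function(placement) {
  if (substr(placement, 1, 1) == "M") c(1L, 2L) else c(3L, 4L)
}

target_reactions <- function(placement) {
  if (substr(placement, 3, 3) == "X") c(1L, 2L) else c(5L, 6L)
}

# NCR complex pair from the two sensor levels (vectorised)
ncr_complexes <- function(spec, s1, s2) {
  den <- 1 + s1 / spec$K_b + s2 / spec$K_b
  list(spec$dcas_total * (s1 / spec$K_b) / den,
       spec$dcas_total * (s2 / spec$K_b) / den)
}

# effector levels of both modules; X1/X2 are moiety levels for local/global,
# sensor levels for ncr
effector_pair <- function(spec, X1, X2) {
  switch(spec$ctype,
    local = list(X1, X2),
    global = {
      E <- X1 + X2
      list(E, E)
    },
    ncr = ncr_complexes(spec, X1, X2)
  )
}

#' Effector level seen by one module
#'
#' @param spec A [controller_spec()].
#' @param state Circuit state `c(m1, m2, P1, P2)`, extended by the sensor
#'   pair `(s1, s2)` for NCR controllers.
#' @param module_index 1 or 2.
#' @return Effector level (copies). For NCR this is the quasi-steady-state
#'   self-inhibiting complex, bounded by the machinery pool.
#' @export
effector <- function(spec, state, module_index) {
  stopifnot(inherits(spec, "controller_spec"), module_index %in% c(1L, 2L))
  check_state(state)
  idx <- if (spec$ctype == "ncr") c(5L, 6L) else moiety_indices(spec$placement)
  if (length(state) < max(idx)) {
    stop("state is missing the controller species", call. = FALSE)
  }
  e <- effector_pair(spec, state[idx[1]], state[idx[2]])
  e[[module_index]]
}

#' Attach a controller to a base network
#'
#' Multiplies the targeted propensity (transcription for `*IX`, translation
#' for `*IL`) of each module by its repression factor
#' `1/(1 + S_c E_i/K_e)`. NCR controllers additionally append the two
#' sensor-RNA species with their production and degradation reactions; the
#' self-inhibiting complexes are evaluated at quasi-steady state of the
#' binding equilibrium in both the stochastic and the linearised
#' treatment. At `S_c = 0` the augmented network reproduces the base
#' propensities on every state.
#'
#' @param network An uncontrolled two-gene `reaction_network`.
#' @param spec A [controller_spec()].
#' @return The augmented `reaction_network`.
#' @export
attach_controller <- function(network, spec) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(spec, "controller_spec"))
  if (!is.null(network$controller)) {
    stop("network already has a controller attached", call. = FALSE)
  }
  if (is.null(network$translation_laws)) {
    stop("controllers require a two-gene circuit network", call. = FALSE)
  }
  base_prop <- network$propensity
  base_grid <- network$propensity_grid
  mi <- moiety_indices(spec$placement)
  tr <- target_reactions(spec$placement)
  Sc <- spec$S_c; Ke <- spec$K_e
  out <- network

  if (spec$ctype == "ncr" && is.na(spec$alpha_s)) {
    x_base <- deterministic_steady_state(network)
    X1 <- x_base[mi[1L]]
    if (X1 <= 0) stop("cannot auto-scale alpha_s: zero module-1 moiety mean",
                      call. = FALSE)
    spec$alpha_s <- spec$d_s * spec$K_b / X1
  }

  if (spec$ctype == "ncr") {
    as_ <- spec$alpha_s; ds <- spec$d_s
    out$species <- c(base_species, "s1", "s2")
    st <- cbind(base_stoich(), s1 = 0, s2 = 0)
    st <- rbind(st,
                prod_s1 = c(0, 0, 0, 0, 1, 0),
                prod_s2 = c(0, 0, 0, 0, 0, 1),
                deg_s1 = c(0, 0, 0, 0, -1, 0),
                deg_s2 = c(0, 0, 0, 0, 0, -1))
    out$stoich <- st
    out$propensity <- function(x) {
      a <- base_prop(x)
      cc <- ncr_complexes(spec, x[5L], x[6L])
      a[tr[1L]] <- a[tr[1L]] / (1 + Sc * cc[[1L]] / Ke)
      a[tr[2L]] <- a[tr[2L]] / (1 + Sc * cc[[2L]] / Ke)
      unname(c(a, as_ * x[mi[1L]], as_ * x[mi[2L]], ds * x[5L], ds * x[6L]))
    }
    out$propensity_grid <- function(X) {
      A <- base_grid(X)
      cc <- ncr_complexes(spec, X[, 5L], X[, 6L])
      A[, tr[1L]] <- A[, tr[1L]] / (1 + Sc * cc[[1L]] / Ke)
      A[, tr[2L]] <- A[, tr[2L]] / (1 + Sc * cc[[2L]] / Ke)
      cbind(A, as_ * X[, mi[1L]], as_ * X[, mi[2L]],
            ds * X[, 5L], ds * X[, 6L])
    }
  } else {
    out$propensity <- function(x) {
      a <- base_prop(x)
      e <- effector_pair(spec, x[mi[1L]], x[mi[2L]])
      a[tr[1L]] <- a[tr[1L]] / (1 + Sc * e[[1L]] / Ke)
      a[tr[2L]] <- a[tr[2L]] / (1 + Sc * e[[2L]] / Ke)
      a
    }
    out$propensity_grid <- function(X) {
      A <- base_grid(X)
      e <- effector_pair(spec, X[, mi[1L]], X[, mi[2L]])
      A[, tr[1L]] <- A[, tr[1L]] / (1 + Sc * e[[1L]] / Ke)
      A[, tr[2L]] <- A[, tr[2L]] / (1 + Sc * e[[2L]] / Ke)
      A
    }
  }
  out$controller <- spec
  out$provenance$controller <- unclass(spec)
  out
}

# stationary sensor levels implied by moiety targets
ncr_sensor_targets <- function(spec, target_m, target_p) {
  X <- if (substr(spec$placement, 1, 1) == "M") target_m else target_p
  spec$alpha_s / spec$d_s * X
}

# full target state vector (with sensors for NCR)
controlled_target_state <- function(spec, target_m, target_p) {
  x <- c(target_m, target_p)
  if (!is.null(spec) && spec$ctype == "ncr") {
    x <- c(x, ncr_sensor_targets(spec, target_m, target_p))
  }
  x
}

#' Rescale a network's rate constants onto target means
#'
#' Adjusts `k_m` and `k_p` of both modules so the mean-field fixed point of
#' the (possibly controlled) network sits exactly at the requested means.
#' Because every repression factor depends only on the state, the flux
#' balances are linear in the rate constants at fixed means and the
#' rescaling is a one-pass closed form. Modules whose target mean is zero
#' keep their constants.
#'
#' @param network A `reaction_network` (controlled or not).
#' @param target_m,target_p Length-2 target mRNA and protein means.
#' @return The rescaled `reaction_network`, whose deterministic fixed point
#'   reproduces the targets.
#' @export
rescale_to_means <- function(network, target_m, target_p) {
  stopifnot(!is.null(network$translation_laws))
  x_t <- controlled_target_state(network$controller, target_m, target_p)
  a <- network$propensity(x_t)
  mods <- network$modules
  for (i in 1:2) {
    if (target_m[i] > 0) {
      if (a[i] <= 0) stop(sprintf("mRNA target for module %d unreachable", i),
                          call. = FALSE)
      mods[[i]]$k_m <- mods[[i]]$k_m * mods[[i]]$d_m * target_m[i] / a[i]
    }
    if (target_p[i] > 0) {
      if (a[4L + i] <= 0) {
        stop(sprintf("protein target for module %d unreachable", i),
             call. = FALSE)
      }
      mods[[i]]$k_p <- mods[[i]]$k_p * mods[[i]]$d_p * target_p[i] / a[4L + i]
    }
  }
  build_network(mods, network$context, controller = network$controller)
}

#' Controller attached on top of orthogonal resources
#'
#' Builds the orthogonal-resource network and attaches the controller,
#' supporting all twelve type/placement combinations for the
#' controller-plus-orthogonal-resources experiments.
#'
#' @param spec A [controller_spec()].
#' @param modules List of two [gene_module()] objects.
#' @param or_context A [resource_context()] in orthogonal mode.
#' @return A controlled `reaction_network`.
#' @export
with_orthogonal <- function(spec, modules, or_context) {
  stopifnot(identical(or_context$mode, "orthogonal"))
  attach_controller(build_network(modules, or_context), spec)
}

#' Fold change in GFP noise under a controller
#'
#' Ratio of the LNA GFP noise (coefficient of variation) with the
#' controller attached to the base case without one, at the same gene
#' doses. For a fair comparison the controlled network's rate constants are
#' first rescaled onto the base operating point ([rescale_to_means()]), so
#' the fold change isolates the feedback's effect on fluctuations rather
#' than its repression of the mean. Also returns the fold change of the
#' total system noise (Pythagorean sum over both reporters); when the RFP
#' dose is zero the absent reporter contributes nothing to it.
#'
#' @param modules Calibrated modules (module 2's dose set as desired).
#' @param context A [resource_context()].
#' @param spec A [controller_spec()].
#' @param base_noise Optional precomputed [lna_protein_noise()] row for the
#'   base network (saves recomputation across a strength grid).
#' @return One-row tibble: `ctype`, `placement`, `S_c`, `norm_gfp`,
#'   `norm_rfp`, `norm_total` and `rfp_mean` (the base RFP mean, the
#'   natural sweep axis).
#' @export
normalized_noise <- function(modules, context, spec, base_noise = NULL) {
  base_net <- build_network(modules, context)
  nb <- base_noise %||% lna_protein_noise(base_net)
  target_m <- c(nb$m1, nb$m2)
  target_p <- c(nb$P1, nb$P2)
  ctrl <- rescale_to_means(attach_controller(base_net, spec),
                           target_m, target_p)
  # the attached spec may carry an auto-resolved alpha_s
  x_t <- controlled_target_state(ctrl$controller, target_m, target_p)
  names(x_t) <- ctrl$species
  nc <- lna_protein_noise(ctrl, fixed_point = x_t)
  absent_rfp <- target_p[2] == 0
  eta_b <- c(sqrt(nb$eta2_P1), if (absent_rfp) 0 else sqrt(nb$eta2_P2))
  eta_c <- c(sqrt(nc$eta2_P1), if (absent_rfp) 0 else sqrt(nc$eta2_P2))
  tibble::tibble(
    ctype = spec$ctype, placement = spec$placement, S_c = spec$S_c,
    norm_gfp = eta_c[1] / eta_b[1],
    norm_rfp = if (absent_rfp) NA_real_ else eta_c[2] / eta_b[2],
    norm_total = total_system_noise(eta_c[1], eta_c[2]) /
      total_system_noise(eta_b[1], eta_b[2]),
    rfp_mean = nb$P2
  )
}

#' Normalized-noise grid over RFP dose and controller strength
#'
#' Evaluates [normalized_noise()] on the rectangular grid of RFP gene doses
#' and controller strengths (the strength grid should start at 0, where the
#' fold change is exactly 1). Per-cell failures (e.g. an unstable
#' controlled fixed point) are flagged in the `ok` column rather than
#' aborting the grid.
#'
#' @param modules,context Base system (module-1 constants fixed; module 2's
#'   dose is swept).
#' @param ctype,placement Controller identity, see [controller_spec()].
#' @param g2_grid Non-negative RFP gene doses.
#' @param sc_grid Non-negative controller strengths.
#' @param ... Extra parameters passed to [controller_spec()].
#' @param base_tag Label recorded for the base case ("competitive" or
#'   "orthogonal" according to `context`).
#' @return A `noise_grid` tibble: one row per cell with `g2`, `rfp_mean`,
#'   `S_c`, `norm_gfp`, `norm_rfp`, `norm_total`, `ok`.
#' @export
noise_heatmap <- function(modules, context, ctype, placement,
                          g2_grid, sc_grid, ..., base_tag = context$mode) {
  stopifnot(all(g2_grid >= 0), all(sc_grid >= 0))
  rows <- purrr::map_dfr(g2_grid, function(g2) {
    mods <- modules
    mods[[2]]$g <- g2
    nb <- lna_protein_noise(build_network(mods, context))
    purrr::map_dfr(sc_grid, function(sc) {
      spec <- controller_spec(ctype, placement, S_c = sc, ...)
      res <- tryCatch(
        normalized_noise(mods, context, spec, base_noise = nb),
        error = function(e) NULL)
      if (is.null(res)) {
        tibble::tibble(ctype = ctype, placement = placement, S_c = sc,
                       norm_gfp = NA_real_, norm_rfp = NA_real_,
                       norm_total = NA_real_, rfp_mean = nb$P2,
                       g2 = g2, ok = FALSE)
      } else {
        dplyr::mutate(res, g2 = g2, ok = TRUE)
      }
    })
  })
  rows$base <- base_tag
  class(rows) <- c("noise_grid", class(rows))
  rows
}

#' Deterministic GFP-versus-RFP dose response
#'
#' Sweeps the RFP gene dose and records the mean-field GFP and RFP protein
#' levels with a controller applied (constants as given — the repression of
#' the means is part of what this curve shows), together with the local
#' slope `dGFP/dRFP` (centred differences along the curve). The slope is
#' the qualitative proxy for resource-competitive noise transmission: a
#' shallower slope means the controller decouples the genes more
#' effectively.
#'
#' @param modules,context Base system.
#' @param spec A [controller_spec()], or `NULL` for the uncontrolled
#'   circuit.
#' @param g2_grid Non-negative RFP gene doses (>= 3 points for slopes).
#' @param rescale_at Optional reference dose: the controlled network's rate
#'   constants are rescaled once so that at this dose its fixed point
#'   coincides with the uncontrolled one, anchoring different controllers
#'   to a common operating point before the sweep. `NULL` sweeps the raw
#'   controlled network.
#' @return Tibble: `g2`, `rfp_mean`, `gfp_mean`, `slope`.
#' @export
deterministic_dose_response <- function(modules, context, spec, g2_grid,
                                        rescale_at = NULL) {
  stopifnot(length(g2_grid) >= 3L)
  if (!is.null(spec) && !is.null(rescale_at)) {
    mods_ref <- modules
    mods_ref[[2]]$g <- rescale_at
    ss_ref <- deterministic_steady_state(build_network(mods_ref, context))
    anchored <- rescale_to_means(
      attach_controller(build_network(mods_ref, context), spec),
      unname(ss_ref[1:2]), unname(ss_ref[3:4]))
    modules <- anchored$modules
    spec <- anchored$controller
  }
  pts <- purrr::map_dfr(g2_grid, function(g2) {
    mods <- modules
    mods[[2]]$g <- g2
    net <- build_network(mods, context)
    if (!is.null(spec)) net <- attach_controller(net, spec)
    ss <- deterministic_steady_state(net)
    tibble::tibble(g2 = g2, rfp_mean = ss[["P2"]], gfp_mean = ss[["P1"]])
  })
  n <- nrow(pts)
  slope <- rep(NA_real_, n)
  if (n >= 2) {
    dg <- diff(pts$gfp_mean)
    dr <- diff(pts$rfp_mean)
    inner <- (dg[-1] + dg[-(n - 1)]) / (dr[-1] + dr[-(n - 1)])
    slope[2:(n - 1)] <- inner
    slope[1] <- dg[1] / dr[1]
    slope[n] <- dg[n - 1] / dr[n - 1]
  }
  pts$slope <- slope
  pts
}
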