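#' Stationary covariance from the linear noise approximation
#'
#' Linearises the mean-field dynamics at the deterministic fixed point and
#' solves the continuous Lyapunov equation `A C + C A' + D = 0`, where `A`
#' is the Jacobian of the drift and `D = sum_r a_r(x*) s_r s_r'` is the
#' diffusion matrix assembled from the stationary propensities and
#' stoichiometries. The fixed point must be linearly stable (all Jacobian
#' eigenvalues with negative real part).
#'
#' @param network A `reaction_network`.
#' @param fixed_point Optional precomputed fixed point (named numeric);
#'   defaults to [deterministic_steady_state()].
#' @return Covariance matrix (species x species) with attributes
#'   `fixed_point` and `residual`.
#' @examples
#' lna_covariance(birth_death_network(5, 1)) # variance = mean = 5
#' @export
lna_covariance <- function(network, fixed_point = NULL) {
  x <- fixed_point %||% deterministic_steady_state(network)
  A <- mean_field_jacobian(network, x)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= -1e-12)) {
    stop(sprintf("fixed point is not linearly stable (max Re(eigenvalue) = %.3e)",
                 max(Re(ev))), call. = FALSE)
  }
  a <- network$propensity(as.numeric(x))
  S <- network$stoich
  D <- crossprod(S * sqrt(pmax(a, 0)))
  n <- nrow(A)
  In <- diag(n)
  # vec(AC + CA') = (I (x) A + A (x) I) vec(C)
  M <- kronecker(In, A) + kronecker(A, In)
  C <- matrix(solve(M, -as.numeric(D)), n, n)
  C <- (C + t(C)) / 2
  res <- max(abs(A %*% C + C %*% t(A) + D)) / max(max(abs(D)), 1)
  if (res >= 1e-10) {
    stop(sprintf("Lyapunov residual %.3e exceeds 1e-10", res), call. = FALSE)
  }
  dimnames(C) <- list(network$species, network$species)
  attr(C, "fixed_point") <- x
  attr(C, "residual") <- res
  C
}

#' Static susceptibilities of the GFP translation propensity
#'
#' `H2j = -d ln f1 / d ln m_j` evaluated at the fixed point, with `f1` the
#' module-1 translation propensity; `H21` is the (own-mRNA) gain and `H23`
#' the cross-mRNA inhibition strength. Closed forms for the saturating
#' sharing law: competitive `H21 = -(J_p + m2*)/(J_p + m1* + m2*)`,
#' `H23 = m2*/(J_p + m1* + m2*)`; unlimited `(-1, 0)`; orthogonal
#' `(-J_p/(J_p + m1*), 0)`; frozen_cross as competitive for `H21` with the
#' frozen cross value, and `H23 = 0`. Only the squares enter the noise
#' decomposition, so the sign convention (fixed by the unlimited-resource
#' value -1) is observationally neutral but kept consistent.
#'
#' @param context A [resource_context()].
#' @param modules Modules, used to locate the fixed point when
#'   `fixed_point` is not given.
#' @param fixed_point Optional named state (needs `m1`, `m2`).
#' @return Named numeric vector `c(H21, H23)`.
#' @export
susceptibilities <- function(context, modules = NULL, fixed_point = NULL) {
  if (is.null(fixed_point)) {
    stopifnot(!is.null(modules))
    fixed_point <- deterministic_steady_state(build_network(modules, context))
  }
  m1 <- fixed_point[["m1"]]
  m2 <- fixed_point[["m2"]]
  if (m1 <= 0) stop("zero GFP mRNA mean: susceptibilities undefined",
                    call. = FALSE)
  Jp <- context$J_p
  out <- switch(context$mode,
    unlimited = c(-1, 0),
    competitive = c(-(Jp + m2) / (Jp + m1 + m2), m2 / (Jp + m1 + m2)),
    orthogonal = c(-Jp / (Jp + m1), 0),
    frozen_cross = {
      mu2 <- context$frozen_means[2]
      c(-(Jp + mu2) / (Jp + m1 + mu2), 0)
    }
  )
  names(out) <- c("H21", "H23")
  out
}

#' Three-term fluctuation-dissipation decomposition of GFP noise
#'
#' Splits the squared coefficient of variation of the GFP protein into
#' three additive sources:
#' \describe{
#'   \item{`eta_p2 = 1/P1`}{low-copy protein birth/death noise;}
#'   \item{`eta_m2`}{noise propagated from the gene's own mRNA:
#'     `(sigma_m1^2/M1^2) H21^2 (1/tau2)/(1/tau1 + 1/tau2)`;}
#'   \item{`eta_rc2`}{resource-competitive noise propagated from the
#'     opposing mRNA through shared translation:
#'     `(sigma_m2^2/M2^2) H23^2 (1/tau2)/(1/tau3 + 1/tau2)`.}
#' }
#' `tau1`, `tau2`, `tau3` are the gfp mRNA, GFP protein and rfp mRNA
#' lifetimes; the lifetime ratios are the usual time-averaging factors. The
#' mRNA variances are taken from the LNA (Poisson here, since gene doses
#' are deterministic constants). Because the two mRNAs are independent
#' upstream sources, the three terms sum exactly to the full LNA `CV^2` of
#' `P1`.
#'
#' @param modules List of two [gene_module()] objects.
#' @param context A [resource_context()].
#' @return A `noise_decomposition` object; see [tidy()] / [glance()]
#'   methods.
#' @examples
#' net_params <- match_means(list(gene_module(), gene_module()),
#'                           resource_context("competitive"))
#' decompose_noise(net_params, resource_context("competitive"))
#' @export
decompose_noise <- function(modules, context) {
  network <- build_network(modules, context)
  x <- deterministic_steady_state(network)
  C <- lna_covariance(network, fixed_point = x)
  H <- susceptibilities(context, fixed_point = x)
  d_m1 <- modules[[1]]$d_m; d_p1 <- modules[[1]]$d_p
  d_m2 <- modules[[2]]$d_m
  tau1 <- 1 / d_m1; tau2 <- 1 / d_p1; tau3 <- 1 / d_m2
  M1 <- x[["m1"]]; M2 <- x[["m2"]]; P1 <- x[["P1"]]
  s2_m1 <- C["m1", "m1"]; s2_m2 <- C["m2", "m2"]
  eta_p2 <- 1 / P1
  eta_m2 <- (s2_m1 / M1^2) * H[["H21"]]^2 * (d_p1 / (d_m1 + d_p1))
  eta_rc2 <- if (M2 > 0) {
    (s2_m2 / M2^2) * H[["H23"]]^2 * (d_p1 / (d_m2 + d_p1))
  } else {
    0 # no opposing expression: the cross channel carries no noise
  }
  structure(list(
    eta_p2 = eta_p2, eta_m2 = eta_m2, eta_rc2 = eta_rc2,
    eta_total2 = eta_p2 + eta_m2 + eta_rc2,
    H21 = H[["H21"]], H23 = H[["H23"]],
    tau1 = tau1, tau2 = tau2, tau3 = tau3,
    sigma_m1_2 = s2_m1, sigma_m2_2 = s2_m2,
    M1 = M1, M2 = M2, P1 = P1,
    mode = context$mode
  ), class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat(sprintf("<noise_decomposition> (%s mode)\n", x$mode))
  cat(sprintf("  eta_p^2  = %.5g\n  eta_m^2  = %.5g\n  eta_RC^2 = %.5g\n",
              x$eta_p2, x$eta_m2, x$eta_rc2))
  cat(sprintf("  total CV^2(P1) = %.5g  (H21 = %.4f, H23 = %.4f)\n",
              x$eta_total2, x$H21, x$H23))
  invisible(x)
}

#' Protein noise and reporter correlation from the LNA
#'
#' Convenience wrapper around [lna_covariance()] returning the quantities
#' the controller experiments consume.
#'
#' @param network A `reaction_network`.
#' @param fixed_point Optional precomputed fixed point.
#' @return One-row tibble: `eta2_P1`, `eta2_P2` (squared CVs), `corr`
#'   (stationary Pearson correlation of the protein pair) and the four
#'   stationary means.
#' @export
lna_protein_noise <- function(network, fixed_point = NULL) {
  C <- lna_covariance(network, fixed_point = fixed_point)
  x <- attr(C, "fixed_point")
  v1 <- max(C["P1", "P1"], 0)
  v2 <- max(C["P2", "P2"], 0)
  tibble::tibble(
    eta2_P1 = v1 / x[["P1"]]^2,
    eta2_P2 = v2 / x[["P2"]]^2,
    corr = C["P1", "P2"] / sqrt(v1 * v2),
    m1 = x[["m1"]], m2 = x[["m2"]], P1 = x[["P1"]], P2 = x[["P2"]]
  )
}

#' Noise decomposition along a translational-capacity sweep
#'
#' Evaluates the three-term decomposition on a grid of `J_p` with the rate
#' constants held fixed (no per-point recalibration), tracing how the noise
#' composition shifts as shared translation is relaxed: the
#' resource-competitive term falls monotonically, the own-mRNA term rises
#' toward its unlimited-resource value, and their sum is non-monotone.
#'
#' @param modules Calibrated modules (held fixed along the sweep).
#' @param context A [resource_context()]; its `J_p` is replaced grid-wise.
#' @param jp_grid Positive vector of translational capacities.
#' @return Tibble with one row per `J_p`: all decomposition components and
#'   the stationary means.
#' @export
sweep_jp <- function(modules, context, jp_grid) {
  stopifnot(all(jp_grid > 0))
  purrr::map_dfr(jp_grid, function(jp) {
    ctx <- context
    ctx$J_p <- jp
    d <- decompose_noise(modules, ctx)
    tibble::tibble(J_p = jp, eta_p2 = d$eta_p2, eta_m2 = d$eta_m2,
                   eta_rc2 = d$eta_rc2, eta_total2 = d$eta_total2,
                   M1 = d$M1, M2 = d$M2, P1 = d$P1)
  })
}

#' Resource-competitive fraction of the total GFP noise
#'
#' Returns `eta_RC^2 / eta_total^2` (variance-fraction convention) for a
#' resource-competitive configuration; zero in the unlimited model.
#'
#' @inheritParams decompose_noise
#' @return A fraction in `[0, 1]`.
#' @export
rc_noise_fraction <- function(modules, context) {
  d <- decompose_noise(modules, context)
  d$eta_rc2 / d$eta_total2
}

#' GFP noise as a function of the achieved RFP mean
#'
#' Sweeps the effective RFP gene dose and compares the GFP total noise
#' between the resource-competitive and orthogonal-resource systems. The
#' orthogonal system is the calibration base: at every dose the competitive
#' constants are rescaled so both systems share the same mRNA and protein
#' means, which keeps the GFP operating point (and hence its birth/death
#' noise) fixed along the sweep and makes the two systems exactly
#' coincident when the RFP dose is zero.
#'
#' @param g2_grid Non-negative vector of RFP gene doses.
#' @param target_m,target_p GFP-module operating point (copies).
#' @param J_p,J_g,d_m,d_p Shared model parameters.
#' @return Tibble with columns `system` ("competitive"/"orthogonal"), `g2`,
#'   `rfp_mean` and the decomposition components.
#' @export
noise_vs_rfp_mean <- function(g2_grid, target_m = 10, target_p = 100,
                              J_p = 10, J_g = 20, d_m = 1, d_p = 0.1) {
  stopifnot(all(g2_grid >= 0))
  ctx_or <- resource_context("orthogonal", J_p = J_p, J_g = J_g)
  ctx_rc <- resource_context("competitive", J_p = J_p, J_g = J_g)
  base_or <- match_means(
    list(gene_module(d_m = d_m, d_p = d_p), gene_module(d_m = d_m, d_p = d_p)),
    ctx_or, target_m = c(target_m, target_m), target_p = c(target_p, target_p))
  purrr::map_dfr(g2_grid, function(g2) {
    mods_or <- base_or
    mods_or[[2]]$g <- g2
    ss_or <- deterministic_steady_state(build_network(mods_or, ctx_or))
    d_or <- decompose_noise(mods_or, ctx_or)
    # rescale the competitive system onto the orthogonal means at this dose
    mods_rc <- mods_or
    if (g2 > 0) {
      mods_rc <- match_means(mods_rc, ctx_rc,
                             target_m = c(ss_or[["m1"]], ss_or[["m2"]]),
                             target_p = c(ss_or[["P1"]], ss_or[["P2"]]))
    } else {
      # single-gene circuit: competitive and orthogonal laws coincide
      mods_rc <- mods_or
    }
    d_rc <- decompose_noise(mods_rc, ctx_rc)
    tibble::tibble(
      system = c("competitive", "orthogonal"),
      g2 = g2,
      rfp_mean = ss_or[["P2"]],
      eta_p2 = c(d_rc$eta_p2, d_or$eta_p2),
      eta_m2 = c(d_rc$eta_m2, d_or$eta_m2),
      eta_rc2 = c(d_rc$eta_rc2, d_or$eta_rc2),
      eta_total2 = c(d_rc$eta_total2, d_or$eta_total2)
    )
  })
}
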