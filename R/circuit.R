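#' Define a gene expression module
#'
#' A module is one reporter gene (GFP or RFP) described by its effective gene
#' dose and four first-order rate constants. In the default configuration the
#' two modules of a circuit are identical except possibly for the gene dose.
#'
#' @param g Effective gene copy number (dimensionless, >= 0). Copy-number
#'   sweeps vary this for the second (RFP) module.
#' @param k_m Transcription rate constant (mRNA copies per time per unit gene
#'   dose).
#' @param k_p Translation rate constant (per mRNA per time).
#' @param d_m mRNA degradation rate (per time, > 0).
#' @param d_p Protein degradation rate (per time, > 0).
#' @return An object of class `gene_module`.
#' @examples
#' gene_module(g = 1, k_m = 10, k_p = 1)
#' @export
gene_module <- function(g = 1, k_m = 10, k_p = 1, d_m = 1, d_p = 0.1) {
  stopifnot(
    "gene dose must be a single non-negative number" =
      is.numeric(g) && length(g) == 1L && is.finite(g) && g >= 0,
    "k_m must be a single non-negative number" =
      is.numeric(k_m) && length(k_m) == 1L && is.finite(k_m) && k_m >= 0,
    "k_p must be a single non-negative number" =
      is.numeric(k_p) && length(k_p) == 1L && is.finite(k_p) && k_p >= 0,
    "d_m must be > 0" = is.numeric(d_m) && length(d_m) == 1L && d_m > 0,
    "d_p must be > 0" = is.numeric(d_p) && length(d_p) == 1L && d_p > 0
  )
  structure(list(g = g, k_m = k_m, k_p = k_p, d_m = d_m, d_p = d_p),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf(
    "<gene_module> g=%g  k_m=%g  k_p=%g  d_m=%g  d_p=%g\n",
    x$g, x$k_m, x$k_p, x$d_m, x$d_p))
  invisible(x)
}

resource_modes <- c("unlimited", "competitive", "orthogonal", "frozen_cross")

#' Define the resource environment of a circuit
#'
#' The resource context fixes how transcription and translation propensities
#' saturate with total demand. Four modes are supported:
#' \describe{
#'   \item{unlimited}{idealised model: rates linear in gene dose / mRNA.}
#'   \item{competitive}{both genes draw on one shared RNAP pool (capacity
#'     `J_g`, in gene-dose units) and one shared ribosome pool (capacity
#'     `J_p`, in mRNA copies), so each gene's rates are inhibited by the
#'     total demand of both.}
#'   \item{orthogonal}{each gene has its own dedicated resource pools:
#'     self-saturation remains but the cross-gene inhibition is removed.}
#'   \item{frozen_cross}{as `competitive`, except that inside each
#'     translation propensity the opposing mRNA is replaced by a fixed
#'     constant (normally its stationary mean). This removes the
#'     resource-competitive noise channel while leaving the deterministic
#'     operating point untouched.}
#' }
#'
#' @param mode One of `"unlimited"`, `"competitive"`, `"orthogonal"`,
#'   `"frozen_cross"` (case-insensitive).
#' @param J_p Translational capacity (mRNA copies at which shared translation
#'   half-saturates). Must be > 0 unless `mode = "unlimited"`; `Inf` recovers
#'   the unlimited law.
#' @param J_g Transcriptional capacity (gene-dose units), same convention.
#' @param frozen_means Length-2 non-negative vector of fixed cross-mRNA
#'   values; required for (and only used by) `frozen_cross`.
#' @return An object of class `resource_context`.
#' @examples
#' resource_context("competitive", J_p = 10, J_g = 20)
#' @export
resource_context <- function(mode = "competitive", J_p = 10, J_g = 20,
                             frozen_means = NULL) {
  mode <- match.arg(tolower(mode), resource_modes)
  if (mode != "unlimited") {
    stopifnot(
      "J_p must be > 0 in resource-limited modes" =
        is.numeric(J_p) && length(J_p) == 1L && J_p > 0,
      "J_g must be > 0 in resource-limited modes" =
        is.numeric(J_g) && length(J_g) == 1L && J_g > 0
    )
  }
  if (mode == "frozen_cross") {
    stopifnot(
      "frozen_means must be a length-2 non-negative vector" =
        is.numeric(frozen_means) && length(frozen_means) == 2L &&
        all(is.finite(frozen_means)) && all(frozen_means >= 0)
    )
  }
  structure(list(mode = mode, J_p = J_p, J_g = J_g,
                 frozen_means = frozen_means),
            class = "resource_context")
}

#' @export
print.resource_context <- function(x, ...) {
  cat(sprintf("<resource_context> mode=%s  J_p=%g  J_g=%g%s\n",
              x$mode, x$J_p, x$J_g,
              if (is.null(x$frozen_means)) "" else
                sprintf("  frozen_means=(%g, %g)",
                        x$frozen_means[1], x$frozen_means[2])))
  invisible(x)
}

check_state <- function(state) {
  if (!is.numeric(state) || length(state) < 2L || any(state < 0) ||
      any(!is.finite(state))) {
    stop("state must be a non-negative finite numeric vector", call. = FALSE)
  }
  invisible(state)
}

#' Transcription propensity of one module
#'
#' Gene doses are deterministic constants, so the transcription propensity is
#' state-independent in every mode; the shared transcriptional pool rescales
#' the mean only. Laws: unlimited `k_m g_i`; competitive (and frozen_cross)
#' `k_m g_i / (1 + (g_1 + g_2)/J_g)`; orthogonal `k_m g_i / (1 + g_i/J_g)`.
#'
#' @param module_index 1 (GFP) or 2 (RFP).
#' @param state Circuit state `c(m1, m2, P1, P2)` (validated, unused by the
#'   base law).
#' @param context A [resource_context()].
#' @param modules List of two [gene_module()] objects.
#' @return Transcription rate (per time).
#' @export
transcription_propensity <- function(module_index, state, context, modules) {
  stopifnot(module_index %in% c(1L, 2L))
  check_state(state)
  mod <- modules[[module_index]]
  g_self <- mod$g
  g_tot <- modules[[1]]$g + modules[[2]]$g
  base <- mod$k_m * g_self
  switch(context$mode,
    unlimited = base,
    competitive = ,
    frozen_cross = base / (1 + g_tot / context$J_g),
    orthogonal = base / (1 + g_self / context$J_g)
  )
}

#' Translation propensity of one module
#'
#' The translation propensity couples the two modules when ribosomes are
#' shared. Laws (with `m_i` the module's own mRNA count and `m_j` the
#' opposing one): unlimited `k_p m_i`; competitive
#' `k_p m_i / (1 + (m_1 + m_2)/J_p)`; orthogonal `k_p m_i / (1 + m_i/J_p)`;
#' frozen_cross `k_p m_i / (1 + (m_i + mu_j)/J_p)` with `mu_j` the fixed
#' cross-mRNA value from the context.
#'
#' @inheritParams transcription_propensity
#' @param state Circuit state `c(m1, m2, P1, P2)`.
#' @return Translation rate (per time).
#' @export
translation_propensity <- function(module_index, state, context, modules) {
  stopifnot(module_index %in% c(1L, 2L))
  check_state(state)
  kp <- modules[[module_index]]$k_p
  m_self <- state[module_index]
  m_other <- state[3L - module_index]
  switch(context$mode,
    unlimited = kp * m_self,
    competitive = kp * m_self / (1 + (m_self + m_other) / context$J_p),
    orthogonal = kp * m_self / (1 + m_self / context$J_p),
    frozen_cross = kp * m_self /
      (1 + (m_self + context$frozen_means[3L - module_index]) / context$J_p)
  )
}

# Translation rate and its partial derivatives for module i, as functions of
# (m1, m2). Used by the mean-field Jacobian and by the CME generator; all
# vectorised over the mRNA arguments.
translation_law <- function(i, context, modules) {
  kp <- modules[[i]]$k_p
  Jp <- context$J_p
  j <- 3L - i
  switch(context$mode,
    unlimited = list(
      f = function(m1, m2) kp * (if (i == 1L) m1 else m2),
      d_self = function(m1, m2) rep_len(kp, length(m1)),
      d_other = function(m1, m2) rep_len(0, length(m1))
    ),
    competitive = list(
      f = function(m1, m2) {
        ms <- if (i == 1L) m1 else m2
        kp * ms / (1 + (m1 + m2) / Jp)
      },
      d_self = function(m1, m2) {
        mo <- if (i == 1L) m2 else m1
        den <- 1 + (m1 + m2) / Jp
        kp * (1 + mo / Jp) / den^2
      },
      d_other = function(m1, m2) {
        ms <- if (i == 1L) m1 else m2
        den <- 1 + (m1 + m2) / Jp
        -kp * ms / (Jp * den^2)
      }
    ),
    orthogonal = list(
      f = function(m1, m2) {
        ms <- if (i == 1L) m1 else m2
        kp * ms / (1 + ms / Jp)
      },
      d_self = function(m1, m2) {
        ms <- if (i == 1L) m1 else m2
        kp / (1 + ms / Jp)^2
      },
      d_other = function(m1, m2) rep_len(0, length(m1))
    ),
    frozen_cross = {
      mu <- context$frozen_means[j]
      list(
        f = function(m1, m2) {
          ms <- if (i == 1L) m1 else m2
          kp * ms / (1 + (ms + mu) / Jp)
        },
        d_self = function(m1, m2) {
          ms <- if (i == 1L) m1 else m2
          kp * (1 + mu / Jp) / (1 + (ms + mu) / Jp)^2
        },
        d_other = function(m1, m2) rep_len(0, length(m1))
      )
    }
  )
}

base_species <- c("m1", "m2", "P1", "P2")

base_stoich <- function() {
  s <- rbind(
    tx1    = c(1, 0, 0, 0),
    tx2    = c(0, 1, 0, 0),
    deg_m1 = c(-1, 0, 0, 0),
    deg_m2 = c(0, -1, 0, 0),
    tl1    = c(0, 0, 1, 0),
    tl2    = c(0, 0, 0, 1),
    deg_P1 = c(0, 0, -1, 0),
    deg_P2 = c(0, 0, 0, -1)
  )
  colnames(s) <- base_species
  s
}

#' Build the reaction network of a two-gene circuit
#'
#' Assembles the eight-reaction birth/death network (transcription,
#' translation, mRNA decay and protein decay for each module) under the rate
#' laws of the given resource context, optionally with a negative-feedback
#' controller attached (see [controller_spec()]). Construction is
#' deterministic: identical inputs give identical networks.
#'
#' @param modules List of two [gene_module()] objects (GFP first, RFP
#'   second).
#' @param context A [resource_context()].
#' @param controller Optional [controller_spec()]; equivalent to calling
#'   [attach_controller()] on the base network.
#' @return An object of class `reaction_network` with fields `species`,
#'   `stoich` (reactions x species), `propensity(x)` (one state vector ->
#'   rate vector), `propensity_grid(X)` (state matrix -> rate matrix),
#'   `modules`, `context`, `controller` and a serialisable `provenance`
#'   record.
#' @examples
#' net <- build_network(list(gene_module(), gene_module()),
#'                      resource_context("unlimited"))
#' net$propensity(c(10, 10, 100, 100))
#' @export
build_network <- function(modules, context, controller = NULL) {
  stopifnot(
    "modules must be a list of two gene_module objects" =
      is.list(modules) && length(modules) == 2L &&
      all(vapply(modules, inherits, TRUE, "gene_module")),
    "context must be a resource_context" = inherits(context, "resource_context")
  )
  T1 <- transcription_propensity(1L, c(0, 0, 0, 0), context, modules)
  T2 <- transcription_propensity(2L, c(0, 0, 0, 0), context, modules)
  dm1 <- modules[[1]]$d_m; dm2 <- modules[[2]]$d_m
  dp1 <- modules[[1]]$d_p; dp2 <- modules[[2]]$d_p
  law1 <- translation_law(1L, context, modules)
  law2 <- translation_law(2L, context, modules)
  f1 <- law1$f; f2 <- law2$f

  propensity <- function(x) {
    c(T1, T2, dm1 * x[1L], dm2 * x[2L],
      f1(x[1L], x[2L]), f2(x[1L], x[2L]), dp1 * x[3L], dp2 * x[4L])
  }
  propensity_grid <- function(X) {
    n <- nrow(X)
    cbind(rep_len(T1, n), rep_len(T2, n), dm1 * X[, 1L], dm2 * X[, 2L],
          f1(X[, 1L], X[, 2L]), f2(X[, 1L], X[, 2L]),
          dp1 * X[, 3L], dp2 * X[, 4L])
  }

  net <- structure(list(
    species = base_species,
    stoich = base_stoich(),
    propensity = propensity,
    propensity_grid = propensity_grid,
    translation_laws = list(law1, law2),
    tx_rates = c(T1, T2),
    modules = modules,
    context = context,
    controller = NULL,
    provenance = list(
      mode = context$mode,
      J_p = context$J_p, J_g = context$J_g,
      frozen_means = context$frozen_means,
      modules = lapply(modules, unclass),
      controller = NULL
    )
  ), class = "reaction_network")
  if (!is.null(controller)) net <- attach_controller(net, controller)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s mode, %d species, %d reactions%s\n",
              x$context$mode, length(x$species), nrow(x$stoich),
              if (is.null(x$controller)) "" else
                sprintf(", %s-%s controller (S_c=%g)",
                        x$controller$ctype, x$controller$placement,
                        x$controller$S_c)))
  invisible(x)
}

# Mean-field drift dx/dt = S^T a(x)
mean_field_drift <- function(network, x) {
  as.numeric(crossprod(network$stoich, network$propensity(x)))
}

# Jacobian of the mean-field drift. Analytic for base networks (the rate laws
# have simple closed-form partials); central finite differences once a
# controller multiplies propensities by effector-dependent factors.
mean_field_jacobian <- function(network, x) {
  n <- length(x)
  if (is.null(network$controller) && !is.null(network$translation_laws)) {
    mods <- network$modules
    l1 <- network$translation_laws[[1]]; l2 <- network$translation_laws[[2]]
    J <- matrix(0, n, n, dimnames = list(network$species, network$species))
    J[1, 1] <- -mods[[1]]$d_m
    J[2, 2] <- -mods[[2]]$d_m
    J[3, 1] <- l1$d_self(x[1], x[2]); J[3, 2] <- l1$d_other(x[1], x[2])
    J[3, 3] <- -mods[[1]]$d_p
    J[4, 1] <- l2$d_other(x[1], x[2]); J[4, 2] <- l2$d_self(x[1], x[2])
    J[4, 4] <- -mods[[2]]$d_p
    return(J)
  }
  J <- matrix(0, n, n, dimnames = list(network$species, network$species))
  h <- pmax(abs(x), 1) * (.Machine$double.eps)^(1 / 3)
  for (j in seq_len(n)) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- max(x[j] - h[j], 0)
    J[, j] <- (mean_field_drift(network, xp) - mean_field_drift(network, xm)) /
      (xp[j] - xm[j])
  }
  J
}

#' Deterministic (mean-field) steady state of a network
#'
#' For base networks the fixed point is available in closed form: the
#' transcription propensities are state-independent, so the mRNA means follow
#' by linear balance and the protein means by evaluating the translation law
#' at those means. Controlled networks are solved by integrating the
#' mean-field ODE towards the attractor and polishing with damped Newton
#' iterations.
#'
#' @param network A [build_network()] object.
#' @param tol Maximum residual norm of the drift at the returned point.
#' @return Named numeric vector of stationary copy numbers.
#' @examples
#' net <- build_network(list(gene_module(), gene_module()),
#'                      resource_context("unlimited"))
#' deterministic_steady_state(net)
#' @export
deterministic_steady_state <- function(network, tol = 1e-10) {
  if (!is.null(network$translation_laws)) {
    mods <- network$modules
    m_star <- network$tx_rates / c(mods[[1]]$d_m, mods[[2]]$d_m)
    x <- c(m_star,
           network$translation_laws[[1]]$f(m_star[1], m_star[2]) / mods[[1]]$d_p,
           network$translation_laws[[2]]$f(m_star[1], m_star[2]) / mods[[2]]$d_p)
    if (is.null(network$controller)) {
      names(x) <- network$species
      return(x)
    }
    if (identical(network$controller$ctype, "ncr")) {
      x <- c(x, ncr_sensor_targets(network$controller, x[1:2], x[3:4]))
    }
    names(x) <- network$species
    t_relax <- 50 / min(mods[[1]]$d_p, mods[[2]]$d_p)
  } else {
    x <- rep(1, length(network$species))
    names(x) <- network$species
    t_relax <- 200
  }
  # warm start from the uncontrolled fixed point, relax along the ODE flow,
  # then Newton-polish
  ode_rhs <- function(t, y, parms) list(mean_field_drift(network, pmax(y, 0)))
  sol <- deSolve::lsoda(y = x, times = c(0, t_relax),
                        func = ode_rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  for (it in seq_len(100L)) {
    r <- mean_field_drift(network, y)
    if (max(abs(r)) < tol) break
    J <- mean_field_jacobian(network, y)
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in steady-state solve",
                            call. = FALSE)
    lambda <- 1
    repeat {
      y_new <- pmax(y + lambda * step, 0)
      if (max(abs(mean_field_drift(network, y_new))) < max(abs(r)) ||
          lambda < 1e-6) break
      lambda <- lambda / 2
    }
    y <- y_new
  }
  r <- mean_field_drift(network, y)
  if (max(abs(r)) >= tol) {
    stop(sprintf(
      "steady-state solve did not converge (residual %.3e, tol %.3e)",
      max(abs(r)), tol), call. = FALSE)
  }
  names(y) <- network$species
  y
}
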