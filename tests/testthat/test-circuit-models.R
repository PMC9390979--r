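test_that("transcription propensity follows the sharing laws", {
  mods <- list(gene_module(k_m = 10), gene_module(k_m = 10))
  st <- c(0, 0, 0, 0)
  expect_equal(
    transcription_propensity(1, st, resource_context("unlimited"), mods), 10)
  expect_equal(
    transcription_propensity(1, st, resource_context("competitive", J_g = 2),
                             mods), 5)
  expect_equal(
    transcription_propensity(1, st, resource_context("orthogonal", J_g = 2),
                             mods), 10 / 1.5)
  # infinite capacity recovers the unlimited law
  expect_equal(
    transcription_propensity(1, st, resource_context("competitive", J_g = Inf),
                             mods), 10)
  expect_error(transcription_propensity(1, c(-1, 0, 0, 0),
                                        resource_context("unlimited"), mods),
               "non-negative")
})

test_that("translation propensity follows the sharing laws", {
  mods <- list(gene_module(k_p = 1), gene_module(k_p = 1))
  st <- c(10, 10, 0, 0)
  expect_equal(
    translation_propensity(1, st, resource_context("unlimited"), mods), 10)
  expect_equal(
    translation_propensity(1, st, resource_context("competitive", J_p = 10),
                           mods), 10 / 3)
  expect_equal(
    translation_propensity(1, st, resource_context("orthogonal", J_p = 10),
                           mods), 5)
  fz <- resource_context("frozen_cross", J_p = 10, frozen_means = c(10, 10))
  expect_equal(translation_propensity(1, st, fz, mods), 10 / 3)
  # frozen cross ignores the live opposing mRNA
  expect_equal(translation_propensity(1, c(10, 37, 0, 0), fz, mods), 10 / 3)
  expect_equal(
    translation_propensity(1, st, resource_context("competitive", J_p = Inf),
                           mods), 10)
})

test_that("propensities approach the unlimited law monotonically in capacity", {
  mods <- default_modules()
  states <- random_states(20, max_copies = 40)
  ur <- resource_context("unlimited")
  for (jp in list(c(1, 10), c(10, 100), c(100, 1e4))) {
    for (k in seq_len(nrow(states))) {
      st <- states[k, ]
      a_lo <- translation_propensity(1, st, rc_context(J_p = jp[1]), mods)
      a_hi <- translation_propensity(1, st, rc_context(J_p = jp[2]), mods)
      a_ur <- translation_propensity(1, st, ur, mods)
      expect_true(abs(a_hi - a_ur) <= abs(a_lo - a_ur) + 1e-12)
    }
  }
})

test_that("build_network returns the 8-reaction base network deterministically", {
  net <- build_network(default_modules(), resource_context("unlimited"))
  expect_s3_class(net, "reaction_network")
  expect_length(net$species, 4L)
  expect_equal(nrow(net$stoich), 8L)
  expect_true(all(rowSums(abs(net$stoich)) >= 1))
  net2 <- build_network(default_modules(), resource_context("unlimited"))
  st <- c(3, 7, 20, 50)
  expect_identical(net$propensity(st), net2$propensity(st))
  expect_error(build_network(default_modules(), "competitive"),
               "resource_context")
})

test_that("scalar and grid propensity paths agree on random states", {
  nets <- list(
    build_network(default_modules(), resource_context("unlimited")),
    build_network(default_modules(), rc_context()),
    build_network(default_modules(), resource_context("orthogonal")),
    build_network(default_modules(),
                  resource_context("frozen_cross", frozen_means = c(9, 11))),
    attach_controller(build_network(default_modules(), rc_context()),
                      controller_spec("local", "MIL", S_c = 3)),
    attach_controller(build_network(default_modules(), rc_context()),
                      controller_spec("global", "PIX", S_c = 5)),
    attach_controller(build_network(default_modules(), rc_context()),
                      controller_spec("ncr", "MIX", S_c = 14, alpha_s = 1))
  )
  for (net in nets) {
    X <- random_states(25, n_species = length(net$species))
    A <- net$propensity_grid(X)
    for (k in seq_len(nrow(X))) {
      expect_equal(as.numeric(A[k, ]), net$propensity(X[k, ]),
                   tolerance = 1e-12)
    }
    expect_true(all(is.finite(A)) && all(A >= 0))
  }
})

test_that("deterministic steady state matches linear balance", {
  ur <- build_network(default_modules(), resource_context("unlimited"))
  expect_equal(deterministic_steady_state(ur),
               c(m1 = 10, m2 = 10, P1 = 100, P2 = 100))
  # shared translation at m* = 10 each, J_p = 10 gives flux 10/3
  rc <- build_network(
    list(gene_module(k_m = 11), gene_module(k_m = 11)), rc_context())
  ss <- deterministic_steady_state(rc)
  expect_equal(unname(ss[c("m1", "P1")]), c(10, (10 / 3) / 0.1),
               tolerance = 1e-12)
  # J_p -> infinity recovers the unlimited fixed point
  rc_inf <- build_network(default_modules(), rc_context(J_p = 1e12, J_g = Inf))
  expect_equal(deterministic_steady_state(rc_inf),
               deterministic_steady_state(ur), tolerance = 1e-9)
})

test_that("module swap permutes the fixed point in asymmetric circuits", {
  ctx <- rc_context()
  mods <- calibrated_modules()$modules
  mods[[2]]$g <- 3
  ss <- deterministic_steady_state(build_network(mods, ctx))
  ss_swap <- deterministic_steady_state(build_network(mods[c(2, 1)], ctx))
  expect_equal(unname(ss[c("m2", "m1", "P2", "P1")]), unname(ss_swap),
               tolerance = 1e-12)
})

test_that("frozen-cross at competitive means shares the competitive fixed point", {
  cal <- calibrated_modules()
  ss_rc <- deterministic_steady_state(build_network(cal$modules, cal$context))
  fz <- resource_context("frozen_cross", J_p = 10, J_g = 20,
                         frozen_means = unname(ss_rc[c("m1", "m2")]))
  ss_fz <- deterministic_steady_state(build_network(cal$modules, fz))
  expect_equal(ss_fz, ss_rc, tolerance = 1e-8)
})

test_that("networks can be built from config lists and files", {
  cfg <- list(mode = "competitive", J_p = 10, J_g = 20,
              calibration = list(target_m = 10, target_p = 100),
              controller = list(ctype = "local", placement = "MIX", S_c = 2))
  net <- circuit_from_config(cfg)
  expect_identical(net$controller$placement, "MIX")
  expect_equal(unname(deterministic_steady_state(
    build_network(net$modules, net$context))[1:2]), c(10, 10))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  net2 <- circuit_from_config(path)
  expect_equal(net2$modules[[1]]$k_m, net$modules[[1]]$k_m)
  expect_error(circuit_from_config(list(mode = "competitive", bogus = 1)),
               "bogus")
  js <- write_provenance(net)
  expect_true(jsonlite::validate(js))
})
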