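test_that("effector levels follow the three controller topologies", {
  st <- c(10, 4, 100, 40)
  expect_equal(effector(controller_spec("global", "MIX", 1), st, 1), 14)
  expect_equal(effector(controller_spec("global", "PIX", 1), st, 2), 140)
  expect_equal(effector(controller_spec("local", "MIL", 1), st, 2), 4)
  expect_equal(effector(controller_spec("local", "PIL", 1), st, 1), 100)
  # symmetric NCR sensors split the machinery pool evenly
  ncr <- controller_spec("ncr", "MIX", 1, K_b = 10, dcas_total = 50,
                         alpha_s = 1)
  st_s <- c(10, 10, 100, 100, 10, 10)
  expect_equal(effector(ncr, st_s, 1), 50 * 1 / 3)
  expect_equal(effector(ncr, st_s, 1), effector(ncr, st_s, 2))
  expect_error(effector(ncr, st, 1), "missing")
  # conservation: complexes never exceed the pool
  X <- random_states(50, n_species = 6L, max_copies = 500, seed = 9)
  for (k in seq_len(nrow(X))) {
    tot <- effector(ncr, X[k, ], 1) + effector(ncr, X[k, ], 2)
    expect_lte(tot, 50 + 1e-12)
  }
})

test_that("zero strength is the exact identity for all twelve configurations", {
  net <- build_network(default_modules(), rc_context())
  cfgs <- all_controller_configs()
  X4 <- random_states(20, n_species = 4L)
  for (k in seq_len(nrow(cfgs))) {
    spec <- controller_spec(cfgs$ctype[k], cfgs$placement[k], S_c = 0)
    ctrl <- attach_controller(net, spec)
    for (j in seq_len(nrow(X4))) {
      x <- X4[j, ]
      if (length(ctrl$species) == 6L) x <- c(x, 7, 13)
      expect_equal(ctrl$propensity(x)[1:8], net$propensity(X4[j, ]),
                   tolerance = 1e-14)
    }
    expect_equal(normalized_noise(net$modules, net$context, spec)$norm_gfp,
                 1, tolerance = 1e-9)
  }
  expect_error(attach_controller(attach_controller(net,
    controller_spec("local", "MIX", 1)), controller_spec("local", "MIX", 1)),
    "already")
})

test_that("feedback onset lowers the controlled module means", {
  net <- build_network(default_modules(), rc_context())
  for (ct in c("local", "global", "ncr")) {
    means <- vapply(c(0, 0.5, 1, 2), function(sc) {
      ss <- deterministic_steady_state(
        attach_controller(net, controller_spec(ct, "MIL", S_c = sc)))
      ss[["P1"]]
    }, 0)
    expect_true(all(diff(means) < 1e-8))
  }
})

test_that("rescaled controlled networks sit exactly on the base operating point", {
  net <- strong_competition_network()
  ss <- deterministic_steady_state(net)
  spec <- controller_spec("ncr", "MIL", S_c = 14)
  ctrl <- rescale_to_means(attach_controller(net, spec),
                           unname(ss[1:2]), unname(ss[3:4]))
  ss_c <- deterministic_steady_state(ctrl)
  expect_equal(unname(ss_c[1:4]), unname(ss), tolerance = 1e-8)
})

test_that("controller families reproduce the qualitative noise phenotypes", {
  net <- strong_competition_network()
  mods <- net$modules
  ctx <- net$context
  g2_grid <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  sweep_ct <- function(ct, pl, sc = 14) {
    purrr::map_dfr(g2_grid, function(g2) {
      m <- mods
      m[[2]]$g <- g2
      normalized_noise(m, ctx, controller_spec(ct, pl, S_c = sc))
    })
  }
  ncr_mix <- sweep_ct("ncr", "MIX")
  ncr_pix <- sweep_ct("ncr", "PIX")
  ncr_mil <- sweep_ct("ncr", "MIL")
  ncr_pil <- sweep_ct("ncr", "PIL")
  # transcription-inhibiting NCR reduces noise over the whole dose range
  expect_true(all(ncr_mix$norm_gfp < 1))
  expect_true(all(ncr_pix$norm_gfp <= 1 + 1e-9))
  # translation-inhibiting NCR amplifies at low dose, reduces at high dose
  expect_gt(ncr_mil$norm_gfp[1], 1)
  expect_gt(ncr_pil$norm_gfp[1], 1)
  expect_lt(ncr_mil$norm_gfp[length(g2_grid)], 1)
  expect_lt(ncr_pil$norm_gfp[length(g2_grid)], 1)
  # a shared loop on translation reinforces resource stealing
  glob_mil <- sweep_ct("global", "MIL")
  expect_gt(max(glob_mil$norm_gfp), 1)
  # local and NCR efficacy cross as the competitor dose grows
  loc_mil <- sweep_ct("local", "MIL")
  diffs <- loc_mil$norm_gfp - ncr_mil$norm_gfp
  expect_gt(diffs[1], 0)
  expect_lt(diffs[length(diffs)], 0)
})

test_that("stronger translation feedback saturates in its noise reduction", {
  net <- strong_competition_network()
  mods <- net$modules
  mods[[2]]$g <- 32
  vals <- purrr::map_dbl(c(0, 1, 2, 4, 8, 14, 20), function(sc) {
    normalized_noise(mods, net$context,
                     controller_spec("ncr", "MIL", S_c = sc))$norm_gfp
  })
  expect_true(all(diff(vals[1:6]) < 0))
  expect_lt(abs(vals[7] - vals[6]), 0.02)
})

test_that("dose responses show the controllers' decoupling ability", {
  g2_grid <- c(0.25, 0.5, 1, 2, 4)
  ur <- calibrated_modules("unlimited")
  dr_ur <- deterministic_dose_response(ur$modules, ur$context, NULL, g2_grid)
  expect_lt(max(abs(dr_ur$slope)), 1e-10)
  net <- strong_competition_network()
  dr_rc <- deterministic_dose_response(net$modules, net$context, NULL,
                                       g2_grid)
  expect_true(all(dr_rc$slope < 0))
  # controllers anchored to the same operating point at unit dose: NCR
  # nearly decouples the GFP mean from the competitor's dose, local does not
  dr_ncr <- deterministic_dose_response(net$modules, net$context,
    controller_spec("ncr", "MIL", S_c = 14), g2_grid, rescale_at = 1)
  dr_loc <- deterministic_dose_response(net$modules, net$context,
    controller_spec("local", "MIL", S_c = 14), g2_grid, rescale_at = 1)
  span <- function(dr) diff(range(dr$gfp_mean))
  expect_lt(span(dr_ncr), 0.5 * span(dr_loc))
  expect_lt(span(dr_ncr), 0.5 * span(dr_rc))
})

test_that("orthogonal pools change which controllers benefit", {
  rc <- strong_competition_network()
  or <- strong_competition_network(mode = "orthogonal")
  g2 <- c(1, 4, 16)
  # absolute GFP noise of the mean-matched controlled system
  abs_eta <- function(base_net, ct, pl) {
    purrr::map_dbl(g2, function(g) {
      m <- base_net$modules
      m[[2]]$g <- g
      bn <- build_network(m, base_net$context)
      ss <- deterministic_steady_state(bn)
      ctl <- rescale_to_means(
        attach_controller(bn, controller_spec(ct, pl, S_c = 14)),
        unname(ss[1:2]), unname(ss[3:4]))
      sqrt(lna_protein_noise(ctl)$eta2_P1)
    })
  }
  # orthogonal resources put the local-MIX system below its competitive twin
  expect_true(all(abs_eta(or, "local", "MIX") < abs_eta(rc, "local", "MIX")))
  # but can leave the translation-inhibiting NCR system worse off
  expect_true(any(abs_eta(or, "ncr", "MIL") > abs_eta(rc, "ncr", "MIL")))
  spec <- controller_spec("local", "MIX", S_c = 0)
  net_or <- with_orthogonal(spec, or$modules, or$context)
  expect_identical(net_or$controller$ctype, "local")
  expect_error(with_orthogonal(spec, rc$modules, rc$context), "orthogonal")
})

test_that("controller linear-noise statistics agree with full simulation", {
  net <- strong_competition_network()
  ss <- deterministic_steady_state(net)
  spec <- controller_spec("ncr", "MIX", S_c = 14)
  ctrl <- rescale_to_means(attach_controller(net, spec),
                           unname(ss[1:2]), unname(ss[3:4]))
  pred <- lna_protein_noise(ctrl)
  tr <- simulate_ssa(ctrl, t_end = 1100, burn_in = 100, seed = 77)
  s <- stationary_statistics(tr)
  cv2_sim <- s$species_stats$cv2[s$species_stats$species == "P1"]
  expect_lt(abs(cv2_sim - pred$eta2_P1) / pred$eta2_P1, 0.35)
  expect_lt(abs(s$correlation$r - pred$corr), 0.15)
})
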