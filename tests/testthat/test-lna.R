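test_that("Lyapunov solution reproduces closed-form covariances", {
  # birth-death: variance = mean
  C <- lna_covariance(birth_death_network(5, 1))
  expect_equal(C["x", "x"], 5, tolerance = 1e-10)
  # two-stage cascade: CV^2(P) = 1/P + (1/m) d_p/(d_m + d_p)
  ur <- build_network(default_modules(), resource_context("unlimited"))
  expect_equal(lna_cv2_p1(ur), 1 / 100 + (1 / 10) * 0.1 / 1.1,
               tolerance = 1e-10)
  # competition makes the reporters anticorrelate
  cal <- calibrated_modules()
  C_rc <- lna_covariance(build_network(cal$modules, cal$context))
  expect_lt(C_rc["P1", "P2"], 0)
  expect_error(lna_covariance(birth_death_network(1, 1e-20),
                              fixed_point = c(x = 1)), "stable")
})

test_that("susceptibility closed forms match numerical differentiation", {
  expect_equal(susceptibilities(resource_context("unlimited"),
                                fixed_point = c(m1 = 10, m2 = 10)),
               c(H21 = -1, H23 = 0))
  ctx <- rc_context()
  H <- susceptibilities(ctx, fixed_point = c(m1 = 10, m2 = 10))
  expect_equal(unname(H), c(-2 / 3, 1 / 3), tolerance = 1e-12)
  # numerical cross-check: H2j = -d ln f1 / d ln m_j
  mods <- default_modules()
  f1 <- function(m1, m2) {
    translation_propensity(1, c(m1, m2, 0, 0), ctx, mods)
  }
  h <- 1e-6
  num_H21 <- -(log(f1(10 * exp(h), 10)) - log(f1(10 * exp(-h), 10))) / (2 * h)
  num_H23 <- -(log(f1(10, 10 * exp(h))) - log(f1(10, 10 * exp(-h)))) / (2 * h)
  expect_equal(unname(H), c(num_H21, num_H23), tolerance = 1e-8)
  expect_error(susceptibilities(ctx, fixed_point = c(m1 = 0, m2 = 10)),
               "zero")
})

test_that("susceptibilities approach the unlimited-resource limits", {
  H <- susceptibilities(rc_context(J_p = 1e8),
                        fixed_point = c(m1 = 10, m2 = 10))
  expect_lt(abs(H[["H21"]] + 1), 1e-6)
  expect_lt(abs(H[["H23"]]), 1e-6)
})

test_that("the three-term decomposition is exact against the full LNA", {
  for (mode in c("unlimited", "competitive", "orthogonal", "frozen_cross")) {
    cal <- calibrated_modules(mode)
    d <- decompose_noise(cal$modules, cal$context)
    cv2 <- lna_cv2_p1(build_network(cal$modules, cal$context))
    expect_equal(d$eta_p2 + d$eta_m2 + d$eta_rc2, d$eta_total2)
    expect_lt(abs(d$eta_total2 - cv2), 1e-8)
    expect_true(all(c(d$eta_p2, d$eta_m2, d$eta_rc2) >= 0))
  }
  ur <- calibrated_modules("unlimited")
  expect_equal(decompose_noise(ur$modules, ur$context)$eta_rc2, 0)
  rc <- calibrated_modules()
  d_rc <- decompose_noise(rc$modules, rc$context)
  expect_true(all(c(d_rc$eta_p2, d_rc$eta_m2, d_rc$eta_rc2) > 0))
})

test_that("capacity sweep shows the double-edged structure", {
  cal <- calibrated_modules()
  grid <- 10^seq(-1, 4, length.out = 25)
  sw <- sweep_jp(cal$modules, cal$context, grid)
  expect_true(all(diff(sw$eta_rc2) < 0))
  expect_true(all(diff(sw$eta_m2) > 0))
  ur <- calibrated_modules("unlimited")
  d_ur <- decompose_noise(ur$modules, ur$context)
  expect_lt(sw$eta_m2[length(grid)], d_ur$eta_m2)
  expect_equal(sw$eta_m2[length(grid)], d_ur$eta_m2, tolerance = 1e-2)
  imin <- which.min(sw$eta_total2)
  expect_gt(imin, 1)
  expect_lt(imin, length(grid))
  # mean-matched competition never exceeds the unlimited noise
  for (jp in grid[seq(1, 25, 4)]) {
    ctx <- rc_context(J_p = jp)
    mm <- match_means(cal$modules, ctx)
    expect_lte(decompose_noise(mm, ctx)$eta_total2, d_ur$eta_total2 + 1e-12)
  }
})

test_that("resource-competitive noise fraction behaves across regimes", {
  ur <- calibrated_modules("unlimited")
  expect_equal(rc_noise_fraction(ur$modules, ur$context), 0)
  # high translational demand: fraction approaches H23^2/(H21^2 + H23^2)
  ctx <- rc_context(J_p = 2)
  mods <- match_means(default_modules(), ctx, target_p = c(1, 1))
  mods[[1]]$k_p <- mods[[2]]$k_p <- 1e4
  lim <- (5 / 11)^2 / ((6 / 11)^2 + (5 / 11)^2)
  expect_equal(rc_noise_fraction(mods, ctx), lim, tolerance = 0.03)
  # strong-competition sweep exceeds a 30% share
  fr <- vapply(10^seq(-2, 2, length.out = 25), function(kp) {
    m <- mods
    m[[1]]$k_p <- m[[2]]$k_p <- kp
    rc_noise_fraction(m, ctx)
  }, 0)
  expect_gt(max(fr), 0.30)
})

test_that("GFP noise against RFP mean separates the two resource systems", {
  tbl <- noise_vs_rfp_mean(c(0, 0.5, 1, 2, 4, 8, 16))
  or <- dplyr::filter(tbl, system == "orthogonal")
  rc <- dplyr::filter(tbl, system == "competitive")
  # identical single-gene circuits when the competitor is absent
  expect_equal(rc$eta_total2[1], or$eta_total2[1], tolerance = 1e-10)
  # orthogonal pools isolate GFP completely
  expect_lt(diff(range(or$eta_total2)), 1e-10)
  # competition transmits the growing RFP load
  expect_true(all(diff(rc$eta_total2) > 0))
  expect_true(all(diff(rc$eta_m2) > 0))
  # the cross term switches on with the competitor and peaks where the
  # opposing mRNA mean reaches J_p + m1*; it rises over the early doses
  expect_true(all(rc$eta_rc2[-1] > 0))
  early <- rc$eta_rc2[rc$g2 <= 2]
  expect_true(all(diff(early) > 0))
  expect_lt(diff(range(rc$eta_p2)), 1e-10)
})

test_that("linear-noise protein statistics agree with simulation", {
  cal <- calibrated_modules()
  net <- build_network(cal$modules, cal$context)
  tr <- simulate_ssa(net, t_end = 5500, burn_in = 500, seed = 57)
  s <- stationary_statistics(tr)
  cv2_sim <- s$species_stats$cv2[s$species_stats$species == "P1"]
  cv2_lna <- lna_cv2_p1(net)
  # batch se of the cv2 is of order se_mean; allow a generous MC band
  expect_lt(abs(cv2_sim - cv2_lna) / cv2_lna, 0.25)
})
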