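# Steady state, loop gains, XYZ coordinates and the linear spectrum.

test_that("sigmoid firing rate has the right midpoint, bound and slope point", {
  p <- default_params
  expect_equal(sigmoid_firing(p$theta, p), 170)            # Q_max / 2
  expect_equal(sigmoid_firing(-10, p), 0, tolerance = 1e-12)
  expect_equal(sigmoid_firing(p$theta + p$sigma_rho, p),
               340 / (1 + exp(-1)), tolerance = 1e-9)
  expect_lt(sigmoid_firing(1, p), p$Q_max + 1e-9)
  v <- seq(-0.01, 0.04, by = 1e-3)
  expect_true(all(diff(sigmoid_firing(v, p)) > 0))
  expect_error(sigmoid_firing(NaN, p), "finite")
})

test_that("steady state solves the fixed-point equation from the 10 s^-1 guess", {
  ss <- solve_steady_state(default_params)
  expect_lt(abs(ss$residual), 1e-9)
  expect_gt(ss$phi_e0, 0); expect_lt(ss$phi_e0, 340)
  expect_equal(ss$phi_i0, ss$phi_e0)
  expect_true(all(c(ss$rho_e, ss$rho_r, ss$rho_s) > 0))
  # the solver's root is the first root found by exhaustive bracketing
  roots <- steady_state_roots(default_params)
  expect_gte(length(roots), 1)
  expect_equal(ss$phi_e0, roots[which.min(abs(roots - 10))], tolerance = 1e-8)
})

test_that("steady cortical rate rises monotonically with the input drive", {
  phis <- vapply(c(0, 0.5, 1, 1.5, 2), function(d)
    solve_steady_state(default_params, phi_n0 = d)$phi_e0, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("decoupled drive (nu_sn = 0) makes the steady state drive-independent", {
  nu <- default_params$nu; nu[["sn"]] <- 0
  p <- nft_params(nu = nu)
  ss <- lapply(c(0, 1, 2), function(d) solve_steady_state(p, phi_n0 = d))
  expect_equal(ss[[1]]$phi_e0, ss[[2]]$phi_e0, tolerance = 1e-10)
  expect_equal(ss[[2]]$phi_e0, ss[[3]]$phi_e0, tolerance = 1e-10)
})

test_that("loop gains and XYZ coordinates follow the printed formulas", {
  g <- gains_and_xyz(default_params)
  # signs: intrathalamic product negative, so Z > 0
  expect_lt(g$G_sr, 0); expect_lt(g$G_ei, 0)
  expect_gt(g$Z, 0)
  expect_equal(g$X, g$G_ee / (1 - g$G_ei))
  # all-zero connection strengths collapse the coordinates to the origin
  p0 <- nft_params(nu = c(ee = 0, ei = 0, es = 1e-12, re = 0, rs = 0,
                          se = 0, sr = 0, sn = 0))
  ss0 <- solve_steady_state(p0, guess = 10)
  g0 <- gains_and_xyz(p0, ss0)
  expect_equal(g0$X, 0, tolerance = 1e-15)
  expect_equal(g0$Y, 0, tolerance = 1e-15)
  expect_equal(g0$Z, 0, tolerance = 1e-15)
  # with the sigmoid slopes held fixed, X is linear in nu_ee and Z untouched
  ss <- solve_steady_state(default_params)
  nu2 <- default_params$nu; nu2[["ee"]] <- 2 * nu2[["ee"]]
  g2 <- gains_and_xyz(nft_params(nu = nu2), ss)
  expect_equal(g2$X, 2 * g$X, tolerance = 1e-12)
  expect_equal(g2$Z, g$Z, tolerance = 1e-12)
})

test_that("transfer function is conjugate-symmetric with the printed DC limit", {
  p <- default_params
  ss <- solve_steady_state(p)
  f <- c(0.3, 1, 5, 12)
  tp <- transfer_spectrum(p, f, ss)
  tm <- transfer_spectrum(p, -f, ss)
  expect_equal(tm$transfer, Conj(tp$transfer), tolerance = 1e-12)
  # omega -> 0 equals the closed form with L = 1 and unit delay factors
  g <- gains_and_xyz(p, ss)
  delta0 <- 1 - (1 / (1 - g$G_ei)) *
    (g$G_ee + (g$G_es * g$G_se + g$G_es * g$G_re * g$G_sr) /
       (1 - g$G_sr * g$G_rs))
  dc_expect <- g$G_es * g$G_sn / ((1 - g$G_ei) * (1 - g$G_sr * g$G_rs) * delta0)
  dc <- transfer_spectrum(p, 1e-9, ss)$transfer
  expect_equal(Re(dc), dc_expect, tolerance = 1e-6)
  expect_lt(abs(Im(dc)), 1e-6 * abs(dc_expect))
})

test_that("linear spectrum has dominant low-frequency power and a spindle lobe", {
  f <- seq(0.1, 30, by = 0.01)
  sp <- transfer_spectrum(default_params, f)
  p_low <- max(sp$power[f <= 2])
  sp_band <- sp$power[f >= 9 & f <= 16]
  # local maximum strictly inside the spindle band
  i <- which.max(sp_band)
  expect_gt(i, 1); expect_lt(i, length(sp_band))
  expect_gt(p_low, max(sp$power[f > 2]))
  expect_gt(max(sp_band), 10 * sp$power[which.min(abs(f - 20))])
})

test_that("stage interpolation is linear in the connection strengths only", {
  nu_b <- default_params$nu * c(1.2, 1.1, 0.9, 1, 1.3, 0.8, 1.1, 1)
  pb <- nft_params(nu = nu_b)
  expect_identical(interpolate_stage(default_params, pb, 0)$nu,
                   default_params$nu[names(default_params$nu)])
  expect_equal(interpolate_stage(default_params, pb, 1)$nu, nu_b[names(nu_b)])
  p23 <- interpolate_stage(default_params, pb, 2 / 3)
  expect_equal(p23$nu[["rs"]],
               (1 / 3) * default_params$nu[["rs"]] + (2 / 3) * nu_b[["rs"]])
  expect_equal(p23$alpha, default_params$alpha)
  pc <- nft_params(alpha = 46)
  expect_error(interpolate_stage(default_params, pc, 0.5), "differs")
})
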