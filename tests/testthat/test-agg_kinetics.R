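test_that("model curve satisfies its boundary conditions and monotonicity", {
  withr::with_seed(21, {
    for (i in 1:15) {
      p <- kinetic_params(dF_pl = runif(1, 10, 500),
                          lam = 10^runif(1, -1.5, 0.5),
                          kap = 10^runif(1, -1.5, 0.7),
                          baseline = runif(1, -5, 5))
      tc <- t_char_of(p)
      tt <- seq(0, 8 * tc, length.out = 200)
      y <- model_curve(p, tt)
      expect_equal(y[1], p$baseline)
      expect_equal(y[length(y)], p$baseline + p$dF_pl, tolerance = 1e-3)
      expect_true(all(diff(y) >= -1e-10))
      expect_true(all(is.finite(y)))
    }
  })
  expect_error(kinetic_params(lam = 0, kap = 0), regexp = "both")
  expect_error(kinetic_params(dF_pl = -1), regexp = "positive")
})

test_that("mass-fraction curve agrees with the moment-equation ODE oracle", {
  # a worked rate pair plus log-spaced corners of the contract region
  tt <- seq(0, 24, by = 0.25)
  expect_lt(max(abs(fibril_mass_fraction(tt, 0.5, 1.0) -
                    ode_oracle_mass(tt, 0.5, 1.0))), 0.01)
  for (lam in c(0.05, 0.5, 5)) {
    for (kap in c(0.05, 0.5, 5)) {
      tend <- 6 * t_char_of(kinetic_params(lam = lam, kap = kap))
      tg <- seq(0, tend, length.out = 60)
      expect_lt(max(abs(fibril_mass_fraction(tg, lam, kap) -
                        ode_oracle_mass(tg, lam, kap))), 0.01)
    }
  }
})

test_that("kap -> 0 reduces to the primary-only (Oosawa) solution", {
  tt <- seq(0, 120, length.out = 80)
  oos <- fibril_mass_fraction(tt, 0.05, 0)
  orc <- ode_oracle_mass(tt, 0.05, 0)
  expect_lt(max(abs(oos - orc)), 1e-4)
  # the dense integrator at small but nonzero kap converges to the same curve
  near <- fibril_mass_fraction(tt, 0.05, 1e-4)
  expect_lt(max(abs(near - oos)), 1e-3)
  # lam = 0 unseeded: no primary nucleation, no fibril mass
  expect_equal(fibril_mass_fraction(tt, 0, 1), rep(0, length(tt)))
})

test_that("fixed-point algebra matches the ODE in its secondary-dominated regime", {
  # the algebraic solution is a controlled approximation only for kap >> lam
  for (kap in c(1, 3)) {
    lam <- kap / 40
    tend <- 6 * t_char_of(kinetic_params(lam = lam, kap = kap))
    tg <- seq(0, tend, length.out = 60)
    fp <- fibril_mass_fraction(tg, lam, kap, method = "fixed_point")
    expect_lt(max(abs(fp - ode_oracle_mass(tg, lam, kap))), 0.01)
    # and it always reproduces the exact early-time curvature lam^2
    h <- 1e-4
    m2 <- (fibril_mass_fraction(2 * h, lam, kap, method = "fixed_point") -
             2 * fibril_mass_fraction(h, lam, kap, method = "fixed_point")) / h^2
    expect_equal(m2, lam^2, tolerance = 1e-2)
  }
})

test_that("t_char is the half-height time and scales with the rates", {
  p <- kinetic_params(lam = 0.1, kap = 0.8, dF_pl = 50, baseline = 3)
  tc <- t_char_of(p)
  expect_equal(model_curve(p, tc), 3 + 25, tolerance = 1e-6)
  withr::with_seed(31, {
    for (i in 1:10) {
      lam <- 10^runif(1, -1.3, 0.5); kap <- 10^runif(1, -1.3, 0.7)
      p1 <- kinetic_params(lam = lam, kap = kap)
      p2 <- kinetic_params(lam = 2 * lam, kap = 2 * kap)
      t1 <- t_char_of(p1); t2 <- t_char_of(p2)
      expect_lt(t2, t1)
      # doubling both rates rescales time exactly by one half
      expect_equal(t2, t1 / 2, tolerance = 1e-6)
      expect_true(is.finite(t1) && t1 > 0)
    }
  })
})

test_that("tangent lag time sits left of the half-time and behaves sensibly", {
  withr::with_seed(41, {
    for (i in 1:12) {
      p <- kinetic_params(lam = 10^runif(1, -1.3, 0.5),
                          kap = 10^runif(1, -1.3, 0.7))
      tl <- t_lag_of(p); tc <- t_char_of(p)
      expect_gte(tl, 0)
      expect_lte(tl, tc + 1e-9)
    }
  })
  # pure-exponential early regime still yields a strictly positive lag
  expect_gt(t_lag_of(kinetic_params(lam = 0.05, kap = 2)), 0)
  # at fixed t_char, stronger secondary nucleation sharpens the transition
  # and pushes the tangent intercept toward t_char
  kaps <- c(0.3, 1, 3)
  ratios <- vapply(kaps, function(kap) {
    lam <- exp(uniroot(function(ll) {
      t_char_of(kinetic_params(lam = exp(ll), kap = kap)) - 5
    }, c(log(1e-5), log(10)))$root)
    p <- kinetic_params(lam = lam, kap = kap)
    t_lag_of(p) / t_char_of(p)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  # threshold variant is available and earlier than the half-time
  p <- kinetic_params(lam = 0.1, kap = 0.8)
  expect_lt(t_lag_of(p, method = "threshold"), t_char_of(p))
})

test_that("critical concentration converts to elongation free energy", {
  expect_equal(dg_from_ccr(1)$dG0, 0)
  # the parent fragment's 42 uM critical concentration at 37 C
  dg <- dg_from_ccr(42e-6, 310.15)
  expect_equal(dg$dG0, 8.314 * 310.15 * log(4.2e-5), tolerance = 1e-12)
  expect_equal(dg$dG0, -2.60e4, tolerance = 0.005)
  expect_lt(dg$dG0, 0)
  # halving c_cr lowers dG0 by RT log 2
  expect_equal(dg_from_ccr(21e-6, 310.15)$dG0 - dg$dG0,
               -8.314 * 310.15 * log(2), tolerance = 1e-9)
  expect_error(dg_from_ccr(-1), regexp = "positive")
})

test_that("fitting a noiseless synthetic trace recovers the parameters", {
  p <- kinetic_params(dF_pl = 100, lam = 0.1, kap = 0.8, baseline = 2)
  tr <- gen_tht_trace(p, noise_spec(sigma = 0), duration = 24, replicates = 1)
  f <- fit_trace(tr)
  expect_lt(abs(f$params$lam / p$lam - 1), 1e-4)
  expect_lt(abs(f$params$kap / p$kap - 1), 1e-4)
  expect_lt(abs(f$params$dF_pl / p$dF_pl - 1), 1e-4)
  expect_lte(f$t_lag, f$t_char)
  # broom-style accessors
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "lam"], f$params$lam)
  expect_equal(glance(f)$t_char, f$t_char)
})

test_that("fitting is invariant to affine rescaling of the fluorescence units", {
  p <- kinetic_params(dF_pl = 100, lam = 0.1, kap = 0.8)
  tr <- gen_tht_trace(p, noise_spec(sigma = 2, seed = 7), 24, 1)
  f1 <- fit_trace(tr)
  tr2 <- dplyr::mutate(tr, fluorescence_au = 3.7 * fluorescence_au + 12)
  f2 <- fit_trace(tr2)
  expect_equal(f2$params$lam, f1$params$lam, tolerance = 1e-4)
  expect_equal(f2$params$kap, f1$params$kap, tolerance = 1e-4)
  expect_equal(f2$params$dF_pl, 3.7 * f1$params$dF_pl, tolerance = 1e-4)
  expect_equal(f2$params$baseline, 3.7 * f1$params$baseline + 12,
               tolerance = 1e-3)
})

test_that("flat traces are rejected with a growth-phase diagnostic", {
  flat <- tibble::tibble(time_h = seq(0, 10, by = 0.5),
                         fluorescence_au = rnorm(21, 50, 0.5))
  expect_error(fit_trace(flat), regexp = "no growth phase",
               class = "photofibril_fit_error")
  expect_error(fit_trace(tibble::tibble(time_h = 1:5,
                                        fluorescence_au = 1:5)),
               regexp = "at least 10")
})

test_that("fitted rates are unbiased at 1% noise across 100 replicates", {
  p <- kinetic_params(dF_pl = 100, lam = 0.1, kap = 0.8)
  est <- vapply(1:100, function(i) {
    tr <- gen_tht_trace(p, noise_spec(sigma = 1, seed = 5000 + i), 24, 1)
    f <- fit_trace(tr)
    c(f$params$lam, f$params$kap)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) / p$lam - 1), 0.03)
  expect_lt(abs(mean(est[2, ]) / p$kap - 1), 0.03)
})
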