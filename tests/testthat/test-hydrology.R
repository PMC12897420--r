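test_that("curve-number runoff matches the closed form and its limits", {
  expect_equal(scs_runoff_depth(0, 86.54), 0)
  expect_equal(scs_runoff_depth(25, 100), 25)  # impervious limit: Q = P
  # closed-form oracle at the package's headline configuration
  expect_equal(scs_runoff_depth(40, 86.54, 0.2), oracle_scs(40, 86.54),
               tolerance = 1e-12)
  expect_equal(oracle_scs(40, 86.54), 14.389, tolerance = 1e-3)
  expect_error(scs_runoff_depth(10, 0), "cn")
  expect_error(scs_runoff_depth(10, 101), "cn")
})

test_that("curve-number runoff is bounded and monotone on a grid", {
  ps <- seq(0, 120, by = 2.5)
  for (cn in c(40, 65, 86.54, 95)) {
    q <- scs_runoff_depth(ps, cn)
    expect_true(all(q >= 0 & q <= ps + 1e-12))
    expect_true(all(diff(q) >= -1e-12))  # non-decreasing in P
  }
  cns <- seq(30, 100, by = 5)
  for (p in c(5, 20, 60)) {
    q <- vapply(cns, function(cn) scs_runoff_depth(p, cn), numeric(1))
    expect_true(all(diff(q) >= -1e-12))  # non-decreasing in CN
  }
})

test_that("Clark unit hydrograph conserves mass over a parameter grid", {
  for (tc in c(3, 12, 24, 48, 60)) {
    for (r in c(0, 6, 12, 36)) {
      uh <- clark_uh(tc, r)
      expect_true(all(uh >= 0))
      expect_equal(sum(uh), 1, tolerance = 1e-6)
    }
  }
})

test_that("Clark routing degenerates to a single daily pulse without storage", {
  expect_equal(clark_uh(24, 0), 1.0)
})

test_that("Clark daily ordinates equal the step-by-step reservoir oracle", {
  for (pars in list(c(24, 12), c(36, 6), c(10, 20))) {
    expect_equal(clark_uh(pars[1], pars[2], internal_dt_h = 1),
                 oracle_clark_daily(pars[1], pars[2], 1),
                 tolerance = 1e-10)
  }
})

test_that("direct routing converts depth to discharge and conserves volume", {
  expect_equal(route_direct(0 * 1:10, clark_uh(24, 12), 0.26), rep(0, 10))
  # unit conversion identity: 1 mm over 1 km2 in one day
  expect_equal(route_direct(c(1, 0), 1, 1)[1], 1000 / 86400)
  expect_equal(route_direct(c(14.39, 0), 1, 0.26)[1],
               14.39 * 0.26 * 1000 / 86400)
  # volume conservation when the tail is contained
  set.seed(7)
  excess <- c(rgamma(30, 1, scale = 4), rep(0, 30))
  uh <- clark_uh(24, 12)
  q <- route_direct(excess, uh, 0.26)
  vol_in <- sum(excess) * 0.26 * 1000          # m3
  vol_out <- sum(q) * 86400
  expect_equal(vol_out, vol_in, tolerance = 1e-6)
})

test_that("baseflow recession follows the closed form and its limits", {
  cfg <- catchment_config(baseflow_mode = "pure_recession")
  qb <- simulate_baseflow(5, cfg)
  expect_equal(qb, 0.005 * 0.95^(0:4))
  expect_equal(qb[3], 0.0045125)
  cfg1 <- catchment_config(k_rec = 1, baseflow_mode = "pure_recession")
  expect_equal(simulate_baseflow(4, cfg1), rep(0.005, 4))
  expect_error(catchment_config(k_rec = 0))
  expect_error(catchment_config(k_rec = 1.2))
})

test_that("event-reset baseflow restarts at wet-spell onsets only", {
  cfg <- catchment_config()
  excess <- c(0, 0, 5, 3, 0, 0, 0, 2, 0)
  qb <- simulate_baseflow(length(excess), cfg, excess_mm = excess)
  expect_equal(qb[3], 0.005)            # onset after dry day
  expect_equal(qb[4], 0.005 * 0.95)     # wet continuation decays
  expect_equal(qb[8], 0.005)            # second spell resets
  expect_true(all(qb <= 0.005 + 1e-15))
  # flow only rises at a reset, i.e. on wet-spell onset days
  rises <- which(diff(qb) > 0) + 1
  onsets <- which(excess > 0 & c(0, head(excess, -1)) == 0)
  expect_true(all(rises %in% onsets))
})

test_that("full simulator composes the stages deterministically", {
  rain0 <- data.frame(date = as.Date("2011-01-01") + 0:59, precip_mm = 0)
  cfg <- catchment_config(baseflow_mode = "pure_recession")
  q <- simulate_discharge(rain0, cfg)
  expect_equal(q$q_total, 0.005 * 0.95^(0:59))  # closed-form zero-rain limit
  expect_equal(q$q_total, q$q_direct + q$q_base)

  rain <- gen_rainfall(400, seed = 11)
  qs <- simulate_discharge(rain, catchment_config())
  expect_true(all(qs$q_total >= 0))
  # runoff volume never exceeds rainfall volume
  vol_rain <- sum(rain$precip_mm) * 0.26 * 1000
  vol_direct <- sum(qs$q_direct) * 86400
  expect_lt(vol_direct, vol_rain)
  expect_identical(qs, simulate_discharge(rain, catchment_config()))
})

test_that("per-day equality with a straight-line reimplementation", {
  # independent oracle: literal loop over the model equations
  rain <- gen_rainfall(6 * 365, seed = 3)
  cfg <- catchment_config()
  q <- simulate_discharge(rain, cfg)

  p <- rain$precip_mm
  ex <- vapply(p, function(pp) oracle_scs(pp, cfg$cn, cfg$lambda_ia),
               numeric(1))
  uh <- oracle_clark_daily(cfg$tc_h, cfg$r_h, cfg$internal_dt_h)
  n <- length(ex)
  qd <- numeric(n)
  for (t in seq_len(n)) {
    for (j in seq_along(uh)) {
      if (t - j + 1 >= 1) qd[t] <- qd[t] + ex[t - j + 1] * uh[j]
    }
  }
  qd <- qd * cfg$area_km2 * 1000 / 86400
  qb <- numeric(n); qb[1] <- cfg$q0_m3s
  for (t in 2:n) {
    onset <- ex[t] > 0 && ex[t - 1] == 0
    qb[t] <- if (onset) cfg$q0_m3s else qb[t - 1] * cfg$k_rec
  }
  expect_equal(q$q_direct, qd, tolerance = 1e-10)
  expect_equal(q$q_base, qb, tolerance = 1e-12)
  expect_equal(q$q_total, qd + qb, tolerance = 1e-10)
})

test_that("rainfall series validation catches malformed input", {
  bad <- data.frame(date = as.Date("2011-01-01") + c(0, 1, 3),
                    precip_mm = c(0, 1, 2))
  expect_error(simulate_discharge(bad, catchment_config()), "consecutive")
  neg <- data.frame(date = as.Date("2011-01-01") + 0:2,
                    precip_mm = c(0, -1, 2))
  expect_error(simulate_discharge(neg, catchment_config()), "negative")
})
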