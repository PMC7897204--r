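test_that("the two printed one-site parameterizations are algebraically equal", {
  # increasing form: delta_obs = delta_max + (delta_min - delta_max)/(1 + 10^(pH - pKa))
  eq_up <- function(pH, pKa, dmin, dmax) dmax + (dmin - dmax) / (1 + 10^(pH - pKa))
  # decreasing form: delta_obs = delta_min + (delta_max - delta_min)/(1 + 10^(pH - pKa))
  eq_dn <- function(pH, pKa, dmin, dmax) dmin + (dmax - dmin) / (1 + 10^(pH - pKa))
  pH <- seq(0, 14, by = 0.1)
  withr::with_seed(42, {
    for (i in 1:20) {
      pKa <- runif(1, 1, 12)
      a <- runif(1, 0, 100); b <- runif(1, 0, 100)
      # protonated-form shift a, deprotonated b, in both directions
      expect_lt(max(abs(hh_predict_1site(pH, pKa, a, b) - eq_up(pH, pKa, a, b))),
                1e-12)
      expect_lt(max(abs(hh_predict_1site(pH, pKa, b, a) -
                          eq_dn(pH, pKa, a, b))), 1e-12)
    }
  })
})

test_that("one-site predictions honour the protonation limits", {
  expect_equal(hh_predict_1site(0, 7, 52.3, 54.8), 52.3, tolerance = 1e-6)
  expect_equal(hh_predict_1site(14, 7, 52.3, 54.8), 54.8, tolerance = 1e-6)
  expect_equal(hh_predict_1site(3.2, 3.2, 52.3, 54.8), (52.3 + 54.8) / 2)
  # frozen oracle: independent arithmetic on the deprotonated fraction
  th <- 1 / (1 + 10^(3.2 - 4))
  expect_equal(hh_predict_1site(4, 3.2, 52.3, 54.8), 52.3 + 2.5 * th)
})

test_that("two-site model collapses, bounds, and matches fraction arithmetic", {
  pH <- seq(1, 10, by = 0.1)
  collapsed <- hh_predict_2site(pH, 3.4, 13.5, 38.4, 39.0, 39.0)
  expect_lt(max(abs(collapsed - hh_predict_1site(pH, 3.4, 38.4, 39.0))), 1e-3)
  expect_equal(hh_predict_2site(0, 3.4, 5.0, 38.4, 39.0, 42.3), 38.4,
               tolerance = 1e-3)
  expect_equal(hh_predict_2site(14, 3.4, 5.0, 38.4, 39.0, 42.3), 42.3,
               tolerance = 1e-6)
  # frozen oracle: fraction-weighted sum evaluated independently
  f1 <- 1 / (1 + 10^(3.4 - 5)); f2 <- 1 / (1 + 10^(5.0 - 5))
  expect_equal(hh_predict_2site(5, 3.4, 5.0, 38.4, 39.0, 42.3),
               38.4 + (39.0 - 38.4) * f1 + (42.3 - 39.0) * f2)
  expect_equal(38.4 + (39.0 - 38.4) * f1 + (42.3 - 39.0) * f2, 40.6352980,
               tolerance = 1e-6)
})

test_that("predictions are monotonic in pH and bounded by the plateaus", {
  pH <- seq(0, 14, by = 0.05)
  withr::with_seed(7, {
    for (i in 1:25) {
      p1 <- runif(1, 2, 6); p2 <- p1 + runif(1, 0.8, 4)
      d <- sort(runif(3, 10, 80))
      if (runif(1) < 0.5) d <- rev(d)  # decreasing direction
      y <- hh_predict_2site(pH, p1, p2, d[1], d[2], d[3])
      expect_true(all(diff(y) >= -1e-9) || all(diff(y) <= 1e-9))
      expect_true(all(y >= min(d) - 1e-9 & y <= max(d) + 1e-9))
      y1 <- hh_predict_1site(pH, p1, d[1], d[3])
      expect_true(all(y1 >= min(d[c(1, 3)]) - 1e-9 &
                        y1 <= max(d[c(1, 3)]) + 1e-9))
    }
  })
})

test_that("plateaus derived from two anchor points invert the model", {
  pl <- derive_plateaus(52.3, 2.3, 54.8, 7.4, pKa = 3.2)
  # frozen from an explicit 2x2 linear solve
  expect_equal(unname(pl), c(51.9852463, 54.8001776), tolerance = 1e-6)
  expect_lt(abs(hh_predict_1site(2.3, 3.2, pl[[1]], pl[[2]]) - 52.3), 1e-9)
  expect_lt(abs(hh_predict_1site(7.4, 3.2, pl[[1]], pl[[2]]) - 54.8), 1e-9)
  # derived prediction at pH 4 from the two anchors, frozen from the oracle
  expect_equal(hh_predict_1site(4, 3.2, pl[[1]], pl[[2]]), 54.4150756,
               tolerance = 1e-6)
  # pH values bracketing the pKa far on each side return the inputs
  pl2 <- derive_plateaus(52.3, 0.2, 54.8, 9.9, pKa = 5)
  expect_equal(unname(pl2), c(52.3, 54.8), tolerance = 1e-3)
  expect_equal(unname(derive_plateaus(53.1, 2.3, 53.1, 7.4, 3.2)),
               c(53.1, 53.1))
  expect_error(derive_plateaus(52.3, 10, 54.8, 11, pKa = 3.2),
               "same side|indistinguishable")
  expect_error(derive_plateaus(52.3, 2.3, 54.8, 2.3, pKa = 3.2), "differ")
})

test_that("noiseless series are recovered exactly and direction is detected", {
  grid <- seq(1.5, 8, length.out = 12)
  ser <- simulate_titration(c(pKa = 3.7, delta_min = 52.3, delta_max = 54.8),
                            grid, noise = 0, seed = 1)
  fit <- fit_titration(ser, "1", seed = 1, n_boot = 0)
  expect_true(fit$converged)
  expect_equal(fit$direction, "acid_lt_base")
  expect_equal(unname(fit$params[["pKa"]]), 3.7, tolerance = 1e-5)
  expect_equal(unname(fit$params[["delta_min"]]), 52.3, tolerance = 1e-5)
  ser_dn <- simulate_titration(c(pKa = 4.2, delta_min = 181.5,
                                 delta_max = 177.5), grid, noise = 0, seed = 1)
  fit_dn <- fit_titration(ser_dn, "1", seed = 1, n_boot = 0)
  expect_equal(fit_dn$direction, "acid_gt_base")
  expect_equal(unname(fit_dn$params[["pKa"]]), 4.2, tolerance = 1e-5)
  expect_error(fit_titration(titration_series(1:4, rnorm(4)), "1"),
               "at least 5")
})

test_that("seeded noisy fits recover parameters and agree with grid search", {
  grid <- seq(1.5, 8, length.out = 12)
  errs <- vapply(1:20, function(s) {
    ser <- simulate_titration(c(pKa = 3.2, delta_min = 52.3,
                                delta_max = 54.8), grid, noise = 0.05,
                              seed = s)
    fit <- fit_titration(ser, "1", seed = s, n_boot = 0)
    oracle <- grid_fit_1site(ser$points$pH, ser$points$shift)
    expect_lt(abs(fit$params[["pKa"]] - oracle$pKa), 0.02)
    abs(fit$params[["pKa"]] - 3.2)
  }, 0)
  expect_lt(median(errs), 0.05)
  expect_true(all(errs < 0.1))
})

test_that("two-site recovery error stays small for well-separated sites", {
  grid <- seq(1.5, 8, length.out = 12)
  errs <- t(vapply(1:30, function(s) {
    ser <- simulate_titration(c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 38.4,
                                delta_mid = 39.9, delta_max2 = 42.3),
                              grid, noise = 0.05, seed = 3000 + s)
    fit <- fit_titration(ser, "2", seed = s, n_boot = 0)
    c(abs(fit$params[["pKa1"]] - 3.4), abs(fit$params[["pKa2"]] - 5.0))
  }, c(0, 0)))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("global fits share pKa values across nuclei and resolve both sites", {
  grid <- seq(1.6, 9.8, length.out = 14)
  # backbone nucleus barely sees site 2; side-chain nucleus barely sees
  # site 1 -- only the joint fit determines both
  ca <- simulate_titration(c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 52.0,
                             delta_mid = 55.5, delta_max2 = 55.9),
                           grid, noise = 0, seed = 1)
  cb <- simulate_titration(c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 38.4,
                             delta_mid = 39.0, delta_max2 = 42.3),
                           grid, noise = 0, seed = 2)
  g <- fit_titration_global(list(Ca = ca, Cb = cb), "2", seed = 1)
  expect_true(g$converged)
  expect_equal(g$pKa, c(3.4, 5.0), tolerance = 1e-4)
  expect_equal(unname(g$plateaus["Ca", ]), c(52.0, 55.5, 55.9),
               tolerance = 1e-3)
  expect_equal(unname(g$plateaus["Cb", ]), c(38.4, 39.0, 42.3),
               tolerance = 1e-3)
  expect_lt(g$rss, 1e-8)
  g1 <- fit_titration_global(list(Ca = simulate_titration(
    c(pKa = 3.2, delta_min = 52.3, delta_max = 54.8), grid, noise = 0,
    seed = 3)), "1", seed = 1)
  expect_equal(g1$pKa, 3.2, tolerance = 1e-4)
})

test_that("model selection picks the generating model by corrected AIC", {
  grid <- seq(1.5, 8.5, length.out = 14)
  two <- simulate_titration(c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 38.4,
                              delta_mid = 39.0, delta_max2 = 42.3),
                            grid, noise = 0.03, seed = 11)
  fit2 <- fit_titration(two, "auto", seed = 1, n_boot = 0)
  expect_equal(fit2$model, "two_site")
  expect_lt(fit2$params[["pKa1"]], fit2$params[["pKa2"]])
  one <- simulate_titration(c(pKa = 3.2, delta_min = 52.3, delta_max = 54.8),
                            grid, noise = 0.03, seed = 12)
  fit1 <- fit_titration(one, "auto", seed = 1, n_boot = 0)
  expect_equal(fit1$model, "one_site")
})

test_that("bootstrap intervals bracket the point estimates", {
  ser <- simulate_titration(c(pKa = 3.2, delta_min = 52.3, delta_max = 54.8),
                            seq(1.5, 8, length.out = 12), noise = 0.05,
                            seed = 3)
  fit <- fit_titration(ser, "1", seed = 3, n_boot = 60)
  expect_false(is.null(fit$ci))
  for (p in names(fit$params)) {
    expect_lte(fit$ci[p, 1L], fit$params[[p]])
    expect_gte(fit$ci[p, 2L], fit$params[[p]])
  }
  # same seed, same intervals
  fit_b <- fit_titration(ser, "1", seed = 3, n_boot = 60)
  expect_identical(fit$ci, fit_b$ci)
})

test_that("fitted pKa values are assigned to groups by transition amplitude", {
  grid <- seq(1.5, 8.5, length.out = 14)
  # backbone nucleus: large first transition; side chain: large second
  fits <- list(
    Ca = fit_titration(simulate_titration(
      c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 52.0, delta_mid = 55.5,
        delta_max2 = 55.9), grid, noise = 0.01, seed = 1), "2", n_boot = 0),
    Hb2 = fit_titration(simulate_titration(
      c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 2.97, delta_mid = 2.95,
        delta_max2 = 2.69), grid, noise = 0.002, seed = 2), "2", n_boot = 0)
  )
  asg <- assign_pka_to_groups(fits)
  expect_equal(asg$group[asg$site == 1], "alpha_carboxyl")
  expect_equal(asg$group[asg$site == 2], "side_chain")
  expect_equal(asg$pKa, c(3.4, 5.0), tolerance = 0.1)
  # swapped amplitudes swap the assignment
  fits_sw <- list(Ca = fits$Hb2, Hb2 = fits$Ca)
  asg_sw <- assign_pka_to_groups(fits_sw)
  expect_equal(asg_sw$group[asg_sw$site == 1], "side_chain")
  expect_equal(asg_sw$group[asg_sw$site == 2], "alpha_carboxyl")
  # single-site isoAsp collection resolves to its only ionizable group
  lib <- rc_library()
  f1 <- list(
    Ca = fit_titration(simulate_titration(
      c(pKa = 3.2, delta_min = 52.3, delta_max = 54.8), grid, noise = 0.01,
      seed = 3), "1", n_boot = 0),
    Hb2 = fit_titration(simulate_titration(
      c(pKa = 3.2, delta_min = 2.93, delta_max = 2.83), grid, noise = 0.002,
      seed = 4), "1", n_boot = 0))
  asg1 <- assign_pka_to_groups(f1, variant = "isoAsp", lib = lib)
  expect_equal(asg1$group, "side_chain")
  expect_equal(asg1$pKa, 3.2, tolerance = 0.1)
  expect_error(assign_pka_to_groups(f1["Ca"]), "side-chain")
})

test_that("near-equal transition amplitudes are flagged unassigned", {
  grid <- seq(1.5, 8.5, length.out = 14)
  fits <- list(
    Ca = fit_titration(simulate_titration(
      c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 50, delta_mid = 51,
        delta_max2 = 52), grid, noise = 0.01, seed = 5), "2", n_boot = 0),
    Hb2 = fit_titration(simulate_titration(
      c(pKa1 = 3.4, pKa2 = 5.0, delta_min0 = 3.0, delta_mid = 3.1,
        delta_max2 = 3.2), grid, noise = 0.001, seed = 6), "2", n_boot = 0))
  asg <- assign_pka_to_groups(fits)
  expect_true(all(asg$group == "unassigned"))
})

test_that("D2O direct-reading pKa correction is applied exactly once", {
  x <- d2o_correct(3.2)
  expect_equal(as.numeric(x), 3.14)
  expect_equal(attr(x, "medium"), "H2O_equivalent")
  expect_equal(as.numeric(d2o_correct(0.06)), 0)
  expect_error(d2o_correct(x), "twice")
})
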