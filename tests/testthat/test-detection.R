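lib <- rc_library()

make_pl <- function(dH, dC, volume = NA_real_, pH = 7.4) {
  peak_list(tibble::tibble(delta_H = dH, delta_C = dC, volume = volume),
            pH = pH, referenced = TRUE)
}

test_that("observed peaks match their diagnostic correlations", {
  diags <- diagnostic_set(lib, 7.4)
  m <- match_peaks(make_pl(3.41, 49.3), diags)
  hit <- m[m$within, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$variant, "Pro_Nterm")
  expect_equal(hit$atom_C, "Cd")
  expect_equal(hit$delta_C, 49.3)
  m2 <- match_peaks(make_pl(2.83, 40.8), diags)
  hit2 <- m2[m2$within, ]
  expect_equal(hit2$variant, "isoAsp")
  expect_equal(paste(hit2$atom_C, hit2$atom_H), "Cb Hb2")
  # empty peak list leaves every diagnostic unmatched
  m0 <- match_peaks(make_pl(numeric(), numeric()), diags)
  expect_true(all(!m0$within))
  expect_true(all(is.na(m0$peak_index)))
})

test_that("matching refuses unreferenced peak lists and is greedy-unique", {
  pl_unref <- peak_list(tibble::tibble(delta_H = 3.41, delta_C = 49.3),
                        pH = 7.4)
  expect_error(match_peaks(pl_unref, diagnostic_set(lib, 7.4)),
               "rereference")
  # one peak may satisfy at most one diagnostic
  diags <- diagnostic_set(lib, 7.4)
  m <- match_peaks(make_pl(c(2.83, 2.75), c(40.8, 40.8)), diags)
  idx <- m$peak_index[m$within]
  expect_equal(anyDuplicated(idx), 0L)
})

test_that("modification calls follow the evidence rules", {
  diags <- rbind(diagnostic_set(lib, 7.4),
                 within(diagnostic_correlations(
                   lib, 7.4, c("Asp_internal", "Pro_internal")),
                   uniqueness <- NA_real_))
  # C-terminal Asp plus N-terminal Pro evidence -> one Asp-Pro cleavage call
  m <- match_peaks(make_pl(c(2.69, 2.59, 3.41, 3.39),
                           c(42.3, 42.3, 49.3, 49.3)), diags)
  rep1 <- call_modifications(m, pH = 7.4)
  expect_equal(rep1$calls$modification, "AspPro_cleavage")
  expect_equal(nrow(rep1$calls), 1L)
  # C-terminal Asp alone -> generic Asp-Xaa cleavage
  m2 <- match_peaks(make_pl(c(2.69, 2.59), c(42.3, 42.3)), diags)
  rep2 <- call_modifications(m2, pH = 7.4)
  expect_equal(rep2$calls$modification, "AspXaa_cleavage")
  # both isoAsp stereo protons -> multi_peak confidence
  m3 <- match_peaks(make_pl(c(2.83, 2.75), c(40.8, 40.8)), diags)
  rep3 <- call_modifications(m3, pH = 7.4)
  expect_equal(rep3$calls$modification, "isoAsp")
  expect_equal(rep3$calls$confidence, "multi_peak")
  # a single stereo partner still calls, at single_peak confidence
  m4 <- match_peaks(make_pl(2.83, 40.8), diags)
  expect_equal(call_modifications(m4, pH = 7.4)$calls$confidence,
               "single_peak")
  # succinimide Hb pair
  m5 <- match_peaks(make_pl(c(3.27, 2.86), c(37.4, 37.4)), diags)
  expect_equal(call_modifications(m5, pH = 7.4)$calls$modification, "Snn")
})

test_that("acidic pH suppresses C-terminal Asp Cb evidence", {
  # a peak in the Asp_Cterm Cb region at pH 2.3 must not trigger a call
  pl <- make_pl(2.97, 38.4, pH = 2.3)
  rep <- detect_modifications(pl, lib)
  expect_false(any(grepl("cleavage", rep$calls$modification)))
  # but N-terminal Pro alone still identifies cleavage at acidic pH
  pl2 <- make_pl(c(3.41, 3.39), c(49.3, 49.3), pH = 2.3)
  rep2 <- detect_modifications(pl2, lib)
  expect_equal(rep2$calls$modification, "AspPro_cleavage")
})

test_that("integral-based fractions behave like a two-state ratio", {
  expect_equal(quantify_fraction(50, 50), 50)
  expect_equal(quantify_fraction(85, 15), 85)
  # invariant to common volume scaling
  expect_equal(quantify_fraction(85e6, 15e6), 85)
  withr::with_seed(21, {
    for (i in 1:20) {
      v <- runif(2, 1, 100)
      f <- quantify_fraction(v[1], v[2])
      expect_gt(f, 0); expect_lt(f, 100)
      expect_equal(quantify_fraction(7.3 * v[1], 7.3 * v[2]), f)
    }
  })
  expect_error(quantify_fraction(0, 10), "positive")
  expect_error(quantify_fraction(10, -1), "positive")
})

test_that("detection reports are deterministic for identical inputs", {
  sim <- simulate_peaklist(simulation_spec("GGDPGG",
    modifications = list(AspPro_cleavage = 0.1), seed = 31))
  r1 <- detect_modifications(sim$peaklist, lib)
  r2 <- detect_modifications(sim$peaklist, lib)
  expect_identical(r1, r2)
})

test_that("heights substitute for missing volumes with a recorded basis", {
  sim <- simulate_peaklist(simulation_spec("GGDPGG",
    modifications = list(AspPro_cleavage = 0.2), seed = 8))
  pl <- sim$peaklist
  pl$peaks$volume <- NA_real_  # heights remain
  rep <- detect_modifications(pl, lib)
  expect_equal(rep$calls$basis, "height_fallback")
  expect_equal(rep$calls$fraction_percent, 20, tolerance = 3)
})

test_that("synthetic screens show no missed and no false calls", {
  # strongly unique diagnostics only (uniqueness > 2), per-axis noise
  # 0.01 ppm 1H / 0.1 ppm 13C
  for (s in 1:20) {
    mods <- switch(s %% 4 + 1,
                   list(),
                   list(AspPro_cleavage = 0.1),
                   list(isoAsp = 0.3),
                   list(AspPro_cleavage = 0.15, isoAsp = 0.2))
    sim <- simulate_peaklist(simulation_spec(
      "MKVLGGDPGGAEFSTYHQNRW", modifications = mods, seed = 1000 + s))
    rep <- detect_modifications(sim$peaklist, lib, min_uniqueness = 2)
    got <- sort(unique(rep$calls$modification))
    expected <- sort(as.character(names(mods)))
    expect_identical(got, expected)
  }
})
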