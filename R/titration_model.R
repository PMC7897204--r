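#' One-site Henderson-Hasselbalch chemical-shift model
#'
#' Predicts the observed fast-exchange chemical shift of a nucleus near a
#' single ionizable group:
#' `delta_obs = delta_min + (delta_max - delta_min) / (1 + 10^(pKa - pH))`,
#' where `delta_min` is the shift of the fully protonated form and
#' `delta_max` that of the fully deprotonated form. The two printed
#' directional forms (shift increasing or decreasing with pH) are the same
#' protonation-fraction average and are handled by a single core; `delta_min`
#' may be numerically larger than `delta_max`.
#'
#' @param pH pH value(s).
#' @param pKa Acid dissociation constant (pH units), in \[0, 14\].
#' @param delta_min Shift of the fully protonated form (ppm).
#' @param delta_max Shift of the fully deprotonated form (ppm).
#' @return Predicted shift(s) in ppm.
#' @examples
#' hh_predict_1site(4, pKa = 3.2, delta_min = 52.3, delta_max = 54.8)
#' @export
hh_predict_1site <- function(pH, pKa, delta_min, delta_max) {
  stopifnot(pKa >= 0, pKa <= 14)
  th <- 1 / (1 + 10^(pKa - pH))  # deprotonated fraction
  delta_min + (delta_max - delta_min) * th
}

#' Two-site (stepwise) Henderson-Hasselbalch chemical-shift model
#'
#' For a nucleus sensing two ionizable groups (e.g. the alpha- and side-chain
#' carboxyls of a C-terminal aspartate) the observed shift is modelled as two
#' stacked one-site transitions sharing an intermediate plateau:
#' `delta_obs = delta_min0 + (delta_mid - delta_min0)/(1 + 10^(pKa1 - pH))
#'            + (delta_max2 - delta_mid)/(1 + 10^(pKa2 - pH))`.
#' `delta_min0` is the fully protonated shift, `delta_max2` the fully
#' deprotonated one, and `delta_mid` the plateau between the two transitions.
#'
#' @param pH pH value(s).
#' @param pKa1,pKa2 The two dissociation constants; `pKa1 < pKa2` by
#'   convention (predictions are symmetric if swapped together with plateaus).
#' @param delta_min0,delta_mid,delta_max2 Plateau shifts (ppm).
#' @return Predicted shift(s) in ppm.
#' @export
hh_predict_2site <- function(pH, pKa1, pKa2, delta_min0, delta_mid,
                             delta_max2) {
  stopifnot(pKa1 >= 0, pKa1 <= 14, pKa2 >= 0, pKa2 <= 14)
  th1 <- 1 / (1 + 10^(pKa1 - pH))
  th2 <- 1 / (1 + 10^(pKa2 - pH))
  delta_min0 + (delta_mid - delta_min0) * th1 + (delta_max2 - delta_mid) * th2
}

#' Construct a titration series
#'
#' @param pH,shift Paired observations (pH units, ppm). pH values must be
#'   unique; the series is sorted by pH.
#' @param variant,atom Nucleus identity (optional but used for group
#'   assignment and plausibility checks).
#' @param medium `"D2O_direct_reading"` (apparent pKa read with an
#'   H2O-calibrated meter) or `"H2O"`.
#' @return A `titration_series` object (tibble of points plus metadata).
#' @export
titration_series <- function(pH, shift, variant = NA_character_,
                             atom = NA_character_,
                             medium = c("D2O_direct_reading", "H2O")) {
  medium <- match.arg(medium)
  stopifnot(length(pH) == length(shift), all(is.finite(pH)),
            all(is.finite(shift)))
  if (anyDuplicated(pH)) stop("pH values must be unique", call. = FALSE)
  if (any(pH < 0 | pH > 14)) stop("pH values must lie in [0, 14]", call. = FALSE)
  ord <- order(pH)
  structure(
    list(points = tibble::tibble(pH = pH[ord], shift = shift[ord]),
         variant = variant, atom = atom, medium = medium),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", x$variant, " ", x$atom, ", ",
      nrow(x$points), " points, pH ", min(x$points$pH), "-",
      max(x$points$pH), " (", x$medium, ")\n", sep = "")
  invisible(x)
}

#' Derive plateau shifts from two measured points and a known pKa
#'
#' Inverts the one-site model through two observations: solves the 2x2
#' linear system `delta_i = delta_min * (1 - f_i) + delta_max * f_i` with
#' `f_i` the deprotonated fraction at `pH_i`. Round-trip prediction at the
#' two input pH values reproduces the inputs to machine precision.
#'
#' @param shift_a,pH_a First observation (ppm, pH units).
#' @param shift_b,pH_b Second observation.
#' @param pKa Known dissociation constant.
#' @return Named numeric `c(delta_min = , delta_max = )`.
#' @examples
#' derive_plateaus(52.3, 2.3, 54.8, 7.4, pKa = 3.2)
#' @export
derive_plateaus <- function(shift_a, pH_a, shift_b, pH_b, pKa) {
  if (pH_a == pH_b) stop("pH_a and pH_b must differ", call. = FALSE)
  fa <- 1 / (1 + 10^(pKa - pH_a))
  fb <- 1 / (1 + 10^(pKa - pH_b))
  if (abs(fa - fb) <= 1e-6) {
    stop("protonation fractions at pH_a and pH_b are indistinguishable ",
         "(both pH far from pKa on the same side); use the observed shifts ",
         "directly as plateaus", call. = FALSE)
  }
  A <- rbind(c(1 - fa, fa), c(1 - fb, fb))
  sol <- solve(A, c(shift_a, shift_b))
  c(delta_min = sol[[1L]], delta_max = sol[[2L]])
}

#' Correct an apparent D2O pKa to its H2O-equivalent value
#'
#' Apparent pKa values read directly in D2O with an H2O-calibrated pH meter
#' run about 0.06 pH units above values measured in H2O (for carboxyl groups
#' under acidic conditions); this subtracts that constant. The result is
#' tagged so the correction cannot be applied twice.
#'
#' @param pKa_star Apparent pKa: a bare number (assumed direct D2O reading)
#'   or a value previously returned by this function.
#' @return Numeric pKa with attribute `medium = "H2O_equivalent"`.
#' @examples
#' d2o_correct(3.2)  # 3.14
#' @export
d2o_correct <- function(pKa_star) {
  med <- attr(pKa_star, "medium")
  if (identical(med, "H2O_equivalent")) {
    stop("pKa value is already H2O-equivalent; refusing to correct twice",
         call. = FALSE)
  }
  out <- as.numeric(pKa_star) - 0.06
  attr(out, "medium") <- "H2O_equivalent"
  out
}

# Residual function factory for the two models, parameterized for nlsLM.
.hh_rss <- function(series, predict_fun) {
  function(par) sum((series$points$shift - predict_fun(series$points$pH, par))^2)
}

.fit_1site_nls <- function(points, start) {
  fit <- try(minpack.lm::nlsLM(
    shift ~ hh_predict_1site(pH, pKa, dmin, dmax),
    data = points,
    start = list(pKa = start[["pKa"]], dmin = start[["dmin"]],
                 dmax = start[["dmax"]]),
    lower = c(pKa = 0, dmin = -20, dmax = -20),
    upper = c(pKa = 14, dmin = 230, dmax = 230),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  fit
}

.fit_2site_nls <- function(points, start) {
  fit <- try(minpack.lm::nlsLM(
    shift ~ hh_predict_2site(pH, pKa1, pKa2, d0, dm, d2),
    data = points,
    start = as.list(start),
    lower = c(pKa1 = 0, pKa2 = 0, d0 = -20, dm = -20, d2 = -20),
    upper = c(pKa1 = 14, pKa2 = 14, d0 = 230, dm = 230, d2 = 230),
    control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
  fit
}

# pKa starting values: pH of steepest observed gradient, plus spread.
.pka_starts <- function(points) {
  dpH <- diff(points$pH)
  grad <- abs(diff(points$shift)) / ifelse(dpH == 0, 1e-9, dpH)
  mid <- (points$pH[-1] + points$pH[-nrow(points)]) / 2
  steep <- mid[which.max(grad)]
  unique(pmin(pmax(c(steep, steep - 1, steep + 1,
                     quantile(points$pH, c(0.25, 0.5, 0.75), names = FALSE)),
                   0.1), 13.9))
}

.aicc <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  kk <- k + 1
  n * log(rss / n + 1e-300) + 2 * kk +
    if (n - kk - 1 > 0) 2 * kk * (kk + 1) / (n - kk - 1) else Inf
}

#' Fit a Henderson-Hasselbalch titration model to a chemical-shift series
#'
#' Unit-weight nonlinear least squares (Levenberg-Marquardt, multi-start on
#' the pKa initial value) for the one- and two-site models. With
#' `n_sites = "auto"` both models are fitted and compared by corrected AIC.
#' Two-site pKa values are reported sorted ascending. Parameter confidence
#' intervals come from residual-resampling bootstrap.
#'
#' @param series A [titration_series()]. One-site fits need >= 5 points,
#'   two-site fits >= 7.
#' @param n_sites `"1"`, `"2"` or `"auto"`.
#' @param seed Integer seed for the bootstrap (mandatory for reproducibility).
#' @param n_boot Bootstrap replicates (default 500; 0 disables the bootstrap).
#' @param level Confidence level for bootstrap percentile intervals.
#' @return A `titration_fit`: list with `model` (`"one_site"`/`"two_site"`),
#'   `params` (named numeric), `direction`, `rss`, `aicc`, `ci` (matrix or
#'   NULL), `n_boot`, `converged`, `seed`, `series`.
#' @export
fit_titration <- function(series, n_sites = c("auto", "1", "2"), seed = 1L,
                          n_boot = 500L, level = 0.95) {
  stopifnot(inherits(series, "titration_series"))
  n_sites <- match.arg(as.character(n_sites[1L]), c("auto", "1", "2"))
  pts <- series$points
  need <- switch(n_sites, "1" = 5L, "2" = 7L, "auto" = 5L)
  if (nrow(pts) < need) {
    stop("need at least ", need, " points for a ", n_sites, "-site fit, got ",
         nrow(pts), call. = FALSE)
  }
  fits <- list()
  if (n_sites %in% c("1", "auto")) fits$one_site <- .fit_one_site(pts)
  if (n_sites == "2" || (n_sites == "auto" && nrow(pts) >= 7L)) {
    fits$two_site <- .fit_two_site(pts)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) {
    return(structure(list(model = NA_character_, params = NULL,
                          direction = NA_character_, rss = NA_real_,
                          aicc = NA_real_, ci = NULL, n_boot = 0L,
                          converged = FALSE, seed = seed, series = series),
                     class = "titration_fit"))
  }
  best_name <- names(fits)[[which.min(vapply(fits, `[[`, 0, "aicc"))]]
  best <- fits[[best_name]]
  direction <- if (pts$shift[[nrow(pts)]] >= pts$shift[[1L]]) {
    "acid_lt_base"
  } else {
    "acid_gt_base"
  }
  ci <- NULL
  if (n_boot > 0L && best$converged) {
    ci <- .bootstrap_ci(pts, best_name, best$params, n_boot, seed, level)
  }
  structure(
    list(model = best_name, params = best$params, direction = direction,
         rss = best$rss, aicc = best$aicc, ci = ci, n_boot = n_boot,
         converged = best$converged, seed = seed, series = series),
    class = "titration_fit"
  )
}

.fit_one_site <- function(pts) {
  n <- nrow(pts)
  dmin0 <- pts$shift[[1L]]
  dmax0 <- pts$shift[[n]]
  best <- NULL
  for (p0 in .pka_starts(pts)) {
    f <- .fit_1site_nls(pts, c(pKa = p0, dmin = dmin0, dmax = dmax0))
    if (inherits(f, "try-error")) next
    rss <- sum(resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- coef(f)
      best <- list(params = c(pKa = unname(cf[["pKa"]]),
                              delta_min = unname(cf[["dmin"]]),
                              delta_max = unname(cf[["dmax"]])),
                   rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) return(NULL)
  best$aicc <- .aicc(best$rss, n, 3L)
  best
}

.fit_two_site <- function(pts) {
  n <- nrow(pts)
  d0 <- pts$shift[[1L]]
  d2 <- pts$shift[[n]]
  dm <- (d0 + d2) / 2
  starts <- .pka_starts(pts)
  grid <- expand.grid(p1 = starts, p2 = starts)
  grid <- grid[grid$p1 < grid$p2 - 0.3, , drop = FALSE]
  if (!nrow(grid)) grid <- data.frame(p1 = min(starts), p2 = min(starts) + 1.5)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    f <- .fit_2site_nls(pts, c(pKa1 = grid$p1[[i]], pKa2 = grid$p2[[i]],
                               d0 = d0, dm = dm, d2 = d2))
    if (inherits(f, "try-error")) next
    rss <- sum(resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- coef(f)
      pars <- c(pKa1 = unname(cf[["pKa1"]]), pKa2 = unname(cf[["pKa2"]]),
                delta_min0 = unname(cf[["d0"]]), delta_mid = unname(cf[["dm"]]),
                delta_max2 = unname(cf[["d2"]]))
      best <- list(params = .sort_two_site(pars), rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) return(NULL)
  best$aicc <- .aicc(best$rss, n, 5L)
  best
}

# Report pKa1 < pKa2. The model is delta_min0 + A1*theta(pKa1) +
# A2*theta(pKa2) with A1 = delta_mid - delta_min0, A2 = delta_max2 -
# delta_mid; exchanging the sites swaps the amplitudes, so the intermediate
# plateau is re-derived to keep predictions identical.
.sort_two_site <- function(p) {
  if (p[["pKa1"]] <= p[["pKa2"]]) return(p)
  a1 <- p[["delta_mid"]] - p[["delta_min0"]]
  c(pKa1 = p[["pKa2"]], pKa2 = p[["pKa1"]],
    delta_min0 = p[["delta_min0"]],
    delta_mid = p[["delta_max2"]] - a1,
    delta_max2 = p[["delta_max2"]])
}

.predict_params <- function(model, params, pH) {
  if (model == "one_site") {
    hh_predict_1site(pH, params[["pKa"]], params[["delta_min"]],
                     params[["delta_max"]])
  } else {
    hh_predict_2site(pH, params[["pKa1"]], params[["pKa2"]],
                     params[["delta_min0"]], params[["delta_mid"]],
                     params[["delta_max2"]])
  }
}

.bootstrap_ci <- function(pts, model, params, n_boot, seed, level) {
  fitted0 <- .predict_params(model, params, pts$pH)
  res0 <- pts$shift - fitted0
  alpha <- (1 - level) / 2
  draws <- withr::with_seed(seed, {
    replicate(n_boot, {
      pb <- pts
      pb$shift <- fitted0 + sample(res0, replace = TRUE)
      f <- if (model == "one_site") .fit_one_site(pb) else .fit_two_site(pb)
      if (is.null(f)) rep(NA_real_, length(params)) else f$params[names(params)]
    })
  })
  draws <- matrix(draws, nrow = length(params),
                  dimnames = list(names(params), NULL))
  t(apply(draws, 1L, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Global titration fit sharing pKa values across nuclei
#'
#' Fits all series of one residue simultaneously with shared dissociation
#' constants and per-nucleus plateau shifts. Because different nuclei report
#' on different titration events with very different amplitudes (a backbone
#' carbon mostly sees the alpha-carboxyl transition, a side-chain carbon the
#' side-chain one), the joint fit resolves both sites even when no single
#' nucleus determines them both, and removes the near-degenerate solutions a
#' single-nucleus two-site fit can fall into.
#'
#' @param series_list Named list of [titration_series()] objects measured on
#'   the same residue (names give the atoms).
#' @param n_sites `"1"` or `"2"` shared sites.
#' @param seed Integer seed (kept for provenance; the fit is deterministic).
#' @return List with `pKa` (length `n_sites`, sorted ascending), `plateaus`
#'   (per-series named matrix), `rss`, `converged`, `fits` (per-series
#'   `titration_fit`-like parameter vectors).
#' @export
fit_titration_global <- function(series_list, n_sites = c("2", "1"),
                                 seed = 1L) {
  n_sites <- match.arg(as.character(n_sites[1L]), c("2", "1"))
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, TRUE, "titration_series")))
  k <- length(series_list)
  pH <- lapply(series_list, function(s) s$points$pH)
  y <- unlist(lapply(series_list, function(s) s$points$shift))
  # residuals for stacked series; par = c(pKa..., plateaus per series)
  n_pk <- if (n_sites == "2") 2L else 1L
  n_pl <- if (n_sites == "2") 3L else 2L
  resid_fun <- function(par) {
    pk <- par[seq_len(n_pk)]
    pred <- unlist(lapply(seq_len(k), function(i) {
      pl <- par[n_pk + (i - 1L) * n_pl + seq_len(n_pl)]
      if (n_sites == "2") {
        hh_predict_2site(pH[[i]], pk[[1L]], pk[[2L]], pl[[1L]], pl[[2L]],
                         pl[[3L]])
      } else {
        hh_predict_1site(pH[[i]], pk[[1L]], pl[[1L]], pl[[2L]])
      }
    }))
    y - pred
  }
  all_pts <- do.call(rbind, lapply(series_list, function(s) s$points))
  starts <- .pka_starts(all_pts[order(all_pts$pH), ])
  start_pk <- if (n_sites == "2") {
    g <- expand.grid(p1 = starts, p2 = starts)
    g <- g[g$p1 < g$p2 - 0.3, , drop = FALSE]
    if (!nrow(g)) g <- data.frame(p1 = min(starts), p2 = min(starts) + 1.5)
    g
  } else {
    data.frame(p1 = starts)
  }
  plateau_start <- unlist(lapply(series_list, function(s) {
    n <- nrow(s$points)
    a <- s$points$shift[[1L]]; b <- s$points$shift[[n]]
    if (n_sites == "2") c(a, (a + b) / 2, b) else c(a, b)
  }))
  best <- NULL
  for (i in seq_len(nrow(start_pk))) {
    par0 <- c(unlist(start_pk[i, ]), plateau_start)
    f <- try(minpack.lm::nls.lm(
      par0, fn = resid_fun,
      lower = c(rep(0, n_pk), rep(-20, k * n_pl)),
      upper = c(rep(14, n_pk), rep(230, k * n_pl)),
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(f$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = f$par, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(pKa = rep(NA_real_, n_pk), plateaus = NULL, rss = NA_real_,
                converged = FALSE, seed = seed))
  }
  pk <- unname(best$par[seq_len(n_pk)])
  plateaus <- do.call(rbind, lapply(seq_len(k), function(i) {
    best$par[n_pk + (i - 1L) * n_pl + seq_len(n_pl)]
  }))
  if (n_sites == "2" && pk[[1L]] > pk[[2L]]) {
    # relabel the sites ascending; exchanging them swaps the transition
    # amplitudes, so each intermediate plateau is re-derived
    pk <- rev(pk)
    plateaus[, 2L] <- plateaus[, 3L] - (plateaus[, 2L] - plateaus[, 1L])
  }
  rownames(plateaus) <- names(series_list)
  colnames(plateaus) <- if (n_sites == "2") {
    c("delta_min0", "delta_mid", "delta_max2")
  } else {
    c("delta_min", "delta_max")
  }
  list(pKa = pk, plateaus = plateaus, rss = best$rss, converged = TRUE,
       seed = seed)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> ", x$model, " (", x$direction, "), converged: ",
      x$converged, "\n", sep = "")
  if (!is.null(x$params)) {
    print(round(x$params, 4))
    cat("rss:", signif(x$rss, 4), " AICc:", signif(x$aicc, 4), "\n")
  }
  if (!is.null(x$ci)) {
    cat("bootstrap CI (", x$n_boot, " replicates):\n", sep = "")
    print(round(x$ci, 4))
  }
  invisible(x)
}

# Plateau-to-plateau amplitude of each fitted transition. With
# `normalize = TRUE` amplitudes are expressed as each site's share of the
# nucleus' total shift change, making 1H and 13C fits commensurable.
.transition_amplitudes <- function(fit, normalize = FALSE) {
  p <- fit$params
  amp <- if (fit$model == "one_site") {
    c(site1 = abs(p[["delta_max"]] - p[["delta_min"]]))
  } else {
    c(site1 = abs(p[["delta_mid"]] - p[["delta_min0"]]),
      site2 = abs(p[["delta_max2"]] - p[["delta_mid"]]))
  }
  if (normalize) amp / max(sum(amp), 1e-12) else amp
}

#' Assign fitted pKa values to chemical groups
#'
#' Given per-nucleus fits of the same residue, each titration event is
#' assigned to the alpha-carboxyl or the side-chain carboxyl group according
#' to which atom class (backbone: C/Ca/Ha; side chain: Cb/Hb/Cg/...) shows
#' the larger plateau-to-plateau amplitude across that transition. Amplitudes
#' are compared as each nucleus' fractional shift change across the
#' transition, so 1H and 13C fits are commensurable; ratios below
#' `min_ratio` are flagged `"unassigned"`. For a single-site
#' collection on a variant with exactly one ionizable group in the library
#' (e.g. isoAsp), that group's label is returned directly.
#'
#' @param fits Named list of `titration_fit` objects; names (or the series'
#'   `atom` fields) give the atom of each fit.
#' @param variant Optional variant label used for the single-group shortcut.
#' @param lib Library used for the single-group lookup.
#' @param min_ratio Minimum backbone/side-chain amplitude ratio (or inverse)
#'   to call a group (default 1.2).
#' @return Tibble with columns `site`, `pKa` (amplitude-weighted mean across
#'   fits) and `group`.
#' @export
assign_pka_to_groups <- function(fits, variant = NULL, lib = rc_library(),
                                 min_ratio = 1.2) {
  atoms <- names(fits)
  if (is.null(atoms)) {
    atoms <- vapply(fits, function(f) f$series$atom, "")
  }
  cls <- .atom_class(atoms)
  if (!any(cls == "backbone") || !any(cls == "side_chain")) {
    stop("need at least one backbone-proximal (C/Ca/Ha) and one ",
         "side-chain-proximal fit", call. = FALSE)
  }
  models <- vapply(fits, `[[`, "", "model")
  n_sites <- if (all(models == "one_site")) 1L else 2L
  if (n_sites == 1L && !is.null(variant)) {
    groups <- unique(lib$pka$group[lib$pka$variant == variant &
                                     lib$pka$source == "fitted"])
    if (length(groups) == 1L) {
      pka <- mean(vapply(fits, function(f) f$params[["pKa"]], 0))
      return(tibble::tibble(site = 1L, pKa = pka, group = groups))
    }
  }
  out <- lapply(seq_len(n_sites), function(site) {
    key <- if (n_sites == 1L) "pKa" else paste0("pKa", site)
    usable <- vapply(fits, function(f) key %in% names(f$params), TRUE)
    amp <- vapply(fits[usable],
                  function(f) .transition_amplitudes(f, normalize = TRUE)[[site]],
                  0)
    # amplitude-weighted combination: a nucleus constrains a titration event
    # in proportion to the shift change it shows across it, so fits with
    # near-zero amplitude for this site contribute (almost) nothing
    pka <- sum(amp * vapply(fits[usable], function(f) f$params[[key]], 0)) /
      sum(amp)
    a_bb <- mean(amp[cls[usable] == "backbone"])
    a_sc <- mean(amp[cls[usable] == "side_chain"])
    ratio <- max(a_bb, a_sc) / max(min(a_bb, a_sc), 1e-12)
    group <- if (ratio < min_ratio) {
      "unassigned"
    } else if (a_bb > a_sc) "alpha_carboxyl" else "side_chain"
    tibble::tibble(site = site, pKa = pka, group = group)
  })
  do.call(rbind, out)
}
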