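#' Match observed peaks to diagnostic correlations
#'
#' Pairs each diagnostic correlation with its nearest observed peak under the
#' scaled elliptical distance `sqrt(((dH - pH)/tolH)^2 + ((dC - pC)/tolC)^2)`.
#' Assignment is greedy nearest-first: match pairs are accepted in order of
#' increasing distance, each peak satisfying at most one diagnostic; ties are
#' broken by the lower 13C coordinate of the diagnostic. `within` flags
#' matches inside the tolerance ellipse (distance <= 1, with a small numeric
#' margin at the boundary).
#'
#' @param pl A referenced [peak_list()] (unreferenced lists are refused;
#'   apply [rereference()] first, with offset 0 if the spectrometer scale is
#'   already DSS-anchored).
#' @param diagnostics Tibble of diagnostic correlations, e.g. from
#'   [diagnostic_set()] at `pl$pH`.
#' @param tolH,tolC Tolerances (ppm).
#' @return Tibble with one row per diagnostic: `variant`, `atom_C`, `atom_H`,
#'   `delta_C`, `delta_H`, `peak_index`, `peak_H`, `peak_C`, `peak_volume`,
#'   `peak_height`, `distance`, `within`.
#' @export
match_peaks <- function(pl, diagnostics, tolH = 0.05, tolC = 0.5) {
  stopifnot(inherits(pl, "peak_list"))
  if (!pl$referenced) {
    stop("peak list has not been referenced; apply rereference() first ",
         "(use offset 0 if the scale is already DSS-anchored)", call. = FALSE)
  }
  diagnostics <- tibble::as_tibble(diagnostics)
  n_d <- nrow(diagnostics)
  empty <- tibble::tibble(
    variant = character(), atom_C = character(), atom_H = character(),
    delta_C = numeric(), delta_H = numeric(), peak_index = integer(),
    peak_H = numeric(), peak_C = numeric(), peak_volume = numeric(),
    peak_height = numeric(), distance = numeric(), within = logical())
  if (n_d == 0L) return(empty)
  out <- tibble::tibble(
    variant = diagnostics$variant, atom_C = diagnostics$atom_C,
    atom_H = diagnostics$atom_H, delta_C = diagnostics$delta_C,
    delta_H = diagnostics$delta_H, peak_index = NA_integer_,
    peak_H = NA_real_, peak_C = NA_real_, peak_volume = NA_real_,
    peak_height = NA_real_, distance = NA_real_, within = FALSE)
  pk <- pl$peaks
  if (nrow(pk) == 0L) return(out)
  d <- outer(diagnostics$delta_H, pk$delta_H, `-`) / tolH
  dc <- outer(diagnostics$delta_C, pk$delta_C, `-`) / tolC
  dist <- sqrt(d^2 + dc^2)
  cand <- expand.grid(di = seq_len(n_d), pi = seq_len(nrow(pk)))
  cand$dist <- dist[cbind(cand$di, cand$pi)]
  cand <- cand[order(cand$dist, diagnostics$delta_C[cand$di]), ]
  used_peak <- logical(nrow(pk))
  used_diag <- logical(n_d)
  for (i in seq_len(nrow(cand))) {
    di <- cand$di[[i]]; pi <- cand$pi[[i]]
    if (used_diag[[di]] || used_peak[[pi]]) next
    used_diag[[di]] <- TRUE
    used_peak[[pi]] <- TRUE
    out$peak_index[[di]] <- pi
    out$peak_H[[di]] <- pk$delta_H[[pi]]
    out$peak_C[[di]] <- pk$delta_C[[pi]]
    out$peak_volume[[di]] <- pk$volume[[pi]]
    out$peak_height[[di]] <- pk$height[[pi]]
    out$distance[[di]] <- cand$dist[[i]]
    out$within[[di]] <- cand$dist[[i]] <= 1 + .boundary_eps
  }
  out
}

# Intact counterpart used for stoichiometry: modified species -> (reference
# species, C atom, H atoms of the matching multiplicity).
.counterpart_map <- list(
  Pro_Nterm = list(ref = "Pro_internal", atom_C = "Cd",
                   atoms_H = c("Hd2", "Hd3")),
  Asp_Cterm = list(ref = "Asp_internal", atom_C = "Cb",
                   atoms_H = c("Hb2", "Hb3")),
  isoAsp = list(ref = "Asp_internal", atom_C = "Cb",
                atoms_H = c("Hb2", "Hb3")),
  Snn = list(ref = "Asp_internal", atom_C = "Cb", atoms_H = c("Hb2", "Hb3"))
)

#' Call modifications from matched diagnostics
#'
#' Applies the evidence rules at the peak-list pH:
#' * **Asp-Xaa cleavage** is called on C-terminal-Asp Cb-Hb evidence, and is
#'   **upgraded to Asp-Pro cleavage** when the N-terminal-proline Cd-Hd
#'   correlation also matches. At acidic pH (< 5) the Asp_Cterm Cb-Hb
#'   correlations overlap the random-coil envelope and are suppressed as
#'   evidence, so a cleavage call then relies on Pro_Nterm alone.
#' * **isoAsp** is called when either Cb-Hb2 or Cb-Hb3 matches
#'   (confidence `multi_peak` when both do), **Snn** likewise on its Hb pair.
#'
#' Stereo-unassigned Hb2/Hb3 (and Hd2/Hd3) are interchangeable: a match to
#' either proton of a pair counts as that pair's evidence.
#'
#' @param matches Output of [match_peaks()].
#' @param pH Peak-list pH the matches were made at.
#' @param quantify Estimate stoichiometry from volumes when the intact
#'   counterpart correlation is also present in `matches` (see
#'   [quantify_fraction()]); heights are used as a fallback, recorded in the
#'   call's `basis`.
#' @return A `detection_report`: `calls` (tibble: `modification`,
#'   `confidence`, `n_evidence`, `fraction_percent`, `basis`), `evidence`
#'   (matched rows), `unmatched_diagnostics`, `parameters`.
#' @export
call_modifications <- function(matches, pH, quantify = TRUE) {
  matches <- tibble::as_tibble(matches)
  hits <- matches[matches$within, , drop = FALSE]
  acidic <- pH < 5

  pair_hit <- function(variant, atom_C, atoms_H) {
    hits[hits$variant == variant & hits$atom_C == atom_C &
           hits$atom_H %in% atoms_H, , drop = FALSE]
  }
  calls <- list()
  add_call <- function(modification, evidence, confidence, fraction, basis) {
    calls[[length(calls) + 1L]] <<- tibble::tibble(
      modification = modification, confidence = confidence,
      n_evidence = nrow(evidence), fraction_percent = fraction, basis = basis)
  }
  frac_for <- function(variant, evidence) {
    if (!quantify || nrow(evidence) == 0L) return(list(f = NA_real_, basis = NA_character_))
    cp <- .counterpart_map[[variant]]
    if (is.null(cp)) return(list(f = NA_real_, basis = NA_character_))
    refs <- pair_hit(cp$ref, cp$atom_C, cp$atoms_H)
    if (!nrow(refs)) return(list(f = NA_real_, basis = NA_character_))
    use_vol <- all(!is.na(evidence$peak_volume)) && all(!is.na(refs$peak_volume))
    mod_v <- if (use_vol) evidence$peak_volume else evidence$peak_height
    ref_v <- if (use_vol) refs$peak_volume else refs$peak_height
    if (any(is.na(mod_v)) || any(is.na(ref_v))) {
      return(list(f = NA_real_, basis = NA_character_))
    }
    # pair stereo partners positionally (Hb2 with Hb2 etc.) where possible
    ev <- evidence[order(evidence$atom_H), , drop = FALSE]
    rf <- refs[order(refs$atom_H), , drop = FALSE]
    k <- min(nrow(ev), nrow(rf))
    mv <- if (use_vol) ev$peak_volume else ev$peak_height
    rv <- if (use_vol) rf$peak_volume else rf$peak_height
    f <- mean(vapply(seq_len(k), function(i) {
      quantify_fraction(mv[[i]], rv[[i]])
    }, 0))
    list(f = f, basis = if (use_vol) "volume" else "height_fallback")
  }

  asp_ct <- pair_hit("Asp_Cterm", "Cb", c("Hb2", "Hb3"))
  pro_nt <- pair_hit("Pro_Nterm", "Cd", c("Hd2", "Hd3"))
  if (acidic) asp_ct <- asp_ct[0L, , drop = FALSE]
  if (nrow(pro_nt)) {
    ev <- rbind(asp_ct, pro_nt)
    q <- frac_for("Pro_Nterm", pro_nt)
    add_call("AspPro_cleavage", ev,
             if (nrow(ev) > 1L) "multi_peak" else "single_peak", q$f, q$basis)
  } else if (nrow(asp_ct)) {
    q <- frac_for("Asp_Cterm", asp_ct)
    add_call("AspXaa_cleavage", asp_ct,
             if (nrow(asp_ct) > 1L) "multi_peak" else "single_peak",
             q$f, q$basis)
  }
  iso <- pair_hit("isoAsp", "Cb", c("Hb2", "Hb3"))
  if (nrow(iso)) {
    q <- frac_for("isoAsp", iso)
    add_call("isoAsp", iso,
             if (nrow(iso) > 1L) "multi_peak" else "single_peak", q$f, q$basis)
  }
  snn <- pair_hit("Snn", "Cb", c("Hb2", "Hb3"))
  if (nrow(snn)) {
    q <- frac_for("Snn", snn)
    add_call("Snn", snn,
             if (nrow(snn) > 1L) "multi_peak" else "single_peak", q$f, q$basis)
  }
  calls_tbl <- if (length(calls)) {
    do.call(rbind, calls)
  } else {
    tibble::tibble(modification = character(), confidence = character(),
                   n_evidence = integer(), fraction_percent = numeric(),
                   basis = character())
  }
  structure(
    list(calls = calls_tbl, evidence = hits,
         unmatched_diagnostics = matches[!matches$within, , drop = FALSE],
         parameters = list(pH = pH, quantification = "equal C-H response assumed (relaxation and transfer differences ignored)")),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report> pH ", x$parameters$pH, ", ",
      nrow(x$calls), " call(s)\n", sep = "")
  if (nrow(x$calls)) print(x$calls)
  invisible(x)
}

#' Modified-species fraction from cross-peak integrals
#'
#' `100 * volume_mod / (volume_mod + volume_ref)`, assuming equal per-C-H
#' signal response of the modified and intact correlations (comparable
#' multiplicity; relaxation and INEPT-transfer differences are ignored, which
#' is recorded as an approximation in every report).
#'
#' @param volume_mod,volume_ref Integrals (or, as a caller-recorded fallback,
#'   heights) of the modified and intact cross-peaks; both must be > 0.
#' @return Fraction in percent, in (0, 100).
#' @export
quantify_fraction <- function(volume_mod, volume_ref) {
  if (!is.finite(volume_mod) || !is.finite(volume_ref) ||
      volume_mod <= 0 || volume_ref <= 0) {
    stop("both integrals must be finite and positive", call. = FALSE)
  }
  100 * volume_mod / (volume_mod + volume_ref)
}

#' End-to-end detection on a referenced peak list
#'
#' Convenience wrapper: builds the diagnostic set at the peak-list pH
#' (uniqueness-filtered against the background envelope, plus the intact
#' counterpart correlations needed for quantification), matches, and calls.
#'
#' @inheritParams match_peaks
#' @param lib A [rc_library()].
#' @param min_uniqueness Uniqueness threshold for the diagnostic set.
#' @return A `detection_report`.
#' @export
detect_modifications <- function(pl, lib = rc_library(), tolH = 0.05,
                                 tolC = 0.5, min_uniqueness = 1) {
  diags <- diagnostic_set(lib, pl$pH, tolH = tolH, tolC = tolC,
                          min_uniqueness = min_uniqueness)
  counterparts <- diagnostic_correlations(
    lib, pl$pH, variants = c("Asp_internal", "Pro_internal"))
  counterparts$uniqueness <- NA_real_
  matches <- match_peaks(pl, rbind(diags, counterparts),
                         tolH = tolH, tolC = tolC)
  report <- call_modifications(matches, pH = pl$pH)
  report$parameters <- c(report$parameters,
                         list(tolH = tolH, tolC = tolC,
                              min_uniqueness = min_uniqueness,
                              library_version = lib$version))
  report
}
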