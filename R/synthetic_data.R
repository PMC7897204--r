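#' Specification for a synthetic denatured-protein peak list
#'
#' Describes the simulated experiment: the protein sequence (background
#' cross-peaks are emitted once per amino-acid type present, matching the
#' degenerate random-coil picture of a denatured chain), the modifications
#' present with their stoichiometric fractions, the sample pH, and the noise
#' model (i.i.d. Gaussian ppm noise per axis; log-normal volumes with a
#' given coefficient of variation around the stoichiometric mean).
#'
#' @param sequence One-letter amino-acid string.
#' @param modifications Named list of fractions in (0, 1\], e.g.
#'   `list(AspPro_cleavage = 0.1)`. Allowed names: `AspPro_cleavage`,
#'   `AspXaa_cleavage`, `isoAsp`, `Snn`.
#' @param pH Sample pH.
#' @param noise_H,noise_C Gaussian ppm noise standard deviations (1H / 13C).
#'   Defaults 0.01 / 0.1 ppm reflect typical peak-picking scatter in
#'   denatured-protein HSQCs.
#' @param volume_cv Fractional standard deviation of peak volumes
#'   (default 0.05).
#' @param base_volume Mean volume of a full-stoichiometry cross-peak.
#' @param per_instance Emit one background peak per residue instance with
#'   `jitter_H`/`jitter_C` ppm of sequence-context jitter, instead of one
#'   per residue type.
#' @param jitter_H,jitter_C Jitter used in per-instance mode (ppm).
#' @param seed Integer seed; mandatory.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(sequence, modifications = list(), pH = 7.4,
                            noise_H = 0.01, noise_C = 0.1, volume_cv = 0.05,
                            base_volume = 1e5, per_instance = FALSE,
                            jitter_H = 0.03, jitter_C = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nchar(sequence) || grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)) {
    stop("sequence must be a non-empty string of one-letter amino-acid codes",
         call. = FALSE)
  }
  if (length(modifications)) {
    if (is.null(names(modifications)) || any(!nzchar(names(modifications)))) {
      stop("modifications must be a named list", call. = FALSE)
    }
    bad <- setdiff(names(modifications),
                   c("AspPro_cleavage", "AspXaa_cleavage", "isoAsp", "Snn"))
    if (length(bad)) {
      stop("unknown modification(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    fr <- unlist(modifications)
    if (any(fr <= 0 | fr > 1)) {
      stop("modification fractions must lie in (0, 1]", call. = FALSE)
    }
  }
  stopifnot(noise_H >= 0, noise_C >= 0, volume_cv >= 0, base_volume > 0)
  .check_mod_compatibility(sequence, names(modifications))
  structure(
    list(sequence = sequence, modifications = modifications, pH = pH,
         noise_H = noise_H, noise_C = noise_C, volume_cv = volume_cv,
         base_volume = base_volume, per_instance = isTRUE(per_instance),
         jitter_H = jitter_H, jitter_C = jitter_C, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

.check_mod_compatibility <- function(sequence, mods) {
  if ("AspPro_cleavage" %in% mods && !grepl("DP", sequence)) {
    stop("AspPro_cleavage requires an Asp-Pro (DP) motif in the sequence",
         call. = FALSE)
  }
  internal_d <- grepl("D", substr(sequence, 1, nchar(sequence) - 1))
  if ("AspXaa_cleavage" %in% mods && !internal_d) {
    stop("AspXaa_cleavage requires a non-C-terminal Asp in the sequence",
         call. = FALSE)
  }
  if (any(c("isoAsp", "Snn") %in% mods) &&
      !grepl("[DN]", substr(sequence, 1, nchar(sequence) - 1))) {
    stop("isoAsp/Snn formation requires an internal Asp or Asn residue",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Marker species emitted for each modification, and the intact species whose
# volume is depleted by the modified fraction.
.mod_species <- list(
  AspPro_cleavage = list(markers = c("Asp_Cterm", "Pro_Nterm"),
                         depleted = c("Asp_internal", "Pro_internal")),
  AspXaa_cleavage = list(markers = "Asp_Cterm", depleted = "Asp_internal"),
  isoAsp = list(markers = "isoAsp", depleted = "Asp_internal"),
  Snn = list(markers = "Snn", depleted = "Asp_internal")
)

#' Simulate a denatured-protein HSQC peak list
#'
#' Emits one background C-H cross-peak per background-table correlation for
#' each residue type in the sequence, plus the diagnostic cross-peaks of each
#' requested modification. Modified-species volumes are scaled by the
#' modification fraction and the corresponding intact-species volumes by one
#' minus that fraction; Gaussian ppm noise is added per axis and volumes are
#' drawn log-normally. The returned ground truth lists every emitted peak's
#' identity, making the generator usable as an oracle for detection and
#' quantification.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `peaklist` (a referenced [peak_list()]) and
#'   `truth` (tibble: `species`, `atom_C`, `atom_H`, `true_H`, `true_C`,
#'   `fraction`).
#' @examples
#' sim <- simulate_peaklist(simulation_spec("GGDPGG",
#'   modifications = list(AspPro_cleavage = 0.1), seed = 1))
#' detect_modifications(sim$peaklist)
#' @export
simulate_peaklist <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  lib <- rc_library()
  aas <- unique(strsplit(spec$sequence, "")[[1L]])
  counts <- table(strsplit(spec$sequence, "")[[1L]])

  # Asp and Pro cross-peaks come from the measured urea-condition internal
  # entries below, not from the generic background rows, so each residue
  # type is represented exactly once.
  bg <- lib$background[lib$background$aa %in% setdiff(aas, c("D", "P")), ,
                       drop = FALSE]
  truth <- tibble::tibble(
    species = paste0("aa_", bg$aa), atom_C = bg$atom_C, atom_H = bg$atom_H,
    true_H = bg$delta_H, true_C = bg$delta_C, fraction = 1)
  if (spec$per_instance) {
    reps <- as.integer(counts[bg$aa])
    truth <- truth[rep(seq_len(nrow(truth)), reps), , drop = FALSE]
  }

  # internal Asp / Pro carry the measured urea-condition coordinates; their
  # volumes are depleted by any modification consuming them
  depletion <- c(Asp_internal = 0, Pro_internal = 0)
  for (mod in names(spec$modifications)) {
    for (dep in .mod_species[[mod]]$depleted) {
      depletion[[dep]] <- depletion[[dep]] + spec$modifications[[mod]]
    }
  }
  internal <- list()
  if ("D" %in% aas) internal <- c(internal, "Asp_internal")
  if ("P" %in% aas) internal <- c(internal, "Pro_internal")
  for (sp in internal) {
    cors <- diagnostic_correlations(lib, spec$pH, variants = sp)
    truth <- rbind(truth, tibble::tibble(
      species = sp, atom_C = cors$atom_C, atom_H = cors$atom_H,
      true_H = cors$delta_H, true_C = cors$delta_C,
      fraction = max(0, 1 - depletion[[sp]])))
  }
  for (mod in names(spec$modifications)) {
    f <- spec$modifications[[mod]]
    for (sp in .mod_species[[mod]]$markers) {
      cors <- diagnostic_correlations(lib, spec$pH, variants = sp)
      truth <- rbind(truth, tibble::tibble(
        species = sp, atom_C = cors$atom_C, atom_H = cors$atom_H,
        true_H = cors$delta_H, true_C = cors$delta_C, fraction = f))
    }
  }
  truth <- truth[truth$fraction > 0, , drop = FALSE]

  n <- nrow(truth)
  peaks <- withr::with_seed(spec$seed, {
    jit_H <- if (spec$per_instance) rnorm(n, 0, spec$jitter_H) else 0
    jit_C <- if (spec$per_instance) rnorm(n, 0, spec$jitter_C) else 0
    sdlog <- sqrt(log(1 + spec$volume_cv^2))
    vol <- spec$base_volume * truth$fraction *
      exp(rnorm(n, -sdlog^2 / 2, sdlog))
    tibble::tibble(
      delta_H = truth$true_H + jit_H + rnorm(n, 0, spec$noise_H),
      delta_C = truth$true_C + jit_C + rnorm(n, 0, spec$noise_C),
      height = vol,
      volume = vol,
      label = paste0(truth$species, ".", truth$atom_C, "-", truth$atom_H))
  })
  pl <- peak_list(peaks, pH = spec$pH, referenced = TRUE)
  list(peaklist = pl, truth = truth)
}

#' Simulate a pH titration series
#'
#' Generative twin of the fitted models: evaluates a one- or two-site
#' Henderson-Hasselbalch curve on a pH grid and adds i.i.d. Gaussian noise.
#'
#' @param true_params Named list/vector: either `(pKa, delta_min, delta_max)`
#'   or `(pKa1, pKa2, delta_min0, delta_mid, delta_max2)`.
#' @param pH_grid pH values within \[0, 14\].
#' @param noise Gaussian noise standard deviation (ppm).
#' @param seed Integer seed.
#' @param variant,atom Metadata passed to [titration_series()].
#' @return A `titration_series`.
#' @export
simulate_titration <- function(true_params, pH_grid, noise = 0, seed = 1L,
                               variant = NA_character_,
                               atom = NA_character_) {
  if (any(pH_grid < 0 | pH_grid > 14)) {
    stop("pH grid must lie within [0, 14]", call. = FALSE)
  }
  p <- as.list(true_params)
  mu <- if ("pKa" %in% names(p)) {
    hh_predict_1site(pH_grid, p$pKa, p$delta_min, p$delta_max)
  } else {
    hh_predict_2site(pH_grid, p$pKa1, p$pKa2, p$delta_min0, p$delta_mid,
                     p$delta_max2)
  }
  shifts <- withr::with_seed(seed, mu + rnorm(length(pH_grid), 0, noise))
  titration_series(pH_grid, shifts, variant = variant, atom = atom)
}
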