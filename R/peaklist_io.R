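#' Construct a 2D peak list
#'
#' Container for observed 1H-13C HSQC cross-peaks plus the spectrum metadata
#' the pipeline needs (sample pH, spectrometer 1H frequency, temperature,
#' solvent). Shifts are stored at 1e-4 ppm precision; all comparisons in the
#' pipeline use tolerances, never equality.
#'
#' @param peaks Data frame with columns `delta_H`, `delta_C` and optionally
#'   `height`, `volume`, `label`.
#' @param pH Sample pH in \[0, 14\].
#' @param field_MHz Spectrometer 1H frequency (> 0), default 600.
#' @param temperature_K Temperature, default 298.
#' @param solvent Free-text solvent description.
#' @param referenced Whether DSS referencing has already been applied.
#' @return A `peak_list` object.
#' @export
peak_list <- function(peaks, pH, field_MHz = 600, temperature_K = 298,
                      solvent = "7 M urea-d4, D2O", referenced = FALSE) {
  stopifnot(is.data.frame(peaks))
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]", call. = FALSE)
  if (field_MHz <= 0) stop("field_MHz must be positive", call. = FALSE)
  peaks <- tibble::as_tibble(peaks)
  if (!"height" %in% names(peaks)) peaks$height <- NA_real_
  if (!"volume" %in% names(peaks)) peaks$volume <- NA_real_
  if (!"label" %in% names(peaks)) peaks$label <- NA_character_
  peaks$delta_H <- round(as.numeric(peaks$delta_H), 4)
  peaks$delta_C <- round(as.numeric(peaks$delta_C), 4)
  .validate_peaks(peaks)
  structure(
    list(peaks = peaks[c("delta_H", "delta_C", "height", "volume", "label")],
         pH = pH, field_MHz = field_MHz, temperature_K = temperature_K,
         solvent = solvent, referenced = isTRUE(referenced)),
    class = "peak_list"
  )
}

.validate_peaks <- function(peaks, lines = seq_len(nrow(peaks))) {
  bad_h <- which(peaks$delta_H < -1 | peaks$delta_H > 12)
  bad_c <- which(peaks$delta_C < 0 | peaks$delta_C > 220)
  bad_v <- which(!is.na(peaks$volume) & peaks$volume < 0)
  bad_i <- which(!is.na(peaks$height) & peaks$height < 0)
  msgs <- c(
    if (length(bad_h)) paste0("1H shift out of [-1, 12] ppm at row(s) ",
                              paste(lines[bad_h], collapse = ", ")),
    if (length(bad_c)) paste0("13C shift out of [0, 220] ppm at row(s) ",
                              paste(lines[bad_c], collapse = ", ")),
    if (length(bad_v)) paste0("negative volume at row(s) ",
                              paste(lines[bad_v], collapse = ", ")),
    if (length(bad_i)) paste0("negative height at row(s) ",
                              paste(lines[bad_i], collapse = ", "))
  )
  if (length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  invisible(peaks)
}

#' @export
print.peak_list <- function(x, ...) {
  cat("<peak_list> ", nrow(x$peaks), " peaks, pH ", x$pH, ", ",
      x$field_MHz, " MHz, ", x$temperature_K, " K, ", x$solvent,
      if (x$referenced) " [referenced]" else " [unreferenced]", "\n", sep = "")
  invisible(x)
}

#' Read a 2D peak list from disk
#'
#' Supports two dialects: Sparky `.list` exports (whitespace table with
#' header `Assignment w1 w2 [Data Height] [Volume]`; `w1` is taken as 13C and
#' `w2` as 1H, the usual axis order for a 13C-HSQC with carbon indirect —
#' use `swap_axes = TRUE` for the opposite convention) and CSV (columns
#' `dH_ppm`, `dC_ppm` and optional `height`, `volume`, `label`). Malformed
#' rows are reported with their line numbers.
#'
#' @param path File path.
#' @param dialect `"sparky"` or `"csv"`.
#' @param pH,field_MHz,temperature_K,solvent Spectrum metadata (files carry
#'   only coordinates); see [peak_list()].
#' @param swap_axes Sparky only: treat `w1` as 1H and `w2` as 13C.
#' @return A `peak_list`.
#' @export
read_peaklist <- function(path, dialect = c("sparky", "csv"), pH,
                          field_MHz = 600, temperature_K = 298,
                          solvent = "7 M urea-d4, D2O", swap_axes = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "sparky") {
    lines <- readLines(path)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) stop("empty Sparky list: ", path, call. = FALSE)
    header_i <- keep[[1L]]
    header <- trimws(lines[[header_i]])
    if (!grepl("^Assignment\\s+w1\\s+w2", header)) {
      stop("unrecognized Sparky header in ", path, ": '", header, "'",
           call. = FALSE)
    }
    has_height <- grepl("Data\\s*Height", header)
    has_volume <- grepl("Volume", header)
    body_i <- keep[-1L]
    if (!length(body_i)) {
      peaks <- tibble::tibble(delta_H = numeric(), delta_C = numeric())
      return(peak_list(peaks, pH = pH, field_MHz = field_MHz,
                       temperature_K = temperature_K, solvent = solvent))
    }
    fields <- strsplit(trimws(lines[body_i]), "\\s+")
    n_expected <- 3L + has_height + has_volume
    bad <- which(lengths(fields) < n_expected)
    if (length(bad)) {
      stop("malformed Sparky row(s) at line(s) ",
           paste(body_i[bad], collapse = ", "), " in ", path, call. = FALSE)
    }
    m <- do.call(rbind, lapply(fields, `[`, seq_len(n_expected)))
    w1 <- suppressWarnings(as.numeric(m[, 2L]))
    w2 <- suppressWarnings(as.numeric(m[, 3L]))
    bad_num <- which(is.na(w1) | is.na(w2))
    if (length(bad_num)) {
      stop("non-numeric shift(s) at line(s) ",
           paste(body_i[bad_num], collapse = ", "), " in ", path,
           call. = FALSE)
    }
    peaks <- tibble::tibble(
      delta_H = if (swap_axes) w1 else w2,
      delta_C = if (swap_axes) w2 else w1,
      height = if (has_height) as.numeric(m[, 4L]) else NA_real_,
      volume = if (has_volume) as.numeric(m[, 3L + has_height + 1L]) else NA_real_,
      label = m[, 1L]
    )
    lines_of_rows <- body_i
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("dH_ppm", "dC_ppm") %in% names(df))) {
      stop("CSV peak list must have columns dH_ppm and dC_ppm: ", path,
           call. = FALSE)
    }
    peaks <- tibble::tibble(
      delta_H = as.numeric(df$dH_ppm),
      delta_C = as.numeric(df$dC_ppm),
      height = if (!is.null(df$height)) as.numeric(df$height) else NA_real_,
      volume = if (!is.null(df$volume)) as.numeric(df$volume) else NA_real_,
      label = if (!is.null(df$label)) as.character(df$label) else NA_character_
    )
    lines_of_rows <- seq_len(nrow(peaks)) + 1L  # header line is line 1
  }
  peaks$delta_H <- round(peaks$delta_H, 4)
  peaks$delta_C <- round(peaks$delta_C, 4)
  .validate_peaks(peaks, lines = lines_of_rows)
  peak_list(peaks, pH = pH, field_MHz = field_MHz,
            temperature_K = temperature_K, solvent = solvent)
}

#' Write a peak list to disk
#'
#' Inverse of [read_peaklist()]; `read_peaklist(write_peaklist(pl))` is
#' loss-free for coordinates, heights, volumes and labels in both dialects.
#'
#' @param pl A `peak_list`.
#' @param path Output path.
#' @param dialect `"sparky"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, dialect = c("sparky", "csv")) {
  stopifnot(inherits(pl, "peak_list"))
  dialect <- match.arg(dialect)
  pk <- pl$peaks
  if (dialect == "sparky") {
    has_height <- any(!is.na(pk$height))
    has_volume <- any(!is.na(pk$volume))
    header <- paste0("      Assignment         w1         w2",
                     if (has_height) "   Data Height" else "",
                     if (has_volume) "       Volume" else "")
    label <- ifelse(is.na(pk$label), "?-?", pk$label)
    rows <- sprintf("%16s %10.4f %10.4f%s%s",
                    label, pk$delta_C, pk$delta_H,
                    if (has_height) sprintf(" %13.6g", pk$height) else "",
                    if (has_volume) sprintf(" %12.6g", pk$volume) else "")
    writeLines(c(header, "", rows), path)
  } else {
    out <- data.frame(dH_ppm = pk$delta_H, dC_ppm = pk$delta_C,
                      height = pk$height, volume = pk$volume,
                      label = pk$label)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Indirect chemical-shift referencing specification
#'
#' The 1H axis is referenced to DSS at 0 ppm from a 1D proton experiment; the
#' heteronuclear axes are referenced indirectly through the IUPAC frequency
#' ratios (13C: 0.251449530, 15N: 0.101329118). The 15N ratio is carried for
#' completeness; no 15N diagnostics are in scope.
#'
#' @param dss_offset_H Observed 1H shift of DSS on the current scale (ppm).
#' @param xi_13C,xi_15N Indirect referencing frequency ratios.
#' @return A `referencing_spec` list.
#' @export
referencing_spec <- function(dss_offset_H, xi_13C = 0.251449530,
                             xi_15N = 0.101329118) {
  stopifnot(is.finite(dss_offset_H), xi_13C > 0, xi_15N > 0)
  structure(list(dss_offset_H = dss_offset_H, xi_13C = xi_13C,
                 xi_15N = xi_15N),
            class = "referencing_spec")
}

#' Apply DSS-based referencing to a peak list
#'
#' Subtracts the observed DSS 1H offset from the proton axis. Because the
#' 13C axis is referenced indirectly as a fixed ratio of the 1H reference
#' frequency, the induced 13C correction is identical in ppm to first order,
#' so the same offset is subtracted from the carbon axis (the second-order
#' term is ~1e-6 ppm at typical offsets and is neglected). Applying
#' referencing twice is rejected via the `referenced` metadata flag;
#' re-applying with the negative offset restores the original list exactly.
#'
#' @param pl A `peak_list`.
#' @param spec A [referencing_spec()], or a bare numeric DSS offset.
#' @param force Allow re-referencing an already referenced list.
#' @return The referenced `peak_list`.
#' @export
rereference <- function(pl, spec, force = FALSE) {
  stopifnot(inherits(pl, "peak_list"))
  if (is.numeric(spec)) spec <- referencing_spec(spec)
  stopifnot(inherits(spec, "referencing_spec"))
  if (pl$referenced && !force) {
    stop("peak list is already referenced; pass force = TRUE to re-apply",
         call. = FALSE)
  }
  pl$peaks$delta_H <- pl$peaks$delta_H - spec$dss_offset_H
  pl$peaks$delta_C <- pl$peaks$delta_C - spec$dss_offset_H
  pl$referenced <- TRUE
  pl
}

#' Write / read a structured report
#'
#' Serializes detection reports and titration fits to JSON (loss-free round
#' trip via [read_report()]) or to a flat TSV of the main table.
#'
#' @param report A `detection_report` or `titration_fit`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path` invisibly; `read_report()` returns the reconstructed object.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- if (inherits(report, "detection_report")) {
      report$calls
    } else if (inherits(report, "titration_fit")) {
      tibble::tibble(parameter = names(report$params),
                     estimate = unname(report$params))
    } else {
      stop("unsupported report type", call. = FALSE)
    }
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(report, "detection_report")) {
    list(type = "detection_report",
         calls = report$calls, evidence = report$evidence,
         unmatched_diagnostics = report$unmatched_diagnostics,
         parameters = report$parameters)
  } else if (inherits(report, "titration_fit")) {
    list(type = "titration_fit", model = report$model,
         params = as.list(report$params), direction = report$direction,
         rss = report$rss, aicc = report$aicc,
         ci = if (is.null(report$ci)) NULL else {
           list(parameter = rownames(report$ci),
                lower = unname(report$ci[, 1L]),
                upper = unname(report$ci[, 2L]))
         },
         n_boot = report$n_boot, converged = report$converged,
         seed = report$seed,
         series = list(pH = report$series$points$pH,
                       shift = report$series$points$shift,
                       variant = report$series$variant,
                       atom = report$series$atom,
                       medium = report$series$medium))
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  ok <- try(jsonlite::write_json(payload, path, digits = NA,
                                 auto_unbox = TRUE, null = "null"),
            silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("could not write report to ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(raw$type, "titration_fit")) {
    series <- titration_series(raw$series$pH, raw$series$shift,
                               variant = raw$series$variant,
                               atom = raw$series$atom,
                               medium = raw$series$medium)
    ci <- NULL
    if (!is.null(raw$ci)) {
      ci <- cbind(lower = raw$ci$lower, upper = raw$ci$upper)
      rownames(ci) <- raw$ci$parameter
      colnames(ci) <- c("2.5%", "97.5%")
    }
    return(structure(
      list(model = raw$model, params = unlist(raw$params),
           direction = raw$direction, rss = raw$rss, aicc = raw$aicc,
           ci = ci, n_boot = raw$n_boot, converged = raw$converged,
           seed = raw$seed, series = series),
      class = "titration_fit"))
  }
  if (identical(raw$type, "detection_report")) {
    return(structure(
      list(calls = tibble::as_tibble(raw$calls),
           evidence = tibble::as_tibble(raw$evidence),
           unmatched_diagnostics = tibble::as_tibble(raw$unmatched_diagnostics),
           parameters = raw$parameters),
      class = "detection_report"))
  }
  stop("unrecognized report file: ", path, call. = FALSE)
}
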