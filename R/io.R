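#' 1D NMR spectrum
#'
#' A frequency-domain 1H spectrum: ppm axis stored decreasing (NMR display
#' convention, high field to the right) with finite intensities and free-form
#' calibration metadata.
#'
#' @param ppm chemical-shift axis in ppm, strictly monotone. Stored
#'   decreasing; an increasing axis is reversed together with the intensities.
#' @param intensities finite numeric vector, same length as `ppm`.
#' @param metadata named list (calibration shifts, seeds, provenance).
#' @return An object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(ppm, intensities, metadata = list()) {
  ppm <- as.numeric(ppm); intensities <- as.numeric(intensities)
  stopifnot(length(ppm) == length(intensities), length(ppm) >= 2L)
  d <- diff(ppm)
  if (all(d > 0)) {
    ppm <- rev(ppm); intensities <- rev(intensities)
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone")
  }
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  structure(list(ppm = ppm, intensities = intensities, metadata = metadata),
            class = "spectrum_1d")
}

#' Integrate a ppm region of a 1D spectrum
#'
#' Trapezoidal integral of the intensities over a closed ppm window.
#'
#' @param spectrum a [spectrum_1d()].
#' @param region `c(lo, hi)` ppm window (order irrelevant).
#' @return Integral in intensity x ppm units.
#' @export
integrate_region <- function(spectrum, region) {
  stopifnot(inherits(spectrum, "spectrum_1d"), length(region) == 2L)
  lo <- min(region); hi <- max(region)
  if (lo < min(spectrum$ppm) || hi > max(spectrum$ppm)) {
    stop("integration region [", lo, ", ", hi, "] ppm lies outside the axis")
  }
  sel <- spectrum$ppm >= lo & spectrum$ppm <= hi
  if (sum(sel) < 2L) stop("integration region covers fewer than 2 points")
  x <- rev(spectrum$ppm[sel])          # ascending for the quadrature
  y <- rev(spectrum$intensities[sel])
  pracma::trapz(x, y)
}

#' Calibrate the chemical-shift axis against a reference peak
#'
#' Shifts the ppm axis so the apex of the reference peak (e.g. DSS, or the
#' lactate methyl signal for HSQC planes) sits at the reference shift. The
#' applied shift is recorded in the metadata; a second calibration is
#' idempotent up to the axis spacing.
#'
#' @param spectrum a [spectrum_1d()].
#' @param reference_peak ppm window expected to contain the reference peak.
#' @param reference_shift ppm value the apex is moved to (default 0).
#' @param snr_min minimal apex height over the noise level to accept the peak.
#' @return The calibrated `spectrum_1d`.
#' @export
calibrate_ppm <- function(spectrum, reference_peak, reference_shift = 0,
                          snr_min = 5) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  lo <- min(reference_peak); hi <- max(reference_peak)
  sel <- spectrum$ppm >= lo & spectrum$ppm <= hi
  if (!any(sel)) stop("reference window contains no axis points")
  noise <- stats::mad(spectrum$intensities, center = 0)
  apex_val <- max(spectrum$intensities[sel])
  if (noise > 0 && apex_val < snr_min * noise) {
    stop("no reference peak above ", snr_min, "x noise in [",
         lo, ", ", hi, "] ppm")
  }
  apex_ppm <- spectrum$ppm[sel][which.max(spectrum$intensities[sel])]
  shift <- reference_shift - apex_ppm
  out <- spectrum
  out$ppm <- spectrum$ppm + shift
  out$metadata$calibration_shift_ppm <-
    (spectrum$metadata$calibration_shift_ppm %||% 0) + shift
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spline baseline correction of a 1D spectrum
#'
#' Fits a natural cubic spline through the medians of signal-free anchor
#' regions and subtracts it. Anchor regions that contain signal well above
#' the local noise are shrunk to their flattest half with a warning.
#'
#' @param spectrum a [spectrum_1d()].
#' @param anchor_regions list of at least 4 ppm windows `c(lo, hi)` believed
#'   signal-free.
#' @return Baseline-corrected `spectrum_1d`; the fitted baseline is stored in
#'   `metadata$baseline`.
#' @export
baseline_spline <- function(spectrum, anchor_regions) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  if (length(anchor_regions) < 4L) {
    stop("need at least 4 anchor regions for a spline baseline")
  }
  noise <- stats::mad(spectrum$intensities)
  anchors <- lapply(anchor_regions, function(reg) {
    sel <- spectrum$ppm >= min(reg) & spectrum$ppm <= max(reg)
    if (sum(sel) < 2L) stop("anchor region [", min(reg), ", ", max(reg),
                            "] covers fewer than 2 points")
    y <- spectrum$intensities[sel]
    x <- spectrum$ppm[sel]
    if (noise > 0 && (max(y) - stats::median(y)) > 10 * noise) {
      warning("anchor region [", min(reg), ", ", max(reg),
              "] contains signal; shrinking to its flattest half")
      ord <- order(abs(y - stats::median(y)))
      keep <- ord[seq_len(ceiling(length(y) / 2))]
      x <- x[keep]; y <- y[keep]
    }
    c(x = stats::median(x), y = stats::median(y))
  })
  ax <- vapply(anchors, `[[`, numeric(1), "x")
  ay <- vapply(anchors, `[[`, numeric(1), "y")
  fit <- stats::splinefun(ax, ay, method = "natural")
  baseline <- fit(spectrum$ppm)
  out <- spectrum
  out$intensities <- spectrum$intensities - baseline
  out$metadata$baseline <- baseline
  out
}

#' Extract a 13C-dimension cross-section from a 2D HSQC plane
#'
#' Averages the plane over a 1H window and cuts a Hz window about the given
#' 13C centre, converting 13C ppm to Hz offsets with the 13C base frequency.
#'
#' @param plane numeric matrix of intensities, rows = 1H axis, cols = 13C
#'   axis.
#' @param h1_ppm,c13_ppm strictly monotone ppm axes of the two dimensions.
#' @param h1_window ppm window on the 1H axis to average over.
#' @param c13_centre_ppm centre of the multiplet on the 13C axis.
#' @param half_width_hz half-width of the extracted window in Hz.
#' @param c13_freq_mhz 13C base frequency in MHz (Hz per ppm); 150.9 for a
#'   600 MHz instrument.
#' @param ... metadata passed to [cross_section()].
#' @return A [cross_section()] with Hz offsets about the centre.
#' @export
extract_cross_section <- function(plane, h1_ppm, c13_ppm, h1_window,
                                  c13_centre_ppm, half_width_hz = 150,
                                  c13_freq_mhz = 150.9, ...) {
  stopifnot(is.matrix(plane), nrow(plane) == length(h1_ppm),
            ncol(plane) == length(c13_ppm))
  hsel <- h1_ppm >= min(h1_window) & h1_ppm <= max(h1_window)
  if (!any(hsel)) stop("1H window lies outside the 1H axis")
  offsets <- (c13_ppm - c13_centre_ppm) * c13_freq_mhz
  csel <- abs(offsets) <= half_width_hz
  if (!any(csel)) stop("13C window lies outside the 13C axis")
  if (half_width_hz > max(abs(offsets))) {
    stop("half-width ", half_width_hz, " Hz exceeds the 13C axis span")
  }
  profile <- colMeans(plane[hsel, csel, drop = FALSE])
  off <- offsets[csel]
  ord <- order(off)
  cross_section(off[ord], profile[ord], ...)
}

# ---- delimited-text interchange -------------------------------------------

#' Write a cross-section as delimited text
#'
#' Two-column (offset_hz, intensity) tab-separated table with a
#' comment-prefixed metadata header carrying sample, metabolite, site, noise
#' and any extra key-value pairs (seed, config hash, ...).
#'
#' @param xs a [cross_section()].
#' @param path output path.
#' @param extra named list of additional header fields.
#' @return `path`, invisibly.
#' @export
write_cross_section <- function(xs, path, extra = list()) {
  stopifnot(inherits(xs, "cross_section"))
  hdr <- c(sample = xs$sample_id, metabolite = xs$metabolite,
           observed_site = xs$observed_site, noise = xs$noise)
  hdr <- c(hdr, unlist(extra))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), as.character(hdr)), con)
  writeLines("# columns: offset_hz\tintensity", con)
  utils::write.table(
    data.frame(offset_hz = xs$offsets_hz, intensity = xs$intensities),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr_lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

#' Read a cross-section written by [write_cross_section()]
#'
#' @param path input path.
#' @return A [cross_section()]; extra header fields land in attribute
#'   `"header"`.
#' @export
read_cross_section <- function(path) {
  hdr <- parse_header(path)
  tab <- utils::read.table(path, comment.char = "#", sep = "\t",
                           col.names = c("offset_hz", "intensity"))
  noise <- suppressWarnings(as.numeric(hdr$noise %||% NA))
  xs <- cross_section(tab$offset_hz, tab$intensity,
                      sample_id = hdr$sample %||% NA_character_,
                      metabolite = hdr$metabolite %||% NA_character_,
                      observed_site = as.integer(hdr$observed_site %||% NA),
                      noise = noise)
  attr(xs, "header") <- hdr
  xs
}

#' Write a 1D spectrum as delimited text
#'
#' @param spectrum a [spectrum_1d()].
#' @param path output path.
#' @param extra named list of additional header fields.
#' @return `path`, invisibly.
#' @export
write_spectrum_1d <- function(spectrum, path, extra = list()) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  meta <- spectrum$metadata
  meta$baseline <- NULL
  hdr <- c(unlist(meta), unlist(extra))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(hdr)) writeLines(sprintf("# %s: %s", names(hdr), as.character(hdr)), con)
  writeLines("# columns: ppm\tintensity", con)
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = spectrum$intensities),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 1D spectrum written by [write_spectrum_1d()]
#'
#' @param path input path.
#' @return A [spectrum_1d()] with header fields in its metadata.
#' @export
read_spectrum_1d <- function(path) {
  hdr <- parse_header(path)
  hdr$columns <- NULL
  tab <- utils::read.table(path, comment.char = "#", sep = "\t",
                           col.names = c("ppm", "intensity"))
  spectrum_1d(tab$ppm, tab$intensity, metadata = hdr)
}

#' Read / write a sample manifest CSV
#'
#' @param path CSV with columns kidney, time_h, sample, volume_l.
#' @return A [sample_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_manifest(df$kidney, df$time_h, df$sample, df$volume_l)
}

#' @rdname read_manifest
#' @param manifest a [sample_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
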