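#' Measured multiplet cross-section
#'
#' A 13C-dimension cross-section through one HSQC cross peak, after chemical
#' shift calibration and centring on the observed carbon, as a vector of
#' intensities over Hz offsets.
#'
#' @param offsets_hz strictly increasing Hz offsets about the multiplet centre.
#' @param intensities finite intensity values, same length.
#' @param sample_id,metabolite,observed_site identifying metadata.
#' @param noise optional known noise standard deviation (estimated from the
#'   signal-free margins during fitting when `NA`).
#' @return An object of class `cross_section`.
#' @export
cross_section <- function(offsets_hz, intensities, sample_id = NA_character_,
                          metabolite = NA_character_,
                          observed_site = NA_integer_, noise = NA_real_) {
  offsets_hz <- as.numeric(offsets_hz)
  intensities <- as.numeric(intensities)
  stopifnot(length(offsets_hz) == length(intensities))
  if (any(diff(offsets_hz) <= 0)) stop("cross-section axis must be strictly increasing")
  if (!all(is.finite(intensities))) stop("cross-section intensities must be finite")
  structure(
    list(sample_id = sample_id, metabolite = metabolite,
         observed_site = as.integer(observed_site),
         offsets_hz = offsets_hz, intensities = intensities,
         noise = as.numeric(noise)),
    class = "cross_section"
  )
}

#' Estimate the noise level of a cross-section
#'
#' Standard deviation of the intensities in signal-free margins at both axis
#' ends, after removing a linear trend (so a sloping baseline does not inflate
#' the estimate).
#'
#' @param xs a `cross_section`.
#' @param margin_hz width of the margin taken at each end, in Hz. Must lie
#'   beyond all multiplet lines.
#' @return Noise standard deviation (>= 0).
#' @export
estimate_noise <- function(xs, margin_hz = 25) {
  stopifnot(inherits(xs, "cross_section"), margin_hz > 0)
  lo <- min(xs$offsets_hz); hi <- max(xs$offsets_hz)
  if (2 * margin_hz >= hi - lo) stop("noise margins wider than the axis span")
  sel <- xs$offsets_hz <= lo + margin_hz | xs$offsets_hz >= hi - margin_hz
  y <- xs$intensities[sel]
  x <- xs$offsets_hz[sel]
  if (all(y == 0)) return(0)
  resid <- stats::residuals(stats::lm(y ~ x))
  stats::sd(resid)
}

#' Deconvolve a multiplet cross-section into isotopomer components
#'
#' Fits the measured cross-section as a non-negative linear combination of the
#' simulated pattern components plus an unconstrained polynomial baseline
#' (quantum-mechanical signal deconvolution). Component amplitudes are
#' physical concentrations and are constrained >= 0; the problem is solved as
#' non-negative least squares with the baseline columns split into positive
#' and negative parts, which is exactly equivalent to leaving the baseline
#' unconstrained.
#'
#' Components that are numerically collinear on the measured axis (pairwise
#' correlation > 0.999) make the split of area between them meaningless; the
#' fit aborts with a diagnostic instead of silently dividing the area.
#'
#' @param xs a [cross_section()].
#' @param basis a [build_basis()] result whose axis spans the measured axis.
#' @param baseline_degree polynomial baseline degree, 0 to 3 (default 1).
#' @param low_signal_k flag the fit `low-signal` when the total fitted area is
#'   below `low_signal_k * noise * sqrt(n) * spacing`.
#' @param poor_fit_k flag the fit `poor-fit` when the residual RMS exceeds
#'   `poor_fit_k * noise`.
#' @return An object of class `deconvolution_result`: component `areas` (basis
#'   ordering), `fractions` (areas normalised to sum 1), `baseline`
#'   coefficients, `residual_rms`, `noise`, `flag` (`"ok"`, `"low-signal"` or
#'   `"poor-fit"`) and `fitted` values.
#' @export
fit_multiplet <- function(xs, basis, baseline_degree = 1L,
                          low_signal_k = 5, poor_fit_k = 3) {
  stopifnot(inherits(xs, "cross_section"), inherits(basis, "multiplet_basis"))
  baseline_degree <- as.integer(baseline_degree)
  if (baseline_degree < 0L || baseline_degree > 3L) {
    stop("baseline_degree must be between 0 and 3")
  }
  if (min(xs$offsets_hz) < min(basis$axis$offsets) ||
      max(xs$offsets_hz) > max(basis$axis$offsets)) {
    stop("cross-section axis extends beyond the basis axis span")
  }
  n_comp <- ncol(basis$components)
  n <- length(xs$offsets_hz)
  if (n < 4 * n_comp) {
    stop("cross-section has ", n, " points; need at least ", 4 * n_comp)
  }

  # component profiles interpolated onto the measured axis
  comp <- vapply(seq_len(n_comp), function(k) {
    stats::approx(basis$axis$offsets, basis$components[, k],
                  xout = xs$offsets_hz)$y
  }, numeric(n))
  comp <- matrix(comp, ncol = n_comp)

  if (n_comp > 1) {
    cc <- suppressWarnings(stats::cor(comp))
    cc[!is.finite(cc)] <- 1
    diag(cc) <- 0
    if (any(cc > 0.999)) {
      bad <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      stop("multiplet components ", bad[1], " and ", bad[2],
           " are numerically collinear on this axis (r > 0.999); ",
           "widen the axis or reduce the linewidth before fitting")
    }
  }

  noise <- if (is.finite(xs$noise) && xs$noise >= 0) xs$noise else {
    tryCatch(estimate_noise(xs), error = function(e) NA_real_)
  }

  # baseline columns scaled to O(1); split +/- so NNLS leaves them free
  xsc <- xs$offsets_hz / max(abs(xs$offsets_hz))
  bl <- vapply(0:baseline_degree, function(d) xsc^d, numeric(n))
  bl <- matrix(bl, ncol = baseline_degree + 1L)
  scale_y <- max(abs(xs$intensities), 1e-300)
  A <- cbind(comp, bl, -bl)
  sol <- pracma::lsqnonneg(A, xs$intensities / scale_y)
  coefs <- sol$x * scale_y
  amplitudes <- coefs[seq_len(n_comp)]
  bl_coefs <- coefs[n_comp + seq_len(baseline_degree + 1L)] -
    coefs[n_comp + baseline_degree + 1L + seq_len(baseline_degree + 1L)]

  fitted <- as.vector(A %*% sol$x) * scale_y
  residual_rms <- sqrt(mean((xs$intensities - fitted)^2))

  areas <- amplitudes * basis$component_areas
  total <- sum(areas)
  fractions <- if (total > 0) areas / total else rep(0, n_comp)

  spacing <- mean(diff(xs$offsets_hz))
  flag <- "ok"
  if (is.finite(noise) && noise > 0) {
    if (total < low_signal_k * noise * sqrt(n) * spacing) {
      flag <- "low-signal"
    } else if (residual_rms > poor_fit_k * noise) {
      flag <- "poor-fit"
    }
  }
  if (total == 0) flag <- "low-signal"

  structure(
    list(sample_id = xs$sample_id, metabolite = xs$metabolite,
         observed_site = xs$observed_site,
         areas = areas, fractions = fractions, baseline = bl_coefs,
         residual_rms = residual_rms, noise = noise, flag = flag,
         fitted = fitted, n_neighbours = basis$n_neighbours),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result> ", x$metabolite, " C", x$observed_site,
      " [", x$flag, "]\n  fractions: ",
      paste(sprintf("%.4f", x$fractions), collapse = " "),
      "\n  residual RMS ", signif(x$residual_rms, 3), "\n", sep = "")
  invisible(x)
}

#' Append deconvolution results to a per-sample CSV
#'
#' One row per component: sample, metabolite, site, component label (number of
#' labelled neighbours encoded by the basis ordering), area, fraction, flag.
#'
#' @param results list of `deconvolution_result` objects (or one).
#' @param path CSV path; created with a header when absent, appended otherwise.
#' @return `path`, invisibly.
#' @export
write_deconvolution_csv <- function(results, path) {
  if (inherits(results, "deconvolution_result")) results <- list(results)
  rows <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample = r$sample_id, metabolite = r$metabolite,
               site = r$observed_site,
               component = seq_along(r$areas),
               area = r$areas, fraction = r$fractions, flag = r$flag)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(path)
}
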