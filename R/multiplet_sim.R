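#' Frequency axis for a multiplet cross-section
#'
#' Evenly spaced offsets in Hz relative to the observed carbon's centre
#' frequency. The default (+/-150 Hz at 0.25 Hz per point) comfortably spans
#' any one-bond 13C-13C doublet-of-doublets plus line wings.
#'
#' @param span_hz half-width of the axis in Hz.
#' @param spacing_hz Hz per point (> 0).
#' @return An object of class `frequency_axis` with fields `offsets` and
#'   `spacing`.
#' @export
frequency_axis <- function(span_hz = 150, spacing_hz = 0.25) {
  stopifnot(span_hz > 0, spacing_hz > 0, span_hz > spacing_hz)
  n <- floor(span_hz / spacing_hz)
  offsets <- seq(-n, n) * spacing_hz
  structure(list(offsets = offsets, spacing = spacing_hz),
            class = "frequency_axis")
}

#' NMR lineshape
#'
#' Unit-area Lorentzian or Gaussian line parameterised by its full width at
#' half maximum. Well-shimmed spectra show Hz-scale widths (sub-1-Hz on the
#' shift reference line), so the default is a 1.5 Hz Lorentzian.
#'
#' @param kind `"lorentzian"` or `"gaussian"`.
#' @param fwhm full width at half maximum in Hz (> 0).
#' @return An object of class `lineshape`.
#' @export
lineshape <- function(kind = c("lorentzian", "gaussian"), fwhm = 1.5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(fwhm), length(fwhm) == 1L, fwhm > 0)
  structure(list(kind = kind, fwhm = fwhm), class = "lineshape")
}

# unit-area profile of one line centred at `centre` on `offsets`
lineshape_profile <- function(shape, offsets, centre = 0) {
  x <- offsets - centre
  if (shape$kind == "lorentzian") {
    hwhm <- shape$fwhm / 2
    (hwhm / pi) / (x^2 + hwhm^2)
  } else {
    sigma <- shape$fwhm / (2 * sqrt(2 * log(2)))
    stats::dnorm(x, sd = sigma)
  }
}

trapz_area <- function(x, y) pracma::trapz(x, y)

#' Simulate one multiplet component
#'
#' First-order (weak-coupling) simulation of the 13C-dimension HSQC multiplet
#' of the observed carbon for a given neighbour labelling pattern: each 13C
#' neighbour splits the signal into a doublet of its one-bond coupling, so the
#' stick spectrum is the iterated convolution of one doublet per labelled
#' neighbour, centred at 0 Hz. Sticks are then convolved with the lineshape.
#' The total area is 1 for every pattern (equal-area normalisation), encoding
#' the assumption that HSQC transfer efficiency does not depend on neighbour
#' labelling.
#'
#' @param system a `spin_system`.
#' @param observed observed site index (must be protonated).
#' @param pattern an `isotopomer` with the observed site 13C.
#' @param axis a [frequency_axis()].
#' @param shape a [lineshape()].
#' @return Numeric intensity vector along `axis$offsets`, unit total area.
#' @examples
#' sys <- builtin_spin_systems()$lactate
#' pats <- neighbour_patterns(sys, 2)
#' prof <- simulate_component(sys, 2, pats[[4]], frequency_axis(), lineshape())
#' @export
simulate_component <- function(system, observed, pattern, axis, shape) {
  stopifnot(inherits(axis, "frequency_axis"), inherits(shape, "lineshape"))
  site <- site_by_index(system, observed)
  if (!is_observable(site)) {
    stop("site ", observed, " is not observable in HSQC")
  }
  idx <- vapply(system$sites, `[[`, integer(1), "index")
  if (!pattern$mask[match(observed, idx)]) {
    stop("pattern leaves the observed carbon 12C: no HSQC signal to simulate")
  }
  nb <- coupled_neighbours(system, observed)
  labelled <- nb[pattern$mask[match(nb, idx)]]

  # stick positions: iterated doublet splitting, one per 13C neighbour
  sticks <- 0
  for (j in labelled) {
    half <- coupling_hz(system, observed, j) / 2
    sticks <- as.vector(outer(sticks, c(-half, half), `+`))
  }
  span <- max(axis$offsets)
  if (max(abs(sticks)) + 5 * shape$fwhm > span) {
    stop("axis too narrow: outermost stick at ", round(max(abs(sticks)), 2),
         " Hz needs at least +/-", round(max(abs(sticks)) + 5 * shape$fwhm, 2),
         " Hz of coverage")
  }
  weight <- 1 / length(sticks)
  profile <- rep(0, length(axis$offsets))
  for (s in sticks) {
    profile <- profile + weight * lineshape_profile(shape, axis$offsets, s)
  }
  # renormalise away the small truncation of line wings at the axis edges
  profile / trapz_area(axis$offsets, profile)
}

#' Build the multiplet component basis of an observed carbon
#'
#' One simulated component per neighbour labelling pattern, in
#' [neighbour_patterns()] order (singlet first, fully coupled component last).
#' All components have equal unit area.
#'
#' @inheritParams simulate_component
#' @return An object of class `multiplet_basis` with fields `system_name`,
#'   `observed`, `axis`, `shape`, `patterns`, `components` (matrix, one column
#'   per pattern) and `component_areas`.
#' @export
build_basis <- function(system, observed, axis = frequency_axis(),
                        shape = lineshape()) {
  patterns <- neighbour_patterns(system, observed)
  components <- vapply(
    patterns,
    function(p) simulate_component(system, observed, p, axis, shape),
    numeric(length(axis$offsets))
  )
  components <- matrix(components, ncol = length(patterns))
  areas <- apply(components, 2, function(y) trapz_area(axis$offsets, y))
  structure(
    list(system_name = system$name, observed = observed, axis = axis,
         shape = shape, patterns = patterns, components = components,
         component_areas = areas,
         n_neighbours = length(coupled_neighbours(system, observed))),
    class = "multiplet_basis"
  )
}

#' @export
print.multiplet_basis <- function(x, ...) {
  cat("<multiplet_basis> ", x$system_name, " C", x$observed, ": ",
      ncol(x$components), " components on ", length(x$axis$offsets),
      " points (", x$shape$kind, " fwhm ", x$shape$fwhm, " Hz)\n", sep = "")
  invisible(x)
}

#' Mix multiplet components with non-negative weights
#'
#' A measured multiplet is a mixture of the pattern components; this builds
#' the corresponding profile. Linear in the weights; the mixed area equals
#' the (unit) component area times the weight sum.
#'
#' @param basis a `multiplet_basis`.
#' @param weights non-negative numeric vector, one per component.
#' @return Intensity vector along the basis axis.
#' @export
mix_components <- function(basis, weights) {
  stopifnot(inherits(basis, "multiplet_basis"))
  weights <- as.numeric(weights)
  if (length(weights) != ncol(basis$components)) {
    stop("need ", ncol(basis$components), " weights, got ", length(weights))
  }
  if (any(weights < 0)) stop("component weights must be non-negative")
  as.vector(basis$components %*% weights)
}

#' Count local maxima of a profile
#'
#' Strict interior local maxima above a relative threshold, used to check the
#' simulated peak structure (singlet, doublets, doublet of doublets).
#'
#' @param y intensity vector.
#' @param rel_threshold ignore maxima below this fraction of the global max.
#' @return Integer count.
#' @export
count_peaks <- function(y, rel_threshold = 0.05) {
  n <- length(y)
  if (n < 3) return(0L)
  mid <- y[2:(n - 1)]
  is_max <- mid > y[1:(n - 2)] & mid > y[3:n] & mid > rel_threshold * max(y)
  sum(is_max)
}
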