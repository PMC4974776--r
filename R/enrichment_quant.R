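#' Natural abundance of 13C
#'
#' The background fraction of carbon that is 13C, 1.1% by default. Unlabelled
#' metabolite pools carry this abundance at every carbon independently.
#'
#' @param p fraction in (0, 0.02).
#' @return An object of class `natural_abundance`.
#' @export
natural_abundance <- function(p = 0.011) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (!(p > 0 && p < 0.02)) stop("natural abundance must lie in (0, 0.02)")
  structure(list(p = p), class = "natural_abundance")
}

#' Probability of a naturally occurring adjacent 13C pair
#'
#' Two adjacent carbons are both 13C by chance with probability p^2
#' (0.0121% at the 1.1% natural abundance), which is why coupled multiplet
#' components in an unlabelled pool are second-order rare and the fully
#' coupled component reports the tracer.
#'
#' @param na a [natural_abundance()] object, or a bare numeric fraction.
#' @return p squared.
#' @examples
#' pair_probability(natural_abundance(0.011))  # 0.000121
#' @export
pair_probability <- function(na = natural_abundance()) {
  p <- if (inherits(na, "natural_abundance")) na$p else as.numeric(na)
  p^2
}

#' Fractional enrichment from multiplet component areas
#'
#' Inverts the deconvolved component areas into the mole fraction X of the
#' tracer-labelled ([U-13C]) species, assuming a two-population pool: a
#' fraction X of molecules fully 13C-labelled and the rest carrying 13C only
#' at natural abundance p independently per carbon.
#'
#' In that model the singlet component (all k coupled neighbours 12C) receives
#' the natural pool's (1-X) p (1-p)^k and the fully coupled component receives
#' the tracer's X, so with A_f and A_s the fully coupled and singlet areas,
#'
#'   r = (A_f / A_s) * p * (1-p)^k,   X = r / (1 + r).
#'
#' The natural pool's own contribution to the fully coupled component (order
#' p^(k+1), the "0.0121%" pair term for k = 1) is negligible and ignored by
#' default; `na_correct = TRUE` subtracts the expected natural-abundance
#' contribution from every non-singlet component before inversion.
#'
#' Intermediate components far above their natural-abundance expectation
#' indicate partially labelled species that the two-population model does not
#' cover; they trigger a warning and are excluded from X.
#'
#' @param result a `deconvolution_result` (or a bare numeric vector of areas
#'   in basis order).
#' @param k number of coupled neighbours; `2^k` must equal the component
#'   count. Taken from the result when available.
#' @param na a [natural_abundance()] object.
#' @param na_correct subtract expected natural-abundance contributions from
#'   coupled components before inversion.
#' @return Enrichment fraction X in `[0, 1]`.
#' @export
enrichment_from_components <- function(result, k = NULL,
                                       na = natural_abundance(),
                                       na_correct = FALSE) {
  areas <- if (inherits(result, "deconvolution_result")) result$areas else as.numeric(result)
  if (is.null(k)) {
    if (inherits(result, "deconvolution_result")) k <- result$n_neighbours
    else stop("k (number of coupled neighbours) must be given")
  }
  if (length(areas) != 2^k) {
    stop("expected 2^", k, " = ", 2^k, " component areas, got ", length(areas))
  }
  p <- na$p
  a_s <- areas[1]
  a_f <- areas[length(areas)]

  if (na_correct && a_s > 0 && k >= 1) {
    # expected natural-pool area in the component with m labelled neighbours
    # is a_s * (p/(1-p))^m; subtract it everywhere but the singlet
    m <- vapply(seq_len(2^k) - 1L, function(code) {
      sum(bitwAnd(bitwShiftR(code, seq_len(max(k, 1)) - 1L), 1L))
    }, numeric(1))
    expected <- a_s * (p / (1 - p))^m
    expected[m == 0] <- 0
    areas <- pmax(areas - expected, 0)
    areas[1] <- a_s
    a_f <- areas[length(areas)]
  }

  if (a_f == 0 && a_s == 0) {
    if (any(areas > 0)) {
      stop("singlet and fully coupled components are both zero while other ",
           "components are not: labelling pattern is not the tracer's")
    }
    return(0)
  }
  if (a_f == 0) return(0)
  if (a_s == 0) return(1)

  if (k >= 2) {
    mid <- areas[-c(1, length(areas))]
    # natural expectation for one labelled neighbour is a_s * p/(1-p)
    if (any(mid > 20 * a_s * p / (1 - p) + 1e-12 * sum(areas))) {
      warning("intermediate multiplet components exceed natural-abundance ",
              "expectation: partially labelled species present, excluded from X")
    }
  }

  r <- (a_f / a_s) * p * (1 - p)^k
  r / (1 + r)
}

#' Absolute labelled concentration and per-sample amount
#'
#' The labelled concentration is the product of the enrichment fraction and
#' the total (1D-derived) concentration; the per-sample amount converts that
#' through the effective sample volume (mM x mL gives umol; x1000 gives nmol).
#' The effective volume is required configuration, not a default.
#'
#' @param X enrichment fraction in `[0, 1]`.
#' @param total_conc_mm total metabolite concentration in mM.
#' @param volume_l effective sample volume in litres.
#' @return List with `labelled_conc_mm` and `amount_nmol`.
#' @examples
#' labelled_amount(0.0325, 1.51, 0.6e-3)  # lactate-like 6 h sample
#' @export
labelled_amount <- function(X, total_conc_mm, volume_l) {
  stopifnot(is.numeric(X), is.numeric(total_conc_mm), is.numeric(volume_l))
  if (any(c(X, total_conc_mm, volume_l) < 0)) stop("inputs must be non-negative")
  if (any(X > 1)) stop("enrichment fraction cannot exceed 1")
  labelled <- X * total_conc_mm
  # mM * L = mmol; * 1e6 = nmol
  list(labelled_conc_mm = labelled, amount_nmol = labelled * volume_l * 1e6)
}

#' Total concentration from a 1D 1H spectrum
#'
#' Ratio quantification against an internal standard of known concentration:
#' integrals are normalised per contributing proton, so
#' `conc = ref_conc * (I / nH) / (I_ref / nH_ref)`.
#'
#' @param spectrum a [spectrum_1d()].
#' @param peak_region ppm window `c(lo, hi)` containing the metabolite peak.
#' @param n_protons protons contributing to the metabolite peak.
#' @param reference list with `region` (ppm window), `concentration` (mM) and
#'   `n_protons` of the internal standard.
#' @return Total concentration in mM.
#' @export
quantify_1d <- function(spectrum, peak_region, n_protons, reference) {
  stopifnot(inherits(spectrum, "spectrum_1d"))
  integral <- integrate_region(spectrum, peak_region)
  ref_integral <- integrate_region(spectrum, reference$region)
  if (ref_integral <= 0) stop("reference integral is not positive")
  reference$concentration * (integral / n_protons) /
    (ref_integral / reference$n_protons)
}

#' One enrichment record
#'
#' The quantified state of one metabolite in one sample: enrichment fraction,
#' total concentration, and the derived labelled concentration and amount.
#'
#' @param sample_id,metabolite,observed_site identification.
#' @param X enrichment fraction in `[0, 1]`.
#' @param total_conc_mm total concentration (mM).
#' @param volume_l effective sample volume (L).
#' @param flag fit flag carried over from deconvolution.
#' @return One-row data frame (class `enrichment_record` rows are plain data).
#' @export
enrichment_record <- function(sample_id, metabolite, observed_site, X,
                              total_conc_mm, volume_l, flag = "ok") {
  stopifnot(X >= 0, X <= 1, total_conc_mm >= 0, volume_l >= 0)
  amt <- labelled_amount(X, total_conc_mm, volume_l)
  data.frame(sample = sample_id, metabolite = metabolite,
             site = observed_site, enrichment = X,
             total_mm = total_conc_mm,
             labelled_mm = amt$labelled_conc_mm,
             volume_l = volume_l,
             amount_nmol = amt$amount_nmol,
             flag = flag, stringsAsFactors = FALSE)
}
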