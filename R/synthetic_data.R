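#' Default per-metabolite truth trajectories
#'
#' Enrichment and total-concentration trajectories emulating the perfusion
#' time course the analysis is designed for: lactate rising from 3.25% to
#' 7.74% enrichment (1.51 to 2.04 mM total) and alanine from 1.25% to 2.83%
#' (0.24 to 0.41 mM) between 6 h and 24 h, with between-kidney SDs matching
#' the same observed spreads. Means and SDs are interpolated linearly in time.
#'
#' @return Data frame with one row per metabolite: observed site and the
#'   trajectory anchors (`x6`, `x24`, `sdx6`, `sdx24` as fractions; `c6`,
#'   `c24`, `sdc6`, `sdc24` in mM).
#' @export
default_truth <- function() {
  data.frame(
    metabolite = c("lactate", "alanine"),
    observed_site = c(2L, 2L),
    x6 = c(0.0325, 0.0125), x24 = c(0.0774, 0.0283),
    sdx6 = c(0.0102, 0.0044), sdx24 = c(0.0157, 0.0119),
    c6 = c(1.51, 0.24), c24 = c(2.04, 0.41),
    sdc6 = c(0.20, 0.018), sdc24 = c(0.57, 0.13),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-cohort configuration
#'
#' Defines the simulated perfusion experiment: cohort size, time points,
#' per-metabolite truth trajectories, between-kidney variation, cross-section
#' signal-to-noise, 1D noise, lineshape and seed. Defaults emulate a 6-kidney
#' perfusion with sampling at 6/12/18/24 h.
#'
#' @param n_kidneys number of kidneys (default 6).
#' @param times_h sampling time points in hours.
#' @param truth per-metabolite trajectory table, see [default_truth()].
#' @param snr peak signal-to-noise ratio of cross-sections (default 200,
#'   cryoprobe-grade spectra).
#' @param noise_1d relative 1D noise (fraction of the reference peak height).
#' @param shape a [lineshape()].
#' @param axis a [frequency_axis()].
#' @param na a [natural_abundance()].
#' @param volume_l effective per-sample volume in litres (default 0.6 mL).
#' @param seed integer random seed, recorded in every output file.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_kidneys = 6L, times_h = c(6, 12, 18, 24),
                          truth = default_truth(), snr = 200,
                          noise_1d = 2e-3, shape = lineshape(),
                          axis = frequency_axis(), na = natural_abundance(),
                          volume_l = 0.6e-3, seed = 1L) {
  stopifnot(n_kidneys >= 2L, all(times_h > 0), snr > 0)
  stopifnot(all(truth$x6 >= 0), all(truth$x24 <= 1),
            all(truth$c6 >= 0), all(truth$c24 >= 0))
  structure(
    list(n_kidneys = as.integer(n_kidneys), times_h = sort(times_h),
         truth = truth, snr = snr, noise_1d = noise_1d, shape = shape,
         axis = axis, na = na, volume_l = volume_l, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# linear interpolation of a trajectory anchored at 6 and 24 h
traj <- function(v6, v24, t) v6 + (v24 - v6) * (t - 6) / (24 - 6)

#' Expected multiplet component weights of a two-population pool
#'
#' For enrichment fraction X, the visible molecules split over the neighbour
#' patterns as: tracer X into the fully coupled component, natural pool
#' (1-X) * p * p^m (1-p)^(k-m) into the component with m labelled neighbours.
#' Weights are per total molecule (they sum to the visible fraction).
#'
#' @param X enrichment fraction.
#' @param k number of coupled neighbours.
#' @param na a [natural_abundance()].
#' @return Numeric vector of `2^k` weights in [neighbour_patterns()] order.
#' @export
expected_component_weights <- function(X, k, na = natural_abundance()) {
  stopifnot(X >= 0, X <= 1, k >= 0)
  p <- na$p
  m <- vapply(seq_len(2^k) - 1L, function(code) {
    sum(bitwAnd(bitwShiftR(code, seq_len(max(k, 1)) - 1L), 1L))
  }, numeric(1))
  if (k == 0) m <- 0
  w <- (1 - X) * p * p^m * (1 - p)^(k - m)
  w[length(w)] <- w[length(w)] + X
  w
}

#' Draw molecules and tabulate their multiplet components
#'
#' Brute-force molecule simulator used as the independent check of the
#' enrichment inversion: draws `n_molecules` molecules that are fully
#' labelled with probability `X` and otherwise carry 13C independently at
#' natural abundance on every carbon, then counts the visible ones (observed
#' carbon 13C) by their neighbour labelling pattern.
#'
#' @param X enrichment fraction in `[0, 1]`.
#' @param system a `spin_system`.
#' @param observed observed site index.
#' @param na a [natural_abundance()].
#' @param n_molecules number of molecules to draw.
#' @param seed optional seed (set only when non-NULL).
#' @return List with `counts` (length `2^k`, [neighbour_patterns()] order),
#'   `invisible` (observed carbon 12C) and `n`.
#' @export
sample_molecule_components <- function(X, system, observed,
                                       na = natural_abundance(),
                                       n_molecules = 1e6, seed = NULL) {
  stopifnot(X >= 0, X <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- na$p
  nb <- coupled_neighbours(system, observed)
  k <- length(nb)
  n <- as.integer(n_molecules)

  labelled <- stats::runif(n) < X
  n_lab <- sum(labelled)
  n_nat <- n - n_lab

  counts <- numeric(2^k)
  counts[2^k] <- n_lab                       # tracer molecules: fully coupled
  obs13 <- stats::runif(n_nat) < p           # natural pool visibility
  n_vis <- sum(obs13)
  if (n_vis > 0 && k > 0) {
    code <- integer(n_vis)
    for (b in seq_len(k)) {
      code <- code + bitwShiftL(as.integer(stats::runif(n_vis) < p), b - 1L)
    }
    tab <- tabulate(code + 1L, nbins = 2^k)
    counts <- counts + tab
  } else if (n_vis > 0) {
    counts[1] <- counts[1] + n_vis
  }
  list(counts = counts, invisible = n - n_lab - n_vis, n = n)
}

draw_kidney_values <- function(mean_t, sd_t, upper = Inf, shared = TRUE,
                               max_tries = 100) {
  # shared = TRUE: one standard-normal deviate per kidney (random effect),
  # scaled by the time-dependent SD; shared = FALSE: independent deviates per
  # time point. Out-of-range values are redrawn (not clipped) so means stay
  # unbiased near zero.
  for (i in seq_len(max_tries)) {
    z <- if (shared) stats::rnorm(1) else stats::rnorm(length(mean_t))
    v <- mean_t + z * sd_t
    if (all(v >= 0) && all(v <= upper)) return(v)
  }
  stop("could not draw non-negative trajectory values in ", max_tries, " tries")
}

#' Generate a complete synthetic perfusion cohort
#'
#' Writes, for every (kidney, time point), one 1D spectrum and one multiplet
#' cross-section per metabolite, plus a sample manifest, the ground truth and
#' the configuration — everything the analysis pipeline reads. Kidney-level
#' enrichment and concentration are drawn around the truth trajectories with
#' the configured between-kidney SD (shared per-kidney random effect,
#' redrawn at the zero bound); cross-sections are expected component mixtures
#' with additive Gaussian noise at the configured SNR; 1D spectra contain a
#' DSS reference singlet and one methyl peak per metabolite scaled to the
#' realised concentration.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created).
#' @param systems spin systems (default [builtin_spin_systems()]).
#' @return List with `manifest`, `truth` (data frame of realised values) and
#'   `dir`, invisibly the same as written to disk.
#' @export
generate_cohort <- function(config, dir, systems = builtin_spin_systems()) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  times <- config$times_h
  tr <- config$truth

  bases <- lapply(seq_len(nrow(tr)), function(i) {
    build_basis(systems[[tr$metabolite[i]]], tr$observed_site[i],
                config$axis, config$shape)
  })
  names(bases) <- tr$metabolite

  manifest_rows <- list()
  truth_rows <- list()
  for (kd in seq_len(config$n_kidneys)) {
    # kidney-level realisations for every metabolite
    real <- lapply(seq_len(nrow(tr)), function(i) {
      x_mean <- traj(tr$x6[i], tr$x24[i], times)
      x_sd <- traj(tr$sdx6[i], tr$sdx24[i], times)
      c_mean <- traj(tr$c6[i], tr$c24[i], times)
      c_sd <- traj(tr$sdc6[i], tr$sdc24[i], times)
      list(X = draw_kidney_values(x_mean, x_sd, upper = 1),
           conc = draw_kidney_values(c_mean, c_sd))
    })
    for (ti in seq_along(times)) {
      sid <- sprintf("K%02d_T%02d", kd, times[ti])
      manifest_rows[[length(manifest_rows) + 1L]] <-
        data.frame(kidney = sprintf("K%02d", kd), time_h = times[ti],
                   sample = sid, volume_l = config$volume_l)

      conc_by_met <- numeric(nrow(tr))
      for (i in seq_len(nrow(tr))) {
        met <- tr$metabolite[i]
        X <- real[[i]]$X[ti]
        conc <- real[[i]]$conc[ti]
        conc_by_met[i] <- conc
        basis <- bases[[met]]
        k <- basis$n_neighbours
        w <- expected_component_weights(X, k, config$na) * conc
        clean <- mix_components(basis, w)
        sigma <- max(clean) / config$snr
        noisy <- clean + stats::rnorm(length(clean), sd = sigma)
        xs <- cross_section(basis$axis$offsets, noisy, sample_id = sid,
                            metabolite = met,
                            observed_site = tr$observed_site[i],
                            noise = sigma)
        write_cross_section(
          xs, file.path(dir, sprintf("%s_%s_xs.tsv", sid, met)),
          extra = list(seed = config$seed, snr = config$snr))
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(kidney = sprintf("K%02d", kd), time_h = times[ti],
                     sample = sid, metabolite = met, X_true = X,
                     conc_true = conc,
                     weights = paste(signif(w, 10), collapse = ";"))
      }
      sp <- synth_1d_spectrum(tr$metabolite, conc_by_met,
                              noise = config$noise_1d)
      sp$metadata$sample <- sid
      sp$metadata$seed <- config$seed
      write_spectrum_1d(sp, file.path(dir, sprintf("%s_1d.tsv", sid)))
    }
  }
  manifest <- do.call(rbind, manifest_rows)
  manifest <- sample_manifest(manifest$kidney, manifest$time_h,
                              manifest$sample, manifest$volume_l)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, n_kidneys = config$n_kidneys,
         times_h = config$times_h, snr = config$snr,
         noise_1d = config$noise_1d, volume_l = config$volume_l,
         natural_abundance = config$na$p,
         lineshape = unclass(config$shape)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truth = truth, dir = dir))
}

#' Default 1D quantification windows
#'
#' Methyl-region peak windows used to integrate the synthetic 1D spectra,
#' plus the DSS reference definition.
#'
#' @return List with `peaks` (data frame: metabolite, lo, hi, n_protons) and
#'   `reference` (list for [quantify_1d()]).
#' @export
default_1d_windows <- function() {
  list(
    peaks = data.frame(
      metabolite = c("lactate", "alanine"),
      lo = c(1.23, 1.39), hi = c(1.39, 1.55),
      n_protons = c(3, 3), stringsAsFactors = FALSE),
    reference = list(region = c(-0.08, 0.08), concentration = 0.5,
                     n_protons = 9)
  )
}

# synthetic methyl-region 1D 1H spectrum: DSS reference at 0 ppm plus one
# J(HH)-split methyl signal per metabolite, intensity proportional to
# concentration x protons
synth_1d_spectrum <- function(metabolites, conc_mm, noise = 2e-3,
                              ref_conc = 0.5, h1_freq_mhz = 600) {
  ppm <- seq(-0.25, 2.0, by = 2.5e-4)
  fwhm_ppm <- 1.2 / h1_freq_mhz
  lor <- function(centre, area) {
    hw <- fwhm_ppm / 2
    area * (hw / pi) / ((ppm - centre)^2 + hw^2)
  }
  y <- lor(0, ref_conc * 9)
  shifts <- c(lactate = 1.31, alanine = 1.47)
  jhh_ppm <- 7 / h1_freq_mhz   # methyl doublet, 3J(HH) ~ 7 Hz
  for (i in seq_along(metabolites)) {
    centre <- shifts[[metabolites[i]]]
    area <- conc_mm[i] * 3
    y <- y + lor(centre - jhh_ppm / 2, area / 2) +
      lor(centre + jhh_ppm / 2, area / 2)
  }
  y <- y + stats::rnorm(length(ppm), sd = noise * max(lor(0, ref_conc * 9)))
  spectrum_1d(ppm, y, metadata = list(h1_freq_mhz = h1_freq_mhz))
}

#' Draw enrichment records directly from a truth trajectory
#'
#' Record-level cohort generator (no spectra): per-kidney enrichment and
#' concentration values drawn exactly as in [generate_cohort()] but returned
#' as [enrichment_record()] rows. Used for statistical calibration studies
#' (type-I error, power) where simulating and refitting spectra adds nothing
#' to the quantity under test.
#'
#' @param config a [cohort_config()].
#' @param kidney_effect `"shared"` draws one random effect per kidney applied
#'   to the whole trajectory (the cohort model of [generate_cohort()]);
#'   `"independent"` draws each (kidney, time) value independently, the
#'   sampling model under which the unpaired pooled t test is exactly
#'   calibrated (used for the type-I-error study).
#' @return List with `records` and `manifest`.
#' @export
generate_records <- function(config, kidney_effect = c("shared", "independent")) {
  kidney_effect <- match.arg(kidney_effect)
  shared <- kidney_effect == "shared"
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  times <- config$times_h
  tr <- config$truth
  man <- list(); recs <- list()
  for (kd in seq_len(config$n_kidneys)) {
    for (i in seq_len(nrow(tr))) {
      X <- draw_kidney_values(traj(tr$x6[i], tr$x24[i], times),
                              traj(tr$sdx6[i], tr$sdx24[i], times),
                              upper = 1, shared = shared)
      conc <- draw_kidney_values(traj(tr$c6[i], tr$c24[i], times),
                                 traj(tr$sdc6[i], tr$sdc24[i], times),
                                 shared = shared)
      for (ti in seq_along(times)) {
        sid <- sprintf("K%02d_T%02d", kd, times[ti])
        recs[[length(recs) + 1L]] <- enrichment_record(
          sid, tr$metabolite[i], tr$observed_site[i], X[ti], conc[ti],
          config$volume_l)
      }
    }
    for (ti in seq_along(times)) {
      man[[length(man) + 1L]] <- data.frame(
        kidney = sprintf("K%02d", kd), time_h = times[ti],
        sample = sprintf("K%02d_T%02d", kd, times[ti]),
        volume_l = config$volume_l)
    }
  }
  man <- do.call(rbind, man)
  list(records = do.call(rbind, recs),
       manifest = sample_manifest(man$kidney, man$time_h, man$sample,
                                  man$volume_l))
}
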