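# shared fixtures: built-in systems are read once, bases are cached per
# (system, site, fwhm) so tests do not rebuild identical component sets

.sys <- builtin_spin_systems()

.basis_cache <- new.env(parent = emptyenv())

cached_basis <- function(name = "lactate", observed = 2, fwhm = 1.5,
                         span = 150, spacing = 0.25) {
  key <- paste(name, observed, fwhm, span, spacing, sep = "|")
  if (is.null(.basis_cache[[key]])) {
    .basis_cache[[key]] <- build_basis(.sys[[name]], observed,
                                       frequency_axis(span, spacing),
                                       lineshape("lorentzian", fwhm))
  }
  .basis_cache[[key]]
}

# brute-force oracle: enumerate all 2^n masks of a system and keep the
# distinct restrictions to the coupled neighbours of `observed` with the
# observed site 13C
brute_force_neighbour_masks <- function(system, observed) {
  n <- length(system$sites)
  idx <- vapply(system$sites, `[[`, integer(1), "index")
  nb <- coupled_neighbours(system, observed)
  seen <- character()
  for (code in 0:(2^n - 1)) {
    mask <- bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L) == 1L
    if (!mask[match(observed, idx)]) next
    key <- paste(as.integer(mask[match(nb, idx)]), collapse = "")
    seen <- union(seen, key)
  }
  sort(seen)
}

# noiseless synthetic cross-section from known mixture weights
mixture_xs <- function(basis, weights, noise_sd = 0, sample_id = "syn",
                       metabolite = basis$system_name) {
  y <- mix_components(basis, weights)
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  cross_section(basis$axis$offsets, y, sample_id, metabolite,
                basis$observed, noise = noise_sd)
}
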