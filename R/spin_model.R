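#' Carbon site of a metabolite spin system
#'
#' A single carbon position with its chemical shifts and proton count. A site
#' is observable in a 1H,13C HSQC experiment only when it carries at least one
#' attached proton.
#'
#' @param index 1-based carbon position (integer, unique within a system).
#' @param c13_shift chemical shift on the 13C axis (ppm).
#' @param h1_shift chemical shift of the attached proton(s) (ppm), or `NA`
#'   for non-protonated carbons (carboxyls, quaternaries).
#' @param n_protons number of attached protons, 0 to 3.
#' @return An object of class `carbon_site`.
#' @export
carbon_site <- function(index, c13_shift, h1_shift = NA_real_, n_protons = 1L) {
  index <- as.integer(index)
  n_protons <- as.integer(n_protons)
  stopifnot(length(index) == 1L, index >= 1L)
  if (!n_protons %in% 0:3) {
    stop("n_protons must be 0, 1, 2 or 3 (site ", index, ")")
  }
  if (is.null(h1_shift)) h1_shift <- NA_real_
  if (n_protons > 0L && is.na(h1_shift)) {
    stop("protonated site ", index, " needs a 1H shift")
  }
  structure(
    list(index = index, c13_shift = as.numeric(c13_shift),
         h1_shift = as.numeric(h1_shift), n_protons = n_protons),
    class = "carbon_site"
  )
}

#' Is a carbon site observable in HSQC?
#'
#' Only 13C nuclei with an attached 1H give an HSQC cross peak.
#'
#' @param site a `carbon_site`.
#' @return `TRUE` when the site carries at least one proton.
#' @export
is_observable <- function(site) {
  stopifnot(inherits(site, "carbon_site"))
  site$n_protons >= 1L
}

#' Metabolite spin system
#'
#' Carbon topology, chemical shifts and one-bond 13C-13C couplings of one
#' metabolite. Couplings are stored symmetrically and must reference existing
#' sites; only one-bond couplings are modelled.
#'
#' @param name metabolite identifier.
#' @param sites list of [carbon_site()] objects with unique indices.
#' @param couplings data frame with columns `i`, `j`, `hz` (one row per
#'   coupled pair, order of `i`/`j` irrelevant, `hz` > 0).
#' @return An object of class `spin_system`.
#' @export
spin_system <- function(name, sites, couplings) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.list(sites), length(sites) >= 1L)
  lapply(sites, function(s) stopifnot(inherits(s, "carbon_site")))
  idx <- vapply(sites, `[[`, integer(1), "index")
  if (anyDuplicated(idx)) stop("duplicate site indices in spin system ", name)
  sites <- sites[order(idx)]
  idx <- sort(idx)

  couplings <- as.data.frame(couplings)
  if (nrow(couplings)) {
    stopifnot(all(c("i", "j", "hz") %in% names(couplings)))
    couplings$i <- as.integer(couplings$i)
    couplings$j <- as.integer(couplings$j)
    couplings$hz <- as.numeric(couplings$hz)
    if (any(!couplings$i %in% idx) || any(!couplings$j %in% idx)) {
      stop("coupling references a site absent from system ", name)
    }
    if (any(couplings$i == couplings$j)) stop("self-coupling in system ", name)
    if (any(couplings$hz <= 0)) stop("coupling constants must be > 0 Hz")
    # canonical order i < j, one row per pair
    swap <- couplings$i > couplings$j
    tmp <- couplings$i[swap]
    couplings$i[swap] <- couplings$j[swap]
    couplings$j[swap] <- tmp
    if (anyDuplicated(couplings[, c("i", "j")])) {
      stop("duplicate coupling entries in system ", name)
    }
    couplings <- couplings[order(couplings$i, couplings$j), , drop = FALSE]
    rownames(couplings) <- NULL
  } else {
    couplings <- data.frame(i = integer(), j = integer(), hz = numeric())
  }

  if (!any(vapply(sites, is_observable, logical(1)))) {
    stop("spin system ", name, " has no HSQC-observable site")
  }
  structure(list(name = name, sites = sites, couplings = couplings),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  obs <- vapply(x$sites, is_observable, logical(1))
  cat("<spin_system> ", x$name, ": ", length(x$sites), " carbons (",
      sum(obs), " HSQC-observable), ", nrow(x$couplings),
      " one-bond 13C-13C couplings\n", sep = "")
  invisible(x)
}

#' Look up a one-bond coupling constant
#'
#' Symmetric lookup: `coupling_hz(sys, i, j)` equals `coupling_hz(sys, j, i)`.
#'
#' @param system a `spin_system`.
#' @param i,j site indices.
#' @return The coupling in Hz, or 0 when the pair is uncoupled.
#' @export
coupling_hz <- function(system, i, j) {
  stopifnot(inherits(system, "spin_system"))
  a <- min(i, j); b <- max(i, j)
  hit <- system$couplings$i == a & system$couplings$j == b
  if (any(hit)) system$couplings$hz[hit][1] else 0
}

#' Coupled neighbours of a site
#'
#' @param system a `spin_system`.
#' @param observed site index.
#' @return Sorted integer vector of site indices coupled to `observed`.
#' @export
coupled_neighbours <- function(system, observed) {
  stopifnot(inherits(system, "spin_system"))
  cp <- system$couplings
  sort(unique(c(cp$j[cp$i == observed], cp$i[cp$j == observed])))
}

site_by_index <- function(system, index) {
  idx <- vapply(system$sites, `[[`, integer(1), "index")
  pos <- match(index, idx)
  if (is.na(pos)) stop("no site with index ", index, " in ", system$name)
  system$sites[[pos]]
}

#' Isotopomer labelling mask
#'
#' A specific 12C/13C placement over the carbon sites of a spin system, in
#' site-index order. The all-`TRUE` mask is the uniformly labelled [U-13C]
#' isotopologue.
#'
#' @param mask logical vector, `TRUE` where the carbon is 13C.
#' @param system optional `spin_system` to validate the mask length against.
#' @return An object of class `isotopomer`.
#' @export
isotopomer <- function(mask, system = NULL) {
  mask <- as.logical(mask)
  if (anyNA(mask)) stop("isotopomer mask must be TRUE/FALSE")
  if (!is.null(system)) {
    stopifnot(inherits(system, "spin_system"))
    if (length(mask) != length(system$sites)) {
      stop("mask length ", length(mask), " does not match ",
           length(system$sites), " sites of ", system$name)
    }
  }
  structure(list(mask = mask), class = "isotopomer")
}

#' Neighbour labelling patterns of an observed carbon
#'
#' Enumerates the isotopomers that are distinguishable in the multiplet of the
#' observed carbon: the observed site is 13C in all of them (otherwise it is
#' HSQC-invisible) and each coupled neighbour is either 12C or 13C. Uncoupled
#' sites are left 12C since they do not affect the multiplet.
#'
#' Ordering is deterministic binary counting over neighbour indices ascending,
#' least-significant neighbour first: the first pattern has all neighbours
#' 12C (the singlet component) and the last has all neighbours 13C (the fully
#' coupled component). This ordering is shared with [build_basis()].
#'
#' @param system a `spin_system`.
#' @param observed index of the observed (protonated) carbon.
#' @return List of `2^k` `isotopomer` objects, `k` = number of coupled
#'   neighbours.
#' @export
neighbour_patterns <- function(system, observed) {
  stopifnot(inherits(system, "spin_system"))
  site <- site_by_index(system, observed)
  if (!is_observable(site)) {
    stop("site ", observed, " of ", system$name,
         " has no attached proton and cannot be observed in HSQC")
  }
  nb <- coupled_neighbours(system, observed)
  k <- length(nb)
  idx <- vapply(system$sites, `[[`, integer(1), "index")
  lapply(seq_len(2^k) - 1L, function(code) {
    mask <- rep(FALSE, length(idx))
    mask[match(observed, idx)] <- TRUE
    if (k > 0) {
      bits <- bitwAnd(bitwShiftR(code, seq_len(k) - 1L), 1L) == 1L
      mask[match(nb, idx)] <- bits
    }
    isotopomer(mask, system)
  })
}

#' Number of 13C-labelled coupled neighbours in a pattern
#'
#' @param system a `spin_system`.
#' @param observed observed site index.
#' @param pattern an `isotopomer`.
#' @return Integer count.
#' @export
n_labelled_neighbours <- function(system, observed, pattern) {
  nb <- coupled_neighbours(system, observed)
  idx <- vapply(system$sites, `[[`, integer(1), "index")
  sum(pattern$mask[match(nb, idx)])
}

#' Read spin systems from a parameter file
#'
#' Parses the structured-text (YAML) spin-system format: a list of entries
#' with keys `name`, `sites` (`index`, `c13_shift`, `h1_shift`, `n_protons`)
#' and `couplings` (`i`, `j`, `hz`).
#'
#' @param path path to a YAML parameter file.
#' @return Named list of `spin_system` objects.
#' @seealso [write_spin_systems()], [builtin_spin_systems()]
#' @export
read_spin_systems <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(entry) {
    sites <- lapply(entry$sites, function(s) {
      carbon_site(s$index, s$c13_shift,
                  if (is.null(s$h1_shift)) NA_real_ else s$h1_shift,
                  s$n_protons)
    })
    cp <- if (length(entry$couplings)) {
      do.call(rbind, lapply(entry$couplings, function(x) {
        data.frame(i = x$i, j = x$j, hz = x$hz)
      }))
    } else {
      data.frame(i = integer(), j = integer(), hz = numeric())
    }
    spin_system(entry$name, sites, cp)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write spin systems to a parameter file
#'
#' Inverse of [read_spin_systems()]: round-tripping a system through the file
#' format yields an identical object.
#'
#' @param systems named list of `spin_system` objects (or a single one).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_spin_systems <- function(systems, path) {
  if (inherits(systems, "spin_system")) systems <- list(systems)
  payload <- lapply(unname(systems), function(sys) {
    list(
      name = sys$name,
      sites = lapply(sys$sites, function(s) {
        list(index = s$index, c13_shift = s$c13_shift,
             h1_shift = if (is.na(s$h1_shift)) NULL else s$h1_shift,
             n_protons = s$n_protons)
      }),
      couplings = if (nrow(sys$couplings)) {
        lapply(seq_len(nrow(sys$couplings)), function(r) {
          list(i = sys$couplings$i[r], j = sys$couplings$j[r],
               hz = sys$couplings$hz[r])
        })
      } else {
        list()
      }
    )
  })
  yaml::write_yaml(payload, path, precision = 12)
  invisible(path)
}

#' Built-in spin systems for the enriched metabolites
#'
#' The four metabolites for which tracer enrichment is quantified: lactate,
#' alanine and acetate (uniformly labelled glycolytic products) and glutamate
#' (C4/C5-labelled via the TCA cycle). Shifts and couplings come from the
#' packaged parameter file `inst/extdata/spin_systems.yaml`, which users may
#' copy and edit; see [read_spin_systems()].
#'
#' @param path optional alternative parameter file.
#' @return Named list of `spin_system` objects.
#' @examples
#' sys <- builtin_spin_systems()
#' names(sys)
#' neighbour_patterns(sys$lactate, observed = 2)  # 4 patterns
#' @export
builtin_spin_systems <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "spin_systems.yaml", package = "hsqcdecon")
  }
  read_spin_systems(path)
}
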