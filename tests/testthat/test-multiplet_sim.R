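test_that("lactate C2 components show singlet, two doublets and a dd", {
  b <- cached_basis("lactate", 2)
  peaks <- apply(b$components, 2, count_peaks)
  expect_equal(peaks, c(1L, 2L, 2L, 4L))

  j12 <- coupling_hz(.sys$lactate, 1, 2)
  j23 <- coupling_hz(.sys$lactate, 2, 3)
  off <- b$axis$offsets

  peak_pos <- function(y) {
    n <- length(y)
    mid <- y[2:(n - 1)]
    off[1 + which(mid > y[1:(n - 2)] & mid > y[3:n] & mid > 0.05 * max(y))]
  }
  # doublet splittings identify which neighbour is labelled
  expect_equal(diff(peak_pos(b$components[, 2])), j12, tolerance = 0.02)
  expect_equal(diff(peak_pos(b$components[, 3])), j23, tolerance = 0.02)
  # doublet-of-doublets outer separation is the coupling sum
  dd <- peak_pos(b$components[, 4])
  expect_length(dd, 4)
  expect_equal(max(dd) - min(dd), j12 + j23, tolerance = 0.02)
})

test_that("all components have equal unit area", {
  for (name in c("lactate", "acetate")) {
    b <- cached_basis(name, 2)
    areas <- apply(b$components, 2, function(y) pracma::trapz(b$axis$offsets, y))
    expect_equal(areas, rep(1, ncol(b$components)), tolerance = 1e-6)
  }
})

test_that("sticks split the area binomially in the narrow-line limit", {
  b <- cached_basis("lactate", 2, fwhm = 0.3)
  off <- b$axis$offsets
  dd <- b$components[, 4]
  # quarter the axis between the four dd peaks: each holds ~1/4 of the area
  j12 <- coupling_hz(.sys$lactate, 1, 2)
  j23 <- coupling_hz(.sys$lactate, 2, 3)
  cuts <- c(-Inf, -j12 / 2, 0, j12 / 2, Inf)
  for (q in 1:4) {
    sel <- off > cuts[q] & off <= cuts[q + 1]
    expect_equal(pracma::trapz(off[sel], dd[sel]), 0.25, tolerance = 0.02)
  }
})

test_that("weak-coupling stick positions match exact two-spin diagonalization", {
  # exact AB oracle: H (Hz) = nu1 Iz1 + nu2 Iz2 + J I1.I2 in the product
  # basis; allowed transitions have nonzero <f|Ix1+Ix2|i> between levels
  # differing by one total spin quantum
  ab_transitions <- function(nu1, nu2, J) {
    iz <- c(0.5, -0.5)
    basis <- expand.grid(s1 = 1:2, s2 = 1:2)
    H <- matrix(0, 4, 4)
    for (a in 1:4) for (b in 1:4) {
      m1a <- iz[basis$s1[a]]; m2a <- iz[basis$s2[a]]
      m1b <- iz[basis$s1[b]]; m2b <- iz[basis$s2[b]]
      if (a == b) {
        H[a, b] <- nu1 * m1a + nu2 * m2a + J * m1a * m2a
      } else if (basis$s1[a] != basis$s1[b] && basis$s2[a] != basis$s2[b] &&
                 m1a + m2a == m1b + m2b) {
        H[a, b] <- J / 2   # flip-flop term, within the M = 0 block only
      }
    }
    eig <- eigen(H, symmetric = TRUE)
    # Ix1 + Ix2 in the product basis
    Ix <- matrix(0, 4, 4)
    for (a in 1:4) for (b in 1:4) {
      d1 <- basis$s1[a] != basis$s1[b]; d2 <- basis$s2[a] != basis$s2[b]
      if (xor(d1, d2)) Ix[a, b] <- 0.5
    }
    IxE <- t(eig$vectors) %*% Ix %*% eig$vectors
    # total Iz is conserved; a single-quantum transition lowers it by 1 and
    # its (signed, rotating-frame) frequency is E_upper - E_lower
    m_tot <- iz[basis$s1] + iz[basis$s2]
    M <- colSums(eig$vectors^2 * m_tot)
    out <- c()
    for (a in 1:4) for (b in 1:4) {
      if (abs(IxE[a, b]) > 1e-8 && abs(M[a] - M[b] - 1) < 1e-9) {
        out <- c(out, eig$values[a] - eig$values[b])
      }
    }
    sort(unique(round(out, 6)))
  }

  # lactate C2-C3 pair at a 150.9 MHz 13C base frequency, frame centred on C2
  lac <- .sys$lactate
  dppm <- lac$sites[[3]]$c13_shift - lac$sites[[2]]$c13_shift
  nu2 <- dppm * 150.9
  J <- coupling_hz(lac, 2, 3)
  trans <- ab_transitions(0, nu2, J)
  near_c2 <- trans[abs(trans) < 2 * J]
  expect_length(near_c2, 2)
  # weak-coupling sticks sit at +/- J/2
  expect_lt(max(abs(sort(near_c2) - c(-J / 2, J / 2))), 0.1)
})

test_that("mixtures are linear, area-conserving and symmetric", {
  b <- cached_basis("lactate", 2)
  off <- b$axis$offsets

  expect_identical(mix_components(b, c(1, 0, 0, 0)), b$components[, 1])
  expect_error(mix_components(b, c(1, -0.1, 0, 0)), "non-negative")
  expect_error(mix_components(b, c(1, 0)), "weights")

  set.seed(7)
  for (i in 1:20) {
    w1 <- runif(4); w2 <- runif(4)
    m1 <- mix_components(b, w1)
    m2 <- mix_components(b, w2)
    m12 <- mix_components(b, w1 + w2)
    expect_lt(max(abs(m12 - (m1 + m2))), 1e-12)
    expect_equal(pracma::trapz(off, m12), sum(w1 + w2), tolerance = 1e-9)
  }

  eq <- mix_components(b, rep(1, 4))
  expect_lt(max(abs(eq - rev(eq))), 1e-9)   # every doublet is symmetric
})

test_that("component peak counts follow 2^(labelled neighbours) generally", {
  set.seed(11)
  for (rep in 1:10) {
    j1 <- runif(1, 30, 60); j2 <- runif(1, 30, 60)
    if (abs(j1 - j2) < 8) next   # merged dd centre peaks are a separate case
    sys <- spin_system("random", list(
      carbon_site(1, 180, NA, 0),
      carbon_site(2, 70, 4.1, 1),
      carbon_site(3, 20, 1.3, 3)
    ), data.frame(i = c(1, 2), j = c(2, 3), hz = c(j1, j2)))
    b <- build_basis(sys, 2, frequency_axis(150, 0.25),
                     lineshape("lorentzian", 1))   # couplings >= 5x fwhm
    for (ci in seq_len(4)) {
      k_lab <- n_labelled_neighbours(sys, 2, b$patterns[[ci]])
      expect_equal(count_peaks(b$components[, ci]), 2^k_lab)
    }
  }
})

test_that("a too-narrow axis is rejected with a clear error", {
  expect_error(
    build_basis(.sys$lactate, 2, frequency_axis(30, 0.25), lineshape()),
    "axis too narrow")
})
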