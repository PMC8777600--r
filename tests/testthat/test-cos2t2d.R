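# 2T2D correlation maps, series assembly, cross-peak detection.

two_point <- function(values) {
  new_spectrum(wl_grid(300, 301, 1), values)
}

test_that("synchronous and asynchronous maps match hand-computed examples", {
  s <- two_point(c(1, 2))
  phi <- synchronous_map(s, s)
  expect_equal(phi$values, matrix(c(1, 2, 2, 4), 2))

  psi <- asynchronous_map(two_point(c(1, 0)), two_point(c(0, 1)))
  expect_equal(psi$values, matrix(c(0, -0.5, 0.5, 0), 2))
})

test_that("map identities hold: symmetry, antisymmetry, diagonal, swap, bilinearity", {
  set.seed(21)
  g <- default_grid()
  s <- new_spectrum(g, rnorm(166))
  r <- new_spectrum(g, rnorm(166))
  phi <- synchronous_map(s, r)
  psi <- asynchronous_map(s, r)

  expect_lt(max(abs(phi$values - t(phi$values))), 1e-12 * max(abs(phi$values)))
  expect_lt(max(abs(psi$values + t(psi$values))), 1e-12 * max(abs(psi$values)))
  expect_equal(diag(psi$values), rep(0, 166))
  expect_equal(diag(phi$values), 0.5 * (s$absorbance^2 + r$absorbance^2))

  # swap rule
  expect_equal(asynchronous_map(r, s)$values, -psi$values)
  expect_equal(synchronous_map(r, s)$values, phi$values)

  # bilinearity
  s3 <- new_spectrum(g, 3 * s$absorbance)
  r2 <- new_spectrum(g, 2 * r$absorbance)
  expect_equal(asynchronous_map(s3, r2)$values, 6 * psi$values)

  # proportional spectra cancel exactly
  prop <- asynchronous_map(s, new_spectrum(g, 4.2 * s$absorbance))
  expect_equal(max(abs(prop$values)), 0)

  expect_error(asynchronous_map(s, new_spectrum(wl_grid(245, 409, 1),
                                                rnorm(165))), "grids")
})

test_that("the averaged adulterant reference is a unit-area, scale-free mean", {
  g <- default_grid()
  a <- gauss_spectrum(280, 8, 2, g)
  b <- gauss_spectrum(380, 8, 5, g)

  # mean of identical spectra = the unit-area-scaled input
  ua <- a$absorbance / (sum(a$absorbance) * 1)
  same <- averaged_adulterant_reference(list(a, a, a))
  expect_equal(same$absorbance, ua)

  # two disjoint equal-area bands -> both present at half their unit height
  m <- averaged_adulterant_reference(list(a, b))
  ub <- b$absorbance / (sum(b$absorbance) * 1)
  expect_equal(m$absorbance, (ua + ub) / 2)

  # arbitrary positive scaling of the inputs changes nothing
  a5 <- new_spectrum(g, 5 * a$absorbance)
  b03 <- new_spectrum(g, 0.3 * b$absorbance)
  expect_equal(averaged_adulterant_reference(list(a5, b03))$absorbance,
               m$absorbance)

  neg <- new_spectrum(g, -a$absorbance)
  expect_error(averaged_adulterant_reference(list(a, neg)), "area")
})

test_that("build_series wires sample and reference traces per series", {
  co <- simulate_cohort(c(authentic = 1, rutin_adulterated = 2,
                          quercetin_adulterated = 2), seed = 4,
                        noise_sigma = 0, jitter = 0)
  for (sr in c("A", "B", "C")) {
    st <- build_series(co, sr)
    expect_length(st$maps, 5L)
    expect_equal(st$series, sr)
    expect_equal(st$kind, "asynchronous")
  }
  # series C: one shared reference label
  stC <- build_series(co, "C")
  expect_equal(unique(vapply(stC$maps, function(m) m$reference_label,
                             character(1))), "avg_adulterants")
  # authentic product: methanolic == reference extract -> series B map zero
  stB <- build_series(co, "B")
  expect_equal(max(abs(stB$maps[[1]]$values)), 0)

  # identical methanol/water traces -> series A map all zero
  g <- default_grid()
  s <- gauss_spectrum(300, 10, 1, g)
  fake <- list(products = list(list(product_id = "Z",
                                    pair = spectrum_pair(s, s, "Z"))))
  stA <- build_series(fake, "A")
  expect_equal(max(abs(stA$maps[[1]]$values)), 0)

  expect_error(build_series(list(products = fake$products,
                                 reference_extract = NULL), "B"),
               "reference")
})

test_that("cross-peak detection finds the unique band pair and rejects misuse", {
  g <- default_grid()
  s <- gauss_spectrum(300, 10, 1, g)
  r <- gauss_spectrum(360, 10, 1, g)
  psi <- asynchronous_map(s, r)
  pk <- detect_cross_peaks(psi)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$nu1, pk$nu2), c(300, 360))
  expect_equal(pk$magnitude, abs(psi$values[wavelengths(g) == 300,
                                            wavelengths(g) == 360]))

  zero <- asynchronous_map(s, s)
  expect_equal(nrow(detect_cross_peaks(zero)), 0L)

  expect_error(detect_cross_peaks(synchronous_map(s, r)), "asynchronous")
})

test_that("plateaus report once, at the lexicographically lowest point", {
  g <- wl_grid(245, 264, 1)
  v <- matrix(0, 20, 20)
  v[3, 12] <- 1; v[3, 13] <- 1; v[4, 12] <- 1  # exact 3-point plateau
  v <- v - t(v)
  m <- ginkgocos:::new_corr_map("asynchronous", g, v)
  pk <- detect_cross_peaks(m, min_offdiag = 2, merge_radius = 1)
  expect_equal(nrow(pk), 1L)
  wl <- wavelengths(g)
  expect_equal(c(pk$nu1, pk$nu2), c(wl[3], wl[12]))
})

test_that("detection agrees with the exhaustive brute-force scan on random maps", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- wl_grid(245, 294, 1)  # 50-point grid
    s <- new_spectrum(g, abs(rnorm(50)) + 0.1)
    r <- new_spectrum(g, abs(rnorm(50)) + 0.1)
    psi <- asynchronous_map(s, r)
    got <- detect_cross_peaks(psi, rel_threshold = 0.15, min_offdiag = 3,
                              merge_radius = 3)
    want <- peak_scan_oracle(psi$values, wavelengths(g), rel_threshold = 0.15,
                             min_offdiag = 3, merge_radius = 3)
    expect_equal(got$nu1, want$nu1, info = paste("seed", seed))
    expect_equal(got$nu2, want$nu2, info = paste("seed", seed))
    expect_equal(got$magnitude, want$magnitude, info = paste("seed", seed))
  }
})

test_that("noise-free series-A peak counts separate authentic from adulterated", {
  co <- simulate_cohort(c(authentic = 1, rutin_adulterated = 1,
                          quercetin_adulterated = 1,
                          quercetin_kaempferol_adulterated = 1),
                        seed = 2, noise_sigma = 0, jitter = 0)
  st <- build_series(co, "A")
  counts <- vapply(st$maps, function(m) nrow(detect_cross_peaks(m)),
                   integer(1))
  expect_equal(counts[1], 0L)          # authentic: proportional traces
  expect_true(all(counts[-1] >= 1L))   # every adulterated archetype
})
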