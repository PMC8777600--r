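# Synthetic UV-Vis generator: Gaussian-band component models, dual-solvent
# extract simulation, and labelled supplement cohorts with matching
# flavonol tables. This stands in for instrument data: flavonols carry two
# absorption bands (band I ~320-385 nm, band II ~240-280 nm), mixtures are
# additive in absorbance, and the aglycones (quercetin, kaempferol)
# extract poorly into water but well into methanol, which is what the
# dual-solvent correlation series exploits.

ARCHETYPES <- c("authentic", "rutin_adulterated", "quercetin_adulterated",
                "quercetin_kaempferol_adulterated", "no_ginkgo")

#' Gaussian band model for one spectral component
#'
#' @param name Component name.
#' @param bands data.frame with columns `center` (nm, within 200--500),
#'   `sigma` (nm, > 0) and `height` (AU, > 0); one row per band.
#' @param f_methanol,f_water Extraction fractions in 80% methanol / water,
#'   both in \[0, 1\]. The simulated extract concentration of a component
#'   is its amount times the solvent's fraction.
#' @return An object of class `band_model`.
#' @export
band_model <- function(name, bands, f_methanol, f_water) {
  stopifnot(is.data.frame(bands),
            all(c("center", "sigma", "height") %in% names(bands)))
  if (!all(bands$height > 0)) stop("band heights must be > 0")
  if (!all(bands$sigma > 0)) stop("band widths must be > 0")
  if (!all(bands$center >= 200 & bands$center <= 500)) {
    stop("band centers must lie within 200-500 nm")
  }
  if (f_methanol < 0 || f_methanol > 1 || f_water < 0 || f_water > 1) {
    stop("extraction fractions must lie in [0, 1]")
  }
  structure(list(name = name, bands = bands,
                 f_methanol = f_methanol, f_water = f_water),
            class = "band_model")
}

#' Default component library
#'
#' Two-Gaussian models at the flavonol band maxima -- rutin 257/355 nm,
#' quercetin 255/368 nm, kaempferol 265/365 nm -- with sigma 12 nm for
#' band II and 18 nm for band I, and band-I:band-II height ratio 1.0
#' (rutin, quercetin) or 0.9 (kaempferol). The `ginkgo_matrix` component
#' is a deliberately non-physical stand-in for the authentic leaf-extract
#' fingerprint: a glycoside-like band pair (265/350 nm) plus a broad
#' short-wavelength shoulder (255 nm, sigma 25, height 0.6). Extraction
#' fractions encode the poor water solubility of the aglycones
#' (quercetin/kaempferol 0.95 in methanol vs 0.10 in water), the partial
#' water solubility of rutin (0.9/0.5), and the solvent-indifference of
#' the glycoside-rich matrix (0.9/0.9).
#'
#' @return Named list of `band_model`s: `rutin`, `quercetin`,
#'   `kaempferol`, `ginkgo_matrix`.
#' @export
flavonol_library <- function() {
  b <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center = m[, 1], sigma = m[, 2], height = m[, 3])
  }
  list(
    rutin = band_model("rutin",
      b(257, 12, 1.0,  355, 18, 1.0), f_methanol = 0.9, f_water = 0.5),
    quercetin = band_model("quercetin",
      b(255, 12, 1.0,  368, 18, 1.0), f_methanol = 0.95, f_water = 0.10),
    kaempferol = band_model("kaempferol",
      b(265, 12, 1.0,  365, 18, 0.9), f_methanol = 0.95, f_water = 0.10),
    ginkgo_matrix = band_model("ginkgo_matrix",
      b(265, 12, 1.0,  350, 18, 1.0,  255, 25, 0.6),
      f_methanol = 0.9, f_water = 0.9)
  )
}

#' Noise-free component spectrum (sum of Gaussian bands)
#'
#' A(v) = sum_b height_b * exp(-(v - center_b)^2 / (2 sigma_b^2)).
#'
#' @param model A `band_model`.
#' @param grid A `wl_grid` (default: the 245--410 nm analysis grid).
#' @return A `spectrum`, labelled with the component name.
#' @export
component_spectrum <- function(model, grid = default_grid()) {
  stopifnot(inherits(model, "band_model"))
  wl <- wavelengths(grid)
  a <- rep(0, length(wl))
  for (k in seq_len(nrow(model$bands))) {
    bd <- model$bands[k, ]
    a <- a + bd$height * exp(-(wl - bd$center)^2 / (2 * bd$sigma^2))
  }
  new_spectrum(grid, a, label = model$name)
}

#' Simulate one extract spectrum of a supplement
#'
#' Additive mixture with solvent-dependent extraction and iid Gaussian
#' noise: A(v) = sum_c amount_c * f_solvent(c) * component_c(v) + eps(v),
#' eps ~ N(0, noise_sigma^2). Seeded and bit-reproducible.
#'
#' @param amounts Named numeric vector of nonnegative component amounts
#'   (arbitrary concentration units); names must exist in `library`.
#' @param solvent `"methanol80"` or `"water"`.
#' @param noise_sigma Additive noise standard deviation (AU); 0 disables.
#' @param seed Integer seed (required when `noise_sigma > 0`).
#' @param library Component library (default [flavonol_library()]).
#' @param grid Wavelength grid.
#' @param label Label for the returned spectrum.
#' @return A `spectrum`.
#' @export
simulate_extract <- function(amounts, solvent = c("methanol80", "water"),
                             noise_sigma = 0, seed = NULL,
                             library = flavonol_library(),
                             grid = default_grid(), label = "") {
  solvent <- match.arg(solvent)
  stopifnot(is.numeric(amounts), !is.null(names(amounts)),
            all(amounts >= 0), any(amounts > 0))
  unknown <- setdiff(names(amounts), names(library))
  if (length(unknown)) {
    stop("unknown component(s) in composition: ",
         paste(unknown, collapse = ", "))
  }
  wl <- wavelengths(grid)
  a <- rep(0, length(wl))
  for (nm in names(amounts)) {
    mod <- library[[nm]]
    f <- if (solvent == "methanol80") mod$f_methanol else mod$f_water
    a <- a + amounts[[nm]] * f * component_spectrum(mod, grid)$absorbance
  }
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sigma > 0")
    a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sigma))
  }
  new_spectrum(grid, a, label = label)
}

# Evaluate expr under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed for product `index` under root `seed`; stable
# under cohort-size changes and kept below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 65011) * 33013 + 7919 * index) %% 2147483647L
}

#' Archetype composition presets
#'
#' Mean component amounts per supplement archetype. Adulterated archetypes
#' carry the adulterant at about six times the matrix signal (split 3 + 3
#' for the dual quercetin/kaempferol archetype); `no_ginkgo` is an
#' equal-parts flavonol blend with no ginkgo matrix at all; `authentic`
#' is the pure matrix.
#'
#' @return Named list (one per archetype) of named amount vectors.
#' @export
archetype_presets <- function() {
  list(
    authentic = c(ginkgo_matrix = 1),
    rutin_adulterated = c(ginkgo_matrix = 1, rutin = 6),
    quercetin_adulterated = c(ginkgo_matrix = 1, quercetin = 6),
    quercetin_kaempferol_adulterated =
      c(ginkgo_matrix = 1, quercetin = 3, kaempferol = 3),
    no_ginkgo = c(rutin = 1, quercetin = 1, kaempferol = 1)
  )
}

#' Simulate a labelled supplement cohort
#'
#' Draws per-product component amounts from archetype presets with
#' lognormal relative jitter, simulates the methanol/water extract pair of
#' every product, and emits the authentic reference-extract spectrum, the
#' three adulterant standard spectra, and a flavonol table computed from
#' the generating amounts (percent of rutin / quercetin / kaempferol in
#' the total component amount). Per-product child seeds are derived
#' deterministically from the root seed and the product index, so growing
#' the cohort does not reshuffle earlier products.
#'
#' @param n_per_archetype Named integer vector, e.g.
#'   `c(authentic = 2, rutin_adulterated = 4)`; names must be archetypes
#'   from [archetype_presets()].
#' @param seed Root integer seed.
#' @param noise_sigma Additive spectral noise sd (AU); default 0.002.
#' @param jitter Lognormal sdlog of the per-product amount jitter
#'   (default 0.15, i.e. about 15% relative spread); 0 disables.
#' @param presets Archetype amount presets (default [archetype_presets()]).
#' @param library Component library.
#' @param grid Wavelength grid.
#' @return An object of class `cohort_dataset` with fields `products`
#'   (list of `product_id`, `archetype`, `amounts`, `pair`),
#'   `reference_extract`, `adulterant_spectra`, `flavonol_table`, `seed`.
#' @export
simulate_cohort <- function(n_per_archetype, seed, noise_sigma = 0.002,
                            jitter = 0.15, presets = archetype_presets(),
                            library = flavonol_library(),
                            grid = default_grid()) {
  stopifnot(!is.null(names(n_per_archetype)), all(n_per_archetype >= 0))
  bad <- setdiff(names(n_per_archetype), names(presets))
  if (length(bad)) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  total <- sum(n_per_archetype)
  if (total == 0) stop("empty cohort: all archetype counts are zero")
  arch_seq <- rep(names(n_per_archetype), times = n_per_archetype)
  products <- vector("list", total)
  tab <- data.frame(product_id = character(total), pct_rutin = 0,
                    pct_quercetin = 0, pct_kaempferol = 0,
                    archetype = character(total), stringsAsFactors = FALSE)
  for (i in seq_len(total)) {
    arch <- arch_seq[i]
    mean_amounts <- presets[[arch]]
    cs <- child_seed(seed, i)
    amounts <- if (jitter > 0) {
      with_seed(cs, mean_amounts *
                  exp(stats::rnorm(length(mean_amounts), 0, jitter)))
    } else mean_amounts
    id <- sprintf("P%02d", i)
    meoh <- simulate_extract(amounts, "methanol80", noise_sigma,
                             seed = cs + 1L, library = library,
                             grid = grid, label = paste0(id, "_meoh"))
    water <- simulate_extract(amounts, "water", noise_sigma,
                              seed = cs + 2L, library = library,
                              grid = grid, label = paste0(id, "_water"))
    products[[i]] <- list(product_id = id, archetype = arch,
                          amounts = amounts,
                          pair = spectrum_pair(meoh, water, id))
    amt <- function(nm) if (nm %in% names(amounts)) amounts[[nm]] else 0
    tot_amt <- sum(amounts)
    tab$product_id[i] <- id
    tab$pct_rutin[i] <- 100 * amt("rutin") / tot_amt
    tab$pct_quercetin[i] <- 100 * amt("quercetin") / tot_amt
    tab$pct_kaempferol[i] <- 100 * amt("kaempferol") / tot_amt
    tab$archetype[i] <- arch
  }
  adults <- c("rutin", "quercetin", "kaempferol")
  adulterant_spectra <- lapply(adults, function(nm)
    simulate_extract(stats::setNames(1, nm), "methanol80", 0,
                     library = library, grid = grid, label = nm))
  names(adulterant_spectra) <- adults
  reference_extract <- simulate_extract(c(ginkgo_matrix = 1), "methanol80",
                                        0, library = library, grid = grid,
                                        label = "GB_reference")
  structure(list(products = products,
                 reference_extract = reference_extract,
                 adulterant_spectra = adulterant_spectra,
                 flavonol_table = tab, seed = seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d products (seed %s): %s\n",
              length(x$products), format(x$seed),
              paste(sprintf("%s=%d",
                            names(table(x$flavonol_table$archetype)),
                            as.integer(table(x$flavonol_table$archetype))),
                    collapse = ", ")))
  invisible(x)
}

#' Packaged chromatographic flavonol table (20 supplements)
#'
#' Percentage contribution of the rutin, quercetin and kaempferol peak
#' areas to the total chromatogram area for supplements S1--S20, as used
#' for the hierarchical clustering of products.
#'
#' @return data.frame with columns `product_id`, `pct_rutin`,
#'   `pct_quercetin`, `pct_kaempferol` (20 rows).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_flavonols.csv",
                      package = "ginkgocos")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged flavonol table fixture is missing")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("product_id", "pct_rutin", "pct_quercetin", "pct_kaempferol")
  if (!all(need %in% names(tab)) || nrow(tab) != 20L) {
    stop("packaged flavonol table fixture is corrupt")
  }
  tab[need]
}
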