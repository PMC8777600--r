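# Two-trace two-dimensional correlation maps, series assembly, and
# cross-peak detection.
#
# A 2T2D correlation map is built from exactly one sample spectrum s and
# one reference spectrum r on a shared grid:
#   synchronous   Phi(v1, v2) = (1/2) [ s(v1) s(v2) + r(v1) r(v2) ]
#   asynchronous  Psi(v1, v2) = (1/2) [ s(v1) r(v2) - r(v1) s(v2) ]
# Psi is antisymmetric with a zero diagonal and vanishes identically when
# s and r are proportional; its cross peaks sit at coordinate pairs of
# bands whose relative weight differs between the two spectra.

new_corr_map <- function(kind, grid, values,
                         sample_label = "", reference_label = "") {
  kind <- match.arg(kind, c("synchronous", "asynchronous"))
  stopifnot(inherits(grid, "wl_grid"), is.matrix(values))
  p <- n_points(grid)
  if (!all(dim(values) == c(p, p))) stop("map values must be ", p, "x", p)
  structure(list(kind = kind, grid = grid, values = values,
                 sample_label = sample_label,
                 reference_label = reference_label),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> %s %dx%d [%s vs %s], max|value| = %.4g\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$sample_label, x$reference_label, max(abs(x$values))))
  invisible(x)
}

check_pair_grids <- function(s, r) {
  stopifnot(inherits(s, "spectrum"), inherits(r, "spectrum"))
  if (!grids_equal(s$grid, r$grid)) {
    stop("sample and reference spectra are on different grids; resample first")
  }
}

#' Synchronous 2T2D correlation map
#'
#' Computes Phi(v1, v2) = (1/2)\[s(v1) s(v2) + r(v1) r(v2)\] on the shared
#' grid of the two spectra. Rows index the sample axis v1, columns the
#' reference axis v2; the map is symmetric.
#'
#' @param s Sample `spectrum`.
#' @param r Reference `spectrum` (same grid; no implicit resampling).
#' @return A `corr_map` of kind `"synchronous"`.
#' @export
synchronous_map <- function(s, r) {
  check_pair_grids(s, r)
  v <- 0.5 * (tcrossprod(s$absorbance) + tcrossprod(r$absorbance))
  new_corr_map("synchronous", s$grid, v, s$label, r$label)
}

#' Asynchronous 2T2D correlation map
#'
#' Computes Psi(v1, v2) = (1/2)\[s(v1) r(v2) - r(v1) s(v2)\]: antisymmetric,
#' zero on the diagonal, and identically zero when the two spectra are
#' proportional. This is the map the screening series are built from.
#'
#' @inheritParams synchronous_map
#' @return A `corr_map` of kind `"asynchronous"`.
#' @export
asynchronous_map <- function(s, r) {
  check_pair_grids(s, r)
  sr <- tcrossprod(s$absorbance, r$absorbance)   # s(v1) r(v2)
  v <- 0.5 * (sr - t(sr))
  new_corr_map("asynchronous", s$grid, v, s$label, r$label)
}

#' Averaged adulterant reference spectrum
#'
#' Each input spectrum is scaled to unit area (sum of absorbances times the
#' grid step), then the pointwise arithmetic mean is taken. Area scaling
#' removes the arbitrary concentration of each standard so no single
#' compound dominates the average.
#'
#' @param adulterants List of at least two `spectrum` objects on one grid.
#' @return A `spectrum` (unit-area mean), labelled `"avg_adulterants"`.
#' @export
averaged_adulterant_reference <- function(adulterants) {
  stopifnot(is.list(adulterants), length(adulterants) >= 2L)
  g <- adulterants[[1]]$grid
  scaled <- lapply(adulterants, function(s) {
    stopifnot(inherits(s, "spectrum"))
    if (!grids_equal(s$grid, g)) stop("adulterant spectra must share one grid")
    area <- sum(s$absorbance) * s$grid$step
    if (area <= 0) stop("cannot area-normalize spectrum '", s$label,
                        "': nonpositive total area")
    s$absorbance / area
  })
  new_spectrum(g, Reduce(`+`, scaled) / length(scaled),
               label = "avg_adulterants")
}

#' Stack of correlation maps for one screening series
#'
#' @param maps List of `corr_map`s sharing grid and kind.
#' @param sample_ids Unique product ids, one per map.
#' @param series Series tag: `"A"`, `"B"` or `"C"`.
#' @return An object of class `map_stack`.
#' @export
map_stack <- function(maps, sample_ids, series = c("A", "B", "C")) {
  series <- match.arg(series)
  stopifnot(is.list(maps), length(maps) >= 1L,
            length(sample_ids) == length(maps))
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  g <- maps[[1]]$grid
  kind <- maps[[1]]$kind
  for (m in maps) {
    stopifnot(inherits(m, "corr_map"))
    if (!grids_equal(m$grid, g) || m$kind != kind) {
      stop("all maps in a stack must share grid and kind")
    }
  }
  structure(list(maps = maps, sample_ids = as.character(sample_ids),
                 series = series, grid = g, kind = kind),
            class = "map_stack")
}

#' Build one of the three screening series of asynchronous maps
#'
#' For every product the 80% methanol extract is the sample trace; the
#' reference trace depends on the series:
#' \describe{
#'   \item{A}{the same product's water extract (dual-solvent contrast:
#'     poorly water-soluble aglycones produce cross peaks);}
#'   \item{B}{the authentic ginkgo reference-extract spectrum;}
#'   \item{C}{the averaged (unit-area) spectrum of the rutin, quercetin
#'     and kaempferol standards.}
#' }
#'
#' @param cohort A `cohort_dataset` (see [simulate_cohort()]) or any list
#'   with fields `products` (list with `pair` of class `spectrum_pair`),
#'   `reference_extract`, and `adulterant_spectra`.
#' @param series `"A"`, `"B"` or `"C"`.
#' @return A `map_stack` of asynchronous maps, one per product.
#' @export
build_series <- function(cohort, series = c("A", "B", "C")) {
  series <- match.arg(series)
  if (length(cohort$products) == 0L) stop("cohort has no products")
  ref <- switch(series,
    A = NULL,
    B = {
      if (is.null(cohort$reference_extract)) {
        stop("series B requires the authentic reference-extract spectrum")
      }
      cohort$reference_extract
    },
    C = {
      if (is.null(cohort$adulterant_spectra) ||
          length(cohort$adulterant_spectra) < 2L) {
        stop("series C requires the adulterant standard spectra")
      }
      averaged_adulterant_reference(cohort$adulterant_spectra)
    })
  maps <- lapply(cohort$products, function(p) {
    r <- if (series == "A") p$pair$water else ref
    asynchronous_map(p$pair$methanol, r)
  })
  map_stack(maps, vapply(cohort$products, function(p) p$product_id,
                         character(1)), series)
}

#' Detect cross peaks in an asynchronous correlation map
#'
#' Scans the upper triangle (v2 > v1; the lower triangle holds the mirror
#' images) for 8-neighbour local maxima of |Psi| that clear a relative
#' magnitude threshold and lie at least `min_offdiag` nm off the diagonal.
#' Peaks closer than `merge_radius` (Chebyshev distance, nm) are merged
#' keeping the strongest. Exact plateaus count once, at their lowest
#' (v1, v2) lexicographic point.
#'
#' @param map An asynchronous `corr_map`.
#' @param rel_threshold Fraction of the global max |Psi| a peak must reach
#'   (0 < rel_threshold < 1; default 0.10).
#' @param min_offdiag Minimum |v1 - v2| in nm (default 5).
#' @param merge_radius Chebyshev merge radius in nm (default 4).
#' @return data.frame with columns `nu1`, `nu2`, `magnitude`, `sign`
#'   (`"+"`/`"-"`), sorted by descending magnitude; zero rows if the map
#'   is all zero.
#' @export
detect_cross_peaks <- function(map, rel_threshold = 0.10,
                               min_offdiag = 5, merge_radius = 4) {
  stopifnot(inherits(map, "corr_map"))
  if (map$kind != "asynchronous") {
    stop("cross-peak detection requires an asynchronous map")
  }
  stopifnot(rel_threshold > 0, rel_threshold < 1)
  A <- abs(map$values)
  top <- max(A)
  empty <- data.frame(nu1 = numeric(0), nu2 = numeric(0),
                      magnitude = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (top == 0) return(empty)
  p <- nrow(A)
  wl <- wavelengths(map$grid)
  # pad with -Inf so borders compare cleanly
  P <- matrix(-Inf, p + 2L, p + 2L)
  P[2:(p + 1L), 2:(p + 1L)] <- A
  ge_all <- matrix(TRUE, p, p)       # >= every 8-neighbour
  gt_prior <- matrix(TRUE, p, p)     # > every lexicographically earlier nbr
  core <- function(di, dj) P[(2:(p + 1L)) + di, (2:(p + 1L)) + dj]
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- core(di, dj)
    ge_all <- ge_all & (A >= nb)
    # neighbour at (i+di, j+dj) earlier than (i, j) lexicographically
    if (di < 0L || (di == 0L && dj < 0L)) {
      gt_prior <- gt_prior & (A > nb | nb == -Inf)
    }
  }
  cand <- which(ge_all & gt_prior, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  i <- cand[, 1]; j <- cand[, 2]
  keep <- (wl[j] > wl[i]) &
    (abs(wl[i] - wl[j]) >= min_offdiag) &
    (A[cand] >= rel_threshold * top)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)
  mag <- A[cbind(i, j)]
  o <- order(-mag, wl[i], wl[j])
  i <- i[o]; j <- j[o]; mag <- mag[o]
  sel <- logical(length(i))
  for (k in seq_along(i)) {
    if (!any(sel)) { sel[k] <- TRUE; next }
    d <- pmax(abs(wl[i[k]] - wl[i[sel]]), abs(wl[j[k]] - wl[j[sel]]))
    if (all(d >= merge_radius)) sel[k] <- TRUE
  }
  i <- i[sel]; j <- j[sel]; mag <- mag[sel]
  data.frame(nu1 = wl[i], nu2 = wl[j], magnitude = mag,
             sign = ifelse(map$values[cbind(i, j)] >= 0, "+", "-"),
             stringsAsFactors = FALSE)
}
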