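# Wavelength grids, spectrum containers, resampling, and text I/O for
# spectra and correlation maps.

#' Uniform wavelength grid
#'
#' A uniform, inclusive-endpoint wavelength axis. The analysis grid used
#' throughout the package is 245--410 nm at 1 nm (166 points), matching
#' typical UV-Vis acquisition for flavonoid fingerprinting.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm); must exceed `start`.
#' @param step Grid spacing (nm); `(stop - start)` must be an integer
#'   multiple of `step` (to within 1e-9).
#' @return An object of class `wl_grid`.
#' @examples
#' g <- wl_grid(245, 410, 1)
#' n_points(g)  # 166
#' @export
wl_grid <- function(start, stop, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1L, length(stop) == 1L, length(step) == 1L)
  if (!(start < stop)) stop("grid start must be < stop")
  if (!(step > 0)) stop("grid step must be > 0")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9) {
    stop("(stop - start) must be divisible by step")
  }
  structure(list(start = start, stop = stop, step = step),
            class = "wl_grid")
}

#' Default analysis grid (245--410 nm, 1 nm)
#' @return A `wl_grid` with 166 points including both endpoints.
#' @export
default_grid <- function() wl_grid(245, 410, 1)

#' Number of points of a wavelength grid
#' @param grid A `wl_grid`.
#' @export
n_points <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  as.integer(round((grid$stop - grid$start) / grid$step)) + 1L
}

#' Wavelength vector of a grid
#' @param grid A `wl_grid`.
#' @return Numeric vector of wavelengths (nm), both endpoints included.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  grid$start + grid$step * (seq_len(n_points(grid)) - 1)
}

grids_equal <- function(a, b, tol = 1e-9) {
  abs(a$start - b$start) <= tol && abs(a$stop - b$stop) <= tol &&
    abs(a$step - b$step) <= tol
}

#' Spectrum container
#'
#' Absorbance (AU, dimensionless) on a uniform wavelength grid. Negative
#' values are permitted (baseline noise); all values must be finite.
#'
#' @param grid A `wl_grid`.
#' @param absorbance Numeric vector, one value per grid point.
#' @param label Free-text label (product code, solvent).
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(grid, absorbance, label = "") {
  stopifnot(inherits(grid, "wl_grid"))
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != n_points(grid)) {
    stop("absorbance length (", length(absorbance),
         ") does not match grid point count (", n_points(grid), ")")
  }
  if (!all(is.finite(absorbance))) stop("absorbance values must be finite")
  structure(list(grid = grid, absorbance = absorbance,
                 label = as.character(label)[1]),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %g-%g nm @ %g nm, A in [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              n_points(x$grid), x$grid$start, x$grid$stop, x$grid$step,
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Paired dual-solvent extract spectra of one product
#'
#' @param methanol,water `spectrum` objects on one shared grid (80%
#'   methanol and aqueous extract of the same product).
#' @param product_id Product code.
#' @return An object of class `spectrum_pair`.
#' @export
spectrum_pair <- function(methanol, water, product_id) {
  stopifnot(inherits(methanol, "spectrum"), inherits(water, "spectrum"))
  if (!grids_equal(methanol$grid, water$grid)) {
    stop("methanol and water spectra must share one grid")
  }
  structure(list(methanol = methanol, water = water,
                 product_id = as.character(product_id)[1]),
            class = "spectrum_pair")
}

# Split a delimited text line into fields (comma, semicolon, tab or space).
split_fields <- function(line) {
  strsplit(trimws(line), "[,;\t ]+")[[1]]
}

#' Read a spectrum from a two-column text file
#'
#' Accepts CSV or whitespace-delimited text with columns wavelength (nm)
#' and absorbance (AU), plus an optional single header line. The spectrum
#' is returned on the file's native grid, re-ordered ascending by
#' wavelength if needed; no resampling is performed (see [resample()]).
#'
#' @param path File path.
#' @param wavelength_col,absorbance_col 1-based column indices.
#' @param label Label for the returned spectrum; defaults to the file name.
#' @return A `spectrum`. The native grid must be uniform.
#' @export
read_spectrum <- function(path, wavelength_col = 1L, absorbance_col = 2L,
                          label = NULL) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("spectrum file has fewer than 2 data rows: ", path)
  first <- suppressWarnings(as.numeric(split_fields(lines[1])))
  skip_header <- anyNA(first)
  data_lines <- if (skip_header) lines[-1] else lines
  line_no <- seq_along(lines)[if (skip_header) -1L else TRUE]
  wl <- numeric(length(data_lines))
  ab <- numeric(length(data_lines))
  for (i in seq_along(data_lines)) {
    v <- suppressWarnings(as.numeric(split_fields(data_lines[i])))
    if (length(v) < max(wavelength_col, absorbance_col) || anyNA(v)) {
      stop("non-numeric or short row at line ", line_no[i], " of ", path)
    }
    wl[i] <- v[wavelength_col]
    ab[i] <- v[absorbance_col]
  }
  if (anyDuplicated(wl)) {
    stop("duplicate wavelengths in ", path, " (first: ",
         wl[anyDuplicated(wl)], " nm)")
  }
  o <- order(wl)
  if (is.unsorted(wl) && is.unsorted(rev(wl))) {
    stop("wavelengths must be strictly monotone in ", path)
  }
  wl <- wl[o]; ab <- ab[o]
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6 * mean(steps)) {
    stop("non-uniform wavelength grid in ", path)
  }
  g <- wl_grid(wl[1], wl[length(wl)], mean(steps))
  new_spectrum(g, ab, label = if (is.null(label)) basename(path) else label)
}

#' Write a spectrum as two-column CSV
#'
#' @param s A `spectrum`.
#' @param path Output path; columns `wavelength_nm,absorbance`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  df <- data.frame(wavelength_nm = wavelengths(s$grid),
                   absorbance = s$absorbance)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; the target grid must lie entirely within the
#' source wavelength range (no extrapolation, ever). Values at shared
#' wavelengths are unchanged.
#'
#' @param s A `spectrum`.
#' @param grid Target `wl_grid`.
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"), inherits(grid, "wl_grid"))
  src <- wavelengths(s$grid)
  tol <- 1e-9
  if (grid$start < src[1] - tol || grid$stop > src[length(src)] + tol) {
    stop(sprintf("target grid %g-%g nm extends beyond source range %g-%g nm",
                 grid$start, grid$stop, src[1], src[length(src)]))
  }
  out <- stats::approx(src, s$absorbance, xout = wavelengths(grid),
                       method = "linear", rule = 1)$y
  # endpoints can fall a hair outside src due to float step accumulation
  if (anyNA(out)) {
    idx <- which(is.na(out))
    out[idx] <- s$absorbance[vapply(wavelengths(grid)[idx], function(w)
      which.min(abs(src - w)), integer(1))]
  }
  new_spectrum(grid, out, label = s$label)
}

#' Write a correlation map as a self-describing CSV matrix
#'
#' First row holds the reference-axis wavelengths, first column the
#' sample-axis wavelengths; the top-left cell carries the map kind.
#'
#' @param map A `corr_map` (see [asynchronous_map()]).
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "corr_map"))
  wl <- wavelengths(map$grid)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)
  header <- paste(c(map$kind, fmt(wl)), collapse = ",")
  body <- vapply(seq_along(wl), function(i)
    paste(c(fmt(wl[i]), fmt(map$values[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a correlation map written by [write_map()]
#'
#' @param path File path.
#' @return A `corr_map`; round-trips values to better than 1e-12 relative
#'   error. Ragged rows or a row/column axis mismatch raise a format error.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  head_fields <- split_fields(gsub(",", " ", lines[1]))
  kind <- head_fields[1]
  if (!kind %in% c("synchronous", "asynchronous")) {
    stop("map file format error: unknown kind '", kind, "'")
  }
  col_wl <- suppressWarnings(as.numeric(head_fields[-1]))
  if (anyNA(col_wl)) stop("map file format error: bad column axis")
  n <- length(col_wl)
  if (length(lines) - 1L != n) {
    stop("map file format error: body has ", length(lines) - 1L,
         " rows for ", n, " axis columns")
  }
  row_wl <- numeric(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(split_fields(gsub(",", " ", lines[i + 1L]))))
    if (length(v) != n + 1L || anyNA(v)) {
      stop("map file format error: ragged or non-numeric row ", i)
    }
    row_wl[i] <- v[1]
    vals[i, ] <- v[-1]
  }
  if (max(abs(row_wl - col_wl)) > 1e-9) {
    stop("map file format error: row and column axes differ")
  }
  step <- mean(diff(col_wl))
  g <- wl_grid(col_wl[1], col_wl[n], step)
  new_corr_map(kind, g, vals)
}
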