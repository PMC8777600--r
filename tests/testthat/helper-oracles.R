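# Independent brute-force oracles used to pin expected values. These are
# deliberately naive re-derivations (literal loops, explicit objective
# recomputation) kept separate from the package implementation.

# Piecewise-linear interpolation at a single wavelength.
interp_oracle <- function(x, y, xout) {
  vapply(xout, function(w) {
    if (w <= x[1]) return(y[1])
    if (w >= x[length(x)]) return(y[length(y)])
    i <- max(which(x <= w))
    if (x[i] == w) return(y[i])
    t <- (w - x[i]) / (x[i + 1] - x[i])
    (1 - t) * y[i] + t * y[i + 1]
  }, numeric(1))
}

# Exhaustive cross-peak scan: loop over every grid point, check the
# 8-neighbourhood, threshold, off-diagonal distance and upper triangle,
# then merge greedily by descending magnitude.
peak_scan_oracle <- function(values, wl, rel_threshold = 0.10,
                             min_offdiag = 5, merge_radius = 4) {
  A <- abs(values)
  top <- max(A)
  p <- nrow(A)
  hits <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (!(wl[j] > wl[i])) next
    if (abs(wl[i] - wl[j]) < min_offdiag) next
    if (A[i, j] < rel_threshold * top) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || jj < 1 || ii > p || jj > p) next
      if (A[ii, jj] > A[i, j]) ok <- FALSE
      if (A[ii, jj] == A[i, j] && (di < 0 || (di == 0 && dj < 0))) ok <- FALSE
    }
    if (ok) hits[[length(hits) + 1]] <- c(i, j, A[i, j])
  }
  if (!length(hits)) {
    return(data.frame(nu1 = numeric(0), nu2 = numeric(0),
                      magnitude = numeric(0)))
  }
  h <- do.call(rbind, hits)
  h <- h[order(-h[, 3], wl[h[, 1]], wl[h[, 2]]), , drop = FALSE]
  sel <- 1L
  if (nrow(h) > 1) for (k in 2:nrow(h)) {
    d <- pmax(abs(wl[h[k, 1]] - wl[h[sel, 1]]),
              abs(wl[h[k, 2]] - wl[h[sel, 2]]))
    if (all(d >= merge_radius)) sel <- c(sel, k)
  }
  h <- h[sel, , drop = FALSE]
  data.frame(nu1 = wl[h[, 1]], nu2 = wl[h[, 2]], magnitude = h[, 3])
}

# Brute-force Ward agglomeration: recompute the within-cluster sum of
# squares increase of every candidate merge at every step; heights on the
# distance scale (sqrt of twice the WCSS increase). Lowest-index pair
# wins ties.
ward_oracle <- function(X) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    M <- X[rows, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M), "-")^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  partitions <- list(clusters)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (a in 1:(length(clusters) - 1)) for (b in (a + 1):length(clusters)) {
      cost <- ess(c(clusters[[a]], clusters[[b]])) -
        ess(clusters[[a]]) - ess(clusters[[b]])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(a, b) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, sqrt(2 * best_cost))
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(partitions = partitions, heights = heights)
}

# Flat k-cluster membership vector from a ward_oracle partition list.
ward_oracle_cut <- function(oracle, k, n) {
  part <- oracle$partitions[[n - k + 1]]
  lab <- integer(n)
  for (c in seq_along(part)) lab[part[[c]]] <- c
  lab
}

# Canonical form of a partition for label-free comparison.
canon_partition <- function(labels, ids = seq_along(labels)) {
  groups <- split(ids, labels)
  groups <- lapply(groups, function(g) sort(as.character(g)))
  unname(sort(vapply(groups, paste, character(1), collapse = "|")))
}

# Literal leave-blind-out cross-validation loop.
cv_oracle <- function(X, k_max, assign, offset = 1e-5) {
  press <- numeric(k_max)
  for (s in sort(unique(assign))) {
    tr <- which(assign != s)
    te <- which(assign == s)
    Xtr <- X[tr, , drop = FALSE]
    rn <- sqrt(rowSums(Xtr^2))
    Xtrn <- Xtr / ifelse(rn == 0, 1, rn)
    mu <- colMeans(Xtrn)
    sc <- apply(Xtrn, 2, sd) + offset
    Xtrp <- sweep(sweep(Xtrn, 2, mu, "-"), 2, sc, "/")
    V <- svd(Xtrp)$v
    for (irow in te) {
      x <- X[irow, ]
      nrm <- sqrt(sum(x^2))
      if (nrm > 0) x <- x / nrm
      xp <- (x - mu) / sc
      for (k in seq_len(k_max)) {
        kk <- min(k, ncol(V), length(tr) - 1)
        Vk <- V[, seq_len(kk), drop = FALSE]
        r <- xp - as.vector(Vk %*% crossprod(Vk, xp))
        press[k] <- press[k] + sum(r^2)
      }
    }
  }
  sqrt(press / (nrow(X) * ncol(X)))
}

# Rank-k reconstruction residual computed directly from a fresh SVD.
rmsec_oracle <- function(X, k) {
  sv <- svd(X)
  Xk <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  sqrt(sum((X - Xk)^2) / (nrow(X) * ncol(X)))
}

# Small random flavonol-style table.
random_table <- function(n, seed) {
  set.seed(seed)
  data.frame(product_id = sprintf("X%02d", seq_len(n)),
             pct_rutin = runif(n, 0, 90),
             pct_quercetin = runif(n, 0, 60),
             pct_kaempferol = runif(n, 0, 30),
             stringsAsFactors = FALSE)
}

# Spectrum with a single Gaussian band (test scaffolding).
gauss_spectrum <- function(center, sigma = 10, height = 1,
                           grid = default_grid(), label = "") {
  wl <- wavelengths(grid)
  new_spectrum(grid, height * exp(-(wl - center)^2 / (2 * sigma^2)), label)
}
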