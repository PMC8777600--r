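# Multiway PCA of correlation-map stacks: unfold the n x p x p array to
# n x p^2, normalize each sample row to unit Euclidean norm, autoscale
# columns with an offset-guarded standard deviation, decompose by SVD,
# and report scores, loadings, explained variance, RMSEC and
# venetian-blinds RMSECV.

#' Unfold a map stack to an n x p^2 matrix
#'
#' Row i is map i flattened row-major (the sample axis v1 varies slowest),
#' so column (a - 1) * p + b holds value (v1_a, v2_b).
#'
#' @param stack A `map_stack`.
#' @return Numeric matrix with rownames from the stack's sample ids.
#' @export
unfold <- function(stack) {
  stopifnot(inherits(stack, "map_stack"))
  X <- t(vapply(stack$maps, function(m) as.vector(t(m$values)),
                numeric(n_points(stack$grid)^2)))
  rownames(X) <- stack$sample_ids
  X
}

#' Refold one unfolded row back into a p x p map matrix
#'
#' Inverse of the [unfold()] convention; `refold(unfold(stack)[i, ], grid)`
#' reproduces map i exactly.
#'
#' @param row Numeric vector of length p^2.
#' @param grid The map `wl_grid` (p points).
#' @return p x p numeric matrix (rows v1, columns v2).
#' @export
refold <- function(row, grid) {
  p <- n_points(grid)
  stopifnot(length(row) == p^2)
  matrix(row, nrow = p, ncol = p, byrow = TRUE)
}

#' Normalize and autoscale an unfolded matrix
#'
#' Step 1: each row is divided by its Euclidean norm (removes
#' concentration scale; zero-norm rows are left unchanged and flagged).
#' Step 2: each column is mean-centered and divided by its standard
#' deviation (n - 1 denominator) plus `offset` -- the additive offset
#' guards near-constant columns against division blow-up.
#'
#' @param X Numeric matrix (n >= 2 rows).
#' @param offset Scale offset added to every column sd (default 1e-5).
#' @return List with `X` (preprocessed matrix) and `params` (class
#'   `preprocess_params`: `row_norms`, `col_means`, `col_scales`,
#'   `offset`, `zero_norm_rows`).
#' @export
mpca_preprocess <- function(X, offset = 1e-5) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) stop("preprocessing requires at least 2 samples")
  stopifnot(offset > 0)
  rn <- sqrt(rowSums(X^2))
  zero <- rn == 0
  if (any(zero)) warning(sum(zero), " zero-norm row(s) left unnormalized")
  Xn <- X / ifelse(rn == 0, 1, rn)
  mu <- colMeans(Xn)
  sc <- apply(Xn, 2, stats::sd) + offset
  Xp <- sweep(sweep(Xn, 2, mu, "-"), 2, sc, "/")
  params <- structure(list(row_norms = rn, col_means = mu, col_scales = sc,
                           offset = offset, zero_norm_rows = which(zero)),
                      class = "preprocess_params")
  list(X = Xp, params = params)
}

apply_preprocess <- function(X, params) {
  rn <- sqrt(rowSums(X^2))
  Xn <- X / ifelse(rn == 0, 1, rn)
  sweep(sweep(Xn, 2, params$col_means, "-"), 2, params$col_scales, "/")
}

# Flip each loading row so its largest-|.| element is positive; flip the
# matching score column. SVD signs are arbitrary; this pins them.
fix_signs <- function(scores, loadings) {
  for (k in seq_len(nrow(loadings))) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) {
      loadings[k, ] <- -loadings[k, ]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Fit a multiway PCA model to a preprocessed matrix
#'
#' Thin SVD X = U D V'; scores = U D, loadings = rows of V', explained
#' variance per component = d_i^2 / sum d^2 * 100, and
#' RMSEC(k) = sqrt(sum of squared residuals of the rank-k reconstruction
#' / (n p^2)). A deterministic sign convention (largest-magnitude loading
#' element positive) makes scores reproducible.
#'
#' @param X Preprocessed matrix from [mpca_preprocess()].
#' @param k_max Number of components (<= min(n - 1, ncol)).
#' @param params Optional `preprocess_params` to store for [mpca_project()].
#' @param grid Optional `wl_grid` for refolding loadings.
#' @return An object of class `mpca_model`: `n_components`, `scores`
#'   (n x k), `loadings` (k x p^2, orthonormal rows),
#'   `explained_variance_pct`, `cumulative_variance_pct`, `rmsec_per_k`,
#'   `singular_values`, `preprocess`, `grid`.
#' @export
fit_mpca <- function(X, k_max, params = NULL, grid = NULL) {
  stopifnot(is.matrix(X))
  n <- nrow(X); p2 <- ncol(X)
  if (k_max > min(n - 1L, p2)) {
    stop("k_max exceeds min(n - 1, number of variables)")
  }
  sv <- svd(X, nu = k_max, nv = k_max)
  d <- sv$d
  scores <- sv$u %*% diag(d[seq_len(k_max)], k_max)
  loadings <- t(sv$v)
  fx <- fix_signs(scores, loadings)
  tot <- sum(d^2)
  evp <- if (tot > 0) d^2 / tot * 100 else rep(0, length(d))
  rmsec <- vapply(seq_len(k_max), function(k) {
    sqrt(sum(d[-seq_len(k)]^2) / (n * p2))
  }, numeric(1))
  rownames(fx$scores) <- rownames(X)
  structure(list(n_components = k_max, scores = fx$scores,
                 loadings = fx$loadings,
                 explained_variance_pct = evp[seq_len(k_max)],
                 cumulative_variance_pct = cumsum(evp)[seq_len(k_max)],
                 rmsec_per_k = rmsec, singular_values = d,
                 preprocess = params, grid = grid),
            class = "mpca_model")
}

#' @export
print.mpca_model <- function(x, ...) {
  cat(sprintf("<mpca_model> %d components on %d samples\n",
              x$n_components, nrow(x$scores)))
  cat("  explained variance (%):",
      paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", "),
      sprintf(" (cumulative %.2f)\n",
              x$cumulative_variance_pct[x$n_components]))
  cat("  RMSEC:", paste(sprintf("%.4f", x$rmsec_per_k), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit MPCA to a map stack (unfold + preprocess + decompose)
#'
#' @param stack A `map_stack`.
#' @param k_max Number of components.
#' @param offset Autoscale offset (default 1e-5).
#' @return An `mpca_model` carrying the preprocessing parameters and grid.
#' @export
mpca <- function(stack, k_max = 3L, offset = 1e-5) {
  X <- unfold(stack)
  pp <- mpca_preprocess(X, offset)
  fit_mpca(pp$X, k_max, params = pp$params, grid = stack$grid)
}

#' Venetian-blinds sample-to-split assignment
#'
#' Blocked order (the default) assigns sample i (1-based) to split
#' `floor((i - 1) / per_blind) %% n_splits + 1`, i.e. consecutive blinds
#' of `per_blind` samples dealt round-robin to the splits; interleaved
#' order assigns `(i - 1) %% n_splits + 1`.
#'
#' @param n Number of samples.
#' @param n_splits Number of CV splits (default 10).
#' @param per_blind Samples per blind (default 2).
#' @param order `"blocked"` or `"interleave"`.
#' @return Integer vector of split indices in 1..n_splits.
#' @export
venetian_blinds <- function(n, n_splits = 10L, per_blind = 2L,
                            order = c("blocked", "interleave")) {
  order <- match.arg(order)
  i <- seq_len(n) - 1L
  if (order == "blocked") (i %/% per_blind) %% n_splits + 1L
  else i %% n_splits + 1L
}

#' Venetian-blinds cross-validation of the MPCA model
#'
#' For each split the preprocessing parameters and the PCA are refit on
#' the retained samples only; the left-out rows are preprocessed with
#' those training parameters and reconstructed from the first k loadings.
#' RMSECV(k) = sqrt(sum over all left-out squared residuals / (n p^2)).
#'
#' @param X Raw unfolded matrix (not preprocessed; preprocessing is part
#'   of what is cross-validated).
#' @param k_max Maximum number of components.
#' @param n_splits,per_blind,order See [venetian_blinds()].
#' @param offset Autoscale offset.
#' @return An object of class `cv_result`: `n_splits`, `per_blind`,
#'   `assignment`, `rmsecv_per_k`.
#' @export
mpca_cross_validate <- function(X, k_max, n_splits = 10L, per_blind = 2L,
                                order = "blocked", offset = 1e-5) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  if (n < n_splits) stop("need at least as many samples as splits")
  assign <- venetian_blinds(n, n_splits, per_blind, order)
  press <- numeric(k_max)
  for (s in sort(unique(assign))) {
    train <- which(assign != s)
    test <- which(assign == s)
    if (length(train) < 2L) {
      stop("training fold for split ", s, " has fewer than 2 samples")
    }
    pp <- mpca_preprocess(X[train, , drop = FALSE], offset)
    kf <- min(k_max, length(train) - 1L, ncol(X))
    sv <- svd(pp$X, nu = 0, nv = kf)
    V <- sv$v                                  # p2 x kf
    Xt <- apply_preprocess(X[test, , drop = FALSE], pp$params)
    Tk <- Xt %*% V                             # test scores
    for (k in seq_len(k_max)) {
      kk <- min(k, kf)
      R <- Xt - Tk[, seq_len(kk), drop = FALSE] %*%
        t(V[, seq_len(kk), drop = FALSE])
      press[k] <- press[k] + sum(R^2)
    }
  }
  structure(list(n_splits = n_splits, per_blind = per_blind,
                 assignment = assign,
                 rmsecv_per_k = sqrt(press / (n * ncol(X)))),
            class = "cv_result")
}

#' Project new maps into a fitted MPCA score space
#'
#' Unfolds the new stack, applies the stored row-normalization and
#' column centering/scaling, and multiplies by the loadings transpose.
#'
#' @param model An `mpca_model` fitted with stored preprocessing
#'   parameters (e.g. via [mpca()]).
#' @param new_maps A `map_stack` on the model grid, or an already
#'   unfolded numeric matrix.
#' @return Scores matrix (rows = new samples, columns = components).
#' @export
mpca_project <- function(model, new_maps) {
  stopifnot(inherits(model, "mpca_model"))
  if (is.null(model$preprocess)) {
    stop("model carries no preprocessing parameters; fit with mpca()")
  }
  X <- if (inherits(new_maps, "map_stack")) {
    if (!is.null(model$grid) && !grids_equal(new_maps$grid, model$grid)) {
      stop("new maps are not on the model grid")
    }
    unfold(new_maps)
  } else {
    stopifnot(is.matrix(new_maps), ncol(new_maps) == ncol(model$loadings))
    new_maps
  }
  apply_preprocess(X, model$preprocess) %*% t(model$loadings)
}
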