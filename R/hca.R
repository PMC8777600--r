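# Hierarchical clustering of the chromatographic flavonol table: Ward's
# minimum-variance agglomeration on Euclidean distances after mean
# centering, plus flat-cluster extraction. Mean centering does not change
# Euclidean distances (it is a translation); it is kept as an explicit
# step because it is the documented preprocessing of the table.

flavonol_cols <- c("pct_rutin", "pct_quercetin", "pct_kaempferol")

# range_check applies to raw percentage tables only; centered tables are
# translated and legitimately hold negative values.
check_flavonol_table <- function(table, range_check = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("product_id", flavonol_cols) %in% names(table)))
  if (anyDuplicated(table$product_id)) stop("product ids must be unique")
  vals <- as.matrix(table[flavonol_cols])
  if (anyNA(vals)) stop("flavonol table contains missing values")
  if (range_check && any(vals < 0 | vals > 100)) {
    stop("flavonol percentages must lie in [0, 100]")
  }
  invisible(vals)
}

#' Mean-center the flavonol columns of a table
#'
#' Subtracts each column mean; pairwise Euclidean row distances are
#' unchanged (translation invariance), so centering affects only the
#' coordinate origin, not the clustering.
#'
#' @param table data.frame with `product_id`, `pct_rutin`,
#'   `pct_quercetin`, `pct_kaempferol`.
#' @return The table with centered flavonol columns.
#' @export
mean_center <- function(table) {
  check_flavonol_table(table, range_check = TRUE)
  if (nrow(table) < 2L) stop("mean centering requires at least 2 rows")
  table[flavonol_cols] <- scale(as.matrix(table[flavonol_cols]),
                                center = TRUE, scale = FALSE)
  table
}

#' Ward linkage of a flavonol table
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (the "ward.D2" convention: squared-distance
#' objective, heights reported on the distance scale). Merge heights are
#' monotone non-decreasing.
#'
#' @param table Flavonol table (typically already passed through
#'   [mean_center()]; centering does not alter the result).
#' @return An object of class `flavonol_dendrogram`: the underlying
#'   `hclust` object plus a `merges` data.frame (`cluster_a`, `cluster_b`,
#'   `height`, `new_size`) in `hclust`'s merge convention (negative =
#'   singleton row, positive = earlier merge).
#' @export
ward_linkage <- function(table) {
  vals <- check_flavonol_table(table)
  if (nrow(table) < 2L) stop("clustering requires at least 2 rows")
  rownames(vals) <- table$product_id
  hc <- stats::hclust(stats::dist(vals, method = "euclidean"),
                      method = "ward.D2")
  sizes <- integer(nrow(hc$merge))
  size_of <- function(x) if (x < 0) 1L else sizes[x]
  for (m in seq_len(nrow(hc$merge))) {
    sizes[m] <- size_of(hc$merge[m, 1]) + size_of(hc$merge[m, 2])
  }
  structure(list(hclust = hc,
                 merges = data.frame(cluster_a = hc$merge[, 1],
                                     cluster_b = hc$merge[, 2],
                                     height = hc$height,
                                     new_size = sizes),
                 product_ids = table$product_id),
            class = "flavonol_dendrogram")
}

#' @export
print.flavonol_dendrogram <- function(x, ...) {
  cat(sprintf("<flavonol_dendrogram> %d products, %d merges, top height %.3f\n",
              length(x$product_ids), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Cut a dendrogram into k flat clusters
#'
#' Undoes the last k - 1 merges. Cluster labels are deterministic:
#' renumbered 1..k in order of first appearance down the product list.
#'
#' @param dend A `flavonol_dendrogram`.
#' @param k Number of clusters (1 <= k <= n).
#' @return data.frame with `product_id` and integer `cluster`.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "flavonol_dendrogram"))
  n <- length(dend$product_ids)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  raw <- stats::cutree(dend$hclust, k = k)
  lab <- match(raw, unique(raw))  # first-seen relabeling
  data.frame(product_id = dend$product_ids, cluster = lab,
             stringsAsFactors = FALSE)
}

#' Cluster a flavonol table end to end
#'
#' Mean-centers (optional), runs Ward/Euclidean linkage, and cuts at `k`.
#'
#' @param table Flavonol table.
#' @param k Number of flat clusters (default 4, the standard reading of
#'   the supplement dendrogram: rutin-dominant, quercetin-dominant,
#'   quercetin+kaempferol ~1:1, and low-flavonol products).
#' @param center Mean-center first (default TRUE).
#' @return List with `dendrogram` (`flavonol_dendrogram`) and `partition`
#'   (data.frame from [cut_dendrogram()]).
#' @export
hca_flavonols <- function(table, k = 4L, center = TRUE) {
  tab <- if (center) mean_center(table) else table
  dend <- ward_linkage(tab)
  list(dendrogram = dend, partition = cut_dendrogram(dend, k))
}
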