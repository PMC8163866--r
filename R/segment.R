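# k-means segmentation of per-pixel spectral features, with the workflow's
# background-cluster rejection. Features are the (few) normalized MIR
# absorbance channels or the (many) unit-norm FT-IR channels; clustering is
# plain Lloyd k-means with k-means++ seeding and restarts, then a
# mask-majority rule rejects clusters that live on the bare slide.

#' Stack co-registered channels into a per-pixel feature table
#'
#' @param x Either a list of matrices / [absorbance_image()]s sharing one
#'   shape, or a [hyper_cube()].
#' @return A `feature_table`: `matrix` (n_pixels x n_features, pixels in
#'   column-major raster order), `shape` (rows, cols), `feature_axis`
#'   (wavenumbers, `NA` where unknown).
#' @export
stack_features <- function(x) {
  if (inherits(x, "hyper_cube")) {
    d <- dim(x$data)
    m <- matrix(x$data, d[1L] * d[2L], d[3L])
    axis <- x$wavenumbers
    shape <- d[1:2]
  } else {
    vals <- lapply(x, image_values)
    dims <- vapply(vals, dim, integer(2L))
    if (any(dims != dims[, 1L])) stopf("channel shapes differ")
    shape <- dims[, 1L]
    m <- vapply(vals, as.vector, numeric(prod(shape)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    axis <- vapply(x, function(im)
      if (inherits(im, "absorbance_image")) im$wavenumber else NA_real_,
      numeric(1L))
  }
  if (!all(is.finite(m))) stopf("non-finite feature values")
  structure(list(matrix = m, shape = as.integer(shape), feature_axis = axis),
            class = "feature_table")
}

#' Reshape a per-pixel vector back onto the source raster
#'
#' @param values Vector of length `prod(features$shape)` in raster order.
#' @param features The `feature_table` the values belong to.
#' @return Matrix of the source shape.
#' @export
unstack_values <- function(values, features) {
  stopifnot(inherits(features, "feature_table"),
            length(values) == prod(features$shape))
  matrix(values, features$shape[1L], features$shape[2L])
}

# k-means++ initial centres (Arthur & Vassilvitskii seeding) on the rows of m.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- m[idx, ]
  d2 <- rowSums((m - matrix(centers[1L, ], n, ncol(m), byrow = TRUE))^2)
  if (k > 1L) for (j in 2:k) {
    tot <- sum(d2)
    idx <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- m[idx, ]
    d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m), byrow = TRUE))^2))
  }
  centers
}

#' k-means segmentation of a feature table
#'
#' Lloyd iterations from k-means++ seeds, best of `restarts` runs by
#' within-cluster sum of squares, deterministic for a fixed seed. Clusters
#' are relabelled in descending size (cluster 0 is always the largest) for
#' stable output. An optional mask restricts clustering to the masked
#' pixels; pixels outside it are labelled -1 directly.
#'
#' @param features A `feature_table` from [stack_features()].
#' @param k Number of clusters (>= 1, <= number of clustered pixels).
#' @param seed Integer RNG seed.
#' @param restarts Independent k-means++ restarts (default 5).
#' @param iter_max Maximum Lloyd iterations per restart (default 100).
#' @param mask Optional logical matrix of the raster shape; `FALSE` pixels
#'   are excluded from clustering and labelled -1.
#' @return A `label_map`: `labels` (matrix, -1 = rejected/background,
#'   0..k-1 = clusters, largest first), `k`, `centroids` (k x n_features),
#'   `seed`, `rejected` (integer vector of rejected cluster ids), `sizes`.
#' @export
kmeans_segment <- function(features, k, seed = 1, restarts = 5L,
                           iter_max = 100L, mask = NULL) {
  stopifnot(inherits(features, "feature_table"))
  if (k < 1L) stopf("`k` must be >= 1")
  m <- features$matrix
  keep <- rep(TRUE, nrow(m))
  if (!is.null(mask)) {
    if (!all(dim(mask) == features$shape)) stopf("mask shape mismatch")
    keep <- as.vector(mask)
  }
  mm <- m[keep, , drop = FALSE]
  if (nrow(mm) < k) stopf("fewer pixels (%d) than clusters (%d)", nrow(mm), k)
  n_distinct <- nrow(unique(mm))
  if (n_distinct < k)
    stopf("only %d distinct feature vectors for k = %d", n_distinct, k)
  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- kmeanspp_centers(mm, k)
      res <- if (k == 1L) {
        ctr <- matrix(colMeans(mm), 1L)
        list(cluster = rep(1L, nrow(mm)), centers = ctr,
             tot.withinss = sum((mm - ctr[rep(1L, nrow(mm)), , drop = FALSE])^2))
      } else suppressWarnings(stats::kmeans(mm, centers = init,
                                            iter.max = iter_max,
                                            algorithm = "Lloyd"))
      if (is.null(best) || res$tot.withinss < best$tot.withinss) best <- res
    }
    best
  })
  # relabel descending cluster size
  sizes <- tabulate(fit$cluster, nbins = k)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k); relab[ord] <- seq_len(k) - 1L
  lab_full <- rep(-1L, nrow(m))
  lab_full[keep] <- relab[fit$cluster]
  structure(list(labels = matrix(lab_full, features$shape[1L], features$shape[2L]),
                 k = as.integer(k),
                 centroids = fit$centers[ord, , drop = FALSE],
                 seed = as.integer(seed),
                 rejected = integer(0L),
                 sizes = sizes[ord],
                 wcss = fit$tot.withinss),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, k = %d, %d rejected, WCSS %.4g\n",
              nrow(x$labels), ncol(x$labels), x$k, length(x$rejected), x$wcss))
  invisible(x)
}

#' Reject clusters that live on the bare slide
#'
#' A cluster whose fraction of pixels outside the tissue mask exceeds
#' `majority` is rejected (labelled -1); the survivors are re-indexed
#' densely, preserving their size order. In simulations the mask is the
#' phantom truth; for measured data use [otsu_mask()] on the mean
#' absorbance.
#'
#' @param map A `label_map`.
#' @param tissue_mask Logical matrix, `TRUE` on tissue.
#' @param majority Off-tissue fraction above which a cluster is rejected,
#'   in \[0.5, 1\] (default 0.5).
#' @return The updated `label_map`; `rejected` records the original ids.
#' @export
reject_background_clusters <- function(map, tissue_mask, majority = 0.5) {
  stopifnot(inherits(map, "label_map"))
  if (!all(dim(tissue_mask) == dim(map$labels))) stopf("mask shape mismatch")
  assert_scalar_num(majority, "majority", 0.5, 1)
  ids <- 0:(map$k - 1L)
  off_frac <- vapply(ids, function(id) {
    px <- map$labels == id
    n <- sum(px)
    if (n == 0L) 1 else sum(px & !tissue_mask) / n
  }, numeric(1L))
  drop <- ids[off_frac > majority]
  kept <- setdiff(ids, drop)
  if (length(kept) == 0L) stopf("all clusters rejected as background")
  new_lab <- map$labels
  for (id in drop) new_lab[map$labels == id] <- -1L
  # dense re-index preserving order
  remap <- stats::setNames(seq_along(kept) - 1L, kept)
  for (i in seq_along(kept)) new_lab[map$labels == kept[i]] <- i - 1L
  map$labels <- new_lab
  map$rejected <- as.integer(drop)
  map$centroids <- map$centroids[kept + 1L, , drop = FALSE]
  map$sizes <- map$sizes[kept + 1L]
  map
}

#' Binary mask of one kept cluster
#'
#' @param map A `label_map` (after rejection, ids are the dense kept ids).
#' @param cluster_id Kept cluster id (0-based).
#' @return Logical matrix.
#' @export
extract_cluster <- function(map, cluster_id) {
  stopifnot(inherits(map, "label_map"))
  present <- sort(unique(as.vector(map$labels)))
  present <- present[present >= 0L]
  if (!(cluster_id %in% present))
    stopf("cluster id %d is rejected or unknown (present: %s)", cluster_id,
          paste(present, collapse = ", "))
  map$labels == cluster_id
}

#' Otsu threshold mask on an image
#'
#' Standard Otsu maximal between-class-variance threshold on 256 histogram
#' bins; returns the above-threshold mask. Used to derive a tissue mask from
#' mean absorbance on measured data.
#'
#' @param image Matrix or [absorbance_image()].
#' @return Logical matrix, `TRUE` above the threshold.
#' @export
otsu_mask <- function(image) {
  x <- image_values(image)
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(matrix(TRUE, nrow(x), ncol(x)))
  nb <- 256L
  h <- tabulate(pmin(floor((x - rng[1L]) / (rng[2L] - rng[1L]) * nb) + 1L, nb),
                nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t_bin <- which.max(sigma_b)
  thr <- rng[1L] + t_bin / nb * (rng[2L] - rng[1L])
  x > thr
}

#' Cluster-label stability across seeds
#'
#' Re-runs [kmeans_segment()] under `n_seeds` seeds and reports the adjusted
#' Rand index of every run against the first, quantifying the k-means
#' reproducibility caveat.
#'
#' @param features A `feature_table`.
#' @param k Cluster count.
#' @param n_seeds Number of seeds (default 10).
#' @param base_seed First seed; runs use `base_seed + 0:(n_seeds-1)`.
#' @param ... Passed to [kmeans_segment()].
#' @return Numeric vector of ARI values of runs 2..n against run 1.
#' @export
segmentation_stability <- function(features, k, n_seeds = 10L, base_seed = 1L, ...) {
  maps <- lapply(seq_len(n_seeds) - 1L + base_seed, function(s)
    kmeans_segment(features, k, seed = s, ...))
  ref <- as.vector(maps[[1L]]$labels)
  vapply(maps[-1L], function(m)
    mclust::adjustedRandIndex(ref, as.vector(m$labels)), numeric(1L))
}
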