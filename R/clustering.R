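# Blood-pool segmentation by cluster analysis of voxel TACs.
#
# Voxels are grouped by the similarity of their raw TACs, so both kinetic
# shape and amplitude separate the classes. Amplitude matters: under
# partial-volume blur a pool's dim fringe voxels have exactly the same
# *normalized* shape as its core (blurring v(t) * mask gives c(x) * v(t)),
# so shape-only features can never exclude them and the cluster-mean TAC
# is diluted; raw features put the fringe in its own low-amplitude
# clusters. The outer voxel layer of each selected cluster is then eroded
# to limit residual partial-volume and spillover contamination before the
# cluster-mean TAC is taken as the input function.

#' Clustering configuration
#'
#' @param n_clusters Number of clusters; 5 is the stable choice for
#'   acetate, 6 for water (see [tracer_cluster_count()]).
#' @param activity_prefilter_percentile Voxels whose time-integrated
#'   activity is at or below this percentile (over all voxels) are treated
#'   as background and excluded before clustering. Default 50.
#' @param seed Integer seed making the k-means initialization deterministic.
#' @param erosion_iterations Number of one-layer erosions applied to the
#'   selected clusters before TAC extraction. Default 1.
#' @param feature_scaling `"raw"` (default) clusters voxel TACs as-is, so
#'   amplitude separates partial-volume fringe from pool cores;
#'   `"unit_peak"` normalizes each TAC to unit peak, clustering on shape
#'   only (adequate for blur-free data).
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 5L, activity_prefilter_percentile = 50,
                           seed = 1L, erosion_iterations = 1L,
                           feature_scaling = c("raw", "unit_peak")) {
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 2L) stop("n_clusters must be >= 2")
  if (activity_prefilter_percentile < 0 || activity_prefilter_percentile >= 100)
    stop("activity_prefilter_percentile must be in [0, 100)")
  erosion_iterations <- as.integer(erosion_iterations)
  if (is.na(erosion_iterations) || erosion_iterations < 0L)
    stop("erosion_iterations must be >= 0")
  structure(list(n_clusters = n_clusters,
                 activity_prefilter_percentile = activity_prefilter_percentile,
                 seed = as.integer(seed),
                 erosion_iterations = erosion_iterations,
                 feature_scaling = match.arg(feature_scaling)),
            class = "cluster_config")
}

#' Cluster count per tracer
#'
#' Six clusters for water, five for acetate (five were found to yield more
#' stable results for acetate).
#'
#' @param tracer `"acetate"` or `"water"`.
#' @return Integer cluster count.
#' @export
tracer_cluster_count <- function(tracer = c("acetate", "water")) {
  tracer <- match.arg(tracer)
  if (tracer == "water") 6L else 5L
}

# Run expr with a private, seeded RNG stream; the caller's stream is
# untouched.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# k-means++ initialization. May return fewer than k centers when the data
# hold fewer than k distinct points (e.g. noiseless phantoms); callers fall
# back to the reduced k.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
  m <- 1L
  while (m < k) {
    if (max(d2) <= 0) break  # fewer distinct points than clusters
    j <- sample.int(n, 1L, prob = d2)
    m <- m + 1L
    idx[m] <- j
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[j, ], "-")^2))
  }
  x[idx[seq_len(m)], , drop = FALSE]
}

#' Cluster voxel TACs into kinetic classes
#'
#' Background voxels (time-integrated activity at or below the prefilter
#' percentile, or with a non-positive peak) are labelled 0. Remaining
#' voxel TACs (raw, or unit-peak normalized under
#' `feature_scaling = "unit_peak"`) are partitioned with k-means (Lloyd
#' iterations from a k-means++ seeded initialization), which is
#' deterministic given `config$seed`.
#'
#' @param series A [dynamic_series()] with at least 8 frames.
#' @param config A [cluster_config()].
#' @return 3D integer array of cluster labels (0 = background).
#' @export
cluster_voxel_tacs <- function(series, config = cluster_config()) {
  nt <- n_frames(series$schedule)
  if (nt < 8L) stop("series must have at least 8 frames covering the bolus transit")
  d <- dim(series$voxels)
  X <- matrix(series$voxels, prod(d[1:3]), nt)
  rng <- range(X)
  if (rng[1] == rng[2]) stop("all-constant image: no kinetics to cluster")
  dur <- series$schedule$frame_duration
  integ <- as.vector(X %*% dur)
  peak <- do.call(pmax, c(lapply(seq_len(nt), function(j) X[, j]), list(na.rm = FALSE)))
  thr <- stats::quantile(integ, config$activity_prefilter_percentile / 100,
                         names = FALSE)
  keep <- integ > thr & peak > 0
  if (sum(keep) < config$n_clusters)
    stop("prefilter keeps ", sum(keep), " voxels, fewer than n_clusters = ",
         config$n_clusters)
  Xn <- X[keep, , drop = FALSE]
  if (identical(config$feature_scaling, "unit_peak")) Xn <- Xn / peak[keep]
  km <- .with_seed(config$seed, {
    centers <- .kmeanspp_centers(Xn, config$n_clusters)
    if (nrow(centers) < config$n_clusters)
      warning("only ", nrow(centers), " distinct TAC shapes; using ",
              nrow(centers), " clusters instead of ", config$n_clusters)
    suppressWarnings(
      stats::kmeans(Xn, centers = centers, iter.max = 200L, algorithm = "Lloyd"))
  })
  labels <- array(0L, dim = d[1:3])
  labels[keep] <- km$cluster
  labels
}

#' Summarize clusters by their mean-TAC peak
#'
#' @param labels 3D label array from [cluster_voxel_tacs()].
#' @param series The [dynamic_series()] the labels came from.
#' @return data.frame with `cluster_id`, `n_voxels`, `peak_value_Bq_per_mL`,
#'   `peak_time_s`.
#' @export
cluster_summary <- function(labels, series) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  mid <- frame_mid(series$schedule)
  rows <- lapply(ids, function(id) {
    ct <- extract_cluster_tac(series, labels == id)
    pk <- which.max(ct$value)
    data.frame(cluster_id = id, n_voxels = sum(labels == id),
               peak_value_Bq_per_mL = ct$value[pk], peak_time_s = mid[pk])
  })
  do.call(rbind, rows)
}

#' Select the arterial and venous blood-pool clusters
#'
#' In `auto` mode clusters are ranked by first-pass likeness of their mean
#' TAC — an early, high, sharp peak, scored as peak value divided by peak
#' mid-time, with the peak required within the first `blood_peak_window_s`
#' seconds (the bolus window covered by short frames). The top-ranked
#' cluster is one pool; the other pool is the best-ranked cluster peaking
#' in a *different frame* (the bolus transits the right heart before the
#' left, so the two pools cannot peak simultaneously — this keeps
#' partial-volume shells of the first pool, which peak in the same frame,
#' from being mistaken for the second pool). The earlier-peaking of the
#' two is venous, the later arterial. `manual` mode reproduces the
#' visual-selection workflow and is authoritative when the two disagree.
#'
#' @param labels 3D label array.
#' @param series The [dynamic_series()].
#' @param mode `"auto"` or `"manual"`.
#' @param manual_ids For manual mode, `c(arterial_id, venous_id)`.
#' @param blood_peak_window_s Latest admissible peak mid-time in auto mode.
#' @return List with `arterial_id` and `venous_id`.
#' @export
select_blood_clusters <- function(labels, series, mode = c("auto", "manual"),
                                  manual_ids = NULL, blood_peak_window_s = 90) {
  mode <- match.arg(mode)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (mode == "manual") {
    if (is.null(manual_ids) || length(manual_ids) != 2L)
      stop("manual mode requires manual_ids = c(arterial_id, venous_id)")
    manual_ids <- as.integer(manual_ids)
    if (manual_ids[1L] == manual_ids[2L])
      stop("arterial and venous cluster ids must differ")
    if (!all(manual_ids %in% ids))
      stop("manual_ids not present in labels: ",
           paste(setdiff(manual_ids, ids), collapse = ", "))
    return(list(arterial_id = manual_ids[1L], venous_id = manual_ids[2L]))
  }
  smry <- cluster_summary(labels, series)
  smry <- smry[smry$peak_time_s <= blood_peak_window_s & smry$peak_value_Bq_per_mL > 0, ]
  if (nrow(smry) < 2L)
    stop("fewer than two blood-like clusters (peak within ",
         blood_peak_window_s, " s); use manual selection")
  smry$score <- smry$peak_value_Bq_per_mL / pmax(smry$peak_time_s, 1e-9)
  smry <- smry[order(-smry$score), ]
  first <- smry[1L, ]
  rest <- smry[smry$peak_time_s != first$peak_time_s, ]
  if (nrow(rest) == 0L)
    stop("all blood-like clusters peak in the same frame; use manual selection")
  second <- rest[1L, ]
  ven <- if (first$peak_time_s < second$peak_time_s) first else second
  art <- if (first$peak_time_s < second$peak_time_s) second else first
  list(arterial_id = as.integer(art$cluster_id),
       venous_id = as.integer(ven$cluster_id))
}

#' Erode a binary mask (one 6-connected layer per iteration)
#'
#' Each iteration removes every voxel that has a face-adjacent neighbor
#' outside the mask (voxels beyond the volume border count as outside), i.e.
#' the outer layer of voxels. `iterations = 0` is the identity. The result
#' may be empty; callers check non-emptiness.
#'
#' @param mask 3D logical array.
#' @param iterations Number of erosion passes (>= 0).
#' @return 3D logical array, a subset of `mask`.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (!is.logical(mask)) mask <- array(as.logical(mask), dim = dim(mask))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) stop("iterations must be >= 0")
  d <- dim(mask)
  i1 <- seq_len(d[1L]) + 1L; i2 <- seq_len(d[2L]) + 1L; i3 <- seq_len(d[3L]) + 1L
  for (k in seq_len(iterations)) {
    if (!any(mask)) break
    p <- array(FALSE, d + 2L)
    p[i1, i2, i3] <- mask
    mask <- p[i1, i2, i3] &
      p[i1 - 1L, i2, i3] & p[i1 + 1L, i2, i3] &
      p[i1, i2 - 1L, i3] & p[i1, i2 + 1L, i3] &
      p[i1, i2, i3 - 1L] & p[i1, i2, i3 + 1L]
  }
  mask
}

#' Mean TAC over a voxel mask
#'
#' Per-frame arithmetic mean of activity over the mask voxels.
#'
#' @param series A [dynamic_series()].
#' @param mask 3D logical array; must contain at least one voxel.
#' @return A [tac()] carrying the series schedule.
#' @export
extract_cluster_tac <- function(series, mask) {
  if (!all(dim(mask) == dim(series$voxels)[1:3]))
    stop("mask shape does not match the series spatial grid")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask: no voxels to average")
  nt <- n_frames(series$schedule)
  X <- matrix(series$voxels, prod(dim(series$voxels)[1:3]), nt)
  v <- colMeans(X[idx, , drop = FALSE])
  tac(frame_mid(series$schedule), v, series$schedule)
}

#' Segment the arterial and venous blood pools
#'
#' Clusters voxel TACs, selects the two blood-pool clusters, and erodes
#' each by `config$erosion_iterations` layers.
#'
#' @inheritParams select_blood_clusters
#' @param config A [cluster_config()].
#' @return Object of class `blood_pool_segmentation`: `labels`,
#'   `arterial_id`, `venous_id`, `eroded_arterial_mask`,
#'   `eroded_venous_mask`, `summary` (cluster table with roles), `config`.
#' @export
segment_blood_pools <- function(series, config = cluster_config(),
                                mode = c("auto", "manual"), manual_ids = NULL) {
  mode <- match.arg(mode)
  labels <- cluster_voxel_tacs(series, config)
  sel <- select_blood_clusters(labels, series, mode, manual_ids)
  art <- erode_mask(labels == sel$arterial_id, config$erosion_iterations)
  ven <- erode_mask(labels == sel$venous_id, config$erosion_iterations)
  if (!any(art)) stop("arterial cluster vanished under erosion")
  if (!any(ven)) stop("venous cluster vanished under erosion")
  smry <- cluster_summary(labels, series)
  smry$role <- ifelse(smry$cluster_id == sel$arterial_id, "arterial",
                      ifelse(smry$cluster_id == sel$venous_id, "venous", "other"))
  structure(list(labels = labels,
                 arterial_id = sel$arterial_id, venous_id = sel$venous_id,
                 eroded_arterial_mask = art, eroded_venous_mask = ven,
                 summary = smry, config = config),
            class = "blood_pool_segmentation")
}

#' @export
print.blood_pool_segmentation <- function(x, ...) {
  cat(sprintf("blood_pool_segmentation: arterial id %d (%d voxels eroded), venous id %d (%d voxels eroded)\n",
              x$arterial_id, sum(x$eroded_arterial_mask),
              x$venous_id, sum(x$eroded_venous_mask)))
  invisible(x)
}
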