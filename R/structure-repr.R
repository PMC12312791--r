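#' Binary residue contact map
#'
#' Entry (i, j) is 1 iff the Euclidean CA-CA distance is strictly below the
#' threshold (default 7 Angstrom); the diagonal is set to 1, which makes the
#' identity matrix the degenerate single-residue case. The result is
#' symmetric by construction.
#'
#' @param coords Numeric matrix of CA coordinates (rows = residues).
#' @param threshold Contact threshold in Angstrom.
#' @return Integer 0/1 matrix `N x N` with attribute `threshold`.
#' @export
contact_map <- function(coords, threshold = 7) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("non-finite coordinate")
  d <- as.matrix(stats::dist(coords))
  cm <- (d < threshold) * 1L
  diag(cm) <- 1L
  storage.mode(cm) <- "integer"
  dimnames(cm) <- NULL
  attr(cm, "threshold") <- threshold
  cm
}

#' Fixed-size centralized point cloud
#'
#' Coordinates are first centred on their centroid. Proteins longer than
#' `n_points` are subsampled uniformly without replacement (seeded,
#' residue order preserved) and the retained subset is re-centred; shorter
#' proteins are zero-padded, with `pad_mask` marking real residues. Padded
#' rows are exactly (0, 0, 0).
#'
#' @param coords Numeric matrix of CA coordinates.
#' @param n_points Fixed cloud size (default 400).
#' @param seed Seed for the subsampling draw (ignored when `N <= n_points`).
#' @return An object of class `point_cloud`: list with `points`
#'   (`n_points x 3`), `pad_mask` (0/1 length `n_points`) and `n_real`.
#' @export
build_point_cloud <- function(coords, n_points = 400L, seed = 1L) {
  if (n_points < 1L) stopf("n_points must be >= 1")
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("non-finite coordinate")
  N <- nrow(coords)
  pts <- sweep(coords, 2, colMeans(coords))
  if (N > n_points) {
    idx <- with_local_seed(seed, sort(sample.int(N, n_points)))
    pts <- pts[idx, , drop = FALSE]
    pts <- sweep(pts, 2, colMeans(pts))
  }
  n_real <- nrow(pts)
  if (n_real < n_points) {
    pts <- rbind(pts, matrix(0, nrow = n_points - n_real, ncol = 3L))
  }
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(
    list(points = pts,
         pad_mask = c(rep(1L, n_real), rep(0L, n_points - n_real)),
         n_real = n_real),
    class = "point_cloud"
  )
}

#' Uniformly random rotation matrix
#'
#' Drawn by normalizing a 4-vector of independent standard normals to a unit
#' quaternion, which is uniform on the 3-D rotation group.
#'
#' @param seed Seed for the draw.
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @export
random_rotation_matrix <- function(seed = 1L) {
  q <- with_local_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Randomly rotate a point cloud
#'
#' Applies one uniform random rotation to the real points; rotation fixes
#' the origin, so padded rows and the (origin) centroid are unchanged, and
#' all pairwise distances are preserved.
#'
#' @param cloud A [build_point_cloud()] result.
#' @param seed Seed for the rotation draw.
#' @return A rotated `point_cloud`.
#' @export
random_rotation <- function(cloud, seed = 1L) {
  R <- random_rotation_matrix(seed)
  real <- cloud$pad_mask == 1L
  pts <- cloud$points
  pts[real, ] <- pts[real, , drop = FALSE] %*% t(R)
  cloud$points <- pts
  cloud
}

#' Rotation augmentation
#'
#' Returns `multiplicity` independently rotated copies of a cloud (default
#' 3, the training-set expansion factor used with rotation augmentation).
#'
#' @param cloud A `point_cloud`.
#' @param multiplicity Number of rotated copies.
#' @param seed Base seed; copy i uses a derived sub-seed.
#' @return List of `point_cloud` objects.
#' @export
augment_rotations <- function(cloud, multiplicity = 3L, seed = 1L) {
  lapply(seq_len(multiplicity), function(i) {
    random_rotation(cloud, derive_seed(seed, "rotation", i))
  })
}
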