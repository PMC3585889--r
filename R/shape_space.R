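#' Statistical shape space over signed distance functions
#'
#' Training masks are rigidly normalized (alignment model) to a canonical
#' frame, converted to signed distance functions (SDFs, negative inside),
#' and summarized by principal component analysis: any plausible organ
#' shape is approximated as
#' \deqn{\hat\phi = \bar\phi + W_p \, x_{pca}}
#' with mean SDF `phi_bar`, orthonormal eigenshape stack `W_p`, and
#' coefficients `x_pca`. The number of retained components `p` is the
#' smallest count whose eigenvalues cover the requested variance fraction
#' (default 0.988). When the space proves too poor for a case, the
#' alignment model absorbs a corrected mask and rebuilds the PCA, so the
#' shape space grows richer over use.
#'
#' @name shape-space
NULL

#' Signed distance function of a binary mask
#'
#' Euclidean distance transform of the background minus that of the object:
#' negative inside the object, positive outside, with the zero crossing on
#' the mask boundary (pixel-center convention: the first pixels on either
#' side of the boundary get -1 and +1).
#'
#' @param mask logical or 0/1 matrix with both object and background pixels.
#' @return numeric matrix (the SDF).
#' @export
sdf_from_mask <- function(mask) {
  m <- as_mask(mask)
  n <- sum(m)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  if (n == length(m)) stop("mask covers the whole frame", call. = FALSE)
  storage <- matrix(as.numeric(m), nrow(m), ncol(m))
  d_in <- as.matrix(EBImage::distmap(storage))        # distance to background
  d_out <- as.matrix(EBImage::distmap(1 - storage))   # distance to object
  d_out - d_in
}

# Area, centroid and principal-axis angle of a mask.
# Coordinates: x = column index, y = row index.
mask_moments <- function(mask) {
  m <- as_mask(mask)
  idx <- which(m, arr.ind = TRUE)
  area <- nrow(idx)
  if (area == 0L) stop("mask is empty", call. = FALSE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  dx <- idx[, 2] - cx; dy <- idx[, 1] - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  if (mu20 + mu02 < 1e-9)
    stop("degenerate mask: zero second moment", call. = FALSE)
  psi <- 0.5 * atan2(2 * mu11, mu20 - mu02)   # major axis angle, (-pi/2, pi/2]
  if (psi <= -pi / 2) psi <- psi + pi
  list(area = area, cx = cx, cy = cy, psi = psi)
}

#' Similarity pose parameters
#'
#' A pose maps image coordinates `x = (col, row)` to canonical-frame
#' coordinates via `q = center(frame) + s * R(theta) (x - (tx, ty))`;
#' `(tx, ty)` is the object center in image coordinates.
#'
#' @param tx,ty object center (pixels, image frame).
#' @param theta rotation (radians), wrapped to (-pi, pi].
#' @param s isotropic scale (> 0).
#' @return list of class `pose_params`.
#' @export
pose_params <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta), s > 0)
  theta <- ((theta + pi) %% (2 * pi)) - pi
  if (theta == -pi) theta <- pi
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
            class = "pose_params")
}

# 2x2 rotation matrix.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Map image coords (n x 2 matrix, columns x=col, y=row) to canonical frame.
pose_forward <- function(pts, pose, frame) {
  ctr <- c((frame[2] + 1) / 2, (frame[1] + 1) / 2)  # (x, y) of frame center
  v <- sweep(pts, 2, c(pose$tx, pose$ty))
  sweep(pose$s * (v %*% t(rot2(pose$theta))), 2, ctr, `+`)
}

# Map canonical coords back to image coords (inverse of pose_forward).
pose_backward <- function(pts, pose, frame) {
  ctr <- c((frame[2] + 1) / 2, (frame[1] + 1) / 2)
  v <- sweep(pts, 2, ctr)
  sweep((v %*% t(rot2(-pose$theta))) / pose$s, 2, c(pose$tx, pose$ty), `+`)
}

# Bilinear interpolation of matrix m at (xs, ys) (x = col, y = row),
# `outside` for samples beyond the grid.
bilinear_sample <- function(m, xs, ys, outside = 0) {
  H <- nrow(m); W <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  # clamp indices for safe subscripting; overwritten with `outside` later
  x0c <- pmin(pmax(x0, 1), W - 1); y0c <- pmin(pmax(y0, 1), H - 1)
  i00 <- (x0c - 1) * H + y0c
  v <- (1 - fx) * (1 - fy) * m[i00] +
    fx * (1 - fy) * m[i00 + H] +
    (1 - fx) * fy * m[i00 + 1] +
    fx * fy * m[i00 + H + 1]
  v[!ok] <- outside
  v
}

# Moment-based coarse pose of a mask against a target area in a frame.
moment_pose <- function(mask, target_area, frame) {
  mm <- mask_moments(mask)
  pose_params(tx = mm$cx, ty = mm$cy, theta = -mm$psi,
              s = sqrt(target_area / mm$area))
}

# Resample a mask into the canonical frame under a pose (bilinear + 0.5
# threshold).
warp_mask_to_canonical <- function(mask, pose, frame) {
  m <- matrix(as.numeric(as_mask(mask)), nrow(mask), ncol(mask))
  grid <- cbind(x = rep(seq_len(frame[2]), each = frame[1]),
                y = rep(seq_len(frame[1]), times = frame[2]))
  src <- pose_backward(grid, pose, frame)
  v <- bilinear_sample(m, src[, 1], src[, 2], outside = 0)
  matrix(v, frame[1], frame[2]) > 0.5
}

#' Align binary shapes to a canonical frame
#'
#' The alignment model: each mask is rigidly normalized by moving its
#' centroid to the frame center, rotating its principal axis (from second
#' central moments) to horizontal, and scaling its area to the mean
#' training area; the normalized mask is then converted to an SDF. The
#' remaining 180-degree principal-axis ambiguity is resolved by keeping the
#' orientation that best overlaps the running mean of the shapes aligned so
#' far (the first shape sets the reference).
#'
#' @param masks list of binary masks (matrices), each with a nonempty object.
#' @param frame canonical frame size `c(H, W)`.
#' @return list with `sdfs` (list of canonical-frame SDFs), `poses` (list of
#'   [pose_params()]), `aligned_masks`, and `mean_area`.
#' @export
align_shapes <- function(masks, frame = c(128L, 128L)) {
  if (length(masks) < 1L) stop("need at least one mask", call. = FALSE)
  areas <- vapply(seq_along(masks), function(i) {
    m <- as_mask(masks[[i]])
    a <- sum(m)
    if (a == 0L) stop("mask ", i, " is empty", call. = FALSE)
    a
  }, numeric(1))
  mean_area <- mean(areas)

  aligned <- vector("list", length(masks))
  poses <- vector("list", length(masks))
  run_mean <- NULL
  for (i in seq_along(masks)) {
    pose <- tryCatch(moment_pose(masks[[i]], mean_area, frame),
                     error = function(e)
                       stop("shape ", i, ": ", conditionMessage(e),
                            call. = FALSE))
    cand <- warp_mask_to_canonical(masks[[i]], pose, frame)
    if (!is.null(run_mean)) {
      pose_flip <- pose_params(pose$tx, pose$ty, pose$theta + pi, pose$s)
      cand_flip <- warp_mask_to_canonical(masks[[i]], pose_flip, frame)
      if (sum(cand_flip & (run_mean > 0.5)) > sum(cand & (run_mean > 0.5))) {
        pose <- pose_flip
        cand <- cand_flip
      }
    }
    if (sum(cand) == 0L)
      stop("shape ", i, " maps to an empty canonical mask", call. = FALSE)
    aligned[[i]] <- cand
    poses[[i]] <- pose
    run_mean <- if (is.null(run_mean)) cand * 1.0
    else (run_mean * (i - 1) + cand) / i
  }
  sdfs <- lapply(aligned, sdf_from_mask)
  list(sdfs = sdfs, poses = poses, aligned_masks = aligned,
       mean_area = mean_area)
}

#' Build a PCA shape space from aligned SDFs
#'
#' Flattens the SDFs, subtracts the pixelwise mean, and takes the singular
#' value decomposition; eigenvalues are the sample variances along each
#' component (divisor `n - 1`). The retained count `p` is the smallest
#' number of leading components whose cumulative variance fraction reaches
#' `variance_retained`, capped at `n - 1`.
#'
#' @param aligned list as returned by [align_shapes()], or a plain list of
#'   SDF matrices on a common frame.
#' @param variance_retained fraction of total variance to cover (0, 1].
#' @param training_masks optional list of the original masks (retained so
#'   the space can later be rebuilt when absorbing a new shape).
#' @param provenance character vector of labels, one per training shape.
#' @return object of class `shape_space`.
#' @export
build_shape_space <- function(aligned, variance_retained = 0.988,
                              training_masks = NULL, provenance = NULL) {
  stopifnot(variance_retained > 0, variance_retained <= 1)
  if (is.list(aligned) && !is.null(aligned$sdfs)) {
    sdfs <- aligned$sdfs
    mean_area <- aligned$mean_area
  } else {
    sdfs <- aligned
    mean_area <- NA_real_
  }
  n <- length(sdfs)
  if (n < 2L) stop("need at least two aligned SDFs", call. = FALSE)
  dims <- dim(sdfs[[1]])
  for (s in sdfs)
    if (!all(dim(s) == dims))
      stop("aligned SDFs must share one frame", call. = FALSE)

  X <- t(vapply(sdfs, as.vector, numeric(prod(dims))))   # n x HW
  mean_vec <- colMeans(X)
  Xc <- sweep(X, 2, mean_vec)
  sv <- svd(Xc, nu = 0, nv = min(n, prod(dims)))
  eig_all <- sv$d^2 / (n - 1)
  total <- sum(eig_all)

  if (total <= 1e-12) {
    p <- 0L
  } else {
    frac <- cumsum(eig_all) / total
    p <- which(frac >= variance_retained - 1e-12)[1]
    p <- min(p, n - 1L)
  }
  eigvecs <- if (p > 0L) array(sv$v[, seq_len(p)], dim = c(dims, p))
  else array(0, dim = c(dims, 0L))

  if (is.null(provenance)) provenance <- sprintf("shape_%02d", seq_len(n))
  structure(list(
    mean_sdf = matrix(mean_vec, dims[1], dims[2]),
    eigvecs = eigvecs,
    eigvals = if (p > 0L) eig_all[seq_len(p)] else numeric(0),
    eigvals_all = eig_all,
    p = as.integer(p),
    frame = as.integer(dims),
    n_train = as.integer(n),
    variance_retained = variance_retained,
    mean_area = mean_area,
    training_masks = training_masks,
    provenance = provenance
  ), class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cov <- if (sum(x$eigvals_all) > 0)
    sum(x$eigvals) / sum(x$eigvals_all) else 1
  cat(sprintf(
    "shape_space: %d training shapes on a %dx%d frame; %d components covering %.1f%% of variance\n",
    x$n_train, x$frame[1], x$frame[2], x$p, 100 * cov))
  invisible(x)
}

#' Build a shape space directly from training masks
#'
#' Convenience wrapper: [align_shapes()] followed by [build_shape_space()],
#' retaining the original masks for later absorption.
#'
#' @inheritParams align_shapes
#' @inheritParams build_shape_space
#' @return a `shape_space`.
#' @export
shape_space_from_masks <- function(masks, variance_retained = 0.988,
                                   frame = c(128L, 128L), provenance = NULL) {
  al <- align_shapes(masks, frame = frame)
  build_shape_space(al, variance_retained = variance_retained,
                    training_masks = masks, provenance = provenance)
}

#' Reconstruct a shape SDF from PCA coefficients
#'
#' Returns `phi_bar + sum_i x_pca[i] * W_p[,,i]`. The combination is only
#' approximately a signed distance function; downstream code uses its zero
#' level set.
#'
#' @param space a `shape_space`.
#' @param x_pca numeric vector of length `space$p`.
#' @return numeric matrix on the canonical frame.
#' @export
reconstruct_shape <- function(space, x_pca) {
  if (length(x_pca) != space$p)
    stop("expected ", space$p, " coefficients, got ", length(x_pca),
         call. = FALSE)
  out <- space$mean_sdf
  for (i in seq_len(space$p))
    out <- out + x_pca[i] * space$eigvecs[, , i]
  out
}

#' Project an SDF onto the shape space
#'
#' Least-squares coefficients of `sdf - phi_bar` on the orthonormal
#' eigenshapes.
#'
#' @param space a `shape_space`.
#' @param sdf canonical-frame SDF matrix.
#' @return numeric vector of length `space$p`.
#' @export
project_shape <- function(space, sdf) {
  if (!all(dim(sdf) == space$frame))
    stop("sdf is not on the canonical frame", call. = FALSE)
  d <- as.vector(sdf - space$mean_sdf)
  vapply(seq_len(space$p),
         function(i) sum(d * as.vector(space$eigvecs[, , i])),
         numeric(1))
}

#' Absorb a new shape into the space (alignment-model update)
#'
#' Re-runs alignment and PCA on the original training set plus the new
#' mask. The original shapes are never dropped, so previously
#' reconstructible shapes remain in the span and the space only grows.
#'
#' @param space a `shape_space` built with `training_masks` retained.
#' @param new_mask binary mask of the corrected shape to absorb.
#' @param provenance label for the new shape.
#' @return a new `shape_space` with `n_train` incremented.
#' @export
absorb_shape <- function(space, new_mask, provenance = "absorbed") {
  if (is.null(space$training_masks))
    stop("shape space was built without retaining its training masks",
         call. = FALSE)
  m <- as_mask(new_mask)
  if (sum(m) == 0L) stop("new mask is empty", call. = FALSE)
  mask_moments(m)  # errors on degenerate shapes before touching the space
  masks <- c(space$training_masks, list(m))
  shape_space_from_masks(masks,
                         variance_retained = space$variance_retained,
                         frame = space$frame,
                         provenance = c(space$provenance, provenance))
}

#' Serialize / load a shape space
#'
#' Single-file serialization of all shape-space fields (mean SDF,
#' eigenshapes, eigenvalues, frame, training masks, provenance) with a
#' format version attribute.
#'
#' @param space a `shape_space`.
#' @param path file path.
#' @return `read_shape_space` returns the `shape_space`.
#' @export
write_shape_space <- function(space, path) {
  stopifnot(inherits(space, "shape_space"))
  obj <- unclass(space)
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_shape_space
#' @export
read_shape_space <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unrecognized shape-space file version", call. = FALSE)
  obj$format_version <- NULL
  structure(obj, class = "shape_space")
}
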