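#' Shape-prior optimization of a binary segmentation
#'
#' After level-set evolution, the binary result is replaced by the member
#' of the PCA shape space that best explains it. With `phi` the signed
#' distance function of the binary mask and `h_xT` the similarity transform
#' (translation, rotation, isotropic scale) from image to canonical
#' coordinates, the shape energy is the contour integral
#' \deqn{F_{shape} = \oint \hat\phi^2(x_{pca}, h_{x_T}(x)) \,
#'   \delta_\varepsilon(\phi(x)) \, |\nabla\phi(x)| \, dx,}
#' the squared (approximate) distance from each boundary point of the mask
#' to the zero level set of the reconstructed shape, integrated along the
#' mask boundary. It is minimized by alternating gradient descent: each
#' iteration first updates the pose, then the eigencoefficients, each with
#' a backtracking step that never accepts an energy increase. Coefficients
#' are kept inside the plausibility box `|x_pca[i]| <= 3 sqrt(eigval[i])`.
#'
#' @name shape-fit
NULL

#' Shape-fit configuration
#'
#' @param step_pose initial pose step, in pixel-equivalent units (rotation
#'   and scale moves are expressed as the boundary displacement they cause).
#' @param step_pca initial coefficient step, as a fraction of
#'   `sqrt(eigval)` per component.
#' @param max_iters maximum alternating iterations.
#' @param tol relative energy-change stopping tolerance.
#' @param eps width (pixels) of the Dirac factor selecting the mask
#'   boundary band.
#' @return list of class `shape_fit_config`.
#' @export
shape_fit_config <- function(step_pose = 0.1, step_pca = 0.05,
                             max_iters = 200L, tol = 1e-5, eps = 1.5) {
  stopifnot(step_pose > 0, step_pca > 0, max_iters >= 1L, tol > 0, eps > 0)
  structure(list(step_pose = step_pose, step_pca = step_pca,
                 max_iters = as.integer(max_iters), tol = tol, eps = eps),
            class = "shape_fit_config")
}

# Bilinear sampling with coordinates clamped to the grid (values beyond the
# frame continue the boundary value).
bilinear_clamp <- function(m, xs, ys) {
  bilinear_sample(m,
                  pmin(pmax(xs, 1), ncol(m)),
                  pmin(pmax(ys, 1), nrow(m)),
                  outside = 0)
}

# Boundary-band description of a target mask: points, Dirac weights and
# gradient magnitude of its SDF. The co-area weight delta(phi)|grad phi|
# integrates over level-set rings whose length grows as (1 + phi*kappa)
# away from the zero set; dividing by that Jacobian removes the
# first-order outward bias the raw band sum would have on curved
# boundaries.
shape_fit_target <- function(mask, eps) {
  m <- as_mask(mask)
  sdf <- sdf_from_mask(m)
  band <- which(abs(sdf) < eps)
  if (length(band) == 0L) stop("empty boundary band", call. = FALSE)
  H <- nrow(sdf)
  rows <- ((band - 1L) %% H) + 1L
  cols <- ((band - 1L) %/% H) + 1L
  gx <- grad_x(sdf); gy <- grad_y(sdf)
  mag <- pmax(sqrt(gx^2 + gy^2), 1e-10)
  kappa <- divergence(gx / mag, gy / mag)
  jac <- pmin(pmax(1 + sdf[band] * kappa[band], 0.2), 5)
  w <- delta_eps(sdf[band], eps) * mag[band] / jac
  list(pts = cbind(x = cols, y = rows), w = w, sdf = sdf, dim = dim(sdf))
}

# Sample the mean and eigenshape fields (and optionally their spatial
# gradients) at canonical points q (n x 2).
sample_fields <- function(space, q, fields) {
  n <- nrow(q)
  M0 <- bilinear_clamp(space$mean_sdf, q[, 1], q[, 2])
  Vm <- if (space$p > 0L)
    vapply(seq_len(space$p),
           function(i) bilinear_clamp(space$eigvecs[, , i], q[, 1], q[, 2]),
           numeric(n))
  else matrix(0, n, 0L)
  out <- list(M0 = M0, Vm = matrix(Vm, n, space$p))
  if (!is.null(fields)) {
    out$Gx0 <- bilinear_clamp(fields$mx, q[, 1], q[, 2])
    out$Gy0 <- bilinear_clamp(fields$my, q[, 1], q[, 2])
    out$Gxm <- matrix(if (space$p > 0L)
      vapply(seq_len(space$p),
             function(i) bilinear_clamp(fields$vx[[i]], q[, 1], q[, 2]),
             numeric(n)) else 0, n, space$p)
    out$Gym <- matrix(if (space$p > 0L)
      vapply(seq_len(space$p),
             function(i) bilinear_clamp(fields$vy[[i]], q[, 1], q[, 2]),
             numeric(n)) else 0, n, space$p)
  }
  out
}

#' Shape energy of a state against a target mask
#'
#' Discretizes the shape-energy contour integral over the boundary band of
#' the target: `sum phi_hat(q)^2 * delta_eps(phi) * |grad phi|` with
#' `q = h_xT(x)` the pose-transformed band points and `phi_hat` the
#' PCA-reconstructed shape, sampled bilinearly (boundary-clamped).
#'
#' @param space a `shape_space`.
#' @param x_pca coefficient vector of length `space$p`.
#' @param pose a [pose_params()].
#' @param target binary mask, or a precomputed internal target object.
#' @param eps Dirac width (pixels) used when `target` is a mask.
#' @return nonnegative scalar.
#' @export
shape_energy <- function(space, x_pca, pose, target, eps = 1.5) {
  if (length(x_pca) != space$p)
    stop("expected ", space$p, " coefficients", call. = FALSE)
  tgt <- if (is.matrix(target)) shape_fit_target(target, eps) else target
  q <- pose_forward(tgt$pts, pose, space$frame)
  inside <- q[, 1] >= 1 & q[, 1] <= space$frame[2] &
    q[, 2] >= 1 & q[, 2] <= space$frame[1]
  if (!any(inside))
    stop("pose maps the entire boundary band outside the canonical frame",
         call. = FALSE)
  sm <- sample_fields(space, q, fields = NULL)
  phat <- sm$M0 + as.vector(sm$Vm %*% x_pca)
  sum(phat^2 * tgt$w)
}

# Energy + analytic gradients wrt x_pca and pose at one state.
shape_fit_grads <- function(space, x_pca, pose, tgt, fields) {
  q <- pose_forward(tgt$pts, pose, space$frame)
  sm <- sample_fields(space, q, fields)
  phat <- sm$M0 + as.vector(sm$Vm %*% x_pca)
  E <- sum(phat^2 * tgt$w)

  fw <- 2 * phat * tgt$w
  g_pca <- as.vector(crossprod(sm$Vm, fw))

  Gx <- sm$Gx0 + as.vector(sm$Gxm %*% x_pca)
  Gy <- sm$Gy0 + as.vector(sm$Gym %*% x_pca)
  R <- rot2(pose$theta)
  Rp <- matrix(c(-sin(pose$theta), cos(pose$theta),
                 -cos(pose$theta), -sin(pose$theta)), 2, 2)
  v <- sweep(tgt$pts, 2, c(pose$tx, pose$ty))
  dq_th <- pose$s * (v %*% t(Rp))
  dq_s <- v %*% t(R)
  g_pose <- c(
    tx = sum(fw * (-pose$s) * (Gx * R[1, 1] + Gy * R[2, 1])),
    ty = sum(fw * (-pose$s) * (Gx * R[1, 2] + Gy * R[2, 2])),
    theta = sum(fw * (Gx * dq_th[, 1] + Gy * dq_th[, 2])),
    s = sum(fw * (Gx * dq_s[, 1] + Gy * dq_s[, 2]))
  )
  list(E = E, g_pca = g_pca, g_pose = g_pose)
}

#' Render the mask of a posed shape-space member
#'
#' Evaluates the reconstructed shape at every image pixel through the pose
#' and thresholds its zero level set; pixels mapping outside the canonical
#' frame are background.
#'
#' @param space a `shape_space`.
#' @param x_pca coefficients of length `space$p`.
#' @param pose a [pose_params()].
#' @param dim output image size `c(H, W)`.
#' @return logical mask.
#' @export
render_fitted_mask <- function(space, x_pca, pose, dim) {
  phat <- reconstruct_shape(space, x_pca)
  grid <- cbind(x = rep(seq_len(dim[2]), each = dim[1]),
                y = rep(seq_len(dim[1]), times = dim[2]))
  q <- pose_forward(grid, pose, space$frame)
  v <- bilinear_sample(phat, q[, 1], q[, 2],
                       outside = sum(space$frame))  # far outside: background
  matrix(v, dim[1], dim[2]) < 0
}

#' Keep the largest component and fill holes of a binary mask
#'
#' Standard cleanup of a raw level-set mask before shape fitting: isolated
#' speckle responses are dropped and interior holes filled.
#'
#' @param mask binary matrix.
#' @return logical mask.
#' @export
clean_binary_mask <- function(mask) {
  m <- as_mask(mask)
  if (sum(m) == 0L) return(m)
  lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m))))
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  m <- lab == keep
  filled <- as.matrix(EBImage::fillHull(matrix(as.numeric(m), nrow(m), ncol(m))))
  filled > 0.5
}

#' Fit the shape space to a binary mask
#'
#' Alternating gradient descent on the shape energy: each iteration updates
#' the pose first, then the eigencoefficients, with per-block adaptive
#' backtracking steps (a step is halved until the energy does not increase,
#' and grown after an accepted move). The initial pose comes from the
#' moment-based coarse alignment of the mask against the mean training
#' area; the 180-degree principal-axis ambiguity is resolved by starting
#' from whichever orientation has the lower energy at zero coefficients.
#'
#' @param space a `shape_space` (with a known mean training area, i.e.
#'   built through [align_shapes()]/[shape_space_from_masks()]), unless
#'   `init_pose` is supplied.
#' @param mask binary segmentation to optimize (e.g. the level-set result).
#' @param init_pose optional [pose_params()] overriding the moment
#'   initialization.
#' @param cfg a [shape_fit_config()].
#' @param clean if `TRUE` (default), apply [clean_binary_mask()] to the
#'   input first.
#' @param max_area optional upper bound (pixels) on the fitted shape's
#'   image-frame area, typically the area of the region-of-interest box the
#'   organ is known to lie in; implemented as a floor on the pose scale, it
#'   keeps the prior from inflating onto a leaked level-set mask.
#' @return list of class `shape_fit` with `x_pca`, `pose`, `energy`,
#'   `iterations`, `trace` (energy per accepted iteration), `converged`,
#'   and `mask` (the fitted mask rendered on the input frame).
#' @export
fit_shape <- function(space, mask, init_pose = NULL,
                      cfg = shape_fit_config(), clean = TRUE,
                      max_area = NULL) {
  m <- as_mask(mask)
  if (sum(m) == 0L) stop("mask is empty", call. = FALSE)
  if (clean) m <- clean_binary_mask(m)
  tgt <- shape_fit_target(m, cfg$eps)

  # a pose scale below s_min would render a shape larger than max_area
  s_min <- if (!is.null(max_area) && !is.na(space$mean_area))
    sqrt(space$mean_area / max_area) else 1e-3

  if (is.null(init_pose)) {
    if (is.na(space$mean_area))
      stop("shape space has no mean training area; supply init_pose",
           call. = FALSE)
    init_pose <- moment_pose(m, space$mean_area, space$frame)
    if (init_pose$s < s_min)
      init_pose <- pose_params(init_pose$tx, init_pose$ty, init_pose$theta,
                               s_min)
  }
  p <- space$p
  x <- numeric(p)
  box <- 3 * sqrt(pmax(space$eigvals, 0))

  # 180-degree ambiguity: pick the cheaper of theta and theta + pi
  pose <- init_pose
  e0 <- shape_energy(space, x, pose, tgt)
  pose_flip <- pose_params(pose$tx, pose$ty, pose$theta + pi, pose$s)
  e0f <- tryCatch(shape_energy(space, x, pose_flip, tgt), error = function(e) Inf)
  if (e0f < e0) {
    pose <- pose_flip
    e0 <- e0f
  }

  # precomputed spatial gradients of the mean and eigenshape fields
  fields <- list(
    mx = grad_x(space$mean_sdf), my = grad_y(space$mean_sdf),
    vx = lapply(seq_len(p), function(i) grad_x(space$eigvecs[, , i])),
    vy = lapply(seq_len(p), function(i) grad_y(space$eigvecs[, , i])))

  # characteristic radius for expressing rotation/scale moves in pixels
  v0 <- sweep(tgt$pts, 2, c(pose$tx, pose$ty))
  rbar <- max(mean(sqrt(rowSums(v0^2))), 1)

  energy <- e0
  e_init <- e0
  trace <- energy
  st_pose <- cfg$step_pose
  st_pca <- cfg$step_pca
  converged <- FALSE

  for (it in seq_len(cfg$max_iters)) {
    gr <- shape_fit_grads(space, x, pose, tgt, fields)

    # --- pose block (updated first) ---
    d <- -gr$g_pose * c(1, 1, 1 / rbar^2, 1 / rbar^2)
    px_norm <- max(abs(d[1]), abs(d[2]), rbar * abs(d[3]), rbar * abs(d[4]))
    if (px_norm > 0) {
      d <- d / px_norm
      step <- st_pose
      accepted <- FALSE
      while (step > 1e-7) {
        cand <- pose_params(pose$tx + step * d[1], pose$ty + step * d[2],
                            pose$theta + step * d[3],
                            max(pose$s + step * d[4], s_min))
        e_c <- tryCatch(shape_energy(space, x, cand, tgt),
                        error = function(e) Inf)
        if (e_c <= energy) {
          pose <- cand
          energy <- e_c
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      st_pose <- if (accepted) min(step * 1.5, 2) else max(step, 1e-6)
    }
    if (pose$s < 0.1 || pose$s > 10)
      stop("shape fit diverged: scale left [0.1, 10] at iteration ", it,
           call. = FALSE)

    # --- coefficient block ---
    if (p > 0L) {
      gr2 <- shape_fit_grads(space, x, pose, tgt, fields)
      d <- -gr2$g_pca
      sd_units <- max(abs(d) / pmax(sqrt(space$eigvals), 1e-8))
      if (sd_units > 0) {
        d <- d / sd_units
        step <- st_pca
        accepted <- FALSE
        while (step > 1e-8) {
          cand <- pmin(pmax(x + step * d, -box), box)
          e_c <- shape_energy(space, cand, pose, tgt)
          if (e_c <= energy) {
            x <- cand
            energy <- e_c
            accepted <- TRUE
            break
          }
          step <- step / 2
        }
        st_pca <- if (accepted) min(step * 1.5, 1) else max(step, 1e-7)
      }
    }

    if (energy > 10 * max(e_init, 1e-12))
      stop("shape fit diverged: energy exceeded 10x its initial value",
           call. = FALSE)
    prev <- trace[length(trace)]
    trace <- c(trace, energy)
    if (abs(prev - energy) <= cfg$tol * max(prev, 1e-12)) {
      converged <- TRUE
      break
    }
  }

  structure(list(x_pca = x, pose = pose, energy = energy,
                 iterations = length(trace) - 1L, trace = trace,
                 converged = converged,
                 mask = render_fitted_mask(space, x, pose, dim(m))),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf(
    "shape_fit: energy %.4g after %d iterations (%s); pose t=(%.2f, %.2f), theta=%.3f rad, s=%.3f\n",
    x$energy, x$iterations, if (x$converged) "converged" else "max iterations",
    x$pose$tx, x$pose$ty, x$pose$theta, x$pose$s))
  invisible(x)
}
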