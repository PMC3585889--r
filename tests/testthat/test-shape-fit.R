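make_space <- function(seed = 7, n = 20) {
  train <- generate_training_set(n, seed = seed)
  shape_space_from_masks(train$masks)
}

test_that("shape energy is near zero at self-consistency and grows away", {
  space <- make_space()
  pose <- pose_params(tx = 64.5 + 3, ty = 64.5 - 2, theta = 5 * pi / 180,
                      s = 1.05)
  set.seed(21)
  x_true <- runif(space$p, -1, 1) * sqrt(space$eigvals)
  target <- render_fitted_mask(space, x_true, pose, c(128L, 128L))

  e_true <- shape_energy(space, x_true, pose, target)
  band <- sum(abs(sdf_from_mask(target)) < 1.5)
  # mean squared boundary distance well below the pixel quantization of
  # the rendered mask (|phi_hat| at band pixels is at most ~0.5)
  expect_lt(e_true, 0.1 * band)

  # mean shape at the same pose scores strictly worse than the truth
  e_mean <- shape_energy(space, numeric(space$p), pose, target)
  expect_lt(e_true, e_mean)

  # translating the pose raises the energy, consistent with direct
  # re-evaluation of the discretized integral
  pose_off <- pose_params(pose$tx + 5, pose$ty, pose$theta, pose$s)
  e_off <- shape_energy(space, x_true, pose_off, target)
  expect_gt(e_off, e_true)

  far <- pose_params(tx = 1e4, ty = 1e4, theta = 0, s = 1)
  expect_error(shape_energy(space, x_true, far, target), "outside")
})

test_that("analytic gradients agree with finite differences", {
  space <- make_space()
  pose <- pose_params(64.5, 64.5, 0.1, 1.02)
  set.seed(5)
  x <- runif(space$p, -0.5, 0.5) * sqrt(space$eigvals)
  target <- render_fitted_mask(space, x, pose_params(66, 63, 0, 1),
                               c(128L, 128L))
  tgt <- kuseg:::shape_fit_target(target, 1.5)
  fields <- list(
    mx = kuseg:::grad_x(space$mean_sdf), my = kuseg:::grad_y(space$mean_sdf),
    vx = lapply(seq_len(space$p), function(i) kuseg:::grad_x(space$eigvecs[, , i])),
    vy = lapply(seq_len(space$p), function(i) kuseg:::grad_y(space$eigvecs[, , i])))
  gr <- kuseg:::shape_fit_grads(space, x, pose, tgt, fields)

  # coefficients: central finite differences
  for (i in c(1, space$p)) {
    hstep <- 1e-4 * sqrt(space$eigvals[i])
    xp <- x; xp[i] <- xp[i] + hstep
    xm <- x; xm[i] <- xm[i] - hstep
    fd <- (shape_energy(space, xp, pose, tgt) -
             shape_energy(space, xm, pose, tgt)) / (2 * hstep)
    expect_equal(gr$g_pca[i], fd, tolerance = 1e-2)
  }
  # pose: translation component
  hstep <- 1e-4
  pp <- pose_params(pose$tx + hstep, pose$ty, pose$theta, pose$s)
  pm <- pose_params(pose$tx - hstep, pose$ty, pose$theta, pose$s)
  fd <- (shape_energy(space, x, pp, tgt) -
           shape_energy(space, x, pm, tgt)) / (2 * hstep)
  # analytic spatial gradients are central-difference fields sampled
  # bilinearly, not exact derivatives of the interpolant: ~2% agreement
  expect_equal(unname(gr$g_pose["tx"]), fd, tolerance = 0.03)
})

test_that("fitting the mean shape at a known pose returns near-zero state", {
  space <- make_space()
  pose <- pose_params(64.5 + 3, 64.5 - 2, 5 * pi / 180, 1.05)
  m <- render_fitted_mask(space, numeric(space$p), pose, c(128L, 128L))
  fit <- fit_shape(space, m)
  expect_lt(abs(fit$pose$tx - pose$tx), 0.5)
  expect_lt(abs(fit$pose$ty - pose$ty), 0.5)
  expect_lt(abs(fit$pose$theta - pose$theta), 1 * pi / 180)
  expect_lt(abs(fit$pose$s - pose$s), 0.02)
  expect_gte(dice_coef(fit$mask, m), 0.98)
})

test_that("ground-truth coefficients and pose are recovered", {
  space <- make_space()
  pose <- pose_params(64.5 + 3, 64.5 - 2, 5 * pi / 180, 1.05)
  set.seed(11)
  x_true <- runif(space$p, -2, 2) * sqrt(space$eigvals)
  x_true <- pmin(pmax(x_true, -2 * sqrt(space$eigvals)),
                 2 * sqrt(space$eigvals))
  m <- render_fitted_mask(space, x_true, pose, c(128L, 128L))
  fit <- fit_shape(space, m)
  expect_lt(abs(fit$pose$tx - pose$tx), 1)
  expect_lt(abs(fit$pose$ty - pose$ty), 1)
  expect_lt(abs(fit$pose$theta - pose$theta), 2 * pi / 180)
  expect_lt(abs(fit$pose$s / pose$s - 1), 0.02)
  expect_gte(dice_coef(fit$mask, m), 0.98)

  # energy trace non-increasing (backtracking contract)
  expect_true(all(diff(fit$trace) <= 1e-12 * pmax(fit$trace[-length(fit$trace)], 1)))

  # the returned mask is exactly the rendered posed shape-space member
  expect_identical(fit$mask,
                   render_fitted_mask(space, fit$x_pca, fit$pose,
                                      dim(m)))
  # coefficients satisfy the plausibility box
  expect_true(all(abs(fit$x_pca) <= 3 * sqrt(space$eigvals) + 1e-12))
})

test_that("fit is robust to salt-noise corruption of the mask", {
  space <- make_space()
  pose <- pose_params(64.5 + 3, 64.5 - 2, 5 * pi / 180, 1.05)
  set.seed(12)
  x_true <- runif(space$p, -1, 1) * sqrt(space$eigvals)
  clean <- render_fitted_mask(space, x_true, pose, c(128L, 128L))
  flip <- matrix(runif(128 * 128) < 0.05, 128, 128)
  noisy <- xor(clean, flip)
  fit <- fit_shape(space, noisy)
  expect_gte(dice_coef(fit$mask, clean), 0.95)
})

test_that("integer translations shift the pose and leave coefficients", {
  space <- make_space()
  pose <- pose_params(60, 62, 0.05, 1.0)
  set.seed(14)
  x_true <- runif(space$p, -1, 1) * sqrt(space$eigvals)
  m <- render_fitted_mask(space, x_true, pose, c(128L, 128L))
  m_sh <- kuseg:::shift_mat(m * 1, 4, -6) > 0.5   # move +6 in x, -4 in y
  fit0 <- fit_shape(space, m)
  fit1 <- fit_shape(space, m_sh)
  expect_lt(abs(fit1$pose$tx - fit0$pose$tx - 6), 0.5)
  expect_lt(abs(fit1$pose$ty - fit0$pose$ty + 4), 0.5)
  expect_lt(max(abs(fit1$x_pca - fit0$x_pca) / sqrt(space$eigvals[1])), 1e-2)
})

test_that("mask cleanup removes specks and fills holes", {
  m <- blob_mask(64, 3)
  noisy <- m
  noisy[2, 2] <- TRUE          # isolated speck
  inside <- which(m, arr.ind = TRUE)
  mid <- inside[which.min(abs(inside[, 1] - mean(inside[, 1])) +
                            abs(inside[, 2] - mean(inside[, 2]))), ]
  noisy[mid[1], mid[2]] <- FALSE  # interior hole
  cleaned <- clean_binary_mask(noisy)
  expect_identical(cleaned, m)
})
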