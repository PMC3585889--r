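test_that("sdf_from_mask gives signed pixel-center distances", {
  # half-plane: values along a row are ..., -2, -1, +1, +2, ...
  m <- matrix(FALSE, 16, 16); m[, 1:8] <- TRUE
  sdf <- sdf_from_mask(m)
  expect_equal(sdf[5, ], c(-8:-1, 1:8))

  # single pixel object: radial distance, monotone along a row
  m2 <- matrix(FALSE, 15, 15); m2[8, 8] <- TRUE
  sdf2 <- sdf_from_mask(m2)
  expect_equal(sdf2[8, 8:15], c(-1, 1:7))
  expect_true(all(diff(sdf2[8, 8:15]) > 0))

  expect_error(sdf_from_mask(matrix(FALSE, 8, 8)), "empty")
  expect_error(sdf_from_mask(matrix(TRUE, 8, 8)), "whole frame")
})

test_that("sdf magnitude matches brute-force nearest-opposite search", {
  m <- blob_mask(48, seed = 5)
  sdf <- sdf_from_mask(m)
  ref <- bruteforce_abs_sdf(m)
  expect_lt(max(abs(abs(sdf) - ref)), 0.75)
  # sign flips exactly across the mask boundary
  expect_true(all(sdf[m] < 0))
  expect_true(all(sdf[!m] > 0))
})

test_that("sdf sign mask round trip is idempotent", {
  m <- blob_mask(48, seed = 11)
  sdf <- sdf_from_mask(m)
  m2 <- lsf_to_mask(sdf)
  expect_identical(m2, m)
  expect_identical(sign(sdf_from_mask(m2)), sign(sdf))
})

test_that("alignment is translation invariant and recovers rotations", {
  base <- generate_phantom(phantom_spec(frame = c(96L, 96L),
                                        axes = c(24, 14), seed = 2))
  shifted <- kuseg:::shift_mat(base * 1, 6, -9) > 0.5
  al <- align_shapes(list(base, shifted), frame = c(96L, 96L))
  expect_lt(max(abs(al$sdfs[[1]] - al$sdfs[[2]])), 1e-6)
  expect_equal(al$poses[[2]]$tx - al$poses[[1]]$tx, 9)
  expect_equal(al$poses[[2]]$ty - al$poses[[1]]$ty, -6)

  # rotated copy aligns onto the unrotated one
  rot <- generate_phantom(phantom_spec(frame = c(96L, 96L),
                                       axes = c(24, 14), angle = 0.5,
                                       seed = 2))
  al2 <- align_shapes(list(base, rot), frame = c(96L, 96L))
  diff_rms <- sqrt(mean((al2$sdfs[[1]] - al2$sdfs[[2]])^2))
  expect_lt(diff_rms, 0.5)
})

test_that("re-aligning an aligned shape is close to the identity pose", {
  base <- generate_phantom(phantom_spec(frame = c(96L, 96L),
                                        axes = c(24, 14), angle = 0.3,
                                        seed = 4))
  al <- align_shapes(list(base), frame = c(96L, 96L))
  al2 <- align_shapes(al$aligned_masks, frame = c(96L, 96L))
  p <- al2$poses[[1]]
  expect_lt(abs(p$tx - 48.5), 0.5)
  expect_lt(abs(p$ty - 48.5), 0.5)
  expect_lt(abs(p$theta), 0.05)
  expect_lt(abs(p$s - 1), 0.02)
})

test_that("degenerate and empty masks are rejected with the shape index", {
  good <- blob_mask(32, 3)
  bad <- matrix(FALSE, 32, 32)
  expect_error(align_shapes(list(good, bad)), "mask 2 is empty")
})

test_that("PCA matches the dense-covariance eigendecomposition oracle", {
  train <- generate_training_set(20, ranges = small_ranges(), seed = 7, frame = c(64L, 64L))
  al <- align_shapes(train$masks, frame = c(64L, 64L))
  space <- build_shape_space(al, variance_retained = 0.988)

  ref <- bruteforce_pca_eigvals(al$sdfs)
  expect_lt(max(abs(ref[seq_len(space$p)] - space$eigvals) /
                  space$eigvals), 1e-8)

  # component count matches the oracle's cumulative-sum count
  p_ref <- which(cumsum(ref) / sum(ref) >= 0.988)[1]
  expect_identical(space$p, as.integer(p_ref))

  # orthonormality and ordering invariants
  V <- vapply(seq_len(space$p), function(i) as.vector(space$eigvecs[, , i]),
              numeric(64 * 64))
  gram <- crossprod(V)
  expect_lt(max(abs(gram - diag(space$p))), 1e-8)
  expect_true(all(diff(space$eigvals) <= 0))
  expect_true(all(space$eigvals >= 0))
  expect_lte(space$p, space$n_train - 1L)
})

test_that("degenerate training sets behave as prescribed", {
  m <- blob_mask(32, 3)
  sdf <- sdf_from_mask(m)
  # identical SDFs: mean equals them, eigenvalues all essentially zero
  sp <- build_shape_space(list(sdf, sdf, sdf), variance_retained = 0.99)
  expect_equal(sp$mean_sdf, sdf)
  expect_true(all(sp$eigvals_all <= 1e-10))

  # two distinct SDFs: one nonzero eigenvalue, eigvec is the difference
  m2 <- blob_mask(32, 8)
  sdf2 <- sdf_from_mask(m2)
  sp2 <- build_shape_space(list(sdf, sdf2), variance_retained = 0.99)
  expect_identical(sp2$p, 1L)
  expect_gt(sp2$eigvals[1], 0)
  if (length(sp2$eigvals_all) > 1)
    expect_lt(sp2$eigvals_all[2] / sp2$eigvals_all[1], 1e-10)
  d <- as.vector(sdf2 - sdf); d <- d / sqrt(sum(d^2))
  v <- as.vector(sp2$eigvecs[, , 1])
  expect_lt(min(max(abs(v - d)), max(abs(v + d))), 1e-8)

  expect_error(build_shape_space(list(sdf, sdf2[1:16, 1:16])), "frame")
})

test_that("reconstruction is linear and full rank recovers training shapes", {
  train <- generate_training_set(8, ranges = small_ranges(), seed = 3, frame = c(64L, 64L))
  al <- align_shapes(train$masks, frame = c(64L, 64L))
  space <- build_shape_space(al, variance_retained = 1)

  expect_equal(reconstruct_shape(space, numeric(space$p)), space$mean_sdf)

  set.seed(5)
  x <- rnorm(space$p)
  lhs <- reconstruct_shape(space, 2 * x) - space$mean_sdf
  rhs <- 2 * (reconstruct_shape(space, x) - space$mean_sdf)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  for (i in c(1, 4, 8)) {
    xp <- project_shape(space, al$sdfs[[i]])
    expect_lt(max(abs(reconstruct_shape(space, xp) - al$sdfs[[i]])), 1e-6)
  }
  expect_error(reconstruct_shape(space, numeric(space$p + 1)), "coefficients")
})

test_that("absorbing shapes grows the space without losing the old span", {
  train <- generate_training_set(6, ranges = small_ranges(), seed = 9, frame = c(64L, 64L))
  space <- shape_space_from_masks(train$masks, variance_retained = 1,
                                  frame = c(64L, 64L))

  # duplicate absorption: rank unchanged, old shapes still reconstruct
  sp_dup <- absorb_shape(space, train$masks[[2]])
  expect_identical(sp_dup$n_train, 7L)
  al_dup <- align_shapes(c(train$masks, train$masks[2]), frame = c(64L, 64L))
  for (i in c(1, 5)) {
    xp <- project_shape(sp_dup, al_dup$sdfs[[i]])
    expect_lt(max(abs(reconstruct_shape(sp_dup, xp) - al_dup$sdfs[[i]])),
              1e-6)
  }

  # novel shape: residual at fixed retention strictly decreases, and the
  # new shape reconstructs at full rank
  lobed <- generate_phantom(phantom_spec(frame = c(64L, 64L),
                                         axes = c(22, 12), bend = 0.02,
                                         notch_depth = 0.4,
                                         fourier_amps = c(2, 1.5),
                                         seed = 77))
  space98 <- shape_space_from_masks(train$masks, variance_retained = 0.988,
                                    frame = c(64L, 64L))
  resid <- function(sp, mask) {
    al <- align_shapes(c(train$masks, list(mask)), frame = c(64L, 64L))
    sdf <- al$sdfs[[length(al$sdfs)]]
    # residual in the canonical frame at the space's retained rank
    xp <- project_shape(sp, sdf)
    sqrt(mean((reconstruct_shape(sp, xp) - sdf)^2))
  }
  before <- resid(space98, lobed)
  sp_new <- absorb_shape(space98, lobed)
  expect_identical(sp_new$n_train, 7L)
  after <- resid(sp_new, lobed)
  expect_lt(after, before)

  sp_full <- absorb_shape(space, lobed)
  al_new <- align_shapes(c(train$masks, list(lobed)), frame = c(64L, 64L))
  xp <- project_shape(sp_full, al_new$sdfs[[7]])
  expect_lt(max(abs(reconstruct_shape(sp_full, xp) - al_new$sdfs[[7]])), 1e-6)

  expect_error(absorb_shape(space, matrix(FALSE, 64, 64)), "empty")
})

test_that("shape spaces serialize and reload losslessly", {
  train <- generate_training_set(4, ranges = small_ranges(), seed = 13, frame = c(64L, 64L))
  space <- shape_space_from_masks(train$masks, frame = c(64L, 64L))
  path <- tempfile(fileext = ".rds")
  write_shape_space(space, path)
  back <- read_shape_space(path)
  expect_equal(back, space)
  unlink(path)
})
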