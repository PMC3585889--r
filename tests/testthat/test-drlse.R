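make_grid <- function(n) {
  list(x = matrix(rep(seq_len(n), each = n), n, n),
       y = matrix(rep(seq_len(n), times = n), n, n))
}

test_that("edge indicator has the required form and locates a step edge", {
  const <- matrix(0.4, 32, 32)
  e <- edge_indicator(const, sigma = 1.5)
  expect_equal(max(abs(e$g - 1)), 0)

  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  e2 <- edge_indicator(step, sigma = 1.5)
  expect_true(min(e2$g) > 0)
  expect_true(max(e2$g) <= 1)
  # minimum of g along each row sits at the step (between columns 32-33)
  mins <- apply(e2$g[10:50, ], 1, which.min)
  expect_true(all(abs(mins - 32.5) <= 1))
  # matches a direct convolve-and-differentiate oracle at an interior pixel
  k <- exp(-(-5:5)^2 / (2 * 1.5^2)); k <- k / sum(k)
  sm_row <- stats::convolve(step[32, ], rev(k), type = "open")[6:69]
  gx <- (sm_row[34] - sm_row[32]) / 2 * e2$grad_scale
  expect_equal(e2$g[32, 33], 1 / (1 + gx^2), tolerance = 1e-6)

  bad <- const; bad[1, 1] <- Inf
  expect_error(edge_indicator(bad), "non-finite")
})

test_that("binary-step initialization and mask round trips", {
  seed <- matrix(FALSE, 32, 32); seed[10:20, 12:25] <- TRUE
  phi0 <- initialize_lsf(seed, c0 = 2)
  expect_true(all(phi0[seed] == -2))
  expect_true(all(phi0[!seed] == 2))
  expect_identical(lsf_to_mask(phi0), seed)

  expect_error(initialize_lsf(matrix(FALSE, 8, 8)), "empty")
  expect_error(initialize_lsf(matrix(TRUE, 8, 8)), "whole frame")
  expect_identical(lsf_to_mask(matrix(2, 5, 5)), matrix(FALSE, 5, 5))
  # phi = 0 boundary pixels are background
  expect_identical(lsf_to_mask(matrix(0, 3, 3)), matrix(FALSE, 3, 3))
})

test_that("disk mask pixel count matches a brute-force distance count", {
  g <- make_grid(64)
  d <- sqrt((g$x - 32.5)^2 + (g$y - 32.5)^2)
  phi <- d - 10.5
  expect_equal(sum(lsf_to_mask(phi)), sum(d < 10.5))
})

test_that("energy terms behave as the functional prescribes", {
  g1 <- list(g = matrix(1, 128, 128))
  cfg <- drlse_config(eps = 1.5)
  gr <- make_grid(128)

  # analytic disk SDF: R tiny, L close to the circumference
  sdf <- sqrt((gr$x - 64.5)^2 + (gr$y - 64.5)^2) - 20
  en <- drlse_energy(sdf, g1, cfg)
  expect_lt(en$R / length(sdf), 1e-2)
  expect_lt(abs(en$L - 2 * pi * 20) / (2 * pi * 20), 0.05)

  # no zero crossing, all positive: L and A vanish
  en2 <- drlse_energy(sdf + 40, g1, cfg)
  expect_lt(en2$L, 1e-10)
  expect_lt(en2$A, 1e-10)

  expect_error(drlse_energy(sdf, list(g = matrix(1, 8, 8)), cfg),
               "dimensions")
})

test_that("evolution on a clean ellipse image recovers the shape", {
  truth <- generate_phantom(phantom_spec(axes = c(38, 24)))
  img <- render_ultrasound(truth, speckle_spec(sigma_s = 0, blur_sigma = 1))
  edge <- edge_indicator(img, sigma = 1.5)
  phi0 <- initialize_lsf(seed_from_truth(truth, 0.30), 2)
  phi <- drlse_evolve(phi0, edge, drlse_config(iters = 500L))
  expect_gte(dice_coef(lsf_to_mask(phi), truth), 0.97)
})

test_that("pure inward ballooning shrinks a disk monotonically", {
  gr <- make_grid(64)
  seed <- sqrt((gr$x - 32.5)^2 + (gr$y - 32.5)^2) < 20
  edge <- list(g = matrix(1, 64, 64))
  phi <- sdf_from_mask(seed)   # live interface from the start
  cfg <- drlse_config(lam = 0.01, alpha = 1.5, iters = 30L)
  areas <- numeric(6)
  for (k in 1:6) {
    phi <- drlse_evolve(phi, edge, cfg)
    areas[k] <- sum(lsf_to_mask(phi))
  }
  expect_true(all(diff(areas) < 0))
  expect_lt(areas[6], sum(seed))
})

test_that("energy descends after the interface-formation transient", {
  truth <- generate_phantom(phantom_spec(axes = c(38, 24), angle = 0.3))
  img <- render_ultrasound(truth, speckle_spec(sigma_s = 0, blur_sigma = 1))
  edge <- edge_indicator(img, sigma = 1.5)
  phi0 <- initialize_lsf(seed_from_truth(truth, 0.30), 2)
  phi <- drlse_evolve(phi0, edge, drlse_config(iters = 400L),
                      track_energy = TRUE)
  tr <- attr(phi, "energy_trace")
  rel <- diff(tr) / abs(tr[-length(tr)])
  # cumulative descent overall, and per-step increases bounded to
  # explicit-Euler noise once the smoothed interface exists
  expect_lt(tr[length(tr)], tr[1])
  expect_lt(max(rel[100:length(rel)]), 1e-4)
})

test_that("signed-distance character is maintained without reinitialization", {
  truth <- generate_phantom(phantom_spec(axes = c(38, 24), angle = 0.3))
  img <- render_ultrasound(truth, speckle_spec(sigma_s = 0, blur_sigma = 1))
  edge <- edge_indicator(img, sigma = 1.5)
  phi0 <- initialize_lsf(seed_from_truth(truth, 0.30), 8)
  phi <- drlse_evolve(phi0, edge, drlse_config(iters = 500L, c0 = 8))
  px <- (phi[, c(2:128, 128)] - phi[, c(1, 1:127)]) / 2
  py <- (phi[c(2:128, 128), ] - phi[c(1, 1:127), ]) / 2
  mag <- sqrt(px^2 + py^2)
  band <- abs(phi) < 6
  expect_gt(sum(band), 1000)
  expect_lte(mean(abs(mag[band] - 1)), 0.2)
})

test_that("evolution is equivariant under 90-degree rotation", {
  truth <- generate_phantom(phantom_spec(axes = c(30, 18), angle = 0.3))
  img <- render_ultrasound(truth, speckle_spec(sigma_s = 0.2, seed = 4))
  cfg <- drlse_config(iters = 100L)
  phiA <- drlse_evolve(initialize_lsf(seed_from_truth(truth, 0.3), 2),
                       edge_indicator(img, 1.5), cfg)
  phiB <- drlse_evolve(initialize_lsf(rot90cw(seed_from_truth(truth, 0.3)), 2),
                       edge_indicator(rot90cw(img), 1.5), cfg)
  expect_lt(max(abs(phiB - rot90cw(phiA))), 1e-4)
})

test_that("exploding evolution aborts with the iteration named", {
  seed <- matrix(FALSE, 16, 16); seed[6:10, 6:10] <- TRUE
  edge <- list(g = matrix(1, 16, 16))
  phi <- initialize_lsf(seed, 2)
  phi[8, 8] <- NA
  expect_error(drlse_evolve(phi, edge, drlse_config(iters = 5L)),
               "iteration")
})
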