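# Independent brute-force oracles and small test utilities. These
# deliberately re-derive quantities by direct looping/summation, not by
# calling the package's vectorized implementations.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# mirror (reflect without edge duplication) pixel lookup, matching the
# package's stated padding convention
reflect_px <- function(m, r, c) {
  ref1 <- function(i, n) {
    j <- (i - 1) %% (2 * n - 2)
    if (j < n) j + 1 else 2 * n - 1 - j
  }
  m[ref1(r, nrow(m)), ref1(c, ncol(m))]
}

# brute-force nonlocal weight between pixels (r1,c1) and (r2,c2):
# double loop over patch offsets with a sum-normalized Gaussian kernel
bruteforce_nl_weight <- function(u0, r1, c1, r2, c2, patch_radius, h, a) {
  zs <- -patch_radius:patch_radius
  g1 <- exp(-zs^2 / (2 * a^2))
  G <- outer(g1, g1)
  G <- G / sum(G)
  d <- 0
  for (zy in zs) for (zx in zs) {
    d <- d + G[zy + patch_radius + 1, zx + patch_radius + 1] *
      (reflect_px(u0, r1 + zy, c1 + zx) - reflect_px(u0, r2 + zy, c2 + zx))^2
  }
  exp(-d / h^2)
}

# direct-summation NLTV energy over a weight graph's stored neighborhoods
bruteforce_nltv_energy <- function(u, u0, graph, lam) {
  tot <- 0
  for (r in seq_len(nrow(u))) for (c in seq_len(ncol(u))) {
    nb <- nl_neighbors(graph, r, c)
    s <- sum((u[cbind(nb$row, nb$col)] - u[r, c])^2 * nb$weight)
    tot <- tot + sqrt(s)
  }
  tot + lam / 2 * sum((u - u0)^2)
}

# brute-force |SDF| oracle: distance from every pixel to the nearest pixel
# of the opposite class (the definition the distance transform implements)
bruteforce_abs_sdf <- function(mask) {
  idx_in <- which(mask, arr.ind = TRUE)
  idx_out <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    tgt <- if (mask[r, c]) idx_out else idx_in
    out[r, c] <- sqrt(min((tgt[, 1] - r)^2 + (tgt[, 2] - c)^2))
  }
  out
}

# eigenvalues of the explicitly formed (n x n Gram trick) covariance of
# flattened, mean-centered fields, divisor n - 1
bruteforce_pca_eigvals <- function(sdfs) {
  X <- t(vapply(sdfs, as.vector, numeric(length(sdfs[[1]]))))
  Xc <- sweep(X, 2, colMeans(X))
  sort(eigen(Xc %*% t(Xc) / (nrow(X) - 1), symmetric = TRUE)$values,
       decreasing = TRUE)
}

# phantom parameter ranges scaled for a 64x64 frame (the package defaults
# target 128x128)
small_ranges <- function() {
  list(a = c(15, 20), b = c(9, 12), angle = c(-0.4, 0.4),
       bend = c(0, 0.012), notch_depth = c(0.05, 0.25),
       amp2 = c(0, 0.6), amp3 = c(0, 0.4))
}

# small deterministic blob mask for SDF tests
blob_mask <- function(n = 64, seed = 5) {
  set.seed(seed)
  cx <- n / 2 + runif(1, -4, 4); cy <- n / 2 + runif(1, -4, 4)
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), times = n), n, n)
  th <- atan2(ys - cy, xs - cx)
  r <- n / 4 * (1 + 0.25 * cos(2 * th + 1) + 0.12 * sin(3 * th))
  sqrt((xs - cx)^2 + (ys - cy)^2) < r
}
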