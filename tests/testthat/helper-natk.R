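# shared generators and independent oracles for the test suite

# random valid single-partner pair set over n positions (roughly half paired)
random_ss <- function(n, seed, p_pair = 0.4) {
  set.seed(seed)
  idx <- sample(0:(n - 1L))
  npair <- floor(n * p_pair / 2)
  pairs <- if (npair > 0)
    cbind(idx[seq_len(npair)], idx[npair + seq_len(npair)]) else NULL
  secondary_structure(n, pairs)
}

# crossing test by exhaustive pair enumeration (independent of the greedy
# layering the package uses)
has_crossing <- function(pairs) {
  if (nrow(pairs) < 2L) return(FALSE)
  for (a in seq_len(nrow(pairs) - 1L)) {
    for (b in seq(a + 1L, nrow(pairs))) {
      i <- pairs[a, 1L]; j <- pairs[a, 2L]
      k <- pairs[b, 1L]; l <- pairs[b, 2L]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(TRUE)
    }
  }
  FALSE
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

euler_rotation <- function(a, b, c) {
  # z-y-z Euler angles in degrees
  rz <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  }
  ry <- function(t) {
    t <- t * pi / 180
    matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  }
  rz(a) %*% ry(b) %*% rz(c)
}

# Brute-force minimum RMSD over rotations: exhaustive coarse Euler grid
# followed by Nelder-Mead polish of the best grid cells.  Centers both
# point sets (the optimal translation aligns centroids), then searches
# rotations only.  No SVD anywhere: independent of the Kabsch path.
rmsd_grid_oracle <- function(X, Y, coarse = 15) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
  }
  grid <- expand.grid(a = seq(0, 360 - coarse, by = coarse),
                      b = seq(0, 180, by = coarse),
                      c = seq(0, 360 - coarse, by = coarse))
  vals <- apply(grid, 1, rmsd_of)
  best <- order(vals)[1:8]
  refined <- vapply(best, function(k) {
    optim(as.numeric(grid[k, ]), rmsd_of, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))$value
  }, 0)
  min(refined)
}

# expand a template-realization pair set rotated by d positions (mod L)
rotate_pairs <- function(pairs, d, L) {
  m <- (pairs + d) %% L
  cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
}

pairs_equal <- function(a, b) {
  key <- function(m) sort(sprintf("%d:%d", pmin(m[, 1], m[, 2]),
                                  pmax(m[, 1], m[, 2])))
  identical(key(a), key(b))
}
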