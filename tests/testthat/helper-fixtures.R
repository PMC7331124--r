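# Shared fixture builders; everything is generated in code at test time.

# solid cube of bone on an n^3 grid, 1 mm spacing
cube_volume <- function(n = 11, hu = 1000) {
  voxel_volume(array(hu, dim = c(n, n, n)), spacing = c(1, 1, 1))
}

# voxelized solid ball: radius r mm on a 1 mm grid with one voxel margin
ball_volume <- function(r = 10) {
  n <- 2 * r + 5
  c0 <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  inside <- (g$i - c0)^2 + (g$j - c0)^2 + (g$k - c0)^2 <= r^2
  arr <- array(-1000, dim = c(n, n, n))
  arr[as.matrix(g[inside, ])] <- 1000
  voxel_volume(arr, spacing = c(1, 1, 1))
}

# 26-connectivity boundary test for an occupancy array
grid_boundary_ids <- function(idx, dims) {
  occ <- array(FALSE, dim = dims)
  occ[idx] <- TRUE
  apply(idx, 1, function(p) {
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1 | q > dims) || !occ[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  })
}

# random well-spread cloud
random_cloud <- function(n, seed = 1, sd = 1) {
  set.seed(seed)
  point_cloud(matrix(rnorm(3 * n, sd = sd), ncol = 3), units = "mm")
}

# small scaled-down simulation settings used across statistical tests
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_animals = 200, n_snps = 1000, n_modes = 3,
             mode_rms = c(1.6, 1.2, 1.0), h2 = c(0.6, 0.6, 0.6),
             n_qtl = 50, n_founders = 50, n_gen = 2, n_sires = 8,
             n_dams = 25, n_hy = 4, n_bm = 3, n_pn = 2, ...)
}

# brute-force recursive kinship (Malecot coancestry) oracle:
# A = 2 * theta, computed independently of the tabular method
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  theta <- matrix(NA_real_, n, n)
  f <- function(i, j) {
    if (is.na(theta[i, j])) {
      val <- if (i == j) {
        0.5 * (1 + (if (!is.na(si[i]) && !is.na(di[i])) f(si[i], di[i]) else 0))
      } else {
        # recurse on the later-born animal (parents precede offspring)
        a <- max(i, j); b <- min(i, j)
        ((if (!is.na(si[a])) f(si[a], b) else 0) +
         (if (!is.na(di[a])) f(di[a], b) else 0)) / 2
      }
      theta[i, j] <<- val
      theta[j, i] <<- val
    }
    theta[i, j]
  }
  for (i in seq_len(n)) for (j in i:n) f(i, j)
  2 * theta
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

# Independent coverage oracle for sparsification: greedy farthest-point
# sampling, which (near-)minimizes the maximum node-to-landmark distance.
greedy_oracle_landmarks <- function(mesh, k) {
  V <- mesh$nodes
  picked <- integer(k)
  picked[1] <- 1L
  d <- sqrt(rowSums(sweep(V, 2, V[1, ])^2))
  for (i in 2:k) {
    picked[i] <- which.max(d)
    d <- pmin(d, sqrt(rowSums(sweep(V, 2, V[picked[i], ])^2)))
  }
  V[picked, , drop = FALSE]
}
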