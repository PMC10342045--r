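toy_ensemble <- function(frames) {
  # frames: list of atoms x 3 matrices
  n_atoms <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), n_atoms, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  atoms <- data.frame(elety = "CA", resid = "ALA", resno = seq_len(n_atoms),
                      chain = "A", stringsAsFactors = FALSE)
  structure_ensemble(coords, atoms, dt = 0.1)
}

test_that("Kabsch superposition is exact for rigid motion", {
  set.seed(1)
  P <- matrix(rnorm(15, sd = 3), 5, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  R <- rand_rotation(2); t <- c(3, -2, 7)
  Q <- P %*% t(R) + rep(t, each = 5)
  fit <- kabsch_superpose(Q, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 atoms")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches brute-force rotation search and bio3d", {
  set.seed(3)
  P <- matrix(rnorm(9, sd = 2), 3, 3)
  Q <- matrix(rnorm(9, sd = 2), 3, 3)
  mine <- kabsch_superpose(P, Q)$rmsd
  # independent oracle: minimize over Euler-angle rotations numerically
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  obj <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- min(vapply(1:10, function(i) {
    set.seed(i)
    stats::optim(runif(3, -pi, pi), obj)$value
  }, numeric(1)))
  expect_equal(mine, best, tolerance = 1e-3)
  # bio3d cross-check on the same pair (bio3d reports 3 decimals)
  b3 <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_equal(mine, b3, tolerance = 1e-3)
})

test_that("RMSD series is zero on rigid-body copies", {
  set.seed(4)
  base <- matrix(rnorm(24, sd = 4), 8, 3)
  frames <- lapply(1:5, function(i) {
    base %*% t(rand_rotation(i)) + rep(rnorm(3, sd = 5), each = 8)
  })
  ens <- toy_ensemble(frames)
  rs <- rmsd_series(ens)
  expect_equal(rs$values, rep(0, 5), tolerance = 1e-8)
  expect_equal(rmsd_series(ens, reference = 3)$values[3], 0, tolerance = 1e-12)
})

test_that("RMSD of noisy ensembles matches the direct formula", {
  set.seed(5)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  sigma <- 0.2
  frames <- c(list(base),
              lapply(1:50, function(i) base + matrix(rnorm(30, sd = sigma), 10)))
  ens <- toy_ensemble(frames)
  rs <- rmsd_series(ens, reference = 1)
  # direct per-frame oracle (superposed RMSD <= raw RMSD)
  raw <- vapply(2:51, function(f) {
    sqrt(mean(rowSums((ens$coords[f, , ] - ens$coords[1, , ])^2)))
  }, numeric(1))
  expect_true(all(rs$values[-1] <= raw + 1e-12))
  # fitting removes 6 rigid degrees of freedom from 3N coordinates
  expected <- sigma * sqrt(3) * sqrt(1 - 6 / (3 * 10))
  expect_equal(mean(rs$values[-1]), expected, tolerance = 0.05)
})

test_that("RMSF matches closed forms", {
  # static ensemble
  base <- matrix(rnorm(15), 5, 3)
  ens0 <- toy_ensemble(lapply(1:4, function(i) base))
  expect_equal(rmsf(ens0)$values, rep(0, 5), tolerance = 1e-12)
  expect_error(rmsf(toy_ensemble(list(base))), "2 frames")
  # one atom oscillating +/- d along x, no superposition
  d <- 0.7
  frames <- lapply(1:40, function(i) {
    m <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 5, 5, 5), 4, 3, byrow = TRUE)
    m[1, 1] <- d * (-1)^i
    m
  })
  r <- rmsf(toy_ensemble(frames), superpose = FALSE)
  expect_equal(r$values[1], d, tolerance = 1e-12)
  expect_equal(r$values[-1], rep(0, 3), tolerance = 1e-12)
  # isotropic Gaussian noise: RMSF -> sigma sqrt(3)
  set.seed(6)
  sigma <- 0.3
  big <- matrix(rnorm(30, sd = 10), 10, 3)
  noisy <- lapply(1:400, function(i) big + matrix(rnorm(30, sd = sigma), 10))
  rn <- rmsf(toy_ensemble(noisy), superpose = FALSE)
  se <- sigma * sqrt(3) / sqrt(2 * 400)
  expect_equal(mean(rn$values), sigma * sqrt(3), tolerance = 3 * se + 0.02)
})

test_that("B-factor conversion applies the crystallographic constant", {
  expect_equal(b_factor(0)$values, 0)
  expect_equal(b_factor(1)$values, 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(b_factor(1)$values, 26.319, tolerance = 1e-3)
  v <- b_factor(c(0.5, 1, 2))$values
  expect_true(all(diff(v) > 0))
})

test_that("radius of gyration matches closed forms and the naive formula", {
  two <- toy_ensemble(list(matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)))
  expect_equal(radius_of_gyration(two)$values, 1)
  one <- toy_ensemble(list(matrix(c(3, 4, 5), 1, 3)))
  expect_equal(radius_of_gyration(one)$values, 0)
  set.seed(7)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  rg <- radius_of_gyration(toy_ensemble(list(P)))$values
  com <- colMeans(P)
  naive <- sqrt(sum(vapply(1:10, function(i) sum((P[i, ] - com)^2),
                           numeric(1))) / 10)
  expect_equal(rg, naive, tolerance = 1e-12)
})

test_that("DCCM identifies perfectly correlated and anticorrelated motion", {
  set.seed(8)
  disp <- rnorm(60)
  frames <- lapply(1:60, function(i) {
    matrix(c(0 + disp[i], 0, 0,
             10 + disp[i], 0, 0,
             20 - disp[i], 0, 0,
             0, 30, 0), 4, 3, byrow = TRUE)
  })
  C <- dccm(toy_ensemble(frames), selection = 1:3, superpose = FALSE)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 3], -1, tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C, t(C), ignore_attr = TRUE)
  # independent noise decorrelates
  big <- matrix(rnorm(12, sd = 10), 4, 3)
  n <- 2000
  noisy <- lapply(1:n, function(i) big + matrix(rnorm(12), 4))
  Cn <- dccm(toy_ensemble(noisy), selection = 1:4, superpose = FALSE)
  off <- Cn[upper.tri(Cn)]
  expect_lt(max(abs(off)), 3.5 / sqrt(n))
})

test_that("Shrake-Rupley SASA matches sphere closed forms", {
  iso <- sasa_shrake_rupley(matrix(0, 1, 3), radii = 1.7)
  expect_equal(iso$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  # near-complete overlap occludes most of both spheres
  two <- sasa_shrake_rupley(matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE),
                            radii = 1.7)
  expect_lt(two$total, 2 * iso$total)
  # occlusion monotonicity: adding atoms never increases earlier SASA
  coords3 <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1.5, 0))
  s2 <- sasa_shrake_rupley(coords3[1:2, ], radii = 1.7)
  s3 <- sasa_shrake_rupley(coords3, radii = 1.7)
  expect_lte(s3$atom_area[1], s2$atom_area[1] + 1e-9)
  # quadrature convergence
  set.seed(9)
  P <- matrix(rnorm(30, sd = 2), 10, 3)
  a1 <- sasa_shrake_rupley(P, radii = 1.7, n_points = 960)$total
  a2 <- sasa_shrake_rupley(P, radii = 1.7, n_points = 1920)$total
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("group distances follow Euclidean geometry", {
  ens <- toy_ensemble(list(matrix(c(0, 0, 0, 3, 4, 0, 1, 1, 1), 3, 3,
                                  byrow = TRUE)))
  expect_equal(group_distance(ens, 1, 2)$values, 5)
  expect_equal(group_distance(ens, 1:3, 1:3)$values, 0)
  shifted <- toy_ensemble(list(ens$coords[1, , ] + 100))
  expect_equal(group_distance(shifted, 1, 2)$values, 5, tolerance = 1e-10)
  expect_error(group_distance(ens, integer(0), 1), "nonempty")
})
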