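test_that("chain sampler handles deterministic transition matrices", {
  id <- ground_truth_chain(diag(2))
  expect_equal(sample_markov_chain(id, 5, start = 0, seed = 1),
               rep(0L, 5))
  alt <- ground_truth_chain(matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_equal(sample_markov_chain(alt, 4, start = 0, seed = 1),
               c(0L, 1L, 0L, 1L))
})

test_that("chain sampler is seed-deterministic and validates input", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  a <- sample_markov_chain(T, 1000, start = 0, seed = 99)
  b <- sample_markov_chain(T, 1000, start = 0, seed = 99)
  expect_identical(a, b)
  expect_error(ground_truth_chain(matrix(c(0.9, 0.2, 0.2, 0.8), 2, byrow = TRUE)),
               "row 1")
})

test_that("empirical pair frequencies recover the transition matrix", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  d <- sample_markov_chain(T, 1e5, start = 0, seed = 7)
  # direct frequency-count oracle
  pairs <- table(d[-length(d)], d[-1])
  T_hat <- pairs / rowSums(pairs)
  expect_lt(max(abs(T_hat - T)), 0.01)
})

test_that("metastable chains are stochastic with a planted spectral gap", {
  for (nb in c(1L, 2L, 4L)) {
    ch <- make_metastable_chain(nb, 3, p_inter = 0.01, seed = nb)
    expect_equal(rowSums(ch$transition_matrix), rep(1, nb * 3), tolerance = 1e-12)
  }
  # eigen-decomposition oracle: one eigenvalue >= 0.9 per block
  ch2 <- make_metastable_chain(2, 2, p_inter = 0.01, seed = 5)
  ev <- eigen(ch2$transition_matrix, only.values = TRUE)$values
  expect_equal(sum(Re(ev) >= 0.9 & abs(Im(ev)) < 1e-12), 2L)
  ch1 <- make_metastable_chain(1, 4, seed = 6)
  ev1 <- sort(Mod(eigen(ch1$transition_matrix, only.values = TRUE)$values),
              decreasing = TRUE)
  expect_lt(ev1[2], 0.9)
})

test_that("Langevin dynamics matches closed-form statistics", {
  # zero-noise limit from a well minimum stays put
  spec0 <- potential_spec("harmonic", kT = 1e-30, dt = 1e-3)
  traj0 <- simulate_langevin(spec0, 100, x0 = 0, seed = 1)
  expect_lt(max(abs(traj0$values)), 1e-10)
  # equipartition: Var(x) = kT in a harmonic well
  sp <- potential_spec("harmonic", kT = 0.5, dt = 5e-3)
  tr <- simulate_langevin(sp, 1e6, x0 = 0, seed = 2)
  expect_equal(stats::var(tr$values[, 1]), 0.5, tolerance = 0.05)
  # symmetric double well: equal occupancy
  dw <- potential_spec("double_well", kT = 1, dt = 1e-3)
  td <- simulate_langevin(dw, 5e5, x0 = -1, seed = 3)
  expect_lt(abs(mean(td$values[, 1] > 0) - 0.5), 0.1)
})

test_that("Langevin divergence is reported with its step index", {
  bad <- potential_spec("custom", dimension = 1,
                        potential = function(x) -x^4,
                        gradient = function(x) -4e6 * x^3, dt = 1)
  expect_error(simulate_langevin(bad, 1000, x0 = 1, seed = 1), "step")
})

test_that("dihedral dataset emulation matches the requested shape", {
  ds <- emulate_dihedral_dataset(n_traj = 3, n_frames = 400, n_features = 25,
                                 n_metastable = 4, seed = 21)
  expect_length(ds$trajectories, 3)
  for (i in 1:3) {
    expect_equal(dim(ds$trajectories[[i]]$values), c(400L, 25L))
    expect_length(ds$ground_truth_labels[[i]], 400)
    expect_true(all(ds$trajectories[[i]]$values > -180 &
                      ds$trajectories[[i]]$values <= 180))
  }
  one <- emulate_dihedral_dataset(n_traj = 1, n_frames = 50, n_features = 5,
                                  n_metastable = 1, seed = 1)
  expect_equal(unique(one$ground_truth_labels[[1]]), 0L)
  # seed determinism
  a <- emulate_dihedral_dataset(n_traj = 2, n_frames = 100, n_features = 6,
                                seed = 3)
  b <- emulate_dihedral_dataset(n_traj = 2, n_frames = 100, n_features = 6,
                                seed = 3)
  expect_identical(a$trajectories[[2]]$values, b$trajectories[[2]]$values)
  expect_identical(a$ground_truth_labels, b$ground_truth_labels)
})

test_that("enforced endpoints land trajectories in the requested end state", {
  ds <- emulate_dihedral_dataset(n_traj = 2, n_frames = 2000, n_features = 8,
                                 n_metastable = 3, p_hop = 0.01,
                                 start_state = 0L, end_state = 2L, seed = 13)
  expect_length(ds$metadata$warnings, 0)
  for (lab in ds$ground_truth_labels) {
    expect_equal(lab[1], 0L)
    tail_modal <- as.integer(names(which.max(table(utils::tail(lab, 100)))))
    expect_equal(tail_modal, 2L)
  }
})

test_that("dataset round-trips through the on-disk format", {
  ds <- emulate_dihedral_dataset(n_traj = 2, n_frames = 60, n_features = 4,
                                 seed = 5)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  back <- read_feature_matrix(file.path(dir, "traj_01.txt"))
  expect_equal(back$values, ds$trajectories[[1]]$values, tolerance = 1e-12)
  expect_equal(read_dtraj(file.path(dir, "labels_02.txt")),
               ds$ground_truth_labels[[2]])
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  expect_equal(meta$n_metastable, 5)
})
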