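make_random_ensemble <- function(n_frames, n_atoms, seed = 1) {
  set.seed(seed)
  coords <- array(rnorm(n_frames * n_atoms * 3, sd = 5), c(n_frames, n_atoms, 3))
  atoms <- data.frame(elety = rep_len(c("N", "CA", "C"), n_atoms),
                      resid = "ALA",
                      resno = rep(seq_len(ceiling(n_atoms / 3)), each = 3)[1:n_atoms],
                      chain = "A", stringsAsFactors = FALSE)
  structure_ensemble(coords, atoms, dt = 0.1)
}

test_that("multi-model PDB writing and reading round-trips coordinates", {
  ens <- make_random_ensemble(3, 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multi_model_pdb(ens, path)
  back <- read_multi_model_pdb(path)
  expect_equal(dim(back$coords), c(3L, 6L, 3L))
  expect_equal(back$coords, ens$coords, tolerance = 1e-3)   # PDB precision
  expect_equal(back$atoms$elety, ens$atoms$elety)
})

test_that("single-model files give a one-frame ensemble", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00",
    "END"), path)
  ens <- read_multi_model_pdb(path)
  expect_equal(dim(ens$coords), c(1L, 3L, 3L))
  expect_equal(ens$coords[1, 2, 1], 1.458)
})

test_that("inconsistent or malformed models are reported precisely", {
  ens <- make_random_ensemble(2, 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multi_model_pdb(ens, path)
  lines <- readLines(path)
  # drop one atom from MODEL 2
  atom_lines <- grep("^ATOM", lines)
  writeLines(lines[-atom_lines[5]], path)
  expect_error(read_multi_model_pdb(path), "MODEL 2")
  # corrupt a coordinate field
  lines2 <- readLines(path)
  substr(lines2[atom_lines[1]], 31, 38) <- "xxxxxxxx"
  writeLines(lines2, path)
  expect_error(read_multi_model_pdb(path), "malformed ATOM record at line 2")
})

test_that("torsion angle follows the standard convention", {
  # planar cis and trans arrangements
  expect_equal(compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  expect_error(compute_dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincide")
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("torsion matches an independent two-plane oracle and is rigid-invariant", {
  set.seed(42)
  for (i in 1:25) {
    ps <- lapply(1:4, function(j) rnorm(3, sd = 3))
    ref <- dihedral_oracle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    val <- compute_dihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    expect_equal(val, ref, tolerance = 1e-9)
    R <- rand_rotation(i)
    t <- rnorm(3, sd = 10)
    moved <- lapply(ps, function(p) as.numeric(R %*% p) + t)
    expect_equal(compute_dihedral(moved[[1]], moved[[2]], moved[[3]], moved[[4]]),
                 val, tolerance = 1e-9)
  }
})

test_that("backbone featurization recovers ideal helical angles", {
  ens <- build_backbone(6, phi = -57, psi = -47)
  ft <- backbone_dihedral_features(ens)
  expect_equal(ncol(ft$values), 2L * 5L)
  phis <- ft$values[1, grepl("^phi", ft$feature_names)]
  psis <- ft$values[1, grepl("^psi", ft$feature_names)]
  expect_equal(unname(phis), rep(-57, 5), tolerance = 2)
  expect_equal(unname(psis), rep(-47, 5), tolerance = 2)
  expect_true(all(ft$periodic))
  expect_equal(ft$dt, ens$dt)
})

test_that("degenerate chains and missing atoms are handled", {
  one <- build_backbone(2)
  sub <- structure_ensemble(one$coords[, 1:3, , drop = FALSE],
                            one$atoms[1:3, ], dt = 0.1)
  ft <- backbone_dihedral_features(sub)
  expect_equal(ncol(ft$values), 0L)
  # remove residue 2's CA
  broken <- structure_ensemble(one$coords[, -5, , drop = FALSE],
                               one$atoms[-5, ], dt = 0.1)
  expect_error(backbone_dihedral_features(broken), "residue 2.*CA")
})

test_that("sin/cos embedding doubles periodic features and preserves norm", {
  set.seed(3)
  ft <- feature_trajectory(matrix(runif(20 * 139, -180, 180), 20, 139),
                           periodic = TRUE)
  emb <- sincos_embed(ft)
  expect_equal(ncol(emb$values), 278L)
  pair_norm <- sqrt(emb$values[, seq(1, 277, 2)]^2 + emb$values[, seq(2, 278, 2)]^2)
  expect_equal(as.numeric(pair_norm), rep(1, 20 * 139), tolerance = 1e-12)
  # constant 0 degrees -> (0, 1); non-periodic passthrough
  mixed <- feature_trajectory(cbind(a = rep(0, 5), b = 1:5),
                              periodic = c(TRUE, FALSE))
  out <- sincos_embed(mixed)
  expect_equal(unname(out$values[, 1]), rep(0, 5))
  expect_equal(unname(out$values[, 2]), rep(1, 5))
  expect_equal(unname(out$values[, 3]), 1:5)
})
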