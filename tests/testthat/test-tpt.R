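T3 <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0, 0.1, 0.9), 3, byrow = TRUE)

make_net <- function(W, A, B, total = NULL) {
  n <- nrow(W)
  Ai <- A + 1L
  total <- total %||% sum(W[Ai, setdiff(seq_len(n), Ai), drop = FALSE])
  structure(list(A = A, B = B, qplus = rep(NA_real_, n),
                 qminus = rep(NA_real_, n), gross = W, net = W,
                 total_flux = total, states = seq_len(n) - 1L,
                 dt = 0.1, lag = 1L),
            class = "flux_network")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("committors satisfy boundary conditions and symmetry", {
  q <- committors(T3, A = 0, B = 2)
  expect_equal(q$qplus, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(q$qminus, c(1, 0.5, 0), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    ch <- make_metastable_chain(2, 3, p_inter = 0.1, seed = i)
    T <- ch$transition_matrix
    q <- committors(T, A = 0, B = 5)
    expect_equal(q$qplus[1], 0)
    expect_equal(q$qplus[6], 1)
    expect_true(all(q$qplus >= -1e-12 & q$qplus <= 1 + 1e-12))
  }
})

test_that("committor solve matches fixed-point iteration of the recursion", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    C <- matrix(stats::rpois(n * n, 15) + 1, n, n)
    T <- estimate_transition_matrix(C, reversible = TRUE)$T
    A <- 0L; B <- n - 1L
    q <- committors(T, A, B)$qplus
    # fixed-point oracle on q_i = sum_{j in B} T_ij + sum_{j notin A,B} T_ij q_j
    qfp <- rep(0.5, n); qfp[A + 1] <- 0; qfp[B + 1] <- 1
    I <- setdiff(seq_len(n), c(A, B) + 1L)
    for (iter in 1:20000) {
      qfp[I] <- rowSums(T[I, B + 1L, drop = FALSE]) +
        as.numeric(T[I, I, drop = FALSE] %*% qfp[I])
    }
    expect_equal(q, qfp, tolerance = 1e-10)
  }
})

test_that("trapped states are named in the committor error", {
  T <- matrix(c(0.5, 0.5, 0, 0,
                0.5, 0.5, 0, 0,
                0, 0, 1, 0,
                0, 0, 0.5, 0.5), 4, byrow = TRUE)
  expect_error(committors(T, A = 0, B = 1), "cannot reach B")
})

test_that("reactive flux reproduces the hand-evaluated three-state network", {
  fn <- reactive_flux(T3, rep(1 / 3, 3), A = 0, B = 2)
  expect_equal(fn$gross[1, 2], 1 / 60, tolerance = 1e-14)
  expect_equal(fn$total_flux, 1 / 60, tolerance = 1e-14)
  # conservation: out of A equals into B
  out_A <- sum(fn$net[1, -1])
  into_B <- sum(fn$net[-3, 3])
  expect_equal(out_A, into_B, tolerance = 1e-12)
  # stationarity is enforced
  expect_error(reactive_flux(T3, c(0.5, 0.3, 0.2), A = 0, B = 2),
               "stationary")
})

test_that("disconnected source and sink carry zero flux", {
  T <- diag(c(0, 0, 0)) + matrix(c(0.5, 0.5, 0, 0.5, 0.5, 0, 0, 0, 1),
                                 3, byrow = TRUE)
  rho <- stats::setNames(c(0.25, 0.25, 0.5), NULL)
  fn <- reactive_flux(T, rho, A = 0, B = 2)
  expect_equal(fn$total_flux, 0)
  d <- suppressWarnings(decompose_pathways(fn))
  expect_length(d$paths, 0)
})

test_that("pathway decomposition matches exhaustive enumeration", {
  # A=0, intermediates 1,2, B=3 with known widest-path order
  W <- matrix(0, 4, 4)
  W[1, 2] <- 3; W[1, 3] <- 1; W[2, 4] <- 2; W[2, 3] <- 1; W[3, 4] <- 1
  net <- make_net(W, A = 0L, B = 3L, total = 3)
  d <- decompose_pathways(net, residual_fraction_stop = 0)
  expect_equal(d$paths[[1]], c(0L, 1L, 3L))
  expect_equal(d$flux[1], 2)
  expect_equal(d$paths[[2]], c(0L, 1L, 2L, 3L))
  expect_equal(d$flux[2], 1)
  expect_equal(d$decomposed_flux, 3)
  expect_equal(d$percentage, c(200 / 3, 100 / 3), tolerance = 1e-10)
})

test_that("single-path networks decompose to one 100% path", {
  W <- matrix(0, 3, 3); W[1, 2] <- 0.4; W[2, 3] <- 0.4
  d <- decompose_pathways(make_net(W, 0L, 2L))
  expect_length(d$paths, 1)
  expect_equal(d$paths[[1]], c(0L, 1L, 2L))
  expect_equal(d$flux, 0.4)
  expect_equal(d$percentage, 100)
})

test_that("full decomposition recovers the total flux on macro networks", {
  set.seed(3)
  for (i in 1:5) {
    ch <- make_metastable_chain(2, 3, p_inter = 0.2, seed = i + 10)
    fn <- reactive_flux(ch$transition_matrix, ch$stationary, A = 0, B = 5)
    d <- decompose_pathways(fn, residual_fraction_stop = 0)
    expect_equal(d$decomposed_flux, fn$total_flux, tolerance = 1e-10)
    expect_true(all(diff(d$flux) <= 1e-14))
  }
})

test_that("committors increase monotonically along a 1-D chain", {
  n <- 7
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) { W[i, i + 1] <- 0.2; W[i + 1, i] <- 0.2 }
  diag(W) <- 1
  T <- W / rowSums(W)
  q <- committors(T, A = 0, B = n - 1)$qplus
  expect_true(all(diff(q) >= -1e-12))
})

test_that("coarse-graining the flux conserves the total", {
  ch <- make_metastable_chain(3, 2, p_inter = 0.1, seed = 12)
  fn <- reactive_flux(ch$transition_matrix, ch$stationary, A = 0:1, B = 4:5)
  # identity partition leaves the network unchanged
  id <- lapply(0:5, identity)
  fi <- coarse_grain_flux(fn, id)
  expect_equal(fi$net, fn$net, tolerance = 1e-14)
  expect_equal(fi$total_flux, fn$total_flux, tolerance = 1e-14)
  # merging all intermediates conserves the total flux
  fm <- coarse_grain_flux(fn, list(0:1, 2:3, 4:5), rho = ch$stationary)
  expect_equal(fm$total_flux, fn$total_flux, tolerance = 1e-12)
  # direct pair-summation oracle for one cross-boundary entry
  expect_equal(fm$gross[1, 2], sum(fn$net[1:2, 3:4]), tolerance = 1e-14)
  expect_error(coarse_grain_flux(fn, list(0:1, 2:4)), "cover")
})

test_that("path percentages reproduce published table arithmetic", {
  t1 <- c(4.00e-3, 2.00e-3, 6.00e-4, 1.00e-4, 3.00e-5, 3.00e-5)
  expect_equal(round(path_percentages(t1, denominator = sum(t1)), 2),
               c(59.17, 29.59, 8.88, 1.48, 0.44, 0.44))
  t4 <- c(6.00e-3, 3.00e-4, 9.00e-5, 1.00e-5, 1.00e-5, 1.00e-5)
  expect_equal(round(path_percentages(t4)[1], 2), 93.46)
  expect_equal(path_percentages(5), 100)
  expect_error(path_percentages(c(0, 0)), "positive")
})

test_that("flux tables format, total and round-trip correctly", {
  d <- structure(list(paths = list(c(0L, 4L), c(0L, 3L, 4L), c(0L, 3L, 2L, 4L),
                                   c(0L, 2L, 4L), c(0L, 3L, 2L, 1L, 4L),
                                   c(0L, 2L, 1L, 4L)),
                      flux = c(4.00e-3, 2.00e-3, 6.00e-4, 1.00e-4, 3.00e-5, 3.00e-5),
                      percentage = path_percentages(
                        c(4.00e-3, 2.00e-3, 6.00e-4, 1.00e-4, 3.00e-5, 3.00e-5)),
                      total_flux = 6.76e-3, decomposed_flux = 6.76e-3,
                      residual_flux = 0, states = 0:4, dt = 0.1, lag = 10L),
                 class = "pathway_decomposition")
  tab <- flux_table(d, state_names = c("SA", "S1", "S2", "S3", "SB"))
  expect_equal(tab$pathway[1], "SA→SB")
  expect_equal(tab$pathway[2], "SA→S3→SB")
  expect_equal(tab$path_flux[nrow(tab)], "6.76e-03")
  expect_equal(tab$percentage[1], "59.17")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flux_table(tab, path)
  back <- read_flux_table(path)
  expect_equal(as.numeric(back$path_flux[1:6]), d$flux, tolerance = 1e-2 * 6.76e-3)
  # empty decomposition renders a bare total
  empty <- structure(list(paths = list(), flux = numeric(0),
                          percentage = numeric(0), total_flux = 0,
                          decomposed_flux = 0, residual_flux = 0,
                          states = 0:1, dt = 0.1, lag = 1L),
                     class = "pathway_decomposition")
  et <- flux_table(empty)
  expect_equal(nrow(et), 1)
  expect_equal(et$pathway, "Total")
})

test_that("double-well discretization puts the barrier committor near one half", {
  dw <- potential_spec("double_well", kT = 0.6, dt = 2e-3)
  tr <- simulate_langevin(dw, 2e5, x0 = -1, seed = 14)
  km <- kmeans_fit(tr, 9, seed = 15)
  d <- assign_microstates(km, tr)
  m <- estimate_msm(list(d), lag = 5)
  centers <- km$centers[m$active_set + 1L, 1]
  A <- which.min(centers) - 1L
  B <- which.max(centers) - 1L
  q <- committors(m$transition_matrix, A, B)$qplus
  barrier <- which.min(abs(centers))
  expect_lt(abs(q[barrier] - 0.5), 0.05)
})
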