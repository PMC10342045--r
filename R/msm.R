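#' Count microstate transitions at a lag
#'
#' Records every jump of length `lag` along the discrete trajectories
#' in a count matrix: C\[i, j\] is the number of frame pairs
#' (t, t + lag) labeled (i, j). Sliding mode counts every starting
#' frame; strided mode counts only t = 0, lag, 2 lag, ... (independent
#' jumps). Trajectories shorter than the lag contribute nothing.
#'
#' @param dtrajs Discrete trajectory (0-based labels) or list of them.
#' @param lag Lag in frames (>= 1).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @param n_states Optional state-space size (default: max label + 1).
#' @return Integer-valued n x n matrix.
#' @export
count_transitions <- function(dtrajs, lag, mode = c("sliding", "strided"),
                              n_states = NULL) {
  dtrajs <- as_dtraj_list(dtrajs)
  lag <- stopifnot_scalar_count(lag, "lag")
  mode <- match.arg(mode)
  n <- n_states %||% (max(unlist(dtrajs)) + 1L)
  C <- matrix(0, n, n)
  for (d in dtrajs) {
    L <- length(d)
    if (L <= lag) next
    starts <- if (mode == "sliding") 1:(L - lag) else seq(1L, L - lag, by = lag)
    i <- d[starts] + 1L
    j <- d[starts + lag] + 1L
    C <- C + unclass(table(factor(i, levels = seq_len(n)),
                           factor(j, levels = seq_len(n))))
  }
  dimnames(C) <- NULL
  C
}

#' Largest strongly connected set of a count matrix
#'
#' States on which a Markov model can be estimated must communicate in
#' both directions; this returns the largest strongly connected
#' component of the directed graph with an edge wherever C > 0. Ties in
#' size go to the component containing the lowest state index.
#'
#' @param C Square count matrix.
#' @return 0-based state indices, sorted.
#' @export
largest_connected_set <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  n <- nrow(C)
  if (n == 1L) return(0L)
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # lowest-index tie-break
    firsts <- vapply(best, function(b) min(which(comp$membership == b)), integer(1))
    best <- best[which.min(firsts)]
  }
  sort(which(comp$membership == best)) - 1L
}

reversible_mle <- function(C, tol = 1e-10, max_iter = 1e6) {
  # maximum-likelihood reversible transition matrix via the standard
  # fixed-point update on symmetric edge weights x_ij
  Csym <- C + t(C)
  ci <- rowSums(C)
  X <- Csym
  T_old <- X / rowSums(X)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    X <- Csym / denom
    X[Csym == 0] <- 0
    T_new <- X / rowSums(X)
    if (max(abs(T_new - T_old)) < tol) {
      return(list(T = T_new, rho = rowSums(X) / sum(X), iterations = it))
    }
    T_old <- T_new
  }
  stop(sprintf("reversible estimator did not converge in %g iterations (residual %.3g)",
               max_iter, max(abs(T_new - T_old))))
}

#' Estimate a transition matrix from counts
#'
#' Non-reversible: simple row normalization of the counts, with the
#' stationary distribution taken as the leading left eigenvector.
#' Reversible (default): the maximum-likelihood row-stochastic matrix
#' satisfying detailed balance rho_i T_ij = rho_j T_ji, found by
#' fixed-point iteration on symmetric edge weights; detailed balance is
#' what makes the backward committor equal 1 - q+ in the flux
#' analysis.
#'
#' @param C Count matrix restricted to a strongly connected set, all
#'   row sums > 0.
#' @param reversible Enforce detailed balance (default TRUE).
#' @return List with `T` (row-stochastic) and `rho` (stationary
#'   distribution).
#' @export
estimate_transition_matrix <- function(C, reversible = TRUE) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (any(C < 0)) stop("count matrix must be nonnegative")
  rs <- rowSums(C)
  if (any(rs == 0)) {
    stop("count matrix has empty rows; restrict to the largest connected set first")
  }
  if (reversible) {
    fit <- reversible_mle(C)
    list(T = fit$T, rho = fit$rho)
  } else {
    T <- C / rs
    list(T = T, rho = stationary_distribution(T))
  }
}

#' Estimate a Markov state model from discrete trajectories
#'
#' Counts transitions at the lag, trims to the largest strongly
#' connected set, and estimates the (by default reversible) transition
#' matrix together with its stationary distribution and eigen-spectrum.
#'
#' @inheritParams count_transitions
#' @param reversible Enforce detailed balance (default TRUE).
#' @param dt Frame spacing in ns (default 0.1), so `lag * dt` is the
#'   physical lag time.
#' @return An object of class `markov_model`: `lag`, `dt`,
#'   `count_matrix` (full), `transition_matrix` (active set),
#'   `stationary`, `eigenvalues` (descending modulus), `active_set`
#'   (0-based original labels), `reversible`.
#' @export
estimate_msm <- function(dtrajs, lag = 10L, reversible = TRUE,
                         mode = "sliding", dt = 0.1, n_states = NULL) {
  dtrajs <- as_dtraj_list(dtrajs)
  C_full <- count_transitions(dtrajs, lag, mode = mode, n_states = n_states)
  active <- largest_connected_set(C_full)
  C <- C_full[active + 1L, active + 1L, drop = FALSE]
  est <- estimate_transition_matrix(C, reversible = reversible)
  ev <- eigen(est$T)$values
  if (reversible && any(abs(Im(ev)) > 1e-10)) {
    stop("reversible transition matrix produced complex eigenvalues")
  }
  ev <- ev[order(Mod(ev), decreasing = TRUE)]
  if (reversible) ev <- Re(ev)
  structure(list(lag = lag, dt = dt, count_matrix = C_full,
                 transition_matrix = est$T, stationary = est$rho,
                 eigenvalues = ev, active_set = active,
                 reversible = reversible, mode = mode),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("<markov_model> %d active states, lag %d frames (%g ns), %s\n",
              length(x$active_set), x$lag, x$lag * x$dt,
              if (x$reversible) "reversible" else "non-reversible"))
  cat("implied timescales (frames):",
      paste(signif(utils::head(timescales_from_eigenvalues(x$eigenvalues, x$lag), 4), 4),
            collapse = ", "), "\n")
  invisible(x)
}

timescales_from_eigenvalues <- function(ev, lag) {
  ev <- ev[-1]                       # drop the stationary eigenvalue
  out <- rep(NA_real_, length(ev))
  ok <- abs(Im(ev)) < 1e-10 & Re(ev) > 0 & Re(ev) < 1
  out[ok] <- -lag / log(Re(ev[ok]))
  out
}

#' Implied relaxation timescales over a grid of lags
#'
#' For each lag an MSM is estimated and the timescales
#' t_i = -lag / log(lambda_{i+1}) are reported, in frames and in ns.
#' The lag at which the timescales stop depending on the lag is the
#' Markov time; non-real or non-positive eigenvalues yield NA
#' (undefined), never a silently dropped row.
#'
#' @inheritParams estimate_msm
#' @param lags Vector of lags (frames).
#' @param n_timescales Number of timescales reported (default 5).
#' @return Data frame: `lag_frames`, `lag_ns`, then `ts1_frames`, ...,
#'   and `ts1_ns`, ...
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 5L,
                               reversible = TRUE, dt = 0.1) {
  dtrajs <- as_dtraj_list(dtrajs)
  rows <- lapply(lags, function(lg) {
    m <- estimate_msm(dtrajs, lag = lg, reversible = reversible, dt = dt)
    ts <- timescales_from_eigenvalues(m$eigenvalues, lg)
    length(ts) <- n_timescales
    ts
  })
  ts_mat <- do.call(rbind, rows)
  out <- data.frame(lag_frames = as.integer(lags), lag_ns = lags * dt)
  for (i in seq_len(n_timescales)) {
    out[[paste0("ts", i, "_frames")]] <- ts_mat[, i]
    out[[paste0("ts", i, "_ns")]] <- ts_mat[, i] * dt
  }
  out
}

#' Chapman--Kolmogorov test
#'
#' Validates memorylessness of an MSM at lag tau by comparing, for
#' k = 1..k_max, the transition probabilities re-estimated directly at
#' lag k tau against the k-th matrix power of the lag-tau model:
#' P(k tau) = P(tau)^k for a Markovian process. The comparison is made
#' on metastable sets when a partition is supplied (the usual
#' practice), otherwise on the microstates themselves. The test passes
#' when the maximum relative deviation over well-populated entries
#' (propagated probability >= `min_prob`) is at most `threshold`.
#'
#' @param msm A `markov_model` estimated at the reference lag.
#' @param dtrajs The discrete trajectories the model was built from.
#' @param k_max Largest multiple of the lag tested (default 5).
#' @param sets Optional list of 0-based microstate-label vectors
#'   defining metastable sets (e.g. from [pcca_plus()] crisp labels),
#'   or a `macro_partition`.
#' @param threshold Pass criterion on the max relative deviation
#'   (default 0.05).
#' @param min_prob Entries with propagated probability below this are
#'   reported but excluded from the pass criterion (default 0.01).
#' @return An object of class `ck_result`: `k`, `estimated` and
#'   `propagated` matrix lists, `max_rel_dev` per k, `pass`.
#' @export
ck_test <- function(msm, dtrajs, k_max = 5L, sets = NULL,
                    threshold = 0.05, min_prob = 0.01) {
  stopifnot(inherits(msm, "markov_model"))
  dtrajs <- as_dtraj_list(dtrajs)
  k_max <- stopifnot_scalar_count(k_max, "k_max")
  lens <- vapply(dtrajs, length, integer(1))
  if (k_max * msm$lag >= max(lens)) {
    stop(sprintf("k_max * lag (%d) must be smaller than the longest trajectory (%d)",
                 k_max * msm$lag, max(lens)))
  }
  if (inherits(sets, "macro_partition")) {
    sets <- split(seq_along(sets$crisp) - 1L, sets$crisp)
  }
  cdtrajs <- if (is.null(sets)) {
    dtrajs
  } else {
    lookup <- rep(NA_integer_, max(unlist(dtrajs)) + 1L)
    for (s in seq_along(sets)) lookup[sets[[s]] + 1L] <- s - 1L
    lapply(dtrajs, function(d) {
      if (anyNA(lookup[d + 1L])) stop("some microstates are not covered by 'sets'")
      lookup[d + 1L]
    })
  }
  base <- estimate_msm(cdtrajs, lag = msm$lag, reversible = msm$reversible,
                       dt = msm$dt)
  n <- nrow(base$transition_matrix)
  estimated <- propagated <- vector("list", k_max)
  max_rel <- numeric(k_max)
  Pk <- diag(n)
  for (k in seq_len(k_max)) {
    Pk <- Pk %*% base$transition_matrix
    mk <- estimate_msm(cdtrajs, lag = k * msm$lag, reversible = msm$reversible,
                       dt = msm$dt)
    # align to the reference active set; unmatched entries become NA
    Ek <- matrix(NA_real_, n, n)
    ia <- match(base$active_set, mk$active_set)
    ok <- !is.na(ia)
    Ek[ok, ok] <- mk$transition_matrix[ia[ok], ia[ok]]
    estimated[[k]] <- Ek
    propagated[[k]] <- Pk
    rel <- abs(Ek - Pk) / Pk
    rel[Pk < min_prob | is.na(Ek)] <- NA
    max_rel[k] <- if (all(is.na(rel))) NA_real_ else max(rel, na.rm = TRUE)
  }
  structure(list(k = seq_len(k_max), estimated = estimated,
                 propagated = propagated, max_rel_dev = max_rel,
                 pass = all(max_rel <= threshold, na.rm = TRUE),
                 threshold = threshold, lag = msm$lag),
            class = "ck_result")
}

#' @export
print.ck_result <- function(x, ...) {
  cat(sprintf("<ck_result> lag %d frames, k = 1..%d, %s\n", x$lag,
              max(x$k), if (x$pass) "PASS" else "FAIL"))
  cat("max relative deviation per k:",
      paste(signif(x$max_rel_dev, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.ck_result <- function(x, ...) {
  n <- nrow(x$propagated[[1]])
  ks <- c(0, x$k)
  graphics::par(mfrow = c(1, n))
  for (i in seq_len(n)) {
    est <- c(1, vapply(x$estimated, function(m) m[i, i], numeric(1)))
    prop <- c(1, vapply(x$propagated, function(m) m[i, i], numeric(1)))
    graphics::plot(ks, prop, type = "l", lty = 2, ylim = c(0, 1),
                   xlab = "k", ylab = sprintf("P[%d,%d]", i, i), ...)
    graphics::lines(ks, est, type = "b")
  }
  invisible(x)
}

#' Write a count or transition matrix as CSV with state labels
#'
#' @param M Square matrix over active states.
#' @param path Output CSV.
#' @param labels 0-based state labels (default `0:(n-1)`).
#' @export
write_state_matrix <- function(M, path, labels = NULL) {
  labels <- labels %||% (seq_len(nrow(M)) - 1L)
  df <- as.data.frame(M)
  names(df) <- paste0("s", labels)
  df <- cbind(state = paste0("s", labels), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
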