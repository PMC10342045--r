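#' Time-lagged independent component analysis
#'
#' Finds the linear projections of a feature trajectory that are
#' maximally autocorrelated at a given lag. These are the slow
#' collective coordinates of the dynamics: with molecular-dynamics
#' input they approximate the dominant eigenfunctions of the underlying
#' transfer operator, which makes TICA the standard dimensionality
#' reduction before microstate clustering.
#'
#' The estimator forms, over all within-trajectory frame pairs
#' (t, t + lag), the mean-free instantaneous covariance C0 and the
#' symmetrized time-lagged covariance Ct = (C + C')/2, then solves the
#' generalized symmetric eigenproblem Ct v = lambda C0 v. Symmetrizing
#' guarantees a real spectrum on finite data; lagged pairs never
#' straddle trajectory boundaries since runs are independent.
#'
#' @param trajs A [feature_trajectory()], numeric matrix, or list of
#'   either; all with the same feature dimension.
#' @param lag Lag in frames (default 10, i.e. 1 ns at 0.1 ns spacing,
#'   matching the Markov-model lag).
#' @param dim Retained dimension: an integer count, or a fraction in
#'   (0, 1) interpreted as the kinetic variance (sum of squared
#'   eigenvalues) to capture. Default 0.95.
#' @param regularization Ridge added to C0 as
#'   `regularization * trace(C0)/d * I`; stabilizes nearly collinear
#'   features such as sine/cosine pairs. Default 1e-8.
#'
#' @return An object of class `tica_model`: mean vector, `C0`, `Ct`,
#'   `eigenvalues` (descending), `eigenvectors` (C0-orthonormal
#'   columns), `lag`, `dim`, `dt`.
#' @export
estimate_tica <- function(trajs, lag = 10L, dim = 0.95,
                          regularization = 1e-8) {
  trajs <- as_traj_list(trajs)
  lag <- stopifnot_scalar_count(lag, "lag")
  lens <- vapply(trajs, function(t) nrow(t$values), integer(1))
  if (lag >= min(lens)) {
    stop(sprintf("lag (%d) must be smaller than the shortest trajectory (%d frames)",
                 lag, min(lens)))
  }
  d <- ncol(trajs[[1]]$values)
  if (any(unlist(lapply(trajs, function(t) t$periodic)))) {
    warning("periodic features present; consider sincos_embed() before TICA")
  }

  # pass 1: mean over both ends of every lagged pair
  n_pairs <- sum(lens - lag)
  s <- numeric(d)
  for (t in trajs) {
    X <- t$values
    L <- nrow(X)
    s <- s + colSums(X[1:(L - lag), , drop = FALSE]) +
      colSums(X[(1 + lag):L, , drop = FALSE])
  }
  mu <- s / (2 * n_pairs)

  # pass 2: covariances
  C0 <- matrix(0, d, d)
  Ct <- matrix(0, d, d)
  for (t in trajs) {
    X <- sweep(t$values, 2L, mu)
    L <- nrow(X)
    X0 <- X[1:(L - lag), , drop = FALSE]
    Xt <- X[(1 + lag):L, , drop = FALSE]
    C0 <- C0 + crossprod(X0) + crossprod(Xt)
    Ct <- Ct + crossprod(X0, Xt)
  }
  C0 <- C0 / (2 * n_pairs)
  Ct <- (Ct + t(Ct)) / (2 * n_pairs)

  tr <- sum(diag(C0))
  if (tr <= 0) {
    stop("all features have zero variance; TICA is undefined on constant data")
  }
  C0r <- C0 + diag(regularization * tr / d, d)

  # whiten on the numerically nonzero subspace of C0
  e0 <- eigen(C0r, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  if (!any(keep)) {
    stop("C0 is numerically singular; increase 'regularization'")
  }
  Lw <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- crossprod(Lw, Ct %*% Lw)
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lambda <- em$values[ord]
  V <- Lw %*% em$vectors[, ord, drop = FALSE]
  if (any(abs(lambda) > 1 + 1e-6)) {
    warning(sprintf("TICA eigenvalue %.6f exceeds 1; estimates are noisy at this lag",
                    max(abs(lambda))))
  }

  n_avail <- length(lambda)
  ndim <- if (dim >= 1) {
    min(as.integer(dim), n_avail)
  } else {
    kv <- cumsum(lambda^2) / sum(lambda^2)
    min(which(kv >= dim))
  }

  structure(list(mean = mu, C0 = C0, Ct = Ct, eigenvalues = lambda,
                 eigenvectors = V, lag = lag, dim = ndim,
                 dt = trajs[[1]]$dt, n_pairs = n_pairs),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> lag %d frames, %d/%d components retained\n",
              x$lag, x$dim, length(x$eigenvalues)))
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project features onto TICA components
#'
#' @param model A `tica_model`.
#' @param ft A [feature_trajectory()] or matrix with the model's
#'   feature dimension.
#' @param dim Number of components to keep (default: the model's
#'   retained dimension).
#' @return A [feature_trajectory()] with columns IC1..ICd.
#' @export
tica_transform <- function(model, ft, dim = NULL) {
  stopifnot(inherits(model, "tica_model"))
  ft <- as_feature_trajectory(ft)
  if (ncol(ft$values) != length(model$mean)) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(ft$values), length(model$mean)))
  }
  dim <- min(dim %||% model$dim, ncol(model$eigenvectors))
  Y <- sweep(ft$values, 2L, model$mean) %*%
    model$eigenvectors[, seq_len(dim), drop = FALSE]
  feature_trajectory(Y, dt = ft$dt, feature_names = paste0("IC", seq_len(dim)))
}

#' Serialize / restore a TICA model as plain text
#'
#' Means, covariance matrices and eigenpairs are written to one
#' YAML archive so a fitted projection can be reused across runs.
#'
#' @param model A `tica_model`.
#' @param path Archive path.
#' @export
write_tica_model <- function(model, path) {
  stopifnot(inherits(model, "tica_model"))
  mat2list <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  yaml::write_yaml(list(
    mean = as.numeric(model$mean), C0 = mat2list(model$C0),
    Ct = mat2list(model$Ct), eigenvalues = as.numeric(model$eigenvalues),
    eigenvectors = mat2list(model$eigenvectors), lag = model$lag,
    dim = model$dim, dt = model$dt, n_pairs = model$n_pairs), path,
    precision = 15)
  invisible(path)
}

#' @rdname write_tica_model
#' @export
read_tica_model <- function(path) {
  y <- yaml::read_yaml(path)
  list2mat <- function(l) do.call(rbind, lapply(l, as.numeric))
  structure(list(mean = as.numeric(y$mean), C0 = list2mat(y$C0),
                 Ct = list2mat(y$Ct), eigenvalues = as.numeric(y$eigenvalues),
                 eigenvectors = list2mat(y$eigenvectors), lag = y$lag,
                 dim = y$dim, dt = y$dt, n_pairs = y$n_pairs),
            class = "tica_model")
}
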