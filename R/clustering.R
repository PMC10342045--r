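kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (k > 1L) {
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  centers
}

#' Microstate definition by restarted k-means
#'
#' Partitions trajectory frames (typically TICA projections) into k
#' microstates: k-means++ initialization followed by Lloyd iterations,
#' repeated `n_restarts` times, keeping the restart with the lowest
#' inertia. Each cluster is a microstate of the Markov model.
#'
#' @param trajs Feature trajectories (see [estimate_tica()] for
#'   accepted forms).
#' @param k Number of clusters.
#' @param n_restarts Independent restarts (default 10).
#' @param seed Integer seed controlling all restarts.
#' @param max_iter,tol Lloyd stopping rule: at most `max_iter`
#'   iterations or center shift below `tol`.
#'
#' @return An object of class `cluster_model`: `centers` (k x d), `k`,
#'   `inertia`, `n_restarts`, `seed`.
#' @export
kmeans_fit <- function(trajs, k, n_restarts = 10L, seed = NULL,
                       max_iter = 300L, tol = 1e-6) {
  trajs <- as_traj_list(trajs)
  k <- stopifnot_scalar_count(k, "k")
  n_restarts <- stopifnot_scalar_count(n_restarts, "n_restarts")
  X <- do.call(rbind, lapply(trajs, function(t) t$values))
  if (nrow(X) < k) {
    stop(sprintf("k (%d) exceeds the number of frames (%d)", k, nrow(X)))
  }
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_init(X, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = init, iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0L)) {
        # empty cluster: re-seed the restart from the farthest points
        message(sprintf("kmeans_fit: restart %d produced an empty cluster; re-seeding", r))
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = kmeanspp_init(X, k),
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(fit)) next
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  centers <- best$centers
  dimnames(centers) <- NULL
  structure(list(centers = centers, k = k, inertia = best$tot.withinss,
                 n_restarts = n_restarts, seed = seed, score = NULL),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, inertia = %.4g (%d restarts)\n",
              x$k, x$inertia, x$n_restarts))
  invisible(x)
}

#' Assign frames to microstates
#'
#' Nearest-center (Euclidean) labels; exact ties go to the lowest
#' center index.
#'
#' @param model A `cluster_model`.
#' @param ft A [feature_trajectory()] or matrix, or a list of them.
#' @return A 0-based integer label vector, or a list of them when a
#'   list was supplied.
#' @export
assign_microstates <- function(model, ft) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.list(ft) && !inherits(ft, "feature_trajectory")) {
    return(lapply(ft, function(x) assign_microstates(model, x)))
  }
  ft <- as_feature_trajectory(ft)
  X <- ft$values
  if (ncol(X) != ncol(model$centers)) {
    stop(sprintf("feature dimension %d does not match cluster model dimension %d",
                 ncol(X), ncol(model$centers)))
  }
  D <- outer(rowSums(X^2), rep(1, model$k)) - 2 * X %*% t(model$centers)
  D <- sweep(D, 2L, rowSums(model$centers^2), "+")
  max.col(-D, ties.method = "first") - 1L
}

vamp_count_matrices <- function(dtrajs, lag) {
  dtrajs <- as_dtraj_list(dtrajs)
  lag <- stopifnot_scalar_count(lag, "lag")
  n <- max(unlist(dtrajs)) + 1L
  C <- matrix(0, n, n)
  for (d in dtrajs) {
    L <- length(d)
    if (L <= lag) next
    i <- d[1:(L - lag)] + 1L
    j <- d[(1 + lag):L] + 1L
    tab <- table(factor(i, levels = seq_len(n)), factor(j, levels = seq_len(n)))
    C <- C + unclass(tab)
  }
  if (sum(C) == 0) stop("no transition pairs: every trajectory is shorter than the lag")
  C
}

#' VAMP-2 score of a microstate discretization
#'
#' Sum of squared leading singular values of the half-weighted
#' transition operator K = C00^(-1/2) C0t Ctt^(-1/2) estimated from
#' the discrete trajectories at the given lag. The constant process
#' contributes 1, so the score of any discretization is >= 1; higher
#' scores mean the microstates resolve more of the slow kinetics,
#' which makes VAMP-2 the selection criterion for the number of
#' clusters.
#'
#' @param dtrajs Discrete trajectory (0-based labels) or list of them.
#' @param lag Lag in frames.
#' @param n_components Number of singular values summed (default
#'   `min(10, n_states)`).
#' @return Scalar score >= ~1 (up to sampling noise). If the count
#'   graph is disconnected, the score is computed on the largest
#'   connected set and a warning is raised.
#' @export
vamp2_score <- function(dtrajs, lag, n_components = 10L) {
  C <- vamp_count_matrices(dtrajs, lag)
  cs <- largest_connected_set(C)
  if (length(cs) < nrow(C)) {
    warning(sprintf("count graph disconnected; scoring on the largest connected set (%d of %d states)",
                    length(cs), nrow(C)))
    C <- C[cs + 1L, cs + 1L, drop = FALSE]
  }
  r0 <- rowSums(C)
  ct <- colSums(C)
  keep <- r0 > 0 & ct > 0
  C <- C[keep, keep, drop = FALSE]
  K <- diag(1 / sqrt(rowSums(C)), nrow(C)) %*% C %*%
    diag(1 / sqrt(colSums(C)), ncol(C))
  s <- svd(K, nu = 0, nv = 0)$d
  s <- s[seq_len(min(n_components, length(s)))]
  sum(s^2)
}

#' Grid search over k with cross-validated VAMP-2 scoring
#'
#' For each candidate k the clustering is fitted on a random subset of
#' trajectories and scored with VAMP-2 on the held-out trajectories;
#' splits are over whole trajectories because frames within a
#' trajectory are autocorrelated. The selected k is the highest mean
#' score, with a one-standard-error tie-break toward smaller k.
#'
#' @param trajs Feature trajectories.
#' @param k_grid Candidate k values.
#' @param lag Lag (frames) for the VAMP-2 score.
#' @param n_restarts k-means restarts per fit.
#' @param seed Integer seed.
#' @param cv_folds Number of shuffle-split folds (default 5).
#' @param n_components Singular values summed in the score (default 5,
#'   one per targeted macrostate).
#'
#' @return List with `best_k` and `table` (data frame: k, mean score,
#'   standard error, number of successful folds).
#' @export
select_k <- function(trajs, k_grid, lag = 10L, n_restarts = 10L,
                     seed = NULL, cv_folds = 5L, n_components = 5L) {
  trajs <- as_traj_list(trajs)
  if (length(k_grid) < 1L) stop("'k_grid' must be nonempty")
  k_grid <- sort(unique(as.integer(k_grid)))
  nt <- length(trajs)
  scores <- matrix(NA_real_, length(k_grid), cv_folds)
  with_local_seed(seed, {
    for (f in seq_len(cv_folds)) {
      if (nt >= 2L) {
        n_train <- max(1L, floor(nt / 2))
        train <- sample.int(nt, n_train)
        test <- setdiff(seq_len(nt), train)
      } else {
        # single trajectory: split frames in half (autocorrelation
        # caveat documented)
        L <- nrow(trajs[[1]]$values)
        half <- floor(L / 2)
        train_t <- list(feature_trajectory(trajs[[1]]$values[1:half, , drop = FALSE],
                                           dt = trajs[[1]]$dt))
        test_t <- list(feature_trajectory(trajs[[1]]$values[(half + 1):L, , drop = FALSE],
                                          dt = trajs[[1]]$dt))
      }
      for (ki in seq_along(k_grid)) {
        res <- tryCatch({
          tr <- if (nt >= 2L) trajs[train] else train_t
          te <- if (nt >= 2L) trajs[test] else test_t
          cm <- kmeans_fit(tr, k_grid[ki], n_restarts = n_restarts,
                           seed = sample.int(.Machine$integer.max, 1L))
          dte <- assign_microstates(cm, te)
          suppressWarnings(vamp2_score(dte, lag, n_components = n_components))
        }, error = function(e) NA_real_)
        scores[ki, f] <- res
      }
    }
  })
  mean_s <- rowMeans(scores, na.rm = TRUE)
  se_s <- apply(scores, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  })
  tab <- data.frame(k = k_grid, mean_score = mean_s, se = se_s,
                    n_folds = rowSums(!is.na(scores)))
  ok <- is.finite(mean_s)
  if (!any(ok)) stop("VAMP-2 scoring failed for every k in the grid")
  i_best <- which(ok)[which.max(mean_s[ok])]
  thr <- mean_s[i_best] - (if (is.finite(se_s[i_best])) se_s[i_best] else 0)
  best_k <- k_grid[min(which(ok & mean_s >= thr))]
  list(best_k = best_k, table = tab)
}
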