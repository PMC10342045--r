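# Right eigenvectors of a reversible transition matrix through the
# symmetric conjugate S = D^(1/2) T D^(-1/2), D = diag(rho): guarantees
# a real spectrum and rho-orthogonal eigenvectors.
reversible_eigen <- function(T, rho) {
  sq <- sqrt(rho)
  S <- t(t(T * sq) / sq)                    # S_ij = sq_i T_ij / sq_j
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  psi <- e$vectors[, ord, drop = FALSE] / sq
  list(values = e$values[ord], vectors = psi)
}

#' PCCA+ metastable coarse-graining
#'
#' Groups the microstates of a reversible Markov model into m
#' metastable macrostates by Perron cluster analysis: the rows of the
#' first m dominant right eigenvectors lie (up to noise) in an
#' (m-1)-simplex whose vertices correspond to the pure metastable
#' states; an inner-simplex vertex search identifies those vertices and
#' the linear transformation onto them yields a fuzzy membership matrix
#' chi (rows sum to 1). Crisp labels are the row-argmax.
#'
#' @param msm A reversible `markov_model`.
#' @param m Number of macrostates (default 5, >= 2, at most the number
#'   of microstates).
#' @return An object of class `macro_partition`: `memberships`
#'   (n_micro x m), `crisp` (0-based macro label per active
#'   microstate), `m`, `weights` (macrostate stationary weights),
#'   `microstates` (the model's active set, original 0-based labels).
#' @export
pcca_plus <- function(msm, m = 5L) {
  stopifnot(inherits(msm, "markov_model"))
  if (!msm$reversible) {
    stop("PCCA+ requires a reversible model (real spectrum); re-estimate with reversible = TRUE")
  }
  m <- stopifnot_scalar_count(m, "m", min = 2L)
  T <- msm$transition_matrix
  n <- nrow(T)
  if (m > n) stop(sprintf("m (%d) exceeds the number of microstates (%d)", m, n))
  eg <- reversible_eigen(T, msm$stationary)
  if (any(eg$values[seq_len(m)] <= 0)) {
    stop(sprintf("eigenvalue %d of the first %d is not positive; choose a smaller m",
                 which(eg$values[seq_len(m)] <= 0)[1], m))
  }
  X <- eg$vectors[, seq_len(m), drop = FALSE]
  X[, 1] <- 1                                  # constant eigenvector

  # inner-simplex vertex search: the first vertex is the row farthest
  # from the centroid; each further vertex maximizes the distance to
  # the affine span of those already chosen (Gram-Schmidt).
  ind <- integer(m)
  Xw <- X
  ctr <- colMeans(Xw)
  d2 <- rowSums(sweep(Xw, 2L, ctr)^2)
  ind[1] <- which.max(d2)
  W <- sweep(Xw, 2L, Xw[ind[1], ])
  if (m > 1L) {
    for (j in 2:m) {
      d2 <- rowSums(W^2)
      ind[j] <- which.max(d2)
      v <- W[ind[j], ]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-14) stop("degenerate eigenvector structure; choose a smaller m")
      v <- v / nv
      W <- W - outer(as.numeric(W %*% v), v)
    }
  }

  A <- solve(X[ind, , drop = FALSE])
  chi <- X %*% A
  if (min(chi) < -0.2) {
    warning(sprintf("PCCA+ memberships substantially infeasible (min %.3f); macrostates may be ill-defined",
                    min(chi)))
  }
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first") - 1L
  if (length(unique(crisp)) < m) {
    stop("a macrostate received no microstates; choose a smaller m")
  }
  weights <- as.numeric(crossprod(chi, msm$stationary))
  structure(list(memberships = chi, crisp = crisp, m = m,
                 weights = weights, microstates = msm$active_set),
            class = "macro_partition")
}

#' @export
print.macro_partition <- function(x, ...) {
  cat(sprintf("<macro_partition> %d microstates -> %d macrostates\n",
              length(x$crisp), x$m))
  cat("stationary weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Map microstate trajectories to macrostate trajectories
#'
#' Frame-wise crisp mapping through the partition; deterministic and
#' idempotent. Labels outside the partition's microstate set (e.g.
#' states trimmed from the connected set) raise an error.
#'
#' @param partition A `macro_partition`.
#' @param dtrajs Microstate trajectory or list of them (0-based).
#' @return List of 0-based macrostate label vectors.
#' @export
coarse_grain_dtrajs <- function(partition, dtrajs) {
  stopifnot(inherits(partition, "macro_partition"))
  dtrajs <- as_dtraj_list(dtrajs)
  lookup <- rep(NA_integer_, max(c(unlist(dtrajs), partition$microstates)) + 1L)
  lookup[partition$microstates + 1L] <- partition$crisp
  lapply(dtrajs, function(d) {
    out <- lookup[d + 1L]
    if (anyNA(out)) {
      stop(sprintf("microstate %d is outside the partition's state set",
                   d[which(is.na(out))[1]]))
    }
    out
  })
}

#' Identify source and sink macrostates from trajectory endpoints
#'
#' The source set A is the modal macrostate over the first `window`
#' frames of every trajectory (majority vote pooled across
#' trajectories) — the initial conformational state; the sink B is the
#' modal macrostate over the last `window` frames — the final
#' convergence state. Explicit `A`/`B` arguments override the
#' auto-detection verbatim.
#'
#' @param macro_dtrajs Macrostate trajectories (list of 0-based label
#'   vectors), e.g. from [coarse_grain_dtrajs()].
#' @param window Frames inspected at each end (default 100).
#' @param A,B Optional explicit 0-based macrostate sets.
#' @return List with elements `A` and `B` (integer vectors).
#' @export
assign_endpoint_states <- function(macro_dtrajs, window = 100L,
                                   A = NULL, B = NULL) {
  macro_dtrajs <- as_dtraj_list(macro_dtrajs)
  if (!is.null(A) && !is.null(B)) {
    A <- as.integer(A); B <- as.integer(B)
    if (length(intersect(A, B)) > 0) stop("A and B must be disjoint")
    return(list(A = A, B = B))
  }
  modal <- function(x) as.integer(names(which.max(table(x))))
  heads <- unlist(lapply(macro_dtrajs, function(d) utils::head(d, window)))
  tails <- unlist(lapply(macro_dtrajs, function(d) utils::tail(d, window)))
  A <- A %||% modal(heads)
  B <- B %||% modal(tails)
  if (length(intersect(A, B)) > 0) {
    stop(sprintf("auto-detected source and sink coincide (state %d); designate A and B manually",
                 A[1]))
  }
  list(A = as.integer(A), B = as.integer(B))
}

#' Conventional macrostate names
#'
#' A-states are named SA, B-states SB, and the remaining macrostates
#' S1, S2, ... in order of decreasing stationary weight.
#'
#' @param partition A `macro_partition`.
#' @param A,B 0-based macrostate index sets.
#' @return Character vector of length m, indexed by macrostate.
#' @export
macrostate_names <- function(partition, A, B) {
  stopifnot(inherits(partition, "macro_partition"))
  nm <- character(partition$m)
  nm[A + 1L] <- "SA"
  nm[B + 1L] <- "SB"
  rest <- setdiff(seq_len(partition$m) - 1L, c(A, B))
  rest <- rest[order(partition$weights[rest + 1L], decreasing = TRUE)]
  nm[rest + 1L] <- paste0("S", seq_along(rest))
  nm
}

#' Serialize a macrostate partition as CSV
#'
#' One row per microstate: original label, fuzzy membership in each
#' macrostate, crisp assignment.
#'
#' @param partition A `macro_partition`.
#' @param path Output CSV.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "macro_partition"))
  df <- data.frame(microstate = partition$microstates)
  for (j in seq_len(partition$m)) {
    df[[paste0("macro", j - 1L)]] <- partition$memberships[, j]
  }
  df$crisp <- partition$crisp
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
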