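#' Ground-truth Markov chain
#'
#' A discrete-time Markov chain with a known row-stochastic transition
#' matrix and stationary distribution, used as planted ground truth when
#' validating estimators: a chain sampled from a known T lets the
#' package check that count matrices, transition-matrix estimates,
#' implied timescales and committors all converge to their analytic
#' values.
#'
#' @param transition_matrix Square row-stochastic matrix.
#' @param labels Optional state identifiers (default `0:(n-1)`).
#'
#' @return An object of class `ground_truth_chain` with elements
#'   `transition_matrix`, `stationary` and `labels`.
#' @export
ground_truth_chain <- function(transition_matrix, labels = NULL) {
  T <- as.matrix(transition_matrix)
  check_stochastic(T)
  n <- nrow(T)
  labels <- labels %||% (seq_len(n) - 1L)
  if (length(labels) != n) stop("'labels' length must equal the state count")
  rho <- stationary_distribution(T)
  if (max(abs(as.numeric(rho %*% T) - rho)) > 1e-10) {
    stop("stationary vector failed to satisfy rho T = rho within 1e-10")
  }
  structure(list(transition_matrix = T, stationary = rho, labels = labels),
            class = "ground_truth_chain")
}

#' @export
print.ground_truth_chain <- function(x, ...) {
  cat(sprintf("<ground_truth_chain> %d states, stationary = (%s)\n",
              nrow(x$transition_matrix),
              paste(signif(x$stationary, 3), collapse = ", ")))
  invisible(x)
}

#' Sample a discrete trajectory from a Markov chain
#'
#' @param chain A [ground_truth_chain()] or a row-stochastic matrix.
#' @param n_steps Number of frames to generate (>= 1).
#' @param start Starting state as a 0-based label, or `"stationary"` to
#'   draw the first frame from the stationary distribution.
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#'
#' @return Integer vector of 0-based state labels, length `n_steps`.
#' @export
#' @examples
#' ch <- ground_truth_chain(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
#' sample_markov_chain(ch, 10, start = 0, seed = 1)
sample_markov_chain <- function(chain, n_steps, start = "stationary", seed = NULL) {
  if (!inherits(chain, "ground_truth_chain")) chain <- ground_truth_chain(chain)
  n_steps <- stopifnot_scalar_count(n_steps, "n_steps")
  T <- chain$transition_matrix
  n <- nrow(T)
  cum <- t(apply(T, 1L, cumsum))
  with_local_seed(seed, {
    s0 <- if (identical(start, "stationary")) {
      sample.int(n, 1L, prob = chain$stationary)
    } else {
      s <- as.integer(start) + 1L
      if (s < 1L || s > n) stop("'start' must be a valid 0-based state index")
      s
    }
    out <- integer(n_steps)
    out[1L] <- s0
    if (n_steps > 1L) {
      u <- stats::runif(n_steps - 1L)
      for (t in 2:n_steps) {
        # inverse-CDF draw on the current row
        out[t] <- findInterval(u[t - 1L], cum[out[t - 1L], ],
                               left.open = TRUE) + 1L
      }
    }
    out - 1L
  })
}

#' Construct a block-structured metastable chain
#'
#' Builds a reversible row-stochastic matrix of `n_blocks` diagonal
#' blocks from a symmetric edge-weight matrix: each state carries a
#' self-weight of 1, states in the same block are joined by weights of
#' order `p_intra`, states in different blocks by weights of order
#' `p_inter`. Row-normalizing the symmetric weights gives a chain in
#' detailed balance with fast intra-block mixing and rare inter-block
#' hops, so the slowest `n_blocks - 1` relaxation processes are
#' separated from the rest by a spectral gap and the blocks are
#' recoverable by PCCA+.
#'
#' @param n_blocks Number of metastable blocks (planted macrostates).
#' @param states_per_block Microstates per block.
#' @param p_intra Edge-weight scale inside a block (sets intra-block
#'   mixing speed).
#' @param p_inter Edge-weight scale across blocks; must be much smaller
#'   than `p_intra` for a clean spectral gap.
#' @param seed Integer seed for the random weight perturbation that
#'   makes the chain generic.
#'
#' @return A [ground_truth_chain()] whose labels are
#'   `0:(n_blocks * states_per_block - 1)`; block membership of state i
#'   is `i %/% states_per_block`.
#' @export
make_metastable_chain <- function(n_blocks, states_per_block = 2L,
                                  p_intra = 0.4, p_inter = 0.01,
                                  seed = NULL) {
  n_blocks <- stopifnot_scalar_count(n_blocks, "n_blocks")
  states_per_block <- stopifnot_scalar_count(states_per_block, "states_per_block")
  if (!(p_intra > 0 && p_intra < 1) || !(p_inter >= 0 && p_inter < 1)) {
    stop("'p_intra' in (0,1) and 'p_inter' in [0,1) required")
  }
  if (n_blocks > 1L && p_inter >= p_intra) {
    stop("'p_inter' must be smaller than 'p_intra' for metastability")
  }
  n <- n_blocks * states_per_block
  block <- rep(seq_len(n_blocks), each = states_per_block)
  W <- with_local_seed(seed, {
    U <- matrix(stats::runif(n * n, 0.5, 1.5), n, n)
    U[lower.tri(U)] <- t(U)[lower.tri(U)]       # symmetric perturbation
    scale <- ifelse(outer(block, block, "=="), p_intra, p_inter)
    W <- scale * U
    diag(W) <- 1
    W
  })
  ground_truth_chain(W / rowSums(W))
}
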