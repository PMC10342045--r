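#' Forward and backward committor probabilities
#'
#' The forward committor q+_i is the probability that a trajectory
#' started in state i reaches the sink set B before the source set A.
#' It satisfies the boundary conditions q+ = 0 on A, q+ = 1 on B and,
#' on the intermediate states, the linear system
#' q+_i = sum_{j in B} T_ij + sum_{j not in A or B} T_ij q+_j,
#' solved here directly. Under detailed balance the backward committor
#' is the complement q-_i = 1 - q+_i (the default); for a
#' non-reversible matrix the general backward solve on the
#' time-reversed chain is available behind `backward = "general"`.
#'
#' @param T Row-stochastic transition matrix.
#' @param A,B Disjoint nonempty 0-based source and sink state sets.
#' @param backward `"reversible"` (q- = 1 - q+) or `"general"`
#'   (time-reversed solve; requires `rho`).
#' @param rho Stationary distribution, needed for
#'   `backward = "general"`.
#' @return List with `qplus` and `qminus` vectors.
#' @export
#' @examples
#' T <- matrix(c(0.9, 0.1, 0, 0.1, 0.8, 0.1, 0, 0.1, 0.9), 3, byrow = TRUE)
#' committors(T, A = 0, B = 2)$qplus   # 0, 0.5, 1
committors <- function(T, A, B, backward = c("reversible", "general"),
                       rho = NULL) {
  check_stochastic(T)
  backward <- match.arg(backward)
  n <- nrow(T)
  A <- as.integer(A) + 1L
  B <- as.integer(B) + 1L
  if (length(A) == 0 || length(B) == 0) stop("A and B must be nonempty")
  if (length(intersect(A, B)) > 0) stop("A and B must be disjoint")
  if (any(c(A, B) < 1L) || any(c(A, B) > n)) stop("A/B indices out of range")
  I <- setdiff(seq_len(n), c(A, B))
  qplus <- numeric(n)
  qplus[B] <- 1
  if (length(I) > 0) {
    M <- diag(length(I)) - T[I, I, drop = FALSE]
    rhs <- rowSums(T[I, B, drop = FALSE])
    sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      # identify intermediates that cannot reach B
      g <- igraph::graph_from_adjacency_matrix((T > 0) * 1, mode = "directed")
      reach <- igraph::subcomponent(g, B[1], mode = "in")
      trapped <- setdiff(I, as.integer(reach))
      stop(sprintf("committor system singular; states {%s} cannot reach B",
                   paste(trapped - 1L, collapse = ", ")))
    }
    qplus[I] <- sol
  }
  qminus <- if (backward == "reversible") {
    1 - qplus
  } else {
    if (is.null(rho)) stop("backward = 'general' requires 'rho'")
    Trev <- t(T * rho) / rho           # Trev_ij = rho_j T_ji / rho_i
    qminus <- numeric(n)
    qminus[A] <- 1
    if (length(I) > 0) {
      M <- diag(length(I)) - Trev[I, I, drop = FALSE]
      rhs <- rowSums(Trev[I, A, drop = FALSE])
      qminus[I] <- solve(M, rhs)
    }
    qminus
  }
  list(qplus = qplus, qminus = qminus)
}

#' Reactive flux network between a source and a sink
#'
#' Computes the transition-path-theory gross flux
#' f_ij = rho_i q-_i T_ij q+_j (the probability flux carried by
#' reactive A-to-B trajectories through the i-to-j edge, per lag step)
#' and the net flux f+_ij = max(f_ij - f_ji, 0). The total A-to-B flux
#' equals both the net flux out of A and the net flux into B
#' (conservation).
#'
#' @param T Row-stochastic transition matrix.
#' @param rho Stationary distribution of `T` (validated to 1e-6).
#' @param A,B Disjoint 0-based source and sink sets.
#' @param qplus,qminus Optional committors (computed from `T` if
#'   omitted).
#' @param dt Frame spacing (ns) carried as metadata.
#' @param lag Lag (frames) of the generating model, metadata for unit
#'   conversion.
#' @return An object of class `flux_network`: `A`, `B`, `qplus`,
#'   `qminus`, `gross`, `net`, `total_flux`, `states` (0-based ids),
#'   `dt`, `lag`.
#' @export
reactive_flux <- function(T, rho, A, B, qplus = NULL, qminus = NULL,
                          dt = 0.1, lag = 1L) {
  check_stochastic(T)
  n <- nrow(T)
  if (length(rho) != n || abs(sum(rho) - 1) > 1e-8) {
    stop("'rho' must be a probability vector matching T")
  }
  if (max(abs(as.numeric(rho %*% T) - rho)) > 1e-6) {
    stop("'rho' is not stationary for T (||rho T - rho|| > 1e-6)")
  }
  if (is.null(qplus) || is.null(qminus)) {
    q <- committors(T, A, B)
    qplus <- qplus %||% q$qplus
    qminus <- qminus %||% q$qminus
  }
  gross <- (rho * qminus) * T * rep(qplus, each = n)
  diag(gross) <- 0
  net <- pmax(gross - t(gross), 0)
  Ai <- as.integer(A) + 1L
  total <- sum(net[Ai, setdiff(seq_len(n), Ai), drop = FALSE])
  Bi <- as.integer(B) + 1L
  into_B <- sum(net[setdiff(seq_len(n), Bi), Bi, drop = FALSE])
  if (abs(total - into_B) > 1e-10 * max(total, 1e-300)) {
    warning(sprintf("flux conservation violated: out of A %.6g vs into B %.6g",
                    total, into_B))
  }
  structure(list(A = as.integer(A), B = as.integer(B), qplus = qplus,
                 qminus = qminus, gross = gross, net = net,
                 total_flux = total, states = seq_len(n) - 1L,
                 dt = dt, lag = lag),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("<flux_network> %d states, A = {%s}, B = {%s}, total flux %.4g per lag step\n",
              length(x$states), paste(x$A, collapse = ","),
              paste(x$B, collapse = ","), x$total_flux))
  invisible(x)
}

#' Coarse-grain a flux network over a macrostate partition
#'
#' Aggregates the microstate net flux across macrostate boundaries
#' (summing f+_ij over all microstate pairs with i in I, j in J) and
#' re-antisymmetrizes, F+_IJ = max(F_IJ - F_JI, 0). The source and
#' sink must be unions of macrostates; total flux is conserved. Macro
#' committors are reported as stationary-weighted averages of the
#' micro committors.
#'
#' @param net A `flux_network` over microstates.
#' @param partition A `macro_partition` whose `microstates` equal the
#'   network's states, or a list of 0-based microstate index sets.
#' @param rho Optional microstate stationary distribution for the
#'   committor averages (uniform if omitted).
#' @return A `flux_network` over macrostates.
#' @export
coarse_grain_flux <- function(net, partition, rho = NULL) {
  stopifnot(inherits(net, "flux_network"))
  groups <- if (inherits(partition, "macro_partition")) {
    if (!identical(sort(partition$microstates), sort(net$states))) {
      stop("partition microstates do not cover the flux network's states")
    }
    lapply(seq_len(partition$m) - 1L, function(k) {
      partition$microstates[partition$crisp == k]
    })
  } else {
    lapply(partition, as.integer)
  }
  covered <- sort(unlist(groups))
  if (!identical(covered, sort(net$states))) {
    stop("partition does not cover every state of the flux network exactly once")
  }
  m <- length(groups)
  member <- integer(length(net$states))
  for (k in seq_len(m)) member[match(groups[[k]], net$states)] <- k
  F <- matrix(0, m, m)
  for (I in seq_len(m)) {
    for (J in seq_len(m)) {
      if (I == J) next
      F[I, J] <- sum(net$net[member == I, member == J, drop = FALSE])
    }
  }
  Fnet <- pmax(F - t(F), 0)
  macro_of <- function(states) sort(unique(member[match(states, net$states)])) - 1L
  A_macro <- macro_of(net$A)
  B_macro <- macro_of(net$B)
  if (!all(net$states[member %in% (A_macro + 1L)] %in% net$A) ||
      !all(net$states[member %in% (B_macro + 1L)] %in% net$B)) {
    stop("A and B must be unions of macrostates")
  }
  rho <- rho %||% rep(1 / length(net$states), length(net$states))
  wmean <- function(q) {
    vapply(seq_len(m), function(k) {
      sum(q[member == k] * rho[member == k]) / sum(rho[member == k])
    }, numeric(1))
  }
  Ai <- A_macro + 1L
  total <- sum(Fnet[Ai, setdiff(seq_len(m), Ai), drop = FALSE])
  into_B <- sum(Fnet[setdiff(seq_len(m), B_macro + 1L), B_macro + 1L, drop = FALSE])
  if (abs(total - into_B) > 1e-10 * max(total, 1e-300)) {
    warning("coarse-grained flux conservation violated")
  }
  structure(list(A = A_macro, B = B_macro, qplus = wmean(net$qplus),
                 qminus = wmean(net$qminus), gross = F, net = Fnet,
                 total_flux = total, states = seq_len(m) - 1L,
                 dt = net$dt, lag = net$lag),
            class = "flux_network")
}

# Widest (maximum-bottleneck) path from the set A to the set B on the
# nonnegative edge matrix W; ties broken toward the lexicographically
# smallest path. Returns NULL if no path with positive width exists.
widest_path <- function(W, A, B) {
  n <- nrow(W)
  width <- rep(-Inf, n)
  paths <- vector("list", n)
  done <- rep(FALSE, n)
  for (a in A) {
    width[a] <- Inf
    paths[[a]] <- a
  }
  lex_less <- function(p, q) {
    k <- min(length(p), length(q))
    for (i in seq_len(k)) {
      if (p[i] != q[i]) return(p[i] < q[i])
    }
    length(p) < length(q)
  }
  repeat {
    cand <- which(!done & width > 0)
    if (length(cand) == 0) return(NULL)
    u <- cand[which.max(width[cand])]
    best <- width[u]
    tied <- cand[width[cand] == best]
    if (length(tied) > 1L) {
      for (t in tied) if (lex_less(paths[[t]], paths[[u]])) u <- t
    }
    if (u %in% B) {
      return(list(path = paths[[u]], width = width[u]))
    }
    done[u] <- TRUE
    for (v in which(W[u, ] > 0)) {
      if (done[v]) next
      w_new <- min(width[u], W[u, v])
      p_new <- c(paths[[u]], v)
      if (w_new > width[v] ||
          (w_new == width[v] && !is.null(paths[[v]]) && lex_less(p_new, paths[[v]]))) {
        width[v] <- w_new
        paths[[v]] <- p_new
      }
    }
  }
}

#' Decompose the reactive flux into ranked pathways
#'
#' Iterative maximum-bottleneck extraction: find the A-to-B path whose
#' minimum net-flux edge is largest, record the path with that
#' bottleneck flux, subtract the flux along the path, and repeat until
#' the residual drops below `residual_fraction_stop` of the total or
#' `max_paths` paths are extracted. Each path's probability is its
#' flux divided by the summed path fluxes.
#'
#' @param net A `flux_network`.
#' @param max_paths Maximum number of paths (default unbounded).
#' @param residual_fraction_stop Stop when the remaining flux falls
#'   below this fraction of the total (default 1e-3).
#' @return An object of class `pathway_decomposition`: `paths` (list
#'   of 0-based state vectors), `flux`, `percentage`, `total_flux`,
#'   `decomposed_flux`, `residual_flux`, plus the network's `dt`,
#'   `lag` and `states`.
#' @export
decompose_pathways <- function(net, max_paths = Inf,
                               residual_fraction_stop = 1e-3) {
  stopifnot(inherits(net, "flux_network"))
  W <- net$net
  A <- net$A + 1L
  B <- net$B + 1L
  total <- net$total_flux
  paths <- list()
  flux <- numeric(0)
  remaining <- total
  if (total > 0) {
    while (length(paths) < max_paths &&
           remaining > residual_fraction_stop * total) {
      wp <- widest_path(W, A, B)
      if (is.null(wp)) break
      f <- wp$width
      idx <- wp$path
      for (e in seq_len(length(idx) - 1L)) {
        W[idx[e], idx[e + 1L]] <- W[idx[e], idx[e + 1L]] - f
      }
      paths[[length(paths) + 1L]] <- idx - 1L
      flux <- c(flux, f)
      remaining <- remaining - f
    }
  } else {
    warning("no reactive A-to-B flux; empty decomposition")
  }
  pct <- if (length(flux) > 0) path_percentages(flux) else numeric(0)
  structure(list(paths = paths, flux = flux, percentage = pct,
                 total_flux = total, decomposed_flux = sum(flux),
                 residual_flux = total - sum(flux), states = net$states,
                 dt = net$dt, lag = net$lag),
            class = "pathway_decomposition")
}

#' @export
print.pathway_decomposition <- function(x, ...) {
  cat(sprintf("<pathway_decomposition> %d paths, %.4g of %.4g flux decomposed\n",
              length(x$paths), x$decomposed_flux, x$total_flux))
  invisible(x)
}

#' Path probabilities from path fluxes
#'
#' P_i = 100 f_i / sum_j f_j: each pathway's share of the decomposed
#' flux. A custom denominator may be supplied, e.g. a published total
#' that was rounded before the percentages were computed.
#'
#' @param fluxes Positive path fluxes.
#' @param denominator Optional custom total (default `sum(fluxes)`).
#' @return Percentages (unrounded; round to 2 decimals for reporting).
#' @export
#' @examples
#' path_percentages(c(4e-3, 2e-3, 6e-4, 1e-4, 3e-5, 3e-5))
path_percentages <- function(fluxes, denominator = NULL) {
  if (length(fluxes) == 0 || all(fluxes == 0)) {
    stop("at least one positive path flux is required")
  }
  if (any(fluxes < 0)) stop("path fluxes must be nonnegative")
  denom <- denominator %||% sum(fluxes)
  100 * fluxes / denom
}

#' Format a pathway decomposition as a flux table
#'
#' Three columns in the conventional layout: the pathway as an arrow
#' chain of state names, the path flux in scientific notation (3
#' significant figures), and the percentage of the decomposed flux (2
#' decimals), with a closing Total row. Fluxes are per lag step by
#' default; `per_second = TRUE` converts using the physical lag time
#' `lag * dt` ns.
#'
#' @param decomp A `pathway_decomposition`.
#' @param state_names Character names per state (e.g. from
#'   [macrostate_names()]); defaults to `s0`, `s1`, ...
#' @param per_second Convert fluxes to events per second.
#' @return Data frame with columns `pathway`, `path_flux`,
#'   `percentage` (character, formatted) and attribute
#'   `numeric_fluxes` with unrounded values.
#' @export
flux_table <- function(decomp, state_names = NULL, per_second = FALSE) {
  stopifnot(inherits(decomp, "pathway_decomposition"))
  state_names <- state_names %||% paste0("s", decomp$states)
  scale <- if (per_second) 1 / (decomp$lag * decomp$dt * 1e-9) else 1
  f <- decomp$flux * scale
  if (length(f) == 0) {
    out <- data.frame(pathway = "Total", path_flux = formatC(0, format = "e", digits = 2),
                      percentage = "0", stringsAsFactors = FALSE)
    attr(out, "numeric_fluxes") <- numeric(0)
    return(out)
  }
  pw <- vapply(decomp$paths, function(p) {
    paste(state_names[p + 1L], collapse = "→")
  }, character(1))
  out <- data.frame(
    pathway = c(pw, "Total"),
    path_flux = formatC(c(f, sum(f)), format = "e", digits = 2),
    percentage = c(sprintf("%.2f", decomp$percentage), "100"),
    stringsAsFactors = FALSE)
  attr(out, "numeric_fluxes") <- f
  out
}

#' Write / read a flux table as TSV
#'
#' @param tab A data frame from [flux_table()].
#' @param path Output TSV path.
#' @export
write_flux_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flux_table
#' @export
read_flux_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Export a flux network as an edge list
#'
#' One row per directed edge with positive net flux: `from`, `to`
#' (0-based state ids), `net_flux`.
#'
#' @param net A `flux_network`.
#' @param path Output CSV.
#' @export
write_flux_network <- function(net, path) {
  stopifnot(inherits(net, "flux_network"))
  idx <- which(net$net > 0, arr.ind = TRUE)
  df <- data.frame(from = net$states[idx[, 1]], to = net$states[idx[, 2]],
                   net_flux = net$net[idx])
  df <- df[order(-df$net_flux), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
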