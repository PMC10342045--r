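#' @keywords internal
"_PACKAGE"

# Run expr with a local RNG state seeded from `seed`; the caller's RNG
# stream is untouched. All stochastic operations in the package route
# their randomness through this helper so a call is a pure function of
# its arguments.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Row-stochasticity check shared by chain/MSM code. Names the first
# offending row so generator bugs are easy to locate.
check_stochastic <- function(T, tol = 1e-12, name = "transition matrix") {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (any(!is.finite(T)) || any(T < -tol) || any(T > 1 + tol)) {
    stop(sprintf("'%s' entries must lie in [0, 1]", name), call. = FALSE)
  }
  rs <- rowSums(T)
  bad <- which(abs(rs - 1) > 1e-8)
  if (length(bad) > 0) {
    stop(sprintf("row %d of %s sums to %.12g, not 1", bad[1], name, rs[bad[1]]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Stationary distribution of a row-stochastic matrix: leading left
# eigenvector, normalized to a probability vector.
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values) - 10 * abs(Im(e$values)))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) {
    stop("leading left eigenvector has negative entries; chain may be periodic or reducible",
         call. = FALSE)
  }
  pmax(v, 0) / sum(pmax(v, 0))
}

# Wrap angles (degrees) into (-180, 180]. One convention everywhere
# prevents seam artifacts at +/-180.
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
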