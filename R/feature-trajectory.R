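#' Feature trajectory
#'
#' A time-ordered frames x features numeric matrix with frame-spacing
#' metadata. This is the currency passed between featurization, TICA and
#' clustering: rows are simulation frames at a constant time spacing,
#' columns are scalar features (e.g. backbone dihedrals or TICA
#' components).
#'
#' @param values Numeric matrix, frames x features. All values finite.
#' @param dt Frame spacing in nanoseconds (default 0.1 ns).
#' @param feature_names Optional character vector, one name per column.
#' @param periodic Logical vector flagging angular features measured in
#'   degrees (wrapped to (-180, 180]); recycled if length 1.
#'
#' @return An object of class `feature_trajectory`.
#' @export
feature_trajectory <- function(values, dt = 0.1, feature_names = NULL,
                               periodic = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("feature trajectory needs at least one frame")
  if (any(!is.finite(values))) stop("feature trajectory values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("'dt' must be a single positive number (ns per frame)")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values) %||% paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("'feature_names' length must equal the feature dimension")
  }
  periodic <- rep_len(as.logical(periodic), ncol(values))
  colnames(values) <- feature_names
  structure(
    list(values = values, dt = dt, feature_names = feature_names,
         periodic = periodic),
    class = "feature_trajectory"
  )
}

#' @export
print.feature_trajectory <- function(x, ...) {
  cat(sprintf("<feature_trajectory> %d frames x %d features, dt = %g ns (%d periodic)\n",
              nrow(x$values), ncol(x$values), x$dt, sum(x$periodic)))
  invisible(x)
}

#' @export
dim.feature_trajectory <- function(x) dim(x$values)

as_feature_trajectory <- function(x, dt = 0.1) {
  if (inherits(x, "feature_trajectory")) x else feature_trajectory(x, dt = dt)
}

# Normalize "one trajectory or a list of them" into a list of
# feature_trajectory objects with a consistent feature dimension.
as_traj_list <- function(trajs, dt = 0.1) {
  if (inherits(trajs, "feature_trajectory") || is.matrix(trajs)) {
    trajs <- list(trajs)
  }
  trajs <- lapply(trajs, as_feature_trajectory, dt = dt)
  d <- vapply(trajs, function(t) ncol(t$values), integer(1))
  if (length(unique(d)) != 1L) {
    stop("all trajectories must share one feature dimension; got ",
         paste(unique(d), collapse = ", "))
  }
  trajs
}

# Discrete (microstate-label) trajectories: normalize to a list of
# integer vectors with 0-based labels allowed anywhere >= 0.
as_dtraj_list <- function(dtrajs) {
  if (is.numeric(dtrajs)) dtrajs <- list(dtrajs)
  dtrajs <- lapply(dtrajs, function(d) {
    d <- as.integer(d)
    if (length(d) < 1L || anyNA(d) || any(d < 0L)) {
      stop("discrete trajectories must be nonempty vectors of labels >= 0")
    }
    d
  })
  if (length(dtrajs) == 0L) stop("no discrete trajectories supplied")
  dtrajs
}

#' Write and read feature matrices as plain text
#'
#' Feature matrices travel as whitespace-delimited text with an optional
#' `#`-prefixed header naming the columns; discrete trajectories as one
#' integer label per line.
#'
#' @param ft A [feature_trajectory()].
#' @param path Output file.
#' @export
write_feature_matrix <- function(ft, path) {
  ft <- as_feature_trajectory(ft)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(ft$feature_names, collapse = " ")), con)
  utils::write.table(ft$values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param dt Frame spacing (ns) to attach on read.
#' @export
read_feature_matrix <- function(path, dt = 0.1) {
  first <- readLines(path, n = 1L)
  nm <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    nm <- strsplit(trimws(sub("^#", "", first)), "\\s+")[[1]]
    skip <- 1L
  }
  m <- as.matrix(utils::read.table(path, skip = skip))
  dimnames(m) <- NULL
  feature_trajectory(m, dt = dt, feature_names = nm)
}

#' @rdname write_feature_matrix
#' @param dtraj Integer label vector.
#' @export
write_dtraj <- function(dtraj, path) {
  writeLines(as.character(as.integer(dtraj)), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_dtraj <- function(path) as.integer(readLines(path))
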