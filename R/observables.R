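#' Observable series container
#'
#' Per-frame (or per-atom) values of a trajectory observable with its
#' units and the atom selection it was computed on.
#'
#' @param name Observable name.
#' @param values Numeric vector.
#' @param units Unit string ("A", "A^2", "1").
#' @param dt Frame spacing (ns); NA for per-atom series.
#' @param selection Atom indices used.
#' @export
observable_series <- function(name, values, units = "A", dt = NA_real_,
                              selection = NULL) {
  if (any(!is.finite(values))) stop("observable values must be finite")
  structure(list(name = name, values = as.numeric(values), units = units,
                 dt = dt, selection = selection),
            class = "observable_series")
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("<observable_series> %s: %d values [%s], mean %.4g\n",
              x$name, length(x$values), x$units, mean(x$values)))
  invisible(x)
}

#' Write an observable series as two-column CSV (time, value)
#'
#' @param series An `observable_series`.
#' @param path Output CSV.
#' @export
write_observable <- function(series, path) {
  t <- if (is.na(series$dt)) seq_along(series$values) - 1 else
    (seq_along(series$values) - 1) * series$dt
  utils::write.csv(data.frame(time = t, value = series$values), path,
                   row.names = FALSE)
  invisible(path)
}

#' Select atoms of a structure ensemble
#'
#' @param ens A [structure_ensemble()].
#' @param elety Atom name(s), e.g. `"CA"`.
#' @param resno Residue numbers to keep.
#' @param chain Chain identifiers to keep.
#' @return Integer atom indices (1-based).
#' @export
select_atoms <- function(ens, elety = NULL, resno = NULL, chain = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  keep <- rep(TRUE, nrow(ens$atoms))
  if (!is.null(elety)) keep <- keep & ens$atoms$elety %in% elety
  if (!is.null(resno)) keep <- keep & ens$atoms$resno %in% resno
  if (!is.null(chain)) keep <- keep & ens$atoms$chain %in% chain
  idx <- which(keep)
  if (length(idx) == 0) stop("selection matched no atoms")
  idx
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation mapping `mobile`
#' onto `reference` via the SVD of the weighted covariance of the
#' centered coordinate sets, with a proper rotation (det = +1)
#' enforced by reflecting the smallest singular direction when needed.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3 and not
#'   collinear.
#' @param weights Optional per-atom weights.
#' @return List with `rotation` (3 x 3, applied as
#'   `(x - center_mobile) %*% t(rotation) + center_reference`),
#'   `translation`, `rmsd`, and `fitted` coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L) {
    stop("'mobile' and 'reference' must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  Pm <- sweep(mobile, 2L, cm)
  Pr <- sweep(reference, 2L, cr)
  if (svd(Pm)$d[2] < 1e-10 || svd(Pr)$d[2] < 1e-10) {
    stop("coordinate set is collinear; superposition is degenerate")
  }
  H <- crossprod(Pm * w, Pr)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pm %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Pr)^2)))
  list(rotation = R, translation = cr - as.numeric(R %*% cm), rmsd = rmsd,
       fitted = sweep(fitted, 2L, cr, "+"))
}

#' Per-frame RMSD to a reference frame
#'
#' Each frame is optimally superposed onto the reference frame over
#' the selection before the root-mean-square deviation is taken, so
#' rigid-body motion does not register as deviation.
#'
#' @param ens A [structure_ensemble()].
#' @param reference Reference frame index (default 1).
#' @param selection Atom indices (default: CA atoms if present, else
#'   all).
#' @return An `observable_series` in Angstrom.
#' @export
rmsd_series <- function(ens, reference = 1L, selection = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  selection <- selection %||% default_selection(ens)
  ref <- ens$coords[reference, selection, , drop = TRUE]
  vals <- vapply(seq_len(dim(ens$coords)[1]), function(f) {
    kabsch_superpose(ens$coords[f, selection, , drop = TRUE], ref)$rmsd
  }, numeric(1))
  observable_series("RMSD", vals, units = "A", dt = ens$dt,
                    selection = selection)
}

default_selection <- function(ens) {
  ca <- which(ens$atoms$elety == "CA")
  if (length(ca) >= 3L) ca else seq_len(nrow(ens$atoms))
}

# Superpose every frame of a frames x atoms x 3 block onto the mean
# structure, iterated (mean is recomputed after each pass).
superpose_to_mean <- function(X, passes = 2L) {
  ref <- apply(X, c(2, 3), mean)
  for (p in seq_len(passes)) {
    for (f in seq_len(dim(X)[1])) {
      X[f, , ] <- kabsch_superpose(X[f, , , drop = TRUE], ref)$fitted
    }
    ref <- apply(X, c(2, 3), mean)
  }
  X
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF_a = sqrt(mean_t |r_a(t) - <r_a>|^2), after (by default)
#' superposing every frame onto the iteratively recomputed mean
#' structure (two passes) so global rigid motion is removed.
#'
#' @param ens A [structure_ensemble()] with >= 2 frames.
#' @param selection Atom indices (default CA).
#' @param superpose Remove global rigid-body motion first (default
#'   TRUE).
#' @return An `observable_series`, one value per selected atom, in
#'   Angstrom.
#' @export
rmsf <- function(ens, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (dim(ens$coords)[1] < 2L) stop("RMSF needs at least 2 frames")
  selection <- selection %||% default_selection(ens)
  X <- ens$coords[, selection, , drop = FALSE]
  if (superpose) X <- superpose_to_mean(X)
  mu <- apply(X, c(2, 3), mean)
  dev2 <- sweep(X, c(2, 3), mu)^2
  vals <- sqrt(apply(dev2, 2L, mean) * 3)   # mean over frames & xyz, summed over xyz
  observable_series("RMSF", vals, units = "A", selection = selection)
}

#' Crystallographic B-factors from fluctuations
#'
#' B = (8 pi^2 / 3) RMSF^2, the isotropic temperature-factor
#' convention, so simulated flexibility can be compared with
#' crystallographic B-factor columns.
#'
#' @param rmsf_values Nonnegative RMSF values (Angstrom) or an
#'   `observable_series`.
#' @return An `observable_series` in Angstrom^2.
#' @export
b_factor <- function(rmsf_values) {
  if (inherits(rmsf_values, "observable_series")) {
    sel <- rmsf_values$selection
    rmsf_values <- rmsf_values$values
  } else sel <- NULL
  if (any(rmsf_values < 0)) stop("RMSF values must be nonnegative")
  observable_series("B-factor", (8 * pi^2 / 3) * rmsf_values^2,
                    units = "A^2", selection = sel)
}

#' Per-frame radius of gyration
#'
#' Rg(t) = sqrt(sum_i w_i |r_i - r_com|^2 / sum_i w_i), a measure of
#' the compactness of the selected atoms.
#'
#' @param ens A [structure_ensemble()].
#' @param selection Atom indices (default CA).
#' @param masses Optional per-atom weights (default: unweighted).
#' @return An `observable_series` in Angstrom.
#' @export
radius_of_gyration <- function(ens, selection = NULL, masses = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  selection <- selection %||% default_selection(ens)
  w <- masses %||% rep(1, length(selection))
  if (sum(w) <= 0) stop("total weight must be positive")
  w <- w / sum(w)
  vals <- vapply(seq_len(dim(ens$coords)[1]), function(f) {
    P <- matrix(ens$coords[f, selection, ], ncol = 3L)
    com <- colSums(P * w)
    sqrt(sum(w * rowSums(sweep(P, 2L, com)^2)))
  }, numeric(1))
  observable_series("Rg", vals, units = "A", dt = ens$dt,
                    selection = selection)
}

#' Dynamical cross-correlation matrix
#'
#' Normalized correlations of atomic displacement vectors,
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), computed after
#' superposing all frames onto the mean structure (unless disabled).
#' +1 means fully correlated motion, -1 fully anticorrelated.
#'
#' @param ens A [structure_ensemble()] with >= 2 frames.
#' @param selection Atom indices (default CA).
#' @param superpose Remove global rigid-body motion first (default
#'   TRUE).
#' @return n x n matrix of class `correlation_matrix`; atoms with zero
#'   fluctuation give NA rows/columns (flagged with a warning).
#' @export
dccm <- function(ens, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (dim(ens$coords)[1] < 2L) stop("DCCM needs at least 2 frames")
  selection <- selection %||% default_selection(ens)
  X <- ens$coords[, selection, , drop = FALSE]
  if (superpose) X <- superpose_to_mean(X)
  mu <- apply(X, c(2, 3), mean)
  D <- sweep(X, c(2, 3), mu)
  n <- length(selection)
  nf <- dim(X)[1]
  # <dr_i . dr_j> = mean over frames of the dot product
  M <- matrix(0, n, n)
  for (k in 1:3) M <- M + crossprod(D[, , k]) / nf
  v <- diag(M)
  zero <- v <= 0
  if (any(zero)) warning(sprintf("%d atoms have zero fluctuation; entries set to NA", sum(zero)))
  denom <- sqrt(outer(v, v))
  C <- M / denom
  C[zero, ] <- NA
  C[, zero] <- NA
  dg <- diag(C)
  dg[!zero] <- 1
  diag(C) <- dg
  structure(C, class = c("correlation_matrix", "matrix"))
}

# quasi-uniform points on the unit sphere (golden-spiral lattice);
# deterministic, so SASA values are reproducible
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Built-in van der Waals radii
#'
#' @param elements Element symbols ("C", "N", "O", "S", "H", "P").
#' @return Radii in Angstrom.
#' @export
element_radii <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- tab[toupper(elements)]
  if (anyNA(r)) {
    r[is.na(r)] <- 1.70   # generic heavy-atom fallback
  }
  as.numeric(r)
}

#' Shrake--Rupley solvent-accessible surface area
#'
#' Classic sphere-point sampling: each atom's surface is expanded by
#' the probe radius and covered with a deterministic quasi-uniform
#' point lattice; a point is accessible if it lies outside every
#' neighboring atom's expanded sphere. Per-atom SASA is the accessible
#' fraction times the expanded sphere area.
#'
#' @param coords n x 3 coordinates (Angstrom) of a single frame.
#' @param radii Per-atom van der Waals radii (see [element_radii()]).
#' @param probe Probe radius, default 1.4 Angstrom (water).
#' @param n_points Lattice points per atom, default 960.
#' @return List with `atom_area` (vector, Angstrom^2) and `total`.
#' @export
sasa_shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  if (any(radii <= 0)) stop("radii must be positive")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  sp <- sphere_points(n_points)
  R <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * R[i], 2L, coords[i, ], "+")
    # neighbors whose expanded spheres can occlude atom i
    d2 <- rowSums(sweep(coords, 2L, coords[i, ])^2)
    nb <- which(d2 < (R + R[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      occl <- rowSums(sweep(pts, 2L, coords[j, ])^2) < R[j]^2
      acc <- acc & !occl
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  list(atom_area = area, total = sum(area))
}

#' Per-frame distance between two atom groups
#'
#' Euclidean distance between the (optionally mass-weighted) centers
#' of two selections — e.g. the gap between two binding-site loops
#' tracked along a simulation.
#'
#' @param ens A [structure_ensemble()].
#' @param selection_a,selection_b Nonempty atom index vectors.
#' @param masses_a,masses_b Optional weights per group.
#' @return An `observable_series` in Angstrom.
#' @export
group_distance <- function(ens, selection_a, selection_b,
                           masses_a = NULL, masses_b = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  if (length(selection_a) == 0 || length(selection_b) == 0) {
    stop("both selections must be nonempty")
  }
  wa <- masses_a %||% rep(1, length(selection_a)); wa <- wa / sum(wa)
  wb <- masses_b %||% rep(1, length(selection_b)); wb <- wb / sum(wb)
  vals <- vapply(seq_len(dim(ens$coords)[1]), function(f) {
    Pa <- matrix(ens$coords[f, selection_a, ], ncol = 3L)
    Pb <- matrix(ens$coords[f, selection_b, ], ncol = 3L)
    sqrt(sum((colSums(Pa * wa) - colSums(Pb * wb))^2))
  }, numeric(1))
  observable_series("group_distance", vals, units = "A", dt = ens$dt,
                    selection = c(selection_a, selection_b))
}
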