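cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Dihedral angle about the p2-p3 axis in degrees, IUPAC sign
#' convention (positive = clockwise rotation of p4 relative to p1 when
#' viewed from p2 toward p3); cis = 0, trans = 180. Uses the
#' atan2-based two-plane construction, which is numerically stable near
#' 0 and 180 degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))  # cis: 0
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0) {
    stop("consecutive points coincide; torsion undefined")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) {
    stop("three consecutive points are collinear; torsion undefined")
  }
  u2 <- b2 / sqrt(sum(b2^2))
  m1 <- cross3(n1, u2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi featurization of a structure ensemble
#'
#' Extracts phi (C[i-1], N[i], CA[i], C[i]) and psi (N[i], CA[i], C[i],
#' N[i+1]) torsions per residue per frame: phi is defined for every
#' residue after the first, psi for every residue before the last, so a
#' chain of n residues yields 2(n-1) angle columns by default. This is
#' the standard way to quantify the backbone geometry of each frame
#' before dimensionality reduction.
#'
#' @param ens A [structure_ensemble()] with N, CA, C atoms present for
#'   the selected residues.
#' @param which Subset of `c("phi", "psi")`.
#' @param residues Optional residue numbers to restrict the torsion
#'   set (a torsion is kept if its central residue is selected),
#'   letting users match a particular published feature count.
#'
#' @return A [feature_trajectory()], columns named like `phi_5`,
#'   `psi_5`, all flagged periodic, frame spacing propagated.
#' @export
backbone_dihedral_features <- function(ens, which = c("phi", "psi"),
                                       residues = NULL) {
  stopifnot(inherits(ens, "structure_ensemble"))
  which <- match.arg(which, several.ok = TRUE)
  at <- ens$atoms
  bb <- c("N", "CA", "C")

  # backbone atom index per (chain, residue)
  keys <- unique(at[, c("chain", "resno")])
  keys <- keys[order(keys$chain, keys$resno), , drop = FALSE]
  idx <- matrix(NA_integer_, nrow(keys), 3L,
                dimnames = list(NULL, bb))
  for (r in seq_len(nrow(keys))) {
    sel <- which(at$chain == keys$chain[r] & at$resno == keys$resno[r])
    for (a in bb) {
      hit <- sel[at$elety[sel] == a]
      if (length(hit) >= 1L) idx[r, a] <- hit[1L]
    }
  }

  quads <- list()
  for (r in seq_len(nrow(keys))) {
    resno <- keys$resno[r]
    if (!is.null(residues) && !(resno %in% residues)) next
    prev_ok <- r > 1L && keys$chain[r - 1L] == keys$chain[r]
    next_ok <- r < nrow(keys) && keys$chain[r + 1L] == keys$chain[r]
    need <- function(rr, a) {
      v <- idx[rr, a]
      if (is.na(v)) {
        stop(sprintf("residue %d (chain %s) is missing backbone atom %s",
                     keys$resno[rr], keys$chain[rr], a))
      }
      v
    }
    if ("phi" %in% which && prev_ok) {
      quads[[paste0("phi_", resno)]] <-
        c(need(r - 1L, "C"), need(r, "N"), need(r, "CA"), need(r, "C"))
    }
    if ("psi" %in% which && next_ok) {
      quads[[paste0("psi_", resno)]] <-
        c(need(r, "N"), need(r, "CA"), need(r, "C"), need(r + 1L, "N"))
    }
  }

  n_frames <- dim(ens$coords)[1]
  vals <- matrix(NA_real_, n_frames, length(quads))
  for (j in seq_along(quads)) {
    q <- quads[[j]]
    for (f in seq_len(n_frames)) {
      vals[f, j] <- compute_dihedral(ens$coords[f, q[1], ], ens$coords[f, q[2], ],
                                     ens$coords[f, q[3], ], ens$coords[f, q[4], ])
    }
  }
  feature_trajectory(vals, dt = ens$dt,
                     feature_names = names(quads) %||% character(0),
                     periodic = TRUE)
}

#' Sine/cosine embedding of periodic features
#'
#' Replaces each periodic (angular, degrees) feature by its sine and
#' cosine, removing the (-180, 180] seam before covariance-based
#' methods; non-periodic features pass through unchanged.
#'
#' @param ft A [feature_trajectory()] with periodic flags set.
#' @return A [feature_trajectory()] with `2 * n_periodic +
#'   n_nonperiodic` columns, none periodic.
#' @export
sincos_embed <- function(ft) {
  ft <- as_feature_trajectory(ft)
  cols <- list()
  nms <- character(0)
  for (j in seq_len(ncol(ft$values))) {
    if (ft$periodic[j]) {
      rad <- ft$values[, j] * pi / 180
      cols <- c(cols, list(sin(rad), cos(rad)))
      nms <- c(nms, paste0(ft$feature_names[j], c("_sin", "_cos")))
    } else {
      cols <- c(cols, list(ft$values[, j]))
      nms <- c(nms, ft$feature_names[j])
    }
  }
  feature_trajectory(do.call(cbind, cols), dt = ft$dt, feature_names = nms,
                     periodic = FALSE)
}
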