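# Shared fixtures: all built in code at test time.

# random proper rotation matrix
rand_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# NeRF internal-coordinate atom placement: position the next atom at
# the given bond length / bond angle / torsion relative to atoms a-b-c.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * (cos(chi) * m - sin(chi) * n))
}

# Ideal polypeptide backbone (N, CA, C per residue) with uniform
# phi/psi, omega = 180; standard bond lengths and angles.
build_backbone <- function(n_res, phi = -57, psi = -47) {
  coords <- matrix(NA_real_, n_res * 3L, 3L)
  atoms <- data.frame(
    elety = rep(c("N", "CA", "C"), n_res),
    resid = "ALA",
    resno = rep(seq_len(n_res), each = 3L),
    chain = "A", stringsAsFactors = FALSE)
  coords[1, ] <- c(0, 0, 0)
  coords[2, ] <- c(1.458, 0, 0)
  coords[3, ] <- place_atom(c(-1, 1, 0), coords[1, ], coords[2, ],
                            1.525, 111.2, phi)
  for (r in 2:n_res) {
    i <- (r - 1L) * 3L
    # N(r): psi torsion about CA(r-1)-C(r-1)
    coords[i + 1, ] <- place_atom(coords[i - 2, ], coords[i - 1, ], coords[i, ],
                                  1.329, 116.2, psi)
    # CA(r): omega torsion about C(r-1)-N(r)
    coords[i + 2, ] <- place_atom(coords[i - 1, ], coords[i, ], coords[i + 1, ],
                                  1.458, 121.7, 180)
    # C(r): phi torsion about N(r)-CA(r)
    coords[i + 3, ] <- place_atom(coords[i, ], coords[i + 1, ], coords[i + 2, ],
                                  1.525, 111.2, phi)
  }
  structure_ensemble(coords, atoms, dt = 0.1)
}

# best label agreement over all permutations of m labels
best_perm_agreement <- function(pred, truth, m) {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- 0
  for (p in perms(seq_len(m) - 1L)) {
    best <- max(best, mean(p[pred + 1L] == truth))
  }
  best
}

# brute-force strongly-connected-set oracle: reachability by repeated
# boolean matrix powers
brute_force_scc_largest <- function(C) {
  n <- nrow(C)
  R <- (C > 0) | diag(n)
  for (k in seq_len(n)) R <- R | (R %*% R) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[R[i, ] & R[, i]] <- cid
    }
  }
  sizes <- table(comp)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  firsts <- vapply(best, function(b) min(which(comp == b)), integer(1))
  sort(which(comp == best[which.min(firsts)])) - 1L
}

# independent torsion oracle: angle between plane normals with the
# sign from the scalar triple product (no atan2 of the in-plane basis)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosv <- max(-1, min(1, cosv))
  ang <- acos(cosv) * 180 / pi
  if (sum(cr(n1, n2) * b2) > 0) ang <- -ang
  ang
}
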