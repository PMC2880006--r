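#' Extract the chiral-carbon path from a structure
#'
#' Returns the Calpha coordinates ("chiral carbons"; glycine's Calpha is
#' included even though it is not formally chiral) of the requested
#' residues, in the requested order. These points are the grid-box centers
#' of the binding path. When alternate locations are present the
#' highest-occupancy conformer wins (ties: first record).
#'
#' @param pdb a file path to a PDB file, or a `bio3d` pdb object.
#' @param chain_id single chain identifier.
#' @param residue_ids ordered integer vector of author residue numbers.
#' @return numeric matrix (length(residue_ids) x 3) of coordinates in
#'   angstroms, rownames the residue ids.
#' @export
extract_ca_path <- function(pdb, chain_id, residue_ids) {
  if (is.character(pdb)) {
    # keep all alternate locations; conformer choice is occupancy-based here
    pdb <- suppressWarnings(bio3d::read.pdb(pdb, rm.alt = FALSE,
                                            verbose = FALSE))
  }
  at <- pdb$atom
  out <- matrix(NA_real_, nrow = length(residue_ids), ncol = 3,
                dimnames = list(residue_ids, c("x", "y", "z")))
  for (r in seq_along(residue_ids)) {
    sel <- which(at$elety == "CA" & at$chain == chain_id &
                   at$resno == residue_ids[r])
    if (!length(sel)) {
      stop(sprintf("chain %s residue %d: no CA atom found",
                   chain_id, residue_ids[r]))
    }
    if (length(sel) > 1L) {
      occ <- at$o[sel]
      occ[is.na(occ)] <- 0
      sel <- sel[which.max(occ)]  # which.max keeps the first on ties
    }
    out[r, ] <- as.numeric(at[sel, c("x", "y", "z")])
  }
  if (nrow(out) >= 2L) {
    d <- sqrt(rowSums((out[-1, , drop = FALSE] -
                         out[-nrow(out), , drop = FALSE])^2))
    if (any(d == 0)) stop("consecutive path points coincide")
  }
  out
}

#' Grid boxes along the binding path
#'
#' One cubic search box per path point, centered on it. The edge follows
#' the empirical sizing rule: 2.5 times the candidate's nitrogen-to-
#' terminal-carbon backbone span. In screening mode (`policy = "max"`) all
#' boxes take 2.5 x the largest span so a single box accommodates every
#' candidate at that grid.
#'
#' @param path numeric matrix (n x 3) of grid centers in angstroms
#'   ([extract_ca_path()] output).
#' @param span backbone N-to-C span(s) in angstroms: a scalar or one value
#'   per path point.
#' @param policy `"per-candidate"` (edge from each span) or `"max"` (all
#'   edges from the largest span).
#' @return data frame with columns `center_x`, `center_y`, `center_z`,
#'   `edge`.
#' @export
grid_boxes <- function(path, span, policy = c("per-candidate", "max")) {
  policy <- match.arg(policy)
  path <- as.matrix(path)
  if (ncol(path) != 3L || nrow(path) < 1L) stop("'path' must be an n x 3 matrix")
  if (any(!is.finite(span)) || any(span <= 0)) {
    stop("'span' must be positive and finite")
  }
  span <- rep_len(span, nrow(path))
  edge <- if (policy == "max") rep(2.5 * max(span), nrow(path)) else 2.5 * span
  data.frame(center_x = path[, 1], center_y = path[, 2],
             center_z = path[, 3], edge = edge)
}

# cross product of 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC signed torsion about the p2-p3 axis, in degrees in
#' (-180, 180]. Zero for a planar cis arrangement, 180 for trans, positive
#' for a right-handed (clockwise looking from p2 to p3) rotation.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (angstroms).
#' @return dihedral angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("undefined dihedral: three consecutive points are collinear")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- cross3(b2u, n1)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# backbone atom order of an Ace-capped dipeptide fragment
BACKBONE_ATOMS <- c("C_ace", "N1", "CA1", "C1", "N2", "CA2", "C2")

#' Backbone torsions of an Ace-capped dipeptide
#'
#' From the seven backbone atoms of a capped dipeptide -- the acetyl
#' carbonyl carbon (which defines phi of the first residue), then N, CA, C
#' of residue t and N, CA, C of residue t+1 -- computes the three angles
#' the emission model consumes: phi_t (C_ace-N1-CA1-C1), psi_t
#' (N1-CA1-C1-N2) and phi_t+1 (C1-N2-CA2-C2).
#'
#' @param atoms numeric 7 x 3 matrix of coordinates in backbone order;
#'   rownames, if present, must be `C_ace, N1, CA1, C1, N2, CA2, C2`.
#' @return named numeric vector `c(phi_t, psi_t, phi_next)` in degrees.
#' @export
backbone_torsions <- function(atoms) {
  atoms <- as.matrix(atoms)
  if (is.null(rownames(atoms))) {
    if (nrow(atoms) != 7L) {
      missing_from <- if (nrow(atoms) == 6L) "C_ace (phi_t undefined without the acetyl cap)"
        else paste(BACKBONE_ATOMS[seq(nrow(atoms) + 1L, 7L)], collapse = ", ")
      stop("missing backbone atom(s): ", missing_from)
    }
    rownames(atoms) <- BACKBONE_ATOMS
  }
  miss <- setdiff(BACKBONE_ATOMS, rownames(atoms))
  if (length(miss)) stop("missing backbone atom(s): ",
                         paste(miss, collapse = ", "))
  atoms <- atoms[BACKBONE_ATOMS, , drop = FALSE]
  if (any(!is.finite(atoms))) stop("non-finite backbone coordinate")
  c(phi_t = dihedral(atoms["C_ace", ], atoms["N1", ], atoms["CA1", ], atoms["C1", ]),
    psi_t = dihedral(atoms["N1", ], atoms["CA1", ], atoms["C1", ], atoms["N2", ]),
    phi_next = dihedral(atoms["C1", ], atoms["N2", ], atoms["CA2", ], atoms["C2", ]))
}

# place atom D given A, B, C with bond length r (C-D), bond angle theta
# (B-C-D, degrees) and torsion chi (A-B-C-D, degrees); the NeRF
# construction used by the forward-kinematics builder
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(C + M %*% d2)
}

#' Build capped-dipeptide backbone geometry from target torsions
#'
#' Forward-kinematics constructor: places the seven backbone atoms of an
#' Ace-capped dipeptide with ideal bond lengths and angles so that
#' [backbone_torsions()] recovers the requested phi_t, psi_t and phi_t+1
#' (the peptide bond omega is trans by default). Used to manufacture
#' synthetic docked conformations with known torsion states.
#'
#' @param phi_t,psi_t,phi_next target torsions in degrees.
#' @param omega peptide-bond torsion between the two residues (default 180).
#' @return 7 x 3 coordinate matrix with rownames `C_ace ... C2`.
#' @export
build_dipeptide_geometry <- function(phi_t, psi_t, phi_next, omega = 180) {
  # ideal backbone internals: C-N 1.329 A, N-CA 1.458 A, CA-C 1.525 A;
  # angles C-N-CA 121.7, N-CA-C 111.2, CA-C-N 116.2 degrees
  atoms <- matrix(NA_real_, nrow = 7, ncol = 3,
                  dimnames = list(BACKBONE_ATOMS, c("x", "y", "z")))
  atoms["C_ace", ] <- c(0, 0, 0)
  atoms["N1", ] <- c(1.329, 0, 0)
  # CA1 in the xy-plane at the C-N-CA angle
  a <- (180 - 121.7) * pi / 180
  atoms["CA1", ] <- atoms["N1", ] + 1.458 * c(cos(a), sin(a), 0)
  atoms["C1", ] <- place_atom(atoms["C_ace", ], atoms["N1", ], atoms["CA1", ],
                              1.525, 111.2, phi_t)
  atoms["N2", ] <- place_atom(atoms["N1", ], atoms["CA1", ], atoms["C1", ],
                              1.329, 116.2, psi_t)
  atoms["CA2", ] <- place_atom(atoms["CA1", ], atoms["C1", ], atoms["N2", ],
                               1.458, 121.7, omega)
  atoms["C2", ] <- place_atom(atoms["C1", ], atoms["N2", ], atoms["CA2", ],
                              1.525, 111.2, phi_next)
  atoms
}
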