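## Ideal regular duplex fixtures: a torsion-built reference residue
## propagated by the helix screw symmetry it implies.

# flatten a residue atom matrix to one n*3 matrix (fixed atom order)
residue_coords <- function(res) res$atoms

# Screw transform mapping residue i to residue i+1 of a regular
# (constant-torsion) chain: rotation angle about the helix axis (twist),
# translation along it (rise), axis direction and a point on the axis.
helix_screw <- function(res_a, res_b) {
  common <- intersect(rownames(res_a$atoms), rownames(res_b$atoms))
  fit <- kabsch_superpose(res_a$atoms[common, , drop = FALSE],
                          res_b$atoms[common, , drop = FALSE])
  R <- fit$rotation; tv <- fit$translation
  # rotation axis: unit eigenvector of R for eigenvalue 1
  ev <- eigen(R)
  axis <- Re(ev$vectors[, which.min(abs(Re(ev$values) - 1))])
  axis <- axis / vnorm(axis)
  rise <- sum(axis * tv)
  if (rise < 0) { axis <- -axis; rise <- -rise }
  # signed twist about +axis
  ref <- c(1, 0, 0)
  if (abs(sum(ref * axis)) > 0.9) ref <- c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / vnorm(u)
  v <- vcross(axis, u)
  Ru <- drop(R %*% u)
  twist <- rad2deg(atan2(sum(Ru * v), sum(Ru * u)))
  # point on axis: solve (I - R) p = t_perp in the plane orthogonal to axis
  t_perp <- tv - rise * axis
  M <- diag(3) - R
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
  p <- drop(sv$v %*% (dinv * crossprod(sv$u, t_perp)))
  list(rotation = R, translation = tv, axis = axis, point = p,
       twist = twist, rise = rise)
}

rotz <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

# Express a residue template in helix-axis coordinates: axis = +z through
# the origin, C1' of the template at angle 0, z = 0.
axis_frame_template <- function(res, screw) {
  a <- screw$axis; p <- screw$point
  c1 <- res$atoms["C1'", ]
  radial <- (c1 - p) - sum((c1 - p) * a) * a
  x <- radial / vnorm(radial)
  y <- vcross(a, x)
  Q <- cbind(x, y, a)
  z0 <- sum((c1 - p) * a)
  atoms <- sweep(res$atoms, 2L, p + z0 * a) %*% Q
  res$atoms <- atoms
  # twist sign in this frame (about +z)
  res
}

#' Generate an ideal regular duplex fixture
#'
#' Builds an idealized antiparallel duplex by propagating a reference
#' base-pair backbone template with a fixed per-step twist and rise:
#' A-form parameters for RNA, B-form for DNA, as implied by the reference
#' torsion sets in [nucleic_geometry()]. The second strand is the first
#' rotated 180 degrees about an in-plane dyad and phased so that paired
#' C1' atoms sit at the documented inter-strand geometry. Residue `k` of
#' strand 1 pairs residue `n_bp - 1 - k` of strand 2 (0-based).
#'
#' @param polymer_class `"RNA"` or `"DNA"`.
#' @param n_bp Number of base pairs (>= 1).
#' @return List with `strands` (two [nucleic_chain]s, 5' to 3'), `pairing`
#'   (two-column 0-based matrix of cross-strand paired residue indices),
#'   `polymer_class`, `twist` (degrees/step) and `rise` (angstrom/step).
#' @examples
#' dup <- ideal_duplex("RNA", 8)
#' dup$rise
#' @export
ideal_duplex <- function(polymer_class = c("RNA", "DNA"), n_bp) {
  polymer_class <- match.arg(polymer_class)
  n_bp <- as.integer(n_bp)
  if (is.na(n_bp) || n_bp < 1L) natk_stop("natk_invalid", "n_bp must be >= 1")
  ref <- build_backbone(form_torsions(4L, polymer_class), polymer_class)
  screw <- helix_screw(ref$residues[[2L]], ref$residues[[3L]])
  tpl <- axis_frame_template(ref$residues[[2L]], screw)
  hp <- .helix_params[[polymer_class]]
  twist <- screw$twist; rise <- screw$rise
  # helix-frame twist sign: measure C1' angle advance in the axis frame
  make_residue <- function(atoms, k, strip_p) {
    nm <- rownames(atoms)
    if (strip_p) {
      keep <- !nm %in% c("P", "OP1", "OP2")
      atoms <- atoms[keep, , drop = FALSE]
    }
    list(class = polymer_class, pucker = tpl$pucker, atoms = atoms)
  }
  strand_a <- lapply(seq_len(n_bp) - 1L, function(k) {
    at <- tpl$atoms %*% t(rotz(k * twist))
    at[, 3L] <- at[, 3L] + k * rise
    rownames(at) <- rownames(tpl$atoms)
    make_residue(at, k, strip_p = (k == 0L))
  })
  # dyad: 180-degree rotation about x, then phase about z and rise shift so
  # that residue n_bp-1-k of strand B pairs residue k of strand A at equal z
  phase_sep <- hp[["phase"]]
  phi <- (n_bp - 1L) * twist - phase_sep
  D <- diag(c(1, -1, -1))
  M <- rotz(phi) %*% D
  dz <- (n_bp - 1L) * rise
  strand_b <- lapply(seq_len(n_bp) - 1L, function(k) {
    at0 <- tpl$atoms %*% t(rotz(k * twist))
    at0[, 3L] <- at0[, 3L] + k * rise
    at <- at0 %*% t(M)
    at[, 3L] <- at[, 3L] + dz
    rownames(at) <- rownames(tpl$atoms)
    make_residue(at, k, strip_p = (k == 0L))
  })
  list(strands = list(nucleic_chain(strand_a), nucleic_chain(strand_b)),
       pairing = cbind(seq_len(n_bp) - 1L, rev(seq_len(n_bp) - 1L)),
       polymer_class = polymer_class, twist = twist, rise = rise)
}
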