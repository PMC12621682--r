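## Full-atom nucleic-acid backbone construction from frames and torsions,
## residue frames, and superposition metrics.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}
vnorm <- function(a) sqrt(sum(a * a))

# angle (degrees) at b
atom_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  rad2deg(acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))))
}

#' Dihedral angle of four points
#'
#' Signed dihedral (degrees, IUPAC convention, in (-180, 180]) of the
#' chain a-b-c-d.
#'
#' @param a,b,c,d Numeric 3-vectors.
#' @return Angle in degrees.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  ang <- -rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang + 360 else ang
}

# NeRF placement: new atom D bonded to refC with |refC-D| = bond,
# angle(refB, refC, D) = angle and dihedral(refA, refB, refC, D) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b; bc <- bc / vnorm(bc)
  w <- (a - b) - sum((a - b) * bc) * bc
  nw <- vnorm(w)
  if (nw < 1e-9)
    natk_stop("natk_degenerate", "collinear reference atoms in placement")
  p <- w / nw
  q <- vcross(bc, p)
  c + bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * p + sin(tor) * q))
}

#' Residue frame from the O4'-C1'-C2' atom triple
#'
#' Local rigid coordinate system per residue: origin at C1'; first axis the
#' unit vector toward O4'; second axis the component of C1'-to-C2'
#' orthogonal to the first, normalized; third axis their cross product.
#' The rotation matrix columns are these axes (orthonormal, det +1).
#'
#' @param o4,c1,c2 Coordinates (3-vectors, angstrom) of O4', C1', C2'.
#' @return Object of class `nucleic_frame`: list with `origin` (3-vector)
#'   and `rotation` (3x3 matrix).
#' @export
frame_from_atoms <- function(o4, c1, c2) {
  a1 <- o4 - c1
  n1 <- vnorm(a1)
  if (n1 < 1e-9) natk_stop("natk_degenerate", "O4' and C1' coincide")
  a1 <- a1 / n1
  v <- c2 - c1
  a2 <- v - sum(v * a1) * a1
  n2 <- vnorm(a2)
  if (n2 < 1e-9) natk_stop("natk_degenerate", "O4', C1', C2' are collinear")
  a2 <- a2 / n2
  structure(list(origin = c1, rotation = cbind(a1, a2, vcross(a1, a2),
                                               deparse.level = 0)),
            class = "nucleic_frame")
}

#' @export
print.nucleic_frame <- function(x, ...) {
  cat("nucleic_frame: origin", sprintf("(%.3f, %.3f, %.3f)", x$origin[1],
                                       x$origin[2], x$origin[3]), "\n")
  print(round(x$rotation, 4))
  invisible(x)
}

#' Per-residue frames of a chain
#'
#' Computes the O4'-C1'-C2' frame of every residue.
#'
#' @param chain A [nucleic_chain].
#' @return List of `nucleic_frame` objects, one per residue.
#' @export
residue_frames <- function(chain) {
  stopifnot(inherits(chain, "nucleic_chain"))
  lapply(chain$residues, function(r)
    frame_from_atoms(r$atoms["O4'", ], r$atoms["C1'", ], r$atoms["C2'", ]))
}

#' Construct a nucleic chain object
#'
#' A polymer-class-aware full-atom chain: per-residue atom coordinate
#' matrices in 5'-to-3' order. Normally produced by [build_backbone()],
#' [ideal_duplex()] or [read_pdb()].
#'
#' @param residues List; each element a list with `class` (`"RNA"` or
#'   `"DNA"`), `atoms` (matrix with atom-name rownames and 3 columns), and
#'   optional `pucker` label.
#' @return Object of class `nucleic_chain`.
#' @export
nucleic_chain <- function(residues) {
  for (r in residues) {
    if (!r$class %in% c("RNA", "DNA"))
      natk_stop("natk_invalid", "polymer class must be RNA or DNA")
    if (!is.matrix(r$atoms) || ncol(r$atoms) != 3L || is.null(rownames(r$atoms)))
      natk_stop("natk_invalid", "residue atoms must be a named n x 3 matrix")
  }
  structure(list(residues = residues), class = "nucleic_chain")
}

#' @export
print.nucleic_chain <- function(x, ...) {
  cls <- vapply(x$residues, `[[`, "", "class")
  cat(sprintf("nucleic_chain: %d residue(s) (%s), %d atoms\n",
              length(x$residues),
              paste(unique(cls), collapse = "/"),
              sum(vapply(x$residues, function(r) nrow(r$atoms), 0L))))
  invisible(x)
}

#' @export
length.nucleic_chain <- function(x) length(x$residues)

.core_backbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                    "O3'", "C2'", "C1'")

#' Validate nucleic-chain invariants
#'
#' Checks the polymer-class chemistry rule (RNA residues carry O2', DNA
#' residues do not), backbone completeness (every residue has the full
#' sugar-phosphate atom set, except the 5'-terminal residue which may lack
#' the phosphate group), and O3'(i) to P(i+1) connectivity within 0.1
#' angstrom of the ideal phosphodiester bond length.
#'
#' @param chain A [nucleic_chain].
#' @return `chain`, invisibly; errors otherwise.
#' @export
validate_chain <- function(chain) {
  stopifnot(inherits(chain, "nucleic_chain"))
  for (k in seq_along(chain$residues)) {
    r <- chain$residues[[k]]
    nm <- rownames(r$atoms)
    has_o2 <- "O2'" %in% nm
    if (r$class == "RNA" && !has_o2)
      natk_stop("natk_invalid", "RNA residue %d lacks O2'", k)
    if (r$class == "DNA" && has_o2)
      natk_stop("natk_invalid", "DNA residue %d has O2'", k)
    need <- .core_backbone
    if (k == 1L) need <- setdiff(need, c("P", "OP1", "OP2"))
    miss <- setdiff(need, nm)
    if (length(miss))
      natk_stop("natk_invalid", "residue %d missing backbone atom(s): %s",
                k, paste(miss, collapse = ", "))
  }
  ideal <- .bb_bond[["O3'-P"]]
  for (k in seq_len(length(chain$residues) - 1L)) {
    d <- vnorm(chain$residues[[k]]$atoms["O3'", ] -
                 chain$residues[[k + 1L]]$atoms["P", ])
    if (abs(d - ideal) > 0.1)
      natk_stop("natk_invalid",
                "O3'(%d)-P(%d) bond is %.3f A (ideal %.3f +/- 0.1)",
                k, k + 1L, d, ideal)
  }
  invisible(chain)
}

#' Reference torsion tables
#'
#' Per-residue backbone torsion tables filled with the fiber A-form (RNA)
#' or B-form (DNA) reference values from [nucleic_geometry()].
#'
#' @param n Residue count.
#' @param polymer_class `"RNA"` or `"DNA"`.
#' @return Data frame with columns `alpha`, `beta`, `gamma`, `delta`,
#'   `epsilon`, `zeta`, `chi`, `pucker`.
#' @export
form_torsions <- function(n, polymer_class = c("RNA", "DNA")) {
  polymer_class <- match.arg(polymer_class)
  tset <- .form_torsions[[polymer_class]]
  out <- as.data.frame(as.list(tset))[rep(1L, n), , drop = FALSE]
  out$pucker <- .default_pucker[[polymer_class]]
  rownames(out) <- NULL
  out
}

check_torsion_range <- function(torsions) {
  cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  for (cc in cols) {
    v <- torsions[[cc]]
    bad <- which(!is.na(v) & (v <= -180 | v > 180))
    if (length(bad))
      natk_stop("natk_invalid",
                "torsion %s of residue %d out of range (-180, 180]", cc, bad[1L])
  }
  invisible(torsions)
}

#' Build a full-atom backbone from torsions
#'
#' Places the sugar-phosphate backbone atom by atom by internal-coordinate
#' (NeRF) construction: each atom from a bond length, bond angle and
#' torsion relative to three previously placed atoms, following the
#' connectivity graph 5' to 3'. The sugar ring is closed with the rigid
#' pucker template of each residue's mode label; O2' is added for RNA
#' residues only; a generic glycosidic nitrogen (N9) and one base reference
#' atom (C4, placed by chi) mark the base attachment. The 5'-terminal
#' residue is built without a phosphate group, so `alpha`/`beta` of residue
#' 1 and `epsilon`/`zeta` of the last residue are unused (may be `NA`).
#'
#' @param torsions Data frame (one row per residue) with columns `alpha`,
#'   `beta`, `gamma`, `delta`, `epsilon`, `zeta`, `chi` in degrees, and
#'   optionally `pucker` (`"C3'-endo"` or `"C2'-endo"`; defaults by class).
#' @param polymer_classes Character vector, `"RNA"`/`"DNA"` per residue
#'   (recycled if length 1).
#' @param start_frame Optional `nucleic_frame` fixing the rigid placement
#'   of the chain; identity by default.
#' @return A [nucleic_chain].
#' @examples
#' ch <- build_backbone(form_torsions(3, "RNA"), "RNA")
#' validate_chain(ch)
#' @export
build_backbone <- function(torsions, polymer_classes, start_frame = NULL) {
  n <- nrow(torsions)
  if (length(polymer_classes) == 1L) polymer_classes <- rep(polymer_classes, n)
  if (length(polymer_classes) != n)
    natk_stop("natk_invalid", "need one polymer class per residue")
  check_torsion_range(torsions)
  pucker <- if ("pucker" %in% names(torsions)) as.character(torsions$pucker)
            else .default_pucker[polymer_classes]
  pucker[is.na(pucker)] <- .default_pucker[polymer_classes[is.na(pucker)]]
  for (p in unique(pucker))
    if (!p %in% names(.pucker_template))
      natk_stop("natk_constants", "unknown sugar pucker mode '%s'", p)

  B <- .bb_bond; A <- .bb_angle
  # seed triad O5'-C5'-C4' of residue 1 in local coordinates
  o5 <- c(0, 0, 0)
  c5 <- c(B[["O5'-C5'"]], 0, 0)
  aa <- deg2rad(A[["O5'-C5'-C4'"]])
  c4 <- c5 + B[["C5'-C4'"]] * c(-cos(aa), sin(aa), 0)
  if (!is.null(start_frame)) {
    stopifnot(inherits(start_frame, "nucleic_frame"))
    R <- start_frame$rotation; o <- start_frame$origin
    o5 <- drop(R %*% o5) + o; c5 <- drop(R %*% c5) + o; c4 <- drop(R %*% c4) + o
  }

  residues <- vector("list", n)
  for (i in seq_len(n)) {
    at <- list("O5'" = o5, "C5'" = c5, "C4'" = c4)
    if (i > 1L) { at$P <- Pnext; at$OP1 <- OP1n; at$OP2 <- OP2n }
    tz <- torsions[i, ]
    need <- function(name) {
      v <- tz[[name]]
      if (is.null(v) || is.na(v))
        natk_stop("natk_invalid", "residue %d: torsion %s is required", i, name)
      v
    }
    at[["C3'"]] <- place_atom(at[["O5'"]], at[["C5'"]], at[["C4'"]],
                              B[["C4'-C3'"]], A[["C5'-C4'-C3'"]], need("gamma"))
    tpl <- .sugar_template[[.pucker_template[[pucker[i]]]]]
    for (r in seq_len(nrow(tpl))) {
      at[[tpl$atom[r]]] <- place_atom(at[[tpl$refA[r]]], at[[tpl$refB[r]]],
                                      at[[tpl$refC[r]]], tpl$bond[r],
                                      tpl$angle[r], tpl$torsion[r])
    }
    at$C4 <- place_atom(at[["O4'"]], at[["C1'"]], at[["N9"]],
                        B[["N9-C4"]], A[["C1'-N9-C4"]], need("chi"))
    at[["O3'"]] <- place_atom(at[["C5'"]], at[["C4'"]], at[["C3'"]],
                              B[["C3'-O3'"]], A[["C4'-C3'-O3'"]], need("delta"))
    if (i < n) {
      Pnext <- place_atom(at[["C4'"]], at[["C3'"]], at[["O3'"]],
                          B[["O3'-P"]], A[["C3'-O3'-P"]], need("epsilon"))
      zeta <- need("zeta")
      o5n <- place_atom(at[["C3'"]], at[["O3'"]], Pnext,
                        B[["P-O5'"]], A[["O3'-P-O5'"]], zeta)
      OP1n <- place_atom(at[["C3'"]], at[["O3'"]], Pnext,
                         B[["P-OP"]], A[["O3'-P-OP"]], zeta + .op_offsets[["OP1"]])
      OP2n <- place_atom(at[["C3'"]], at[["O3'"]], Pnext,
                         B[["P-OP"]], A[["O3'-P-OP"]], zeta + .op_offsets[["OP2"]])
      tznext <- torsions[i + 1L, ]
      if (is.na(tznext[["alpha"]]) || is.na(tznext[["beta"]]))
        natk_stop("natk_invalid", "residue %d: alpha/beta are required", i + 1L)
      c5n <- place_atom(at[["O3'"]], Pnext, o5n,
                        B[["O5'-C5'"]], A[["P-O5'-C5'"]], tznext[["alpha"]])
      c4n <- place_atom(Pnext, o5n, c5n,
                        B[["C5'-C4'"]], A[["O5'-C5'-C4'"]], tznext[["beta"]])
      o5 <- o5n; c5 <- c5n; c4 <- c4n
    }
    ord <- intersect(c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                       "O3'", "C2'", "C1'", "O2'", "N9", "C4"), names(at))
    m <- do.call(rbind, at[ord])
    rownames(m) <- ord
    residues[[i]] <- list(class = polymer_classes[i], pucker = pucker[i],
                          atoms = m)
  }
  nucleic_chain(residues)
}

#' Extract backbone torsions from a chain
#'
#' Measures the standard nucleic-acid dihedrals over the backbone atom
#' quadruplets: alpha = O3'(i-1)-P-O5'-C5', beta = P-O5'-C5'-C4', gamma =
#' O5'-C5'-C4'-C3', delta = C5'-C4'-C3'-O3', epsilon = C4'-C3'-O3'-P(i+1),
#' zeta = C3'-O3'-P(i+1)-O5'(i+1), chi = O4'-C1'-N9-C4. Torsions undefined
#' at chain termini are `NA`. `extract_torsions(build_backbone(T))`
#' recovers `T` (where defined) to numerical precision.
#'
#' @param chain A [nucleic_chain].
#' @return Data frame with columns `alpha` ... `zeta`, `chi`, `pucker`.
#' @export
extract_torsions <- function(chain) {
  stopifnot(inherits(chain, "nucleic_chain"))
  n <- length(chain$residues)
  get <- function(i, name) {
    at <- chain$residues[[i]]$atoms
    if (!name %in% rownames(at))
      natk_stop("natk_extract", "residue %d is missing atom %s", i, name)
    at[name, ]
  }
  out <- data.frame(alpha = rep(NA_real_, n), beta = NA_real_, gamma = NA_real_,
                    delta = NA_real_, epsilon = NA_real_, zeta = NA_real_,
                    chi = NA_real_,
                    pucker = vapply(chain$residues, function(r)
                      if (is.null(r$pucker)) NA_character_ else r$pucker, ""))
  for (i in seq_len(n)) {
    if (i > 1L) {
      out$alpha[i] <- dihedral(get(i - 1L, "O3'"), get(i, "P"),
                               get(i, "O5'"), get(i, "C5'"))
      out$beta[i] <- dihedral(get(i, "P"), get(i, "O5'"),
                              get(i, "C5'"), get(i, "C4'"))
    }
    out$gamma[i] <- dihedral(get(i, "O5'"), get(i, "C5'"),
                             get(i, "C4'"), get(i, "C3'"))
    out$delta[i] <- dihedral(get(i, "C5'"), get(i, "C4'"),
                             get(i, "C3'"), get(i, "O3'"))
    if (all(c("N9", "C4") %in% rownames(chain$residues[[i]]$atoms)))
      out$chi[i] <- dihedral(get(i, "O4'"), get(i, "C1'"),
                             get(i, "N9"), get(i, "C4"))
    if (i < n) {
      out$epsilon[i] <- dihedral(get(i, "C4'"), get(i, "C3'"),
                                 get(i, "O3'"), get(i + 1L, "P"))
      out$zeta[i] <- dihedral(get(i, "C3'"), get(i, "O3'"),
                              get(i + 1L, "P"), get(i + 1L, "O5'"))
    }
  }
  out
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `X` onto
#' `Y` (reflections excluded), with the post-transform root-mean-square
#' deviation.
#'
#' @param X,Y Equal-size n x 3 coordinate matrices, n >= 3.
#' @return List with `rotation` (3x3), `translation` (3-vector; the fit is
#'   `X %*% t(rotation) + translation`), and `rmsd` (angstrom).
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    natk_stop("natk_shape", "X and Y must be equal-size n x 3 matrices")
  if (nrow(X) < 3L)
    natk_stop("natk_shape", "need at least 3 points to superpose")
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cy - drop(R %*% cx)
  fitted <- sweep(X %*% t(R), 2L, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' TM-score d0 normalization
#'
#' The published length-dependent distance scale of the TM-score, by
#' molecule class: RNA mode `0.6 * sqrt(L - 0.5) - 2.5` floored at 0.3;
#' protein mode `1.24 * (L - 15)^(1/3) - 1.8` floored at 0.5.
#'
#' @param L_norm Normalization length.
#' @param mode `"rna"` or `"protein"`.
#' @return d0 in angstrom.
#' @export
tm_d0 <- function(L_norm, mode = c("rna", "protein")) {
  mode <- match.arg(mode)
  if (mode == "rna") {
    max(0.3, 0.6 * sqrt(max(L_norm - 0.5, 0)) - 2.5)
  } else {
    max(0.5, if (L_norm > 15) 1.24 * (L_norm - 15)^(1 / 3) - 1.8 else 0.5)
  }
}

#' Length-normalized TM-score
#'
#' `score = (1 / L_norm) * sum over corresponded pairs of
#' 1 / (1 + (d_i / d0)^2)`, evaluated after a score-optimal superposition.
#' The superposition search is iterative: Kabsch fits seeded on the full
#' correspondence and on sliding contiguous fragments (half and quarter
#' length), each refined by re-fitting on the inlier pairs within a growing
#' distance cutoff until the inlier set stabilizes; the best score over all
#' seeds is returned. With `superpose = FALSE` the score is evaluated in
#' the given coordinates (closed form).
#'
#' @param X,Y Coordinate matrices (n x 3), e.g. design and reference C1'
#'   traces.
#' @param correspondence Two-column matrix of 1-based row indices
#'   (`X` row, `Y` row); defaults to the identity correspondence.
#' @param L_norm Normalization length (defaults to `nrow(X)`, the design
#'   length); must be at least the correspondence size.
#' @param d0_mode Molecule class for the d0 formula (`"rna"` default).
#' @param d0 Optional explicit d0 override (angstrom).
#' @param superpose Search for the score-optimal superposition (default).
#' @return Score in (0, 1].
#' @export
tm_score <- function(X, Y, correspondence = NULL, L_norm = NULL,
                     d0_mode = c("rna", "protein"), d0 = NULL,
                     superpose = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(correspondence))
    correspondence <- cbind(seq_len(min(nrow(X), nrow(Y))),
                            seq_len(min(nrow(X), nrow(Y))))
  correspondence <- matrix(as.integer(correspondence), ncol = 2L)
  m <- nrow(correspondence)
  if (!m) natk_stop("natk_undefined", "empty correspondence: score undefined")
  if (any(correspondence[, 1L] > nrow(X)) || any(correspondence[, 2L] > nrow(Y)) ||
      any(correspondence < 1L))
    natk_stop("natk_invalid", "correspondence indices out of range")
  if (is.null(L_norm)) L_norm <- nrow(X)
  if (L_norm < m)
    natk_stop("natk_invalid", "L_norm (%d) smaller than correspondence (%d)",
              L_norm, m)
  if (is.null(d0)) d0 <- tm_d0(L_norm, match.arg(d0_mode))
  Xc <- X[correspondence[, 1L], , drop = FALSE]
  Yc <- Y[correspondence[, 2L], , drop = FALSE]
  score_of <- function(Xfit) {
    d2 <- rowSums((Xfit - Yc)^2)
    sum(1 / (1 + d2 / d0^2)) / L_norm
  }
  if (!superpose) return(score_of(Xc))
  if (m < 3L)
    natk_stop("natk_invalid", "superposition needs >= 3 corresponded pairs")

  seeds <- list(seq_len(m))
  for (fl in unique(pmax(4L, c(m %/% 2L, m %/% 4L)))) {
    if (fl >= m) next
    starts <- unique(c(seq(1L, m - fl + 1L, by = max(1L, fl %/% 2L)), m - fl + 1L))
    for (s in starts) seeds[[length(seeds) + 1L]] <- seq(s, s + fl - 1L)
  }
  best <- 0
  for (seed in seeds) {
    sub <- seed
    if (length(sub) < 3L) next
    for (iter in 1:30) {
      fit <- kabsch_superpose(Xc[sub, , drop = FALSE], Yc[sub, , drop = FALSE])
      Xfit <- sweep(Xc %*% t(fit$rotation), 2L, fit$translation, "+")
      best <- max(best, score_of(Xfit))
      d <- sqrt(rowSums((Xfit - Yc)^2))
      cut <- d0
      repeat {
        newsub <- which(d < cut)
        if (length(newsub) >= 3L) break
        cut <- cut + 0.5
      }
      if (identical(newsub, sub)) break
      sub <- newsub
    }
  }
  best
}

#' Alignment coverage
#'
#' Fraction of the design covered by a structural alignment:
#' `coverage = L_aligned / L_design`.
#'
#' @param L_aligned Number of aligned residues.
#' @param L_design Design length (must be >= 1).
#' @return Fraction in `[0, 1]` (or above 1 if the alignment exceeds the
#'   design length).
#' @examples
#' coverage(133, 240)  # 0.554..., the printed 0.55 at two decimals
#' @export
coverage <- function(L_aligned, L_design) {
  if (L_design < 1) natk_stop("natk_invalid", "L_design must be >= 1")
  if (L_aligned < 0) natk_stop("natk_invalid", "L_aligned must be >= 0")
  L_aligned / L_design
}
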