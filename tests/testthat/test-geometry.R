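random_torsions <- function(n, seed) {
  set.seed(seed)
  df <- as.data.frame(matrix(runif(n * 7, -179, 180), n, 7))
  names(df) <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  df$alpha[1] <- df$beta[1] <- NA
  df$epsilon[n] <- df$zeta[n] <- NA
  df
}

rigid_apply <- function(chain, R, tv) {
  chain$residues <- lapply(chain$residues, function(r) {
    r$atoms <- sweep(r$atoms %*% t(R), 2, tv, "+")
    r
  })
  chain
}

test_that("residue frames follow the O4'-C1'-C2' convention", {
  f <- frame_from_atoms(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$rotation, diag(3), tolerance = 1e-12)

  # equivariance: pre-rotated atoms give the rotated frame
  for (seed in 1:8) {
    R <- random_rotation(seed)
    tv <- rnorm(3)
    o4 <- rnorm(3); c1 <- rnorm(3); c2 <- rnorm(3)
    f0 <- frame_from_atoms(o4, c1, c2)
    f1 <- frame_from_atoms(drop(R %*% o4) + tv, drop(R %*% c1) + tv,
                           drop(R %*% c2) + tv)
    expect_equal(f1$rotation, R %*% f0$rotation, tolerance = 1e-8)
    expect_equal(f1$origin, drop(R %*% c1) + tv, tolerance = 1e-12)
    # orthonormality, right-handedness
    expect_equal(crossprod(f1$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(f1$rotation), 1, tolerance = 1e-8)
  }

  expect_error(frame_from_atoms(c(1, 0, 0), c(0, 0, 0), c(2, 0, 0)),
               class = "natk_degenerate")
  expect_error(frame_from_atoms(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               class = "natk_degenerate")
})

test_that("dihedral measurement handles the planar cis case and rigidity", {
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(abs(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))),
               180)
})

test_that("build/extract torsion round trip is exact to 1e-6 degrees", {
  for (seed in 1:6) {
    n <- 5L
    tor <- random_torsions(n, seed)
    classes <- sample(c("RNA", "DNA"), n, replace = TRUE)
    ch <- build_backbone(tor, classes)
    back <- extract_torsions(ch)
    for (cc in c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")) {
      ok <- !is.na(tor[[cc]])
      expect_equal(back[[cc]][ok], tor[[cc]][ok], tolerance = 1e-6)
    }
    # NA exactly at the undefined terminal torsions
    expect_true(all(is.na(back$alpha[1]), is.na(back$beta[1]),
                    is.na(back$epsilon[n]), is.na(back$zeta[n])))
  }
})

test_that("torsions are invariant under rigid motion of the chain", {
  ch <- build_backbone(form_torsions(4, "RNA"), "RNA")
  moved <- rigid_apply(ch, random_rotation(3), c(10, -4, 2))
  expect_equal(extract_torsions(moved)[, 1:7], extract_torsions(ch)[, 1:7],
               tolerance = 1e-8)
})

test_that("polymer class conditions chemistry and connectivity is ideal", {
  rna <- build_backbone(form_torsions(2, "RNA"), "RNA")
  dna <- build_backbone(form_torsions(2, "DNA"), "DNA")
  expect_true("O2'" %in% rownames(rna$residues[[1]]$atoms))
  expect_false("O2'" %in% rownames(dna$residues[[1]]$atoms))
  expect_no_error(validate_chain(rna))
  expect_no_error(validate_chain(dna))
  # 5'-terminal residue carries no phosphate group
  expect_false(any(c("P", "OP1", "OP2") %in% rownames(rna$residues[[1]]$atoms)))
  # phosphodiester O3'(1)-P(2) reproduces the constants-table bond length
  d <- sqrt(sum((rna$residues[[1]]$atoms["O3'", ] -
                   rna$residues[[2]]$atoms["P", ])^2))
  expect_equal(d, nucleic_geometry()$bonds[["O3'-P"]], tolerance = 1e-6)

  expect_error(build_backbone(cbind(form_torsions(2, "RNA")[1:7],
                                    pucker = "C1'-exo"), "RNA"),
               class = "natk_constants")
  bad <- form_torsions(2, "RNA"); bad$gamma[1] <- 720
  expect_error(build_backbone(bad, "RNA"), class = "natk_invalid")
})

test_that("start frames rigidly place the whole chain", {
  f <- frame_from_atoms(c(4, 1, 2), c(3, 1, 2), c(3, 2, 2))
  a <- build_backbone(form_torsions(3, "RNA"), "RNA")
  b <- build_backbone(form_torsions(3, "RNA"), "RNA", start_frame = f)
  ga <- do.call(rbind, lapply(a$residues, function(r) r$atoms))
  gb <- do.call(rbind, lapply(b$residues, function(r) r$atoms))
  expect_equal(gb, sweep(ga %*% t(f$rotation), 2, f$origin, "+"),
               tolerance = 1e-9)
})

test_that("ideal duplexes reproduce the constants-table helix parameters", {
  geom <- nucleic_geometry()
  for (cls in c("RNA", "DNA")) {
    dup <- ideal_duplex(cls, 6)
    hp <- geom$helix_params[[cls]]
    # rise: distance between successive C1' projections onto the helix axis
    z <- vapply(dup$strands[[1]]$residues, function(r) r$atoms["C1'", 3], 0)
    expect_equal(diff(z), rep(hp[["rise"]], 5), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(dup$rise, hp[["rise"]], tolerance = 1e-6)
    expect_equal(dup$twist, hp[["twist"]], tolerance = 1e-6)
    for (s in dup$strands) expect_no_error(validate_chain(s))
    # interior residues have constant torsions (regularity by construction)
    tt <- extract_torsions(dup$strands[[2]])
    spread <- apply(tt[2:5, 1:7], 2, function(v) diff(range(v)))
    expect_true(all(spread < 1e-9))
    # antiparallel pairing map
    expect_equal(dup$pairing[, 2], rev(dup$pairing[, 1]))
  }
  d1 <- ideal_duplex("RNA", 1)
  expect_length(d1$strands[[1]], 1L)
  expect_length(d1$strands[[2]], 1L)
  expect_equal(unname(d1$pairing), cbind(0L, 0L), ignore_attr = TRUE)
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(X, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  for (seed in 1:6) {
    R <- random_rotation(seed); tv <- rnorm(3) * 5
    Y <- sweep(X %*% t(R), 2, tv, "+")
    fit <- kabsch_superpose(X, Y)
    expect_equal(fit$rmsd, 0, tolerance = 1e-9)
    expect_equal(fit$rotation, R, tolerance = 1e-8)
    expect_equal(fit$translation, tv, tolerance = 1e-8)
  }

  expect_error(kabsch_superpose(X, X[1:5, ]), class = "natk_shape")
  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), class = "natk_shape")
})

test_that("Kabsch RMSD agrees with the rotation-grid brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed + 40)
    n <- sample(4:6, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    Y <- matrix(rnorm(n * 3), n, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, rmsd_grid_oracle(X, Y),
                 tolerance = 1e-3)
    # invariance to pre-rotation of either set
    R <- random_rotation(seed)
    expect_equal(kabsch_superpose(X %*% t(R), Y)$rmsd,
                 kabsch_superpose(X, Y)$rmsd, tolerance = 1e-9)
  }
})

test_that("TM-score matches its closed form and superposition finds identity", {
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(tm_score(X, X), 1)
  R <- random_rotation(9)
  Y <- sweep(X %*% t(R), 2, c(3, -1, 2), "+")
  expect_equal(tm_score(X, Y), 1, tolerance = 1e-9)

  # closed form of one term: a single pair at distance exactly d0
  d0 <- tm_d0(1, "rna")
  expect_equal(tm_score(matrix(c(0, 0, 0), 1), matrix(c(d0, 0, 0), 1),
                        cbind(1, 1), L_norm = 1, superpose = FALSE), 0.5)

  # limit: huge distances drive the score to 0
  far <- tm_score(matrix(c(0, 0, 0), 1), matrix(c(1e8, 0, 0), 1),
                  cbind(1, 1), L_norm = 1, superpose = FALSE)
  expect_lt(far, 1e-10)

  # monotone non-increasing as one corresponded distance grows
  base <- cbind(seq(0, 10, length.out = 8), 0, 0)
  prev <- Inf
  for (delta in c(0, 0.5, 1, 2, 4)) {
    Y2 <- base
    Y2[4, 2] <- delta
    sc <- tm_score(base, Y2, L_norm = 8, superpose = FALSE)
    expect_lte(sc, prev)
    expect_lte(sc, 1)
    prev <- sc
  }

  expect_error(tm_score(X, X, correspondence = matrix(integer(), 0, 2)),
               class = "natk_undefined")
  expect_error(tm_score(X, X, L_norm = 2), class = "natk_invalid")
})

test_that("coverage is the aligned fraction of the design", {
  expect_equal(round(coverage(133, 240), 2), 0.55)
  expect_equal(coverage(240, 240), 1.0)
  expect_equal(coverage(0, 240), 0.0)
  expect_error(coverage(10, 0), class = "natk_invalid")
})

test_that("PDB round trip preserves coordinates and polymer classes", {
  dup <- ideal_duplex("RNA", 3)
  path <- tempfile(fileext = ".pdb")
  write_pdb(dup$strands, path)
  back <- read_pdb(path)
  expect_length(back, 2L)
  for (k in 1:2) {
    orig <- dup$strands[[k]]
    got <- back[[k]]
    expect_equal(length(got), length(orig))
    for (ri in seq_along(orig$residues)) {
      expect_equal(got$residues[[ri]]$class, orig$residues[[ri]]$class)
      expect_equal(got$residues[[ri]]$atoms[rownames(orig$residues[[ri]]$atoms), ],
                   orig$residues[[ri]]$atoms, tolerance = 1e-3)
    }
  }

  tor <- form_torsions(4, "DNA")
  tpath <- tempfile(fileext = ".tsv")
  write_torsion_table(tor, tpath)
  expect_equal(read_torsion_table(tpath)[, 1:7], tor[, 1:7])
})
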