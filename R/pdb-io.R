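## PDB interchange for nucleic chains (via bio3d).  Sequence-agnostic
## residue names: "N" for RNA, "DN" for DNA.

#' Write nucleic chains to a PDB file
#'
#' Standard atom naming with primes, one chain ID per [nucleic_chain]
#' (A, B, ...), TER-separated. Residue names are the sequence-agnostic
#' "N" (RNA) and "DN" (DNA).
#'
#' @param chains A [nucleic_chain] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chains, path) {
  if (inherits(chains, "nucleic_chain")) chains <- list(chains)
  xyz <- NULL; elety <- character(); resno <- integer()
  resid <- character(); chain_id <- character()
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    stopifnot(inherits(ch, "nucleic_chain"))
    for (ri in seq_along(ch$residues)) {
      r <- ch$residues[[ri]]
      xyz <- rbind(xyz, r$atoms)
      elety <- c(elety, rownames(r$atoms))
      resno <- c(resno, rep(ri, nrow(r$atoms)))
      resid <- c(resid, rep(if (r$class == "RNA") "N" else "DN", nrow(r$atoms)))
      chain_id <- c(chain_id, rep(LETTERS[ci], nrow(r$atoms)))
    }
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), elety = elety,
                   resno = resno, resid = resid, chain = chain_id)
  invisible(path)
}

#' Read nucleic chains from a PDB file
#'
#' Splits the ATOM records by chain ID and residue number; polymer class is
#' taken from the residue name (DA/DC/DG/DT/DN are DNA) or, failing that,
#' from O2' presence.
#'
#' @param path PDB file path.
#' @return List of [nucleic_chain] objects, named by chain ID.
#' @export
read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) natk_stop("natk_parse", "no ATOM records in %s", path)
  out <- list()
  for (cid in unique(at$chain)) {
    sub <- at[at$chain == cid, , drop = FALSE]
    residues <- lapply(unique(sub$resno), function(rn) {
      rr <- sub[sub$resno == rn, , drop = FALSE]
      m <- unname(as.matrix(rr[, c("x", "y", "z")]))
      rownames(m) <- rr$elety
      cls <- if (any(rr$resid %in% c("DA", "DC", "DG", "DT", "DN"))) "DNA"
             else if (any(rr$resid %in% c("A", "C", "G", "U", "N"))) "RNA"
             else if ("O2'" %in% rr$elety) "RNA" else "DNA"
      list(class = cls, atoms = m)
    })
    out[[cid]] <- nucleic_chain(residues)
  }
  out
}

#' Read and write torsion tables
#'
#' Tab-separated per-residue torsion tables with header columns `alpha`,
#' `beta`, `gamma`, `delta`, `epsilon`, `zeta`, `chi` (degrees) and
#' optional `pucker`; `NA` marks torsions undefined at chain termini.
#'
#' @param path File path.
#' @param torsions Data frame as used by [build_backbone()].
#' @return `read_torsion_table`: the data frame.
#' @export
read_torsion_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  check_torsion_range(df)
}

#' @rdname read_torsion_table
#' @export
write_torsion_table <- function(torsions, path) {
  utils::write.table(torsions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
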