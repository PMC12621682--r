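## Design screening: secondary-structure F1, simulated chemical-probing
## reactivity and concordance, record filtering, sequence preparation.

#' Base-pair F1 score
#'
#' Precision, recall and F1 of a predicted base-pair set against the
#' designed set; pairs match only on exact (i, j) identity. Two empty sets
#' agree perfectly (1, 1, 1): "no pairs" was predicted and designed. If
#' exactly one set is empty all three components are 0.
#'
#' @param predicted,designed Pair sets: two-column 0-based matrices,
#'   lists of length-2 vectors, or [secondary_structure] objects.
#' @return Named list `precision`, `recall`, `f1`.
#' @examples
#' ss_f1(rbind(c(0, 5), c(1, 4)), rbind(c(0, 5), c(2, 3)))
#' @export
ss_f1 <- function(predicted, designed) {
  as_set <- function(x) {
    if (inherits(x, "secondary_structure")) x <- x$pairs
    m <- as_pair_matrix(x)
    sprintf("%d:%d", m[, 1L], m[, 2L])
  }
  p <- as_set(predicted); d <- as_set(designed)
  if (!length(p) && !length(d))
    return(list(precision = 1, recall = 1, f1 = 1))
  inter <- length(intersect(p, d))
  precision <- if (length(p)) inter / length(p) else 0
  recall <- if (length(d)) inter / length(d) else 0
  f1 <- 2 * inter / (length(p) + length(d))
  list(precision = precision, recall = recall, f1 = f1)
}

#' Simulate a chemical-probing reactivity profile
#'
#' Generates per-nucleotide reactivities from a structure the way probing
#' assays such as SHAPE behave: paired bases are protected (low
#' reactivity), unpaired/loop bases are flexible (high reactivity).
#' Reactivities are drawn from a mean-preserving log-normal noise model:
#' `mu * exp(sigma * Z - sigma^2 / 2)` with standard-normal `Z`, so the
#' expectation at a position equals its class mean and values are
#' non-negative and right-skewed, as probing data are. `sigma = 0` gives
#' the class means exactly; identical seeds give identical profiles.
#'
#' @param ss A [secondary_structure].
#' @param mu_paired,mu_unpaired Class mean reactivities (arbitrary
#'   normalized units); `mu_unpaired > mu_paired >= 0`.
#' @param sigma Log-scale noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Object of class `reactivity_profile`: numeric vector of length
#'   `ss$length` with attribute `"length"` matched to the structure.
#' @export
simulate_reactivity <- function(ss, mu_paired = 0.1, mu_unpaired = 0.8,
                                sigma = 0.3, seed = 1L) {
  stopifnot(inherits(ss, "secondary_structure"))
  if (!(mu_unpaired > mu_paired) || mu_paired < 0)
    natk_stop("natk_invalid", "need mu_unpaired > mu_paired >= 0")
  if (sigma < 0) natk_stop("natk_invalid", "sigma must be >= 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  mu <- ifelse(paired_mask(ss), mu_paired, mu_unpaired)
  z <- stats::rnorm(ss$length)
  r <- mu * exp(sigma * z - sigma^2 / 2)
  r <- pmax(r, 0)
  structure(r, class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("reactivity_profile: %d position(s), mean %.3f, range [%.3f, %.3f]\n",
              length(x), mean(x), min(x), max(x)))
  invisible(x)
}

#' Reactivity-structure concordance
#'
#' Quantifies how well a reactivity profile matches a design's paired /
#' unpaired pattern: positions with reactivity above `threshold` are
#' classified unpaired, and the score is the balanced accuracy against the
#' structure's labels (mean of the per-class correct fractions).
#' Degenerate structures (all paired or all unpaired) use the single
#' defined class fraction. This is a documented surrogate for external
#' probing-concordance scores; it is not the Eterna Target OpenKnot Score.
#'
#' @param profile Numeric reactivity vector (non-negative), same length as
#'   the structure.
#' @param ss A [secondary_structure].
#' @param threshold Reactivity classification threshold (> 0).
#' @return Score in `[0, 1]`.
#' @export
reactivity_concordance <- function(profile, ss, threshold = 0.4) {
  stopifnot(inherits(ss, "secondary_structure"))
  profile <- as.numeric(profile)
  if (length(profile) != ss$length)
    natk_stop("natk_shape", "profile length %d != structure length %d",
              length(profile), ss$length)
  if (threshold <= 0) natk_stop("natk_invalid", "threshold must be > 0")
  if (any(profile < 0)) natk_stop("natk_invalid", "reactivities must be >= 0")
  paired <- paired_mask(ss)
  called_unpaired <- profile > threshold
  fracs <- c(
    if (any(paired)) mean(!called_unpaired[paired]),
    if (any(!paired)) mean(called_unpaired[!paired])
  )
  mean(fracs)
}

#' Reactivity profile input and output
#'
#' Two-column tab-separated text: 0-based position, reactivity. `#` starts
#' a comment.
#'
#' @param path File path.
#' @param profile Numeric reactivity vector.
#' @return `read_reactivity`: numeric vector.
#' @export
read_reactivity <- function(path) {
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  f <- do.call(rbind, strsplit(lines, "[\t ]+"))
  pos <- as.integer(f[, 1L])
  val <- as.numeric(f[, 2L])
  out <- numeric(max(pos) + 1L)
  out[pos + 1L] <- val
  structure(out, class = "reactivity_profile")
}

#' @rdname read_reactivity
#' @export
write_reactivity <- function(profile, path) {
  writeLines(sprintf("%d\t%.6g", seq_along(profile) - 1L, as.numeric(profile)),
             path)
  invisible(path)
}

#' Default self-consistency filter thresholds
#'
#' The screening bounds applied to predicted-structure agreement before
#' ordering designs: predictor confidence pLDDT strictly above 0.87,
#' backbone RMSD strictly below 2.2 angstrom, and all-atom RMSD strictly
#' below 3.5 angstrom.
#'
#' @return Data frame with columns `field`, `op`, `value`.
#' @export
design_filter_defaults <- function() {
  data.frame(field = c("plddt", "backbone_rmsd", "allatom_rmsd"),
             op = c(">", "<", "<"),
             value = c(0.87, 2.2, 3.5),
             stringsAsFactors = FALSE)
}

.record_fields <- c("id", "plddt", "backbone_rmsd", "allatom_rmsd",
                    "f1", "tm_score", "coverage")

#' Filter design records by metric thresholds
#'
#' Keeps the records satisfying every bound, preserving order. All
#' inequalities are strict, matching the way such filters are quoted
#' (confidence `> 0.87`, RMSDs `< 2.2` / `< 3.5`); a record whose value
#' for a referenced field is missing (`NA`) fails that bound. pLDDT may be
#' given on the 0-1 or 0-100 scale (`plddt_scale`); on the percent scale
#' confidence bounds are compared against `value * 100`.
#'
#' @param records Data frame with column `id` and any of `plddt`,
#'   `backbone_rmsd`, `allatom_rmsd`, `f1`, `tm_score`, `coverage`.
#' @param thresholds Data frame with columns `field`, `op` (`">"` or
#'   `"<"`), `value`; defaults to [design_filter_defaults()].
#' @param plddt_scale `"fraction"` (0-1, default) or `"percent"` (0-100).
#' @return The surviving rows of `records`.
#' @examples
#' recs <- data.frame(id = c("d1", "d2"), plddt = c(0.90, 0.87),
#'                    backbone_rmsd = c(2.0, 2.0), allatom_rmsd = c(3.0, 3.0))
#' filter_designs(recs)  # d2 rejected: 0.87 is not > 0.87
#' @export
filter_designs <- function(records, thresholds = design_filter_defaults(),
                           plddt_scale = c("fraction", "percent")) {
  plddt_scale <- match.arg(plddt_scale)
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  thresholds <- as.data.frame(thresholds)
  unknown <- setdiff(thresholds$field, .record_fields)
  if (length(unknown))
    natk_stop("natk_config", "threshold references unknown field '%s'", unknown[1L])
  missing_cols <- setdiff(thresholds$field, names(records))
  keep <- rep(TRUE, nrow(records))
  for (k in seq_len(nrow(thresholds))) {
    fld <- thresholds$field[k]; op <- thresholds$op[k]; val <- thresholds$value[k]
    if (!op %in% c(">", "<"))
      natk_stop("natk_config", "threshold op must be '>' or '<'")
    if (fld == "plddt" && plddt_scale == "percent") val <- val * 100
    v <- if (fld %in% names(records)) records[[fld]] else rep(NA_real_, nrow(records))
    ok <- if (op == ">") v > val else v < val
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  records[keep, , drop = FALSE]
}

#' Read and write design-record tables
#'
#' Tab-separated with a header line; columns as in [filter_designs()].
#'
#' @param path File path.
#' @param records Data frame of design records.
#' @return `read_design_records`: the data frame.
#' @export
read_design_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' @rdname read_design_records
#' @export
write_design_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Prepend a transcription leader to a sequence
#'
#' Adds a 5' leader unconditionally (no deduplication against an existing
#' matching prefix); the default `"GG"` promotes T7 transcription and adds
#' 2 nt to each synthesized monomer.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `U`/`T`.
#' @param leader Leader string over the same alphabet (default `"GG"`).
#' @return `leader` + `sequence`.
#' @examples
#' prepend_leader("GGACUCGG")  # still gains 2 nt
#' @export
prepend_leader <- function(sequence, leader = "GG") {
  for (s in c(sequence, leader)) {
    bad <- regmatches(s, regexpr("[^ACGUTacgut]", s))
    if (length(bad) && nzchar(bad))
      natk_stop("natk_alphabet", "invalid nucleotide character '%s'", bad)
  }
  paste0(leader, sequence)
}
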