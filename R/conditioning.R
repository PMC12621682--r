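## Three-channel base-pair conditioning tensors.
##
## Channel semantics (one-hot over the third dimension):
##   [1,0,0] = unspecified (no constraint)
##   [0,1,0] = explicitly non-pairing
##   [0,0,1] = paired
## The tensor is symmetric and its diagonal stays unspecified, including
## across chain boundaries.

CH_UNSPECIFIED <- 1L
CH_NONPAIRING <- 2L
CH_PAIRED <- 3L

#' Construct an empty conditioning tensor
#'
#' An `L x L x 3` one-hot array of pairwise constraints used to condition
#' generative nucleic-acid design: each cell `(i, j)` is unspecified,
#' explicitly non-pairing, or paired. The array is symmetric and the
#' diagonal is always unspecified.
#'
#' @param L Total nucleotide count.
#' @param chain_breaks Optional 0-based chain-start indices (bookkeeping for
#'   multi-chain templates; the encoding itself is chain-agnostic).
#' @return Object of class `conditioning_tensor`: fields `L`, `A`
#'   (`L x L x 3` 0/1 array), `chain_breaks`.
#' @export
conditioning_tensor <- function(L, chain_breaks = integer()) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) natk_stop("natk_invalid", "L must be a positive integer")
  A <- array(0L, dim = c(L, L, 3L))
  A[, , CH_UNSPECIFIED] <- 1L
  structure(list(L = L, A = A, chain_breaks = sort(unique(as.integer(chain_breaks)))),
            class = "conditioning_tensor")
}

#' Validate conditioning-tensor invariants
#'
#' Checks that every cell is exactly one-hot, the array is symmetric in its
#' first two dimensions, and the diagonal is unspecified.
#'
#' @param tensor A [conditioning_tensor].
#' @return `tensor`, invisibly; errors with class `natk_invalid` otherwise.
#' @export
validate_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "conditioning_tensor"))
  A <- tensor$A
  if (!all(dim(A) == c(tensor$L, tensor$L, 3L)))
    natk_stop("natk_invalid", "tensor dimensions do not match L")
  hot <- A[, , 1L] + A[, , 2L] + A[, , 3L]
  if (!all(hot == 1L) || !all(A %in% c(0L, 1L)))
    natk_stop("natk_invalid", "tensor cells must be exactly one-hot")
  for (ch in 1:3)
    if (!identical(A[, , ch], t(A[, , ch])))
      natk_stop("natk_invalid", "tensor must be symmetric: A[i,j] == A[j,i]")
  if (!all(diag(A[, , CH_UNSPECIFIED]) == 1L))
    natk_stop("natk_invalid", "diagonal cells must be unspecified")
  invisible(tensor)
}

#' @export
print.conditioning_tensor <- function(x, ...) {
  d <- channel_matrix(x)
  np <- sum(d[upper.tri(d)] == CH_NONPAIRING)
  pp <- sum(d[upper.tri(d)] == CH_PAIRED)
  cat(sprintf(
    "conditioning_tensor: L=%d, %d paired cell(s), %d non-pairing cell(s), %d chain(s)\n",
    x$L, pp, np, length(x$chain_breaks) + 1L))
  invisible(x)
}

# L x L matrix of channel indices (1 = unspecified, 2 = non-pairing, 3 = paired).
channel_matrix <- function(tensor) {
  A <- tensor$A
  A[, , 1L] * CH_UNSPECIFIED + A[, , 2L] * CH_NONPAIRING + A[, , 3L] * CH_PAIRED
}

# Set cell (i, j) (0-based) and its mirror to `channel`.  Overwriting one
# constrained channel with a different constrained channel is a conflict;
# re-writing the same channel is idempotent.
set_cell <- function(tensor, i, j, channel) {
  ii <- i + 1L; jj <- j + 1L
  if (i == j)
    natk_stop("natk_conflict", "cannot constrain diagonal cell (%d, %d)", i, j)
  cur <- which(tensor$A[ii, jj, ] == 1L)
  if (cur != CH_UNSPECIFIED && cur != channel)
    natk_stop("natk_conflict",
              "conflicting assignment for cell (%d, %d): already %s, requested %s",
              i, j, channel_name(cur), channel_name(channel))
  tensor$A[ii, jj, ] <- tensor$A[jj, ii, ] <- 0L
  tensor$A[ii, jj, channel] <- tensor$A[jj, ii, channel] <- 1L
  tensor
}

channel_name <- function(ch) c("unspecified", "non-pairing", "paired")[ch]

#' Encode explicit pair constraints into a conditioning tensor
#'
#' Listed paired cells (and their mirrors) get the paired channel, listed
#' non-pairing cells the non-pairing channel; everything else, including the
#' diagonal, stays unspecified.
#'
#' @param L Total nucleotide count.
#' @param paired,nonpaired Two-column 0-based index matrices (or lists of
#'   length-2 vectors); they must be disjoint and contain no self-pairs.
#' @param chain_breaks Optional chain-start bookkeeping.
#' @return A [conditioning_tensor].
#' @examples
#' tn <- encode_pairs(4, paired = rbind(c(0, 3)), nonpaired = rbind(c(1, 2)))
#' decode_tensor(tn)
#' @export
encode_pairs <- function(L, paired = NULL, nonpaired = NULL, chain_breaks = integer()) {
  tensor <- conditioning_tensor(L, chain_breaks)
  paired <- as_pair_matrix(paired)
  nonpaired <- as_pair_matrix(nonpaired)
  for (m in list(paired, nonpaired)) {
    if (nrow(m) && (any(m < 0L) || any(m >= L)))
      natk_stop("natk_invalid", "constraint index out of range [0, %d)", L)
    if (nrow(m) && any(m[, 1L] == m[, 2L]))
      natk_stop("natk_invalid", "self-pair (i, i) is not a valid constraint")
  }
  for (k in seq_len(nrow(paired)))
    tensor <- set_cell(tensor, paired[k, 1L], paired[k, 2L], CH_PAIRED)
  for (k in seq_len(nrow(nonpaired)))
    tensor <- set_cell(tensor, nonpaired[k, 1L], nonpaired[k, 2L], CH_NONPAIRING)
  tensor
}

#' Describe a paired region pair with orientation
#'
#' Two equal-width, non-overlapping half-open 0-based intervals whose
#' positions pair with each other either antiparallel (a canonical duplex;
#' the paired cells fall on the anti-diagonal of the region submatrix) or
#' parallel (triple-helix / G-quadruplex style; cells on the main diagonal).
#'
#' @param region_a,region_b Length-2 vectors `c(start, end)`, half-open.
#' @param orientation `"antiparallel"` (default) or `"parallel"`.
#' @return Object of class `region_pair`.
#' @export
region_pair <- function(region_a, region_b,
                        orientation = c("antiparallel", "parallel")) {
  orientation <- match.arg(orientation)
  region_a <- as.integer(region_a); region_b <- as.integer(region_b)
  for (r in list(region_a, region_b))
    if (length(r) != 2L || r[2L] <= r[1L] || r[1L] < 0L)
      natk_stop("natk_invalid", "regions must be half-open [start, end) with end > start >= 0")
  if (diff(region_a) != diff(region_b))
    natk_stop("natk_shape", "regions must have equal width (%d vs %d)",
              diff(region_a), diff(region_b))
  if (max(region_a[1L], region_b[1L]) < min(region_a[2L], region_b[2L]))
    natk_stop("natk_overlap", "region_a and region_b overlap")
  structure(list(region_a = region_a, region_b = region_b,
                 orientation = orientation),
            class = "region_pair")
}

# The (i, j) pairs implied by a region pair, as a 0-based two-column matrix.
region_pair_map <- function(rp) {
  w <- diff(rp$region_a)
  k <- seq_len(w) - 1L
  a <- rp$region_a[1L] + k
  b <- if (rp$orientation == "antiparallel") rp$region_b[2L] - 1L - k
       else rp$region_b[1L] + k
  cbind(i = pmin(a, b), j = pmax(a, b))
}

#' Encode a region pair into a conditioning tensor
#'
#' Adds the pairing implied by `rp` on top of `tensor`. Antiparallel regions
#' pair `(a_start + k, b_end - 1 - k)`; parallel regions pair
#' `(a_start + k, b_start + k)`. Multiple region pairs may accumulate on one
#' tensor, and a base may be paired in more than one region pair (triplex /
#' quadruplex support); writing paired over non-pairing is a conflict error.
#'
#' @param tensor A [conditioning_tensor].
#' @param rp A [region_pair] (or arguments forwarded to [region_pair()]).
#' @return The updated [conditioning_tensor].
#' @export
encode_region_pair <- function(tensor, rp) {
  stopifnot(inherits(tensor, "conditioning_tensor"))
  if (!inherits(rp, "region_pair")) rp <- do.call(region_pair, rp)
  if (rp$region_a[2L] > tensor$L || rp$region_b[2L] > tensor$L)
    natk_stop("natk_invalid", "region exceeds tensor length %d", tensor$L)
  m <- region_pair_map(rp)
  for (k in seq_len(nrow(m)))
    tensor <- set_cell(tensor, m[k, 1L], m[k, 2L], CH_PAIRED)
  tensor
}

#' Decode a conditioning tensor into constraint sets
#'
#' Returns the upper-triangle paired and non-pairing cells;
#' `encode_pairs(L, paired, nonpaired)` on the result reproduces the tensor.
#' Input is validated (symmetry, one-hot, diagonal).
#'
#' @param tensor A [conditioning_tensor].
#' @return List with two-column 0-based matrices `paired` and `nonpaired`.
#' @export
decode_tensor <- function(tensor) {
  validate_tensor(tensor)
  ch <- channel_matrix(tensor)
  ut <- upper.tri(ch)
  pick <- function(channel) {
    w <- which(ut & ch == channel, arr.ind = TRUE)
    as_pair_matrix(w - 1L)
  }
  list(paired = pick(CH_PAIRED), nonpaired = pick(CH_NONPAIRING))
}

#' Conditioning tensor from a secondary structure
#'
#' Every pair of `ss` becomes a paired constraint. With
#' `unpaired_as_nonpairing = TRUE`, every off-diagonal cell between two
#' positions that are both unpaired in `ss` is set to the non-pairing
#' channel (loop enforcement); otherwise those cells stay unspecified.
#'
#' @param ss A [secondary_structure].
#' @param unpaired_as_nonpairing Enforce loops as explicitly non-pairing.
#' @return A [conditioning_tensor].
#' @export
from_secondary_structure <- function(ss, unpaired_as_nonpairing = FALSE) {
  stopifnot(inherits(ss, "secondary_structure"))
  nonpaired <- NULL
  if (unpaired_as_nonpairing) {
    un <- which(!paired_mask(ss)) - 1L
    if (length(un) >= 2L) nonpaired <- t(utils::combn(un, 2L))
  }
  encode_pairs(ss$length, paired = ss$pairs, nonpaired = nonpaired,
               chain_breaks = ss$chain_breaks)
}

#' Multi-chain strand-exchange template
#'
#' Builds the conditioning tensor and equivalent multi-chain secondary
#' structure for a set of duplex blocks between chains, in the global
#' indexing given by concatenating the chains in listed order. A chain may
#' participate in blocks with two or more partner chains, giving
#' strand-exchange (Holliday-junction-like) topologies that control
#' long-range connectivity.
#'
#' @param chain_lengths Integer vector of per-chain nucleotide counts.
#' @param duplex_blocks List of blocks, each a list (or vector-compatible
#'   list) with elements `chain_a`, `interval_a`, `chain_b`, `interval_b`,
#'   `orientation`; chains are 0-based indices into `chain_lengths`,
#'   intervals are half-open 0-based within their chain.
#' @return List with elements `tensor` ([conditioning_tensor]) and
#'   `ss` ([secondary_structure]).
#' @examples
#' # two 10-nt strands crossing over at half length (strand exchange)
#' sx <- strand_exchange_template(
#'   c(10, 10),
#'   list(list(chain_a = 0, interval_a = c(0, 5),
#'             chain_b = 1, interval_b = c(5, 10), orientation = "antiparallel"),
#'        list(chain_a = 0, interval_a = c(5, 10),
#'             chain_b = 1, interval_b = c(0, 5), orientation = "antiparallel")))
#' sx$ss
#' @export
strand_exchange_template <- function(chain_lengths, duplex_blocks) {
  chain_lengths <- as.integer(chain_lengths)
  if (!length(chain_lengths) || any(chain_lengths < 1L))
    natk_stop("natk_invalid", "chain lengths must be positive")
  offsets <- c(0L, cumsum(chain_lengths))
  L <- offsets[length(offsets)]
  chain_breaks <- offsets[-c(1L, length(offsets))]
  tensor <- conditioning_tensor(L, chain_breaks)
  all_pairs <- NULL
  for (blk in duplex_blocks) {
    ca <- as.integer(blk$chain_a); cb <- as.integer(blk$chain_b)
    for (cc in c(ca, cb))
      if (cc < 0L || cc >= length(chain_lengths))
        natk_stop("natk_invalid", "chain index %d out of range", cc)
    ia <- as.integer(blk$interval_a); ib <- as.integer(blk$interval_b)
    if (ia[2L] > chain_lengths[ca + 1L] || ib[2L] > chain_lengths[cb + 1L] ||
        min(ia, ib) < 0L)
      natk_stop("natk_bounds", "duplex block exceeds its chain")
    ori <- if (is.null(blk$orientation)) "antiparallel" else blk$orientation
    rp <- region_pair(ia + offsets[ca + 1L], ib + offsets[cb + 1L], ori)
    tensor <- encode_region_pair(tensor, rp)
    all_pairs <- rbind(all_pairs, region_pair_map(rp))
  }
  multi <- anyDuplicated(c(as_pair_matrix(all_pairs))) > 0L
  ss <- secondary_structure(L, all_pairs, chain_breaks = chain_breaks,
                            multi_partner_allowed = multi)
  list(tensor = tensor, ss = ss)
}

#' Tensor file input and output
#'
#' Two formats are provided. The dense container is a single file with a
#' text header (magic line, `L`, `chain_breaks`, `encoding`) terminated by a
#' blank line and followed by `L*L` raw bytes of 0-based channel indices in
#' column-major order. The sparse export is a plain-text table of
#' constrained cells `i<TAB>j<TAB>channel` (`channel` is `nonpairing` or
#' `paired`; unspecified cells are implicit).
#'
#' @param tensor A [conditioning_tensor].
#' @param path File path.
#' @return Readers return a [conditioning_tensor]; writers return `path`.
#' @export
write_tensor <- function(tensor, path) {
  validate_tensor(tensor)
  header <- paste0(
    "natk-tensor 1\n",
    "L ", tensor$L, "\n",
    "chain_breaks ", paste(tensor$chain_breaks, collapse = ","), "\n",
    "encoding uint8 channel-index column-major 0=unspecified 1=nonpairing 2=paired\n",
    "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.raw(channel_matrix(tensor) - 1L), con)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  sep <- as.raw(0x0a)
  # header ends at the first blank line ("\n\n")
  endpos <- NA_integer_
  for (k in seq_len(length(raw) - 1L))
    if (raw[k] == sep && raw[k + 1L] == sep) { endpos <- k + 1L; break }
  if (is.na(endpos)) natk_stop("natk_parse", "missing tensor header terminator")
  header <- strsplit(rawToChar(raw[seq_len(endpos - 2L)]), "\n", fixed = TRUE)[[1]]
  if (!startsWith(header[1L], "natk-tensor"))
    natk_stop("natk_parse", "not a natk tensor file")
  fields <- strsplit(header[-1L], " ", fixed = TRUE)
  vals <- stats::setNames(
    lapply(fields, function(f) paste(f[-1L], collapse = " ")),
    vapply(fields, `[`, "", 1L))
  L <- as.integer(vals$L)
  cb <- if (nzchar(vals$chain_breaks))
    as.integer(strsplit(vals$chain_breaks, ",", fixed = TRUE)[[1]]) else integer()
  body <- as.integer(raw[seq(endpos + 1L, length(raw))])
  if (length(body) != L * L)
    natk_stop("natk_parse", "tensor body has %d bytes, expected %d", length(body), L * L)
  ch <- matrix(body + 1L, nrow = L)
  tensor <- conditioning_tensor(L, cb)
  A <- array(0L, dim = c(L, L, 3L))
  for (c3 in 1:3) A[, , c3] <- (ch == c3) + 0L
  tensor$A <- A
  validate_tensor(tensor)
}

#' @rdname write_tensor
#' @export
write_tensor_sparse <- function(tensor, path) {
  sets <- decode_tensor(tensor)
  lines <- c(sprintf("# natk-tensor-sparse L=%d chain_breaks=%s", tensor$L,
                     paste(tensor$chain_breaks, collapse = ",")),
             sprintf("%d\t%d\tnonpairing", sets$nonpaired[, 1L], sets$nonpaired[, 2L]),
             sprintf("%d\t%d\tpaired", sets$paired[, 1L], sets$paired[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tensor
#' @export
read_tensor_sparse <- function(path) {
  lines <- readLines(path)
  head <- lines[1L]
  if (!grepl("natk-tensor-sparse", head))
    natk_stop("natk_parse", "not a sparse natk tensor file")
  L <- as.integer(sub(".*L=([0-9]+).*", "\\1", head))
  cbs <- sub(".*chain_breaks=([0-9,]*).*", "\\1", head)
  cb <- if (nzchar(cbs)) as.integer(strsplit(cbs, ",")[[1]]) else integer()
  body <- lines[-1L]
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
  paired <- NULL; nonpaired <- NULL
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cell <- as.integer(f[1:2])
    if (f[3L] == "paired") paired <- rbind(paired, cell)
    else if (f[3L] == "nonpairing") nonpaired <- rbind(nonpaired, cell)
    else natk_stop("natk_parse", "unknown channel '%s'", f[3L])
  }
  encode_pairs(L, paired, nonpaired, chain_breaks = cb)
}

#' Read a region-pair configuration file
#'
#' YAML list of entries with `region_a`, `region_b` (two-element start/end
#' arrays, half-open 0-based) and optional `orientation`
#' (default antiparallel).
#'
#' @param path File path.
#' @return List of [region_pair] objects.
#' @export
read_region_pairs <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e)
    region_pair(e$region_a, e$region_b,
                if (is.null(e$orientation)) "antiparallel" else e$orientation))
}
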