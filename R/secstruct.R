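#' Bracket alphabet for pseudoknotted dot-bracket notation
#'
#' Ordered bracket layers used when parsing and writing dot-bracket strings:
#' `()`, `[]`, `{}`, `<>`, then `Aa` through `Zz`. Layer 1 encodes nested
#' (pseudoknot-free) pairs; each additional layer encodes one further order of
#' pseudoknot.
#'
#' @format Character vector; each element is a two-character string
#'   `opener` + `closer`.
#' @export
dotbracket_alphabet <- c("()", "[]", "{}", "<>", paste0(LETTERS, letters))

.chain_separators <- c("&", "+")

natk_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "natk_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Construct a secondary structure
#'
#' A secondary structure is a set of base pairs over `length` nucleotides
#' (all chains concatenated 5' to 3'), optionally pseudoknotted (crossing
#' pairs) and optionally multi-chain. All nucleotide indices are 0-based.
#'
#' @param length Total nucleotide count across all chains.
#' @param pairs Two-column integer matrix (or list of length-2 vectors) of
#'   paired positions; stored orientation-free with `i < j`, duplicates
#'   removed.
#' @param chain_breaks Sorted 0-based indices at which a new chain starts
#'   (the first chain's start, 0, is implicit and never listed).
#' @param multi_partner_allowed If `FALSE` (default) each position may pair
#'   at most once; set `TRUE` for triplex/quadruplex pair sets.
#' @return An object of class `secondary_structure` with fields `length`,
#'   `pairs` (sorted two-column matrix), `chain_breaks`,
#'   `multi_partner_allowed`.
#' @examples
#' ss <- secondary_structure(6, rbind(c(0, 5), c(1, 4)))
#' write_dotbracket(ss)
#' @export
secondary_structure <- function(length, pairs = NULL, chain_breaks = integer(),
                                multi_partner_allowed = FALSE) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L)
    natk_stop("natk_invalid", "structure length must be a non-negative integer")
  pairs <- as_pair_matrix(pairs)
  if (nrow(pairs)) {
    if (any(pairs < 0L) || any(pairs >= length))
      natk_stop("natk_invalid", "pair index out of range [0, %d)", length)
    if (any(pairs[, 1L] == pairs[, 2L]))
      natk_stop("natk_invalid", "self-pair (i, i) is not allowed")
  }
  chain_breaks <- sort(unique(as.integer(chain_breaks)))
  if (any(chain_breaks <= 0L) || any(chain_breaks >= length & length > 0L))
    natk_stop("natk_invalid", "chain breaks must lie strictly inside (0, length)")
  ss <- structure(
    list(length = length, pairs = pairs, chain_breaks = chain_breaks,
         multi_partner_allowed = isTRUE(multi_partner_allowed)),
    class = "secondary_structure"
  )
  if (!ss$multi_partner_allowed) {
    idx <- c(pairs)
    if (anyDuplicated(idx))
      natk_stop("natk_invalid",
                "position %d pairs more than once (set multi_partner_allowed)",
                idx[duplicated(idx)][1L])
  }
  ss
}

# Normalize pair input to a sorted, unique, i<j integer matrix.
as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      (!is.matrix(pairs) && !length(pairs))) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(pairs)) pairs <- do.call(rbind, lapply(pairs, as.integer))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' @export
print.secondary_structure <- function(x, ...) {
  nchain <- length(x$chain_breaks) + 1L
  cat(sprintf("secondary_structure: %d nt, %d pair(s), %d chain(s)",
              x$length, nrow(x$pairs), nchain))
  if (x$multi_partner_allowed) cat(", multi-partner")
  cat("\n")
  if (x$length && !x$multi_partner_allowed && x$length <= 200L) {
    db <- tryCatch(write_dotbracket(x), error = function(e) NULL)
    if (!is.null(db)) cat(" ", db, "\n")
  }
  invisible(x)
}

#' Parse a pseudoknotted dot-bracket string
#'
#' Each bracket layer of the alphabet is matched independently with its own
#' stack, so crossing (pseudoknotted) pairs of arbitrary order can be
#' expressed with additional layers. `&` and `+` both act as chain
#' separators; they are excluded from position indexing.
#'
#' @param s Dot-bracket string over `.`, chain separators and the alphabet.
#' @param alphabet Ordered bracket-pair strings, by layer.
#' @return A [secondary_structure].
#' @examples
#' parse_dotbracket("((..[[..))..]]")$pairs
#' @export
parse_dotbracket <- function(s, alphabet = dotbracket_alphabet) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  openers <- substr(alphabet, 1L, 1L)
  closers <- substr(alphabet, 2L, 2L)
  stacks <- rep(list(integer()), length(alphabet))
  pairs <- list()
  chain_breaks <- integer()
  pos <- 0L  # 0-based index of the next nucleotide
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% .chain_separators) {
      if (pos > 0L) chain_breaks <- c(chain_breaks, pos)
      next
    }
    if (ch == ".") { pos <- pos + 1L; next }
    lay <- match(ch, openers)
    if (!is.na(lay)) {
      stacks[[lay]] <- c(stacks[[lay]], pos)
      pos <- pos + 1L
      next
    }
    lay <- match(ch, closers)
    if (!is.na(lay)) {
      st <- stacks[[lay]]
      if (!length(st))
        natk_stop("natk_parse",
                  "unbalanced closer '%s' (layer %d) at string position %d",
                  ch, lay, k)
      pairs[[length(pairs) + 1L]] <- c(st[length(st)], pos)
      stacks[[lay]] <- st[-length(st)]
      pos <- pos + 1L
      next
    }
    natk_stop("natk_parse", "unknown character '%s' at string position %d", ch, k)
  }
  open_left <- which(vapply(stacks, length, 1L) > 0L)
  if (length(open_left))
    natk_stop("natk_parse", "unbalanced opener '%s' in layer %d",
              openers[open_left[1L]], open_left[1L])
  chain_breaks <- chain_breaks[chain_breaks < pos]
  secondary_structure(pos, pairs, chain_breaks = chain_breaks)
}

# Greedy layer assignment for crossing pairs: pairs in ascending opener
# order each take the lowest layer they do not cross.  Returns an integer
# layer per row of ss$pairs (1-based), or integer() if no pairs.
assign_layers <- function(pairs) {
  n <- nrow(pairs)
  if (!n) return(integer())
  layers <- integer(n)
  for (p in seq_len(n)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    lay <- 1L
    repeat {
      members <- which(layers == lay)
      crossing <- any(pairs[members, 1L] < i & i < pairs[members, 2L] &
                        pairs[members, 2L] < j)
      if (!crossing) break
      lay <- lay + 1L
    }
    layers[p] <- lay
  }
  layers
}

#' Write a secondary structure as a dot-bracket string
#'
#' Crossing pairs are assigned to bracket layers by greedy coloring of the
#' pair-crossing conflict graph (lowest available layer, pairs processed by
#' ascending opener index), so `parse_dotbracket(write_dotbracket(ss))`
#' recovers `ss`. Chain breaks are emitted as `&`.
#'
#' @param ss A [secondary_structure]; must not be multi-partner (dot-bracket
#'   cannot express base triples).
#' @param alphabet Ordered bracket-pair strings, by layer.
#' @return A dot-bracket string.
#' @export
write_dotbracket <- function(ss, alphabet = dotbracket_alphabet) {
  stopifnot(inherits(ss, "secondary_structure"))
  if (ss$multi_partner_allowed && anyDuplicated(c(ss$pairs)))
    natk_stop("natk_unrepresentable",
              "multi-partner pair sets cannot be written as dot-bracket")
  layers <- assign_layers(ss$pairs)
  if (length(layers) && max(layers) > length(alphabet))
    natk_stop("natk_capacity",
              "structure needs %d bracket layers but alphabet has %d",
              max(layers), length(alphabet))
  chars <- rep(".", ss$length)
  if (nrow(ss$pairs)) {
    chars[ss$pairs[, 1L] + 1L] <- substr(alphabet[layers], 1L, 1L)
    chars[ss$pairs[, 2L] + 1L] <- substr(alphabet[layers], 2L, 2L)
  }
  # insert '&' before each chain start, from the right so indices stay valid
  for (b in rev(ss$chain_breaks)) chars <- append(chars, "&", after = b)
  paste(chars, collapse = "")
}

#' Pseudoknot order of a structure
#'
#' The number of bracket layers required by the greedy layering minus one:
#' 0 for fully nested (or empty) structures, 1 for simple pseudoknots such
#' as kissing loops, and so on.
#'
#' @param ss A [secondary_structure].
#' @return Non-negative integer.
#' @examples
#' pseudoknot_order(parse_dotbracket("((..[[..))..]]"))
#' @export
pseudoknot_order <- function(ss) {
  stopifnot(inherits(ss, "secondary_structure"))
  layers <- assign_layers(ss$pairs)
  if (!length(layers)) 0L else max(layers) - 1L
}

#' Read and write dot-bracket record files
#'
#' One structure per record: a `>` header line with the record name, an
#' optional sequence line, and the structure line. `read_dotbracket_file`
#' returns a named list of [secondary_structure] objects; sequences, when
#' present, are attached as attribute `"sequence"`.
#'
#' @param path File path.
#' @param structures Named list of [secondary_structure] for writing;
#'   optional `sequences` is a parallel character vector.
#' @param sequences Optional sequences written between header and structure.
#' @return `read_dotbracket_file`: named list of structures.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) natk_stop("natk_parse", "no '>' records in %s", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (r in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[r]])
    body <- lines[seq(heads[r] + 1L, bounds[r + 1L] - 1L)]
    if (!length(body) || length(body) > 2L)
      natk_stop("natk_parse", "record '%s' must have 1-2 body lines", name)
    ss <- parse_dotbracket(trimws(body[length(body)]))
    if (length(body) == 2L) attr(ss, "sequence") <- trimws(body[1L])
    out[[name]] <- ss
  }
  out
}

#' @rdname read_dotbracket_file
#' @export
write_dotbracket_file <- function(structures, path, sequences = NULL) {
  if (inherits(structures, "secondary_structure"))
    structures <- list(structure_1 = structures)
  nm <- names(structures)
  if (is.null(nm)) nm <- paste0("structure_", seq_along(structures))
  lines <- character()
  for (k in seq_along(structures)) {
    lines <- c(lines, paste0(">", nm[k]))
    if (!is.null(sequences)) lines <- c(lines, sequences[[k]])
    lines <- c(lines, write_dotbracket(structures[[k]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write pair tables
#'
#' Tab-separated pair tables with 0-based columns `i`, `j`, one pair per
#' line; `#` starts a comment. `read_pair_table` needs the structure length
#' (it is not stored in the format) unless a `# length=N` comment is present.
#'
#' @param path File path.
#' @param length Structure length; overrides any `# length=` comment.
#' @param ss A [secondary_structure] to write.
#' @return `read_pair_table`: a [secondary_structure].
#' @export
read_pair_table <- function(path, length = NULL) {
  lines <- readLines(path)
  if (is.null(length)) {
    m <- unlist(regmatches(lines, regexpr("#\\s*length\\s*=\\s*[0-9]+", lines)))
    if (length(m)) length <- as.integer(sub(".*=\\s*", "", m[1L]))
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pairs <- if (length(lines)) {
    do.call(rbind, lapply(strsplit(lines, "[\t ]+"), function(f) {
      if (length(f) < 2L) natk_stop("natk_parse", "pair table line needs i and j")
      as.integer(f[1:2])
    }))
  } else NULL
  if (is.null(length)) {
    if (is.null(pairs))
      natk_stop("natk_parse", "cannot infer length of an empty pair table")
    length <- max(pairs) + 1L
  }
  secondary_structure(length, pairs)
}

#' @rdname read_pair_table
#' @export
write_pair_table <- function(ss, path) {
  stopifnot(inherits(ss, "secondary_structure"))
  lines <- c(sprintf("# length=%d", ss$length),
             if (length(ss$chain_breaks))
               sprintf("# chain_breaks=%s", paste(ss$chain_breaks, collapse = ",")),
             sprintf("%d\t%d", ss$pairs[, 1L], ss$pairs[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

# Per-position pairing status (TRUE where the position occurs in any pair).
paired_mask <- function(ss) {
  m <- logical(ss$length)
  m[c(ss$pairs) + 1L] <- TRUE
  m
}
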