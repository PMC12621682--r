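## Graph-level pseudocycle templating: subunit segment specs, symmetric
## propagation, randomized length diversification, and realization into a
## secondary structure plus conditioning tensor.

#' Segment specification
#'
#' One coarse-grained segment of a subunit: a helix side, a loop, or a
#' hinge, with inclusive nucleotide length bounds.
#'
#' @param name Segment label, unique within the subunit.
#' @param min_len,max_len Inclusive length bounds, `1 <= min <= max`.
#' @param role `"helix_side"`, `"loop"`, or `"hinge"`.
#' @return Object of class `segment_spec`.
#' @export
segment_spec <- function(name, min_len, max_len = min_len,
                         role = c("helix_side", "loop", "hinge")) {
  role <- match.arg(role)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || min_len < 1L || max_len < min_len)
    natk_stop("natk_invalid", "segment '%s': need 1 <= min <= max", name)
  structure(list(name = as.character(name), min_len = min_len,
                 max_len = max_len, role = role),
            class = "segment_spec")
}

#' Pairing graph for a symmetric pseudocycle
#'
#' Segment-level topology of one subunit plus its symmetric pairing: an
#' ordered 5'-to-3' segment list, intra-subunit partner edges, inter-subunit
#' edges connecting each subunit `s` to subunit `(s + 1) mod n`, and the
#' symmetry order `n`. Partner segments must share identical length bounds
#' (their realized lengths are tied).
#'
#' @param segments List of [segment_spec] (5' to 3' within one subunit).
#' @param intra_edges,inter_edges Lists of edges
#'   `list(a, b, orientation = "antiparallel")` naming partner segments;
#'   `inter_edges` pair segment `a` of subunit `s` with segment `b` of
#'   subunit `s + 1 mod n`.
#' @param symmetry_order Number of subunits, `n >= 1`.
#' @return Object of class `pairing_graph`.
#' @export
pairing_graph <- function(segments, intra_edges = list(), inter_edges = list(),
                          symmetry_order = 1L) {
  n <- as.integer(symmetry_order)
  if (is.na(n) || n < 1L) natk_stop("natk_invalid", "symmetry_order must be >= 1")
  segments <- lapply(segments, function(s) {
    if (inherits(s, "segment_spec")) s else do.call(segment_spec, s)
  })
  nm <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(nm))
    natk_stop("natk_invalid", "duplicate segment name '%s'", nm[duplicated(nm)][1L])
  norm_edge <- function(e) {
    ori <- if (is.null(e$orientation) || is.na(e$orientation[1])) "antiparallel"
           else match.arg(e$orientation, c("antiparallel", "parallel"))
    a <- if (!is.null(e$a)) e$a else e[[1L]]
    b <- if (!is.null(e$b)) e$b else e[[2L]]
    for (s in c(a, b))
      if (!s %in% nm) natk_stop("natk_invalid", "edge references unknown segment '%s'", s)
    list(a = a, b = b, orientation = ori)
  }
  intra_edges <- lapply(intra_edges, norm_edge)
  inter_edges <- lapply(inter_edges, norm_edge)
  seg_of <- stats::setNames(segments, nm)
  for (e in c(intra_edges, inter_edges)) {
    sa <- seg_of[[e$a]]; sb <- seg_of[[e$b]]
    if (sa$min_len != sb$min_len || sa$max_len != sb$max_len)
      natk_stop("natk_invalid",
                "partner segments '%s' and '%s' must share length bounds", e$a, e$b)
  }
  # a segment may appear in only one edge; an inter edge may pair a segment
  # with its own copy in the next subunit (self-kissing), counted once
  used <- unlist(lapply(c(intra_edges, inter_edges), function(e) unique(c(e$a, e$b))))
  if (anyDuplicated(used))
    natk_stop("natk_invalid", "segment '%s' appears in more than one edge",
              used[duplicated(used)][1L])
  structure(list(segments = segments, intra_edges = intra_edges,
                 inter_edges = inter_edges, symmetry_order = n),
            class = "pairing_graph")
}

#' @export
print.pairing_graph <- function(x, ...) {
  cat(sprintf("pairing_graph: %d segment(s)/subunit, %d intra + %d inter edge(s), C%d symmetry\n",
              length(x$segments), length(x$intra_edges), length(x$inter_edges),
              x$symmetry_order))
  invisible(x)
}

#' Propagate a subunit symmetrically
#'
#' Expands the subunit into `n` copies concatenated 5' to 3' into one chain
#' (pseudo-symmetric single-chain connectivity). Intra edges are replicated
#' per subunit; inter edges connect subunit `s` to subunit `(s + 1) mod n`.
#' Expanded segment names are `"name@s"` with 0-based subunit index `s`.
#'
#' @param graph A [pairing_graph].
#' @return List with `segments` (expanded list, each with added `subunit`
#'   field) and `edges` (global edge list).
#' @export
propagate_symmetry <- function(graph) {
  stopifnot(inherits(graph, "pairing_graph"))
  n <- graph$symmetry_order
  if (n == 1L && length(graph$inter_edges))
    natk_stop("natk_topology",
              "inter-subunit edges cannot reference a distinct subunit when symmetry_order is 1")
  segments <- list()
  for (s in seq_len(n) - 1L) {
    for (seg in graph$segments) {
      seg$subunit <- s
      seg$global_name <- paste0(seg$name, "@", s)
      segments[[length(segments) + 1L]] <- seg
    }
  }
  edges <- list()
  for (s in seq_len(n) - 1L) {
    for (e in graph$intra_edges)
      edges[[length(edges) + 1L]] <- list(a = paste0(e$a, "@", s),
                                          b = paste0(e$b, "@", s),
                                          orientation = e$orientation)
    for (e in graph$inter_edges)
      edges[[length(edges) + 1L]] <- list(a = paste0(e$a, "@", s),
                                          b = paste0(e$b, "@", (s + 1L) %% n),
                                          orientation = e$orientation)
  }
  list(segments = segments, edges = edges)
}

# Tied length groups: segments joined by any edge share one realized length.
# Because propagation is symmetric, sampling happens at the per-subunit
# segment level; returns a list of character vectors of segment names.
length_groups <- function(graph) {
  nm <- vapply(graph$segments, `[[`, "", "name")
  group <- stats::setNames(seq_along(nm), nm)
  for (e in c(graph$intra_edges, graph$inter_edges)) {
    ga <- group[[e$a]]; gb <- group[[e$b]]
    group[group == gb] <- ga
  }
  split(nm, group[nm])
}

#' Randomly sample segment lengths
#'
#' Draws each segment's length uniformly from its inclusive bounds with a
#' seeded generator; segments tied by a pairing edge share one draw. With a
#' `target_total`, whole assignments are rejection-sampled until the
#' per-subunit sum times the symmetry order equals the target, or
#' `max_tries` is exhausted. Identical seed and graph give identical
#' lengths.
#'
#' @param graph A [pairing_graph].
#' @param seed Integer seed.
#' @param target_total Optional total nucleotide count over all subunits.
#' @param max_tries Rejection-sampling attempt budget (default 10000).
#' @return Named integer vector of per-subunit segment lengths.
#' @export
sample_lengths <- function(graph, seed, target_total = NULL, max_tries = 10000L) {
  stopifnot(inherits(graph, "pairing_graph"))
  n <- graph$symmetry_order
  segs <- stats::setNames(graph$segments,
                          vapply(graph$segments, `[[`, "", "name"))
  if (!is.null(target_total)) {
    lo <- n * sum(vapply(segs, `[[`, 0L, "min_len"))
    hi <- n * sum(vapply(segs, `[[`, 0L, "max_len"))
    if (target_total < lo || target_total > hi)
      natk_stop("natk_feasibility",
                "target_total %d outside feasible range [%d, %d]",
                target_total, lo, hi)
  }
  groups <- length_groups(graph)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  draw <- function() {
    lens <- integer(0)
    for (g in groups) {
      s <- segs[[g[1L]]]
      l <- if (s$min_len == s$max_len) s$min_len
           else sample(seq.int(s$min_len, s$max_len), 1L)
      lens[g] <- l
    }
    lens[names(segs)]
  }
  if (is.null(target_total)) return(draw())
  for (k in seq_len(max_tries)) {
    lens <- draw()
    if (n * sum(lens) == target_total) return(lens)
  }
  natk_stop("natk_sampling",
            "no assignment summing to %d found in %d tries", target_total, max_tries)
}

#' Realize a pseudocycle template
#'
#' Assigns global 0-based intervals to the symmetrically propagated
#' segments in 5'-to-3' order, converts every pairing edge to a region pair
#' (antiparallel unless declared parallel), and builds the single-chain
#' [secondary_structure] and [conditioning_tensor]. Hinge and loop segments
#' remain unpaired. Inter-subunit edges that cross intra-subunit helices
#' export with correct pseudoknot bracket layering.
#'
#' @param graph A [pairing_graph].
#' @param lengths Named per-subunit segment lengths as returned by
#'   [sample_lengths()].
#' @param seed Seed recorded on the realization (bookkeeping only).
#' @return Object of class `template_realization`: `lengths` (per-subunit),
#'   `subunit_length`, `ss`, `tensor`, `seed`.
#' @export
realize_template <- function(graph, lengths, seed = NA_integer_) {
  stopifnot(inherits(graph, "pairing_graph"))
  for (seg in graph$segments) {
    l <- lengths[[seg$name]]
    if (is.null(l) || is.na(l))
      natk_stop("natk_invalid", "no length for segment '%s'", seg$name)
    if (l < seg$min_len || l > seg$max_len)
      natk_stop("natk_invalid", "length %d for '%s' violates bounds [%d, %d]",
                l, seg$name, seg$min_len, seg$max_len)
  }
  expanded <- propagate_symmetry(graph)
  glens <- vapply(expanded$segments, function(s) as.integer(lengths[[s$name]]), 0L)
  starts <- cumsum(c(0L, glens[-length(glens)]))
  L <- sum(glens)
  iv <- stats::setNames(
    lapply(seq_along(glens), function(k) c(starts[k], starts[k] + glens[k])),
    vapply(expanded$segments, `[[`, "", "global_name"))
  tensor <- conditioning_tensor(L)
  pairs <- NULL
  for (e in expanded$edges) {
    rp <- region_pair(iv[[e$a]], iv[[e$b]], e$orientation)
    tensor <- encode_region_pair(tensor, rp)
    pairs <- rbind(pairs, region_pair_map(rp))
  }
  ss <- secondary_structure(L, pairs)
  structure(list(lengths = lengths, subunit_length = L %/% graph$symmetry_order,
                 symmetry_order = graph$symmetry_order,
                 ss = ss, tensor = tensor, seed = seed),
            class = "template_realization")
}

#' @export
print.template_realization <- function(x, ...) {
  cat(sprintf("template_realization: %d nt total, C%d symmetry (%d nt/subunit), %d pair(s)\n",
              x$ss$length, x$symmetry_order, x$subunit_length, nrow(x$ss$pairs)))
  invisible(x)
}

#' Generate a pseudocycle template end to end
#'
#' Convenience wrapper: [sample_lengths()] then [realize_template()].
#'
#' @inheritParams sample_lengths
#' @return A `template_realization`.
#' @export
generate_template <- function(graph, seed, target_total = NULL, max_tries = 10000L) {
  lengths <- sample_lengths(graph, seed, target_total, max_tries)
  realize_template(graph, lengths, seed = as.integer(seed))
}

#' Read a topology specification file
#'
#' YAML with fields `segments` (list of `{name, min, max, role}`),
#' `intra_edges` / `inter_edges` (lists of `{a, b, orientation}`),
#' `symmetry_order`, and optional `target_total` and `seed`.
#'
#' @param path File path.
#' @return List with `graph` ([pairing_graph]), `target_total`, `seed`.
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  segs <- lapply(cfg$segments, function(s)
    segment_spec(s$name, s$min, if (is.null(s$max)) s$min else s$max,
                 if (is.null(s$role)) "helix_side" else s$role))
  graph <- pairing_graph(
    segs,
    intra_edges = if (is.null(cfg$intra_edges)) list() else cfg$intra_edges,
    inter_edges = if (is.null(cfg$inter_edges)) list() else cfg$inter_edges,
    symmetry_order = if (is.null(cfg$symmetry_order)) 1L else cfg$symmetry_order)
  list(graph = graph,
       target_total = cfg$target_total,
       seed = if (is.null(cfg$seed)) NA_integer_ else as.integer(cfg$seed))
}

#' Built-in twofold 372-nt pseudocycle topology
#'
#' The packaged example topology (`inst/extdata/pc2_372.yaml`): a twofold
#' symmetric single-chain pseudocycle whose two 186-nt subunits each carry
#' three hairpins plus a kissing-loop pair to the partner subunit, realized
#' at a 372-nt total. Subunit segment lengths are this package's own
#' plausible layout for that design class.
#'
#' @return Path to the YAML topology file.
#' @export
example_topology_pc2_372 <- function() {
  system.file("extdata", "pc2_372.yaml", package = "natk", mustWork = TRUE)
}
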