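# Single-substitution motif distance graphs: nodes weighted by promoter
# counts, edges at Hamming distance 1, orientation from the more frequent
# motif to the less frequent, seeds = locally maximal nodes.

.neighbours1 <- function(motif) {
  ch <- strsplit(motif, "")[[1L]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_along(ch)) for (b in setdiff(bases, ch[i])) {
    v <- ch; v[i] <- b
    out <- c(out, paste(v, collapse = ""))
  }
  out
}

#' Build a single-substitution motif distance graph
#'
#' Nodes are motifs weighted by the number of promoters containing them;
#' edges connect motifs differing by exactly one substitution. Core nodes
#' (count at least `core_threshold`) form the backbone: edges between two
#' non-core nodes are excluded, i.e. peripheral motifs attach only to the
#' core. Each edge is oriented from the higher-count endpoint to the lower;
#' ties leave the edge unoriented (flagged) so neither endpoint can be a
#' seed through it. Construction is deterministic: nodes and edges are in
#' lexicographic order.
#'
#' With `merge`, a named list of motif groups (e.g.
#' `list(TATAWA = expand_pattern("TATAWA"))`), each group becomes a single
#' labelled node whose count is the supplied count for the label if present
#' or the sum of its members' counts otherwise (a sum double-counts
#' promoters carrying several members; supply a de-duplicated count when
#' that matters). A merged node is adjacent to a motif when any member is.
#'
#' @param counts Named numeric vector: motif -> promoter count.
#' @param core_threshold Core membership threshold (default 200).
#' @param merge Optional named list of motif groups to merge.
#' @return An object of class `motif_graph` with `nodes` (motif, count,
#'   core), `edges` (from, to, count_from, count_to, oriented; directed
#'   high -> low) and `seeds`.
#' @export
motif_graph <- function(counts, core_threshold = 200, merge = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'counts' must be a fully named vector")
  if (any(counts < 0)) stop("counts must be >= 0")
  motifs <- toupper(names(counts))
  if (anyDuplicated(motifs)) stop("duplicated motifs in 'counts'")
  if (length(unique(nchar(motifs))) > 1L)
    stop("motifs must all have the same length")
  names(counts) <- motifs

  members <- as.list(motifs)         # node -> member motifs
  names(members) <- motifs
  node_counts <- counts
  if (!is.null(merge)) {
    for (lab in names(merge)) {
      grp <- toupper(merge[[lab]])
      present <- intersect(grp, motifs)
      if (!length(present)) next
      members <- members[setdiff(names(members), present)]
      members[[lab]] <- present
      node_counts <- node_counts[setdiff(names(node_counts), present)]
      node_counts[lab] <- if (lab %in% names(counts)) counts[lab]
                          else sum(counts[present])
    }
  }
  nodes <- sort(names(members))
  cnt <- node_counts[nodes]
  core <- cnt >= core_threshold

  # adjacency: two nodes are linked when any member pair is at distance 1
  all_members <- unlist(members, use.names = FALSE)
  owner <- rep(names(members), lengths(members))
  from <- character(0); to <- character(0)
  for (nd in nodes) {
    nb <- unique(unlist(lapply(members[[nd]], .neighbours1)))
    hit <- owner[match(nb, all_members, nomatch = 0L)]
    hit <- setdiff(unique(hit), nd)
    if (length(hit)) { from <- c(from, rep(nd, length(hit))); to <- c(to, hit) }
  }
  # each pair appears twice; keep one, drop non-core/non-core links
  if (length(from)) {
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(paste(a, b)) & (core[a] | core[b])
    a <- a[keep]; b <- b[keep]
    ca <- cnt[a]; cb <- cnt[b]
    efrom <- ifelse(ca >= cb, a, b)
    eto <- ifelse(ca >= cb, b, a)
    edges <- data.frame(from = efrom, to = eto,
                        count_from = cnt[efrom], count_to = cnt[eto],
                        oriented = ca != cb, stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        count_from = numeric(), count_to = numeric(),
                        oriented = logical(), stringsAsFactors = FALSE)
  }
  g <- structure(list(nodes = data.frame(motif = nodes, count = unname(cnt),
                                         core = unname(core),
                                         stringsAsFactors = FALSE),
                      edges = edges, core_threshold = core_threshold),
                 class = "motif_graph")
  g$seeds <- find_seeds(g)
  g
}

#' Seed motifs of a distance graph
#'
#' A seed is a core node all of whose graph neighbours have a strictly
#' lower promoter count; isolated core nodes are seeds. A count tie across
#' an edge disqualifies both endpoints through that edge.
#'
#' @param graph A `motif_graph`.
#' @return Character vector of seed motifs, sorted.
#' @export
find_seeds <- function(graph) {
  stopifnot(inherits(graph, "motif_graph"))
  nd <- graph$nodes
  cnt <- structure(nd$count, names = nd$motif)
  beaten <- character(0)
  e <- graph$edges
  if (nrow(e)) {
    # a node fails when some neighbour has count >= its own
    beaten <- unique(c(e$to[e$count_from >= e$count_to],
                       e$from[e$count_to >= e$count_from]))
  }
  sort(nd$motif[nd$core & !(nd$motif %in% beaten)])
}

#' @export
print.motif_graph <- function(x, ...) {
  cat(sprintf("motif_graph: %d nodes (%d core, threshold %g), %d edges\n",
              nrow(x$nodes), sum(x$nodes$core), x$core_threshold,
              nrow(x$edges)))
  if (nrow(x$edges) && any(!x$edges$oriented))
    cat(sprintf("  %d tied (unoriented) edge(s)\n", sum(!x$edges$oriented)))
  cat("  seeds:", if (length(x$seeds)) paste(x$seeds, collapse = " ")
                  else "(none)", "\n")
  invisible(x)
}
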