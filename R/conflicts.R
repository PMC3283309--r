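# Haploid and diploid conflict detection.
#
# A deletion cluster claims a deletion of at least `del_min` bases inside
# its breakpoint region, while every mapped read (from any cluster or any
# concordant pair) blocks the positions it covers. A set of clusters (plus
# concordant mappings, treated as clusters with minimal deletion length
# zero) is haploid-consistent if every cluster still finds a free interval
# of its minimal deletion length. Minimal conflicting sets contain exactly
# two or three elements; they become the hyperedges of a conflict
# hypergraph whose two-colorings are exactly the consistent assignments to
# the two copies of a diploid chromosome.

#' Build conflict nodes from clusters and concordant mappings
#'
#' Each cluster contributes a node whose *demand* is its minimal deletion
#' length, whose breakpoint region is the cluster's, and whose blocked
#' region is the cluster's span hull (all positions covered by its reads or
#' surrounding them). Each concordant mapping contributes a demand-zero
#' node blocking its full span.
#'
#' @param clusters List of valid [deletion_cluster] objects.
#' @param concordant Annotated mapping rows with `class == "concordant"`,
#'   or `NULL`.
#' @return A `data.frame` with columns `node`, `kind`, `chrom`,
#'   `br_start`, `br_end`, `demand`, `blocked_start`, `blocked_end`.
#' @export
conflict_nodes <- function(clusters = list(), concordant = NULL) {
  parts <- list()
  if (length(clusters)) {
    ok <- vapply(clusters, function(cl) isTRUE(cl$valid), logical(1))
    if (!all(ok)) stop("all cluster nodes must be valid clusters")
    parts$cl <- data.frame(
      node = vapply(clusters, function(cl) cl$id, character(1)),
      kind = "cluster",
      chrom = vapply(clusters, function(cl) cl$chrom, character(1)),
      br_start = vapply(clusters, function(cl) cl$br[1], numeric(1)),
      br_end = vapply(clusters, function(cl) cl$br[2], numeric(1)),
      demand = vapply(clusters, function(cl) cl$del_min, numeric(1)),
      blocked_start = vapply(clusters, function(cl) cl$span_hull[1], numeric(1)),
      blocked_end = vapply(clusters, function(cl) cl$span_hull[2], numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(concordant) && nrow(concordant)) {
    if (any(concordant$class != "concordant"))
      stop("`concordant` must contain concordant mappings only")
    parts$co <- data.frame(
      node = concordant$id,
      kind = "concordant",
      chrom = concordant$chrom,
      br_start = concordant$span_start,
      br_end = concordant$span_end,
      demand = 0,
      blocked_start = concordant$span_start,
      blocked_end = concordant$span_end,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(parts)) do.call(rbind, parts) else {
    data.frame(node = character(0), kind = character(0), chrom = character(0),
               br_start = numeric(0), br_end = numeric(0), demand = numeric(0),
               blocked_start = numeric(0), blocked_end = numeric(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (anyDuplicated(out$node)) stop("node ids must be unique")
  out
}

# Internal consistency kernel over node vectors; idx are row indices.
.consistent_idx <- function(idx, chrom, brs, bre, dem, bls, ble) {
  for (i in idx) {
    if (dem[i] <= 0) next
    others <- idx[idx != i & chrom[idx] == chrom[i]]
    if (max_free_length(brs[i], bre[i], bls[others], ble[others]) < dem[i])
      return(FALSE)
  }
  TRUE
}

#' Free space of a cluster node given blocking neighbours
#'
#' The maximal sub-intervals of the node's breakpoint region not covered by
#' the blocked regions of the other nodes.
#'
#' @param nodes Node table from [conflict_nodes()].
#' @param node Node id (or row index) of a cluster node.
#' @param others Node ids (or row indices) acting as blockers; defaults to
#'   all other nodes on the same chromosome.
#' @return Two-column matrix (`start`, `end`) of free intervals.
#' @export
free_space <- function(nodes, node, others = NULL) {
  i <- if (is.character(node)) match(node, nodes$node) else as.integer(node)
  if (is.na(i) || i < 1 || i > nrow(nodes)) stop("unknown node")
  o <- if (is.null(others)) {
    setdiff(which(nodes$chrom == nodes$chrom[i]), i)
  } else if (is.character(others)) {
    match(others, nodes$node)
  } else {
    as.integer(others)
  }
  o <- setdiff(o, i)
  subtract_intervals(nodes$br_start[i], nodes$br_end[i],
                     nodes$blocked_start[o], nodes$blocked_end[o])
}

#' Haploid consistency of a set of clusters and concordant mappings
#'
#' A node set is consistent on one chromosome copy iff every cluster node
#' retains, inside its breakpoint region and outside all other nodes'
#' blocked regions, a free interval at least as long as its minimal
#' deletion length. The empty set is vacuously consistent.
#'
#' @param nodes Node table from [conflict_nodes()].
#' @param idx Optional subset of nodes (ids or row indices) to test;
#'   defaults to all.
#' @return `TRUE` or `FALSE`.
#' @export
is_consistent_haploid <- function(nodes, idx = NULL) {
  ix <- if (is.null(idx)) seq_len(nrow(nodes)) else if (is.character(idx)) {
    match(idx, nodes$node)
  } else {
    as.integer(idx)
  }
  if (anyNA(ix)) stop("unknown node id in `idx`")
  .consistent_idx(ix, nodes$chrom, nodes$br_start, nodes$br_end,
                  nodes$demand, nodes$blocked_start, nodes$blocked_end)
}

# Interaction test: can node j influence node i's free space or vice versa?
.interacts <- function(nodes, i, j) {
  nodes$chrom[i] == nodes$chrom[j] &&
    (intervals_overlap(nodes$blocked_start[j], nodes$blocked_end[j],
                       nodes$br_start[i], nodes$br_end[i]) ||
     intervals_overlap(nodes$blocked_start[i], nodes$blocked_end[i],
                       nodes$br_start[j], nodes$br_end[j]))
}

#' Enumerate all minimal conflicting sets (haploid)
#'
#' Searches every pair and every overlap-connected triple of nodes for
#' conflicts whose proper subsets are all consistent. For sets of clusters
#' this search is complete: a minimal conflicting set in a haploid genome
#' contains exactly two or exactly three clusters. Triples with two or more
#' concordant (demand-zero) nodes are skipped: a demand-zero node only ever
#' blocks, so two of them cannot both be essential unless a smaller
#' conflict already exists.
#'
#' @param nodes Node table from [conflict_nodes()]. Every cluster node must
#'   be self-consistent (`demand <= br length`), which holds for valid
#'   clusters by construction.
#' @return A `conflict_hypergraph`: list with `nodes` (the input table) and
#'   `edges` (list of character vectors of node ids, each of size 2 or 3).
#' @export
enumerate_minimal_conflicts <- function(nodes) {
  n <- nrow(nodes)
  chrom <- nodes$chrom; brs <- nodes$br_start; bre <- nodes$br_end
  dem <- nodes$demand; bls <- nodes$blocked_start; ble <- nodes$blocked_end
  bad <- dem > interval_length(brs, bre)
  if (any(bad)) {
    stop("self-conflicting node(s): ", paste(nodes$node[bad], collapse = ", "))
  }
  edges <- list()
  if (n < 2) return(conflict_hypergraph(nodes, edges))

  is_cluster <- nodes$kind == "cluster"
  adj <- vector("list", n)
  pair_conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is_cluster[i] && !is_cluster[j]) next
      if (!.interacts(nodes, i, j)) next
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      if (!.consistent_idx(c(i, j), chrom, brs, bre, dem, bls, ble)) {
        pair_conflict[i, j] <- pair_conflict[j, i] <- TRUE
        edges[[length(edges) + 1L]] <- nodes$node[c(i, j)]
      }
    }
  }

  # Connected triples with all pairs consistent but the whole conflicting.
  seen <- new.env(hash = TRUE)
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j <= i) next
      for (k in sort(unique(c(adj[[i]], adj[[j]])))) {
        if (k == i || k == j) next
        trip <- sort(c(i, j, k))
        key <- paste(trip, collapse = ".")
        if (!is.null(seen[[key]])) next
        assign(key, TRUE, envir = seen)
        if (sum(!is_cluster[trip]) > 1L) next
        if (pair_conflict[trip[1], trip[2]] || pair_conflict[trip[1], trip[3]] ||
            pair_conflict[trip[2], trip[3]]) next
        if (!.consistent_idx(trip, chrom, brs, bre, dem, bls, ble)) {
          edges[[length(edges) + 1L]] <- nodes$node[trip]
        }
      }
    }
  }
  conflict_hypergraph(nodes, edges)
}

#' Conflict hypergraph
#'
#' @param nodes Node table from [conflict_nodes()].
#' @param edges List of character vectors of node ids (each of size 2 or 3).
#' @return An object of class `conflict_hypergraph`.
#' @export
conflict_hypergraph <- function(nodes, edges) {
  for (e in edges) {
    if (!length(e) %in% c(2L, 3L)) stop("hyperedges must have size 2 or 3")
    if (!all(e %in% nodes$node)) stop("hyperedge references unknown node")
  }
  structure(list(nodes = nodes, edges = edges), class = "conflict_hypergraph")
}

#' @export
print.conflict_hypergraph <- function(x, ...) {
  cat(sprintf("conflict_hypergraph: %d nodes, %d minimal conflicting sets\n",
              nrow(x$nodes), length(x$edges)))
  invisible(x)
}

#' Pairwise-conflicting triples (diploid conflict heuristic)
#'
#' Three clusters — or two clusters and one concordant mapping — that are
#' *pairwise* in haploid conflict cannot be placed on two chromosome copies
#' without a per-copy conflict. Enumerating such triples is a polynomial
#' lower-bound heuristic for diploid inconsistency; it deliberately misses
#' non-pairwise diploid structures, which require at least six clusters in
#' very specific arrangements.
#'
#' @param nodes Node table from [conflict_nodes()].
#' @return List of character vectors of three node ids.
#' @export
diploid_conflict_triplets <- function(nodes) {
  n <- nrow(nodes)
  if (n < 3) return(list())
  chrom <- nodes$chrom; brs <- nodes$br_start; bre <- nodes$br_end
  dem <- nodes$demand; bls <- nodes$blocked_start; ble <- nodes$blocked_end
  is_cluster <- nodes$kind == "cluster"
  conf <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is_cluster[i] && !is_cluster[j]) next
      if (!.interacts(nodes, i, j)) next
      conf[i, j] <- conf[j, i] <-
        !.consistent_idx(c(i, j), chrom, brs, bre, dem, bls, ble)
    }
  }
  out <- list()
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      if (!conf[i, j]) next
      for (k in (j + 1):n) {
        if (conf[i, k] && conf[j, k] && sum(!is_cluster[c(i, j, k)]) <= 1L) {
          out[[length(out) + 1L]] <- nodes$node[c(i, j, k)]
        }
      }
    }
  }
  out
}

#' Exact two-coloring of a conflict hypergraph
#'
#' Assigns one of two colors (chromosome copies) to each node such that no
#' hyperedge is monochromatic, or proves that no such coloring exists. A
#' valid coloring corresponds to an assignment of clusters to the two
#' copies of a diploid chromosome with no per-copy conflict. The general
#' problem is NP-hard even with edges of size two and three, so the exact
#' backtracking search refuses instances larger than `max_nodes`.
#'
#' @param h A [conflict_hypergraph].
#' @param max_nodes Refusal threshold for the exact search.
#' @return List with `satisfiable` (logical) and `coloring` (named integer
#'   vector over `{1, 2}`, or `NULL` when unsatisfiable). Nodes not covered
#'   by any edge are colored 1.
#' @export
two_color <- function(h, max_nodes = 20) {
  stopifnot(inherits(h, "conflict_hypergraph"))
  ids <- h$nodes$node
  if (length(ids) > max_nodes) {
    stop(sprintf(paste0("two_color: %d nodes exceed max_nodes = %d; ",
                        "use diploid_conflict_triplets() for large instances"),
                 length(ids), max_nodes))
  }
  coloring <- stats::setNames(rep(1L, length(ids)), ids)
  if (!length(h$edges)) return(list(satisfiable = TRUE, coloring = coloring))

  active <- sort(unique(unlist(h$edges)))
  eidx <- lapply(h$edges, function(e) match(e, active))
  m <- length(active)
  col <- integer(m)  # 0 = unset

  edge_ok <- function() {
    for (e in eidx) {
      ce <- col[e]
      if (all(ce != 0L) && length(unique(ce)) == 1L) return(FALSE)
    }
    TRUE
  }
  solve <- function(i) {
    if (i > m) return(TRUE)
    for (cc in 1:2) {
      col[i] <<- cc
      if (edge_ok() && solve(i + 1L)) return(TRUE)
    }
    col[i] <<- 0L
    FALSE
  }
  if (!solve(1L)) return(list(satisfiable = FALSE, coloring = NULL))
  coloring[active] <- col
  list(satisfiable = TRUE, coloring = coloring)
}
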