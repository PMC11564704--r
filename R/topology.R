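#' Lattice topology objects
#'
#' A lattice topology is a tiered directed acyclic graph: vertices are
#' numbered tier by tier, left to right, and every edge goes from a vertex in
#' tier \eqn{t} to a vertex in tier \eqn{t+1}. The default topology used for
#' the dynamic graph pattern has 9 tiers of sizes 1, 2, 3, 3, 3, 3, 2, 1, 1
#' (hence the "123" of the name), 19 vertices and 28 directed edges, with
#' vertex 1 the unique source and vertex 19 the unique sink. Every
#' source-to-sink path visits exactly one vertex per tier.
#'
#' @param tiers integer vector of tier sizes (first and last must be 1).
#' @param edges two-column integer matrix of directed edges (parent, child).
#'
#' @return An object of class `lattice_topology`: a list with elements
#'   `tiers`, `edges` (sorted by parent then child), `n_vertices` and `tier`
#'   (tier index of each vertex).
#' @seealso [default_lattice()], [lattice_walk()], [read_lattice()]
#' @export
lattice_topology <- function(tiers, edges) {
  tiers <- as.integer(tiers)
  if (length(tiers) < 2L || any(tiers < 1L))
    stop("tiers must be a vector of positive sizes")
  if (tiers[1L] != 1L || tiers[length(tiers)] != 1L)
    stop("first and last tiers must contain a single vertex")
  nv <- sum(tiers)
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  if (any(is.na(edges)) || any(edges < 1L) || any(edges > nv))
    stop("edge endpoints must be vertex ids in 1..", nv)
  tier_of <- rep(seq_along(tiers), tiers)
  if (any(tier_of[edges[, 2L]] - tier_of[edges[, 1L]] != 1L))
    stop("every edge must connect consecutive tiers")
  if (anyDuplicated(edges))
    stop("duplicate edges")
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  topo <- structure(
    list(tiers = tiers, edges = edges, n_vertices = nv, tier = tier_of),
    class = "lattice_topology")
  # connectivity: every non-sink vertex needs a child, every non-source a
  # parent, so every vertex lies on a source-to-sink path
  no_child <- setdiff(seq_len(nv - 1L), edges[, 1L])
  no_parent <- setdiff(seq_len(nv)[-1L], edges[, 2L])
  if (length(no_child))
    stop("vertex ", no_child[1L], " has no outgoing edge")
  if (length(no_parent))
    stop("vertex ", no_parent[1L], " has no incoming edge")
  topo
}

#' The default 19-vertex lattice
#'
#' Builds the shipped 9-tier topology (tier sizes 1, 2, 3, 3, 3, 3, 2, 1, 1;
#' 19 vertices; 28 directed edges). Between tiers the edges follow a fixed
#' rule: when the tier grows, parent \eqn{i} feeds children \eqn{i} and
#' \eqn{i+1}; when sizes are equal, parent \eqn{i} feeds children \eqn{i} and
#' \eqn{i+1} truncated at the right edge; when the tier shrinks, child
#' \eqn{j} is fed by parents \eqn{j} and \eqn{j+1}. A replacement topology
#' can be loaded from file with [read_lattice()].
#'
#' @return A `lattice_topology`.
#' @examples
#' topo <- default_lattice()
#' topo$n_vertices  # 19
#' nrow(topo$edges) # 28
#' @export
default_lattice <- function() {
  tiers <- c(1L, 2L, 3L, 3L, 3L, 3L, 2L, 1L, 1L)
  starts <- cumsum(c(0L, tiers[-length(tiers)]))
  edges <- list()
  for (t in seq_len(length(tiers) - 1L)) {
    a <- tiers[t]; b <- tiers[t + 1L]
    pa <- starts[t]; ch <- starts[t + 1L]
    if (b > a) {            # expanding: i -> i, i+1
      e <- cbind(rep(seq_len(a), each = 2L),
                 as.vector(vapply(seq_len(a), function(i) c(i, i + 1L),
                                  integer(2L))))
    } else if (b == a) {    # equal: i -> i, i+1 truncated
      e <- do.call(rbind, lapply(seq_len(a), function(i) {
        cbind(i, intersect(c(i, i + 1L), seq_len(b)))
      }))
    } else {                # contracting: j <- j, j+1
      e <- do.call(rbind, lapply(seq_len(b), function(j) {
        cbind(c(j, j + 1L), j)
      }))
      e <- e[e[, 1L] <= a, , drop = FALSE]
    }
    edges[[t]] <- cbind(pa + e[, 1L], ch + e[, 2L])
  }
  lattice_topology(tiers, do.call(rbind, edges))
}

#' Children of a lattice vertex
#'
#' @param topology a `lattice_topology`.
#' @param vertex a vertex id.
#' @return Integer vector of child ids, sorted ascending; empty for the sink.
#' @export
lattice_children <- function(topology, vertex) {
  stopifnot(inherits(topology, "lattice_topology"))
  vertex <- as.integer(vertex)
  if (length(vertex) != 1L || is.na(vertex) ||
      vertex < 1L || vertex > topology$n_vertices)
    stop("unknown vertex id: ", vertex)
  sort(topology$edges[topology$edges[, 1L] == vertex, 2L])
}

# child list for all vertices, in C++-friendly form
children_list <- function(topology) {
  lapply(seq_len(topology$n_vertices), function(v) {
    unname(sort(topology$edges[topology$edges[, 1L] == v, 2L]))
  })
}

#' Enumerate all source-to-sink paths
#'
#' Exhaustively lists every directed path from vertex 1 to the sink. The
#' default lattice is small, so this is cheap; it is mainly useful for
#' validating a topology (every path must visit one vertex per tier).
#'
#' @param topology a `lattice_topology`.
#' @return A list of integer vectors, one per path.
#' @export
enumerate_paths <- function(topology) {
  stopifnot(inherits(topology, "lattice_topology"))
  sink <- topology$n_vertices
  ch <- children_list(topology)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == sink) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (child in ch[[v]]) walk(c(path, child))
  }
  walk(1L)
  out
}

#' Greedy probability walk through the lattice
#'
#' Starting at vertex 1, repeatedly moves to the child whose probability is
#' smallest (`kind = "minimum"`) or largest (`kind = "maximum"`), ending at
#' the sink. Ties are broken towards the lowest child id, so the walk is
#' deterministic. The result always has one vertex per tier.
#'
#' @param topology a `lattice_topology`.
#' @param probabilities numeric vector with one probability per vertex.
#' @param kind `"minimum"` or `"maximum"`.
#' @return An integer vector of vertex ids (class `walking_path`, with a
#'   `kind` attribute), starting at 1 and ending at the sink.
#' @examples
#' lattice_walk(default_lattice(), rep(0.05, 19), "minimum")
#' @export
lattice_walk <- function(topology, probabilities,
                         kind = c("minimum", "maximum")) {
  stopifnot(inherits(topology, "lattice_topology"))
  kind <- match.arg(kind)
  if (length(probabilities) != topology$n_vertices)
    stop("need one probability per vertex (",
         topology$n_vertices, "), got ", length(probabilities))
  if (any(is.na(probabilities)))
    stop("missing probability for a vertex")
  ch <- children_list(topology)
  path <- integer(length(topology$tiers))
  path[1L] <- 1L
  cur <- 1L
  for (t in seq_len(length(path) - 1L)) {
    cand <- ch[[cur]]
    p <- probabilities[cand]
    cur <- if (kind == "minimum") cand[which.min(p)] else cand[which.max(p)]
    path[t + 1L] <- cur
  }
  structure(path, kind = kind, class = "walking_path")
}

#' Write / read a lattice topology as plain text
#'
#' The format is line-oriented: a `tiers` line listing the tier sizes,
#' followed by one `edge <parent> <child>` line per directed edge. Lines
#' starting with `#` are comments.
#'
#' @param topology a `lattice_topology`.
#' @param path file path.
#' @return `write_lattice` returns `path` invisibly; `read_lattice` returns a
#'   `lattice_topology`.
#' @export
write_lattice <- function(topology, path) {
  stopifnot(inherits(topology, "lattice_topology"))
  lines <- c(
    "# lattice topology: tier sizes, then one directed edge per line",
    paste("tiers", paste(topology$tiers, collapse = " ")),
    paste("edge", topology$edges[, 1L], topology$edges[, 2L]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  keys <- vapply(toks, `[[`, "", 1L)
  tiers_line <- toks[keys == "tiers"]
  if (length(tiers_line) != 1L)
    stop("topology file must contain exactly one 'tiers' line")
  tiers <- as.integer(tiers_line[[1L]][-1L])
  ed <- toks[keys == "edge"]
  if (!length(ed)) stop("topology file contains no edges")
  edges <- t(vapply(ed, function(x) as.integer(x[2:3]), integer(2L)))
  lattice_topology(tiers, edges)
}

#' @export
print.lattice_topology <- function(x, ...) {
  cat("Lattice topology: ", x$n_vertices, " vertices, ",
      nrow(x$edges), " edges, ", length(x$tiers), " tiers (",
      paste(x$tiers, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' @export
print.walking_path <- function(x, ...) {
  cat(attr(x, "kind"), "walk:", paste(unclass(x), collapse = " -> "), "\n")
  invisible(x)
}
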