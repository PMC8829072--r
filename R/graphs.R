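#' Undirected contact networks
#'
#' The simulator runs on simple undirected graphs whose nodes are
#' individuals and whose edges are social contacts.  Graphs are stored as
#' an edge matrix with 0-based node ids (the on-disk edge-list format is
#' also 0-based).
#'
#' @param n_nodes number of nodes; node ids are \code{0 .. n_nodes - 1}.
#' @param edges two-column integer matrix of 0-based endpoint pairs.
#' @param provenance optional list recording the generator and its
#'   parameters (kept for reproducibility manifests).
#' @return An object of class \code{"isvor_graph"} with fields
#'   \code{n_nodes}, \code{edges} (canonicalized: \code{u < v}, sorted,
#'   deduplicated) and \code{provenance}.
#' @examples
#' g <- isvor_graph(3, rbind(c(0, 1), c(1, 2)))
#' g$n_nodes
#' @export
isvor_graph <- function(n_nodes, edges, provenance = NULL) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 1L)
    stop("n_nodes must be a positive integer", call. = FALSE)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (any(is.na(edges)))
    stop("edges must be integer node ids", call. = FALSE)
  if (any(edges < 0L) || any(edges >= n_nodes))
    stop("edge endpoints must lie in 0 .. n_nodes - 1", call. = FALSE)
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed", call. = FALSE)
  # canonical form: u < v, lexicographic order, no duplicates
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  o <- order(u, v)
  u <- u[o]; v <- v[o]
  dup <- duplicated(u * as.double(n_nodes) + v)
  if (any(dup)) { u <- u[!dup]; v <- v[!dup] }
  structure(list(n_nodes = n_nodes, edges = cbind(u = u, v = v),
                 provenance = provenance),
            class = "isvor_graph")
}

#' @rdname isvor_graph
#' @param x object to test/print.
#' @export
is_isvor_graph <- function(x) inherits(x, "isvor_graph")

#' @rdname isvor_graph
#' @param ... ignored.
#' @export
print.isvor_graph <- function(x, ...) {
  cat("isvor_graph:", x$n_nodes, "nodes,", nrow(x$edges), "edges\n")
  if (!is.null(x$provenance))
    cat("  generator:", x$provenance$family,
        paste(sprintf("%s=%s", names(x$provenance$args),
                      unlist(x$provenance$args)), collapse = ", "),
        if (!is.null(x$provenance$seed)) paste0("seed=", x$provenance$seed),
        "\n")
  invisible(x)
}

from_igraph <- function(ig, provenance = NULL) {
  el <- igraph::as_edgelist(ig, names = FALSE) - 1L
  isvor_graph(igraph::vcount(ig), el, provenance = provenance)
}

#' Convert to an igraph object
#' @param g an \code{isvor_graph}.
#' @return an \code{igraph} graph with 1-based vertex ids.
#' @export
as_igraph <- function(g) {
  stopifnot(is_isvor_graph(g))
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, as.vector(t(g$edges + 1L)))
  ig
}

#' Generate a Watts-Strogatz small-world network
#'
#' Standard construction: a ring lattice where every node is connected to
#' its \code{k} nearest neighbours (\code{k/2} on each side), followed by
#' random rewiring of each lattice edge with probability \code{p} to a
#' uniformly chosen target, avoiding self-loops and duplicate edges.  The
#' edge count is exactly \code{n * k / 2} for every seed.
#'
#' @param n node count.
#' @param k even ring-lattice degree, \code{2 <= k < n}.
#' @param p rewiring probability in \code{[0, 1]}.
#' @param seed optional integer seed (applied with \code{set.seed}).
#' @return an \code{\link{isvor_graph}}.
#' @examples
#' g <- generate_ws(10, 2, 0)   # intact ring
#' nrow(g$edges)                # 10
#' @export
generate_ws <- function(n, k, p, seed = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(k) || k %% 2L != 0L || k < 2L || k >= n)
    stop("ws_k must be even and satisfy 2 <= k < n (got k=", k, ", n=", n, ")",
         call. = FALSE)
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop("ws_p must be a probability in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::sample_smallworld(dim = 1, size = n, nei = k %/% 2L, p = p,
                                  loops = FALSE, multiple = FALSE)
  from_igraph(ig, provenance = list(family = "ws",
                                    args = list(n = n, k = k, p = p),
                                    seed = seed))
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Standard preferential attachment: the graph grows one node at a time
#' and each new node attaches (up to) \code{m} edges to existing nodes
#' with probability proportional to their degree.  The mean degree
#' approaches \code{2 m} for large \code{n}; the heavy-tailed degree
#' distribution is an emergent property.
#'
#' @param n node count.
#' @param m edges attached per new node, \code{1 <= m < n}.
#' @param seed optional integer seed.
#' @return an \code{\link{isvor_graph}}.
#' @examples
#' g <- generate_ba(200, 1, seed = 1)  # a tree: 199 edges
#' @export
generate_ba <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(m) || m < 1L || m >= n)
    stop("ba_m must satisfy 1 <= m < n (got m=", m, ", n=", n, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ig <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  from_igraph(ig, provenance = list(family = "ba",
                                    args = list(n = n, m = m),
                                    seed = seed))
}

#' Network specification
#'
#' A declarative description of a network substrate, so experiments can
#' regenerate a fresh instance per replicate.
#'
#' @param family one of \code{"ws"}, \code{"ba"}, \code{"edgelist"},
#'   \code{"fixture"}.
#' @param n node count (ws/ba).
#' @param k even ring-lattice degree (ws).
#' @param p rewiring probability (ws).
#' @param m edges per new node (ba).
#' @param path edge-list file (family \code{"edgelist"}).
#' @param graph a fixed \code{isvor_graph} (family \code{"fixture"}).
#' @return an object of class \code{"network_spec"}.
#' @examples
#' ws <- network_spec("ws", n = 2000, k = 10, p = 0.4)
#' ba <- network_spec("ba", n = 2000, m = 5)
#' @export
network_spec <- function(family = c("ws", "ba", "edgelist", "fixture"),
                         n = 2000, k = 10, p = 0.4, m = 5,
                         path = NULL, graph = NULL) {
  family <- match.arg(family)
  spec <- structure(list(family = family, n = as.integer(n),
                         k = as.integer(k), p = p, m = as.integer(m),
                         path = path, graph = graph),
                    class = "network_spec")
  if (family == "ws" && (spec$k %% 2L != 0L || spec$k >= spec$n))
    stop("ws_k must be even and < n", call. = FALSE)
  if (family == "ba" && (spec$m < 1L || spec$m >= spec$n))
    stop("ba_m must satisfy 1 <= m < n", call. = FALSE)
  if (family == "edgelist" && is.null(path))
    stop("family 'edgelist' needs a path", call. = FALSE)
  if (family == "fixture" && !is_isvor_graph(graph))
    stop("family 'fixture' needs an isvor_graph", call. = FALSE)
  spec
}

#' Realize a network specification
#' @param spec a \code{\link{network_spec}}.
#' @param seed integer seed used for the random families.
#' @return an \code{\link{isvor_graph}}.
#' @export
graph_from_spec <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  switch(spec$family,
         ws = generate_ws(spec$n, spec$k, spec$p, seed = seed),
         ba = generate_ba(spec$n, spec$m, seed = seed),
         edgelist = read_edgelist(spec$path),
         fixture = spec$graph)
}

#' Degree summary of a graph
#'
#' @param g an \code{\link{isvor_graph}} with at least one node.
#' @return a list with \code{mean_degree} (\code{2 |E| / n}),
#'   \code{max_degree}, and \code{degree_histogram} (a named table keyed
#'   by observed degree).
#' @examples
#' degree_summary(generate_ws(10, 2, 0))
#' @export
degree_summary <- function(g) {
  if (!is_isvor_graph(g) || g$n_nodes < 1L)
    stop("degree_summary needs a non-empty isvor_graph", call. = FALSE)
  deg <- tabulate(c(g$edges) + 1L, nbins = g$n_nodes)
  hist <- table(deg)
  list(mean_degree = 2 * nrow(g$edges) / g$n_nodes,
       max_degree = if (length(deg)) max(deg) else 0L,
       degree_histogram = hist)
}

# 0-based CSR adjacency for the compiled stepping kernels
adjacency_csr <- function(g) {
  n <- g$n_nodes
  deg <- tabulate(c(g$edges) + 1L, nbins = n)
  off <- c(0L, cumsum(deg))
  nb <- integer(2L * nrow(g$edges))
  pos <- off[seq_len(n)]  # next free slot per node
  u <- g$edges[, 1L]; v <- g$edges[, 2L]
  for (i in seq_along(u)) {
    nb[pos[u[i] + 1L] + 1L] <- v[i]; pos[u[i] + 1L] <- pos[u[i] + 1L] + 1L
    nb[pos[v[i] + 1L] + 1L] <- u[i]; pos[v[i] + 1L] <- pos[v[i] + 1L] + 1L
  }
  list(off = off, nb = nb)
}

#' Read / write edge-list files
#'
#' Plain-text format: one edge per line as two whitespace-separated
#' 0-based integer node ids; lines starting with \code{#} are comments.
#' \code{write_edgelist} prefixes a format header comment.  A written
#' graph reads back with an identical canonical edge set.
#'
#' @param path file path.
#' @param n_nodes optional node count; defaults to \code{max(id) + 1}.
#' @return \code{read_edgelist} returns an \code{\link{isvor_graph}};
#'   \code{write_edgelist} returns \code{path} invisibly.
#' @examples
#' f <- tempfile()
#' write_edgelist(generate_ws(50, 4, 0.2, seed = 1), f)
#' g <- read_edgelist(f)
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#\\s*n_nodes\\s+\\d+\\s*$", lines, value = TRUE)
  if (is.null(n_nodes) && length(hdr))
    n_nodes <- as.integer(sub("^#\\s*n_nodes\\s+(\\d+)\\s*$", "\\1", hdr[1L]))
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    if (is.null(n_nodes)) stop("empty edge list and no n_nodes given",
                               call. = FALSE)
    return(isvor_graph(n_nodes, NULL))
  }
  parts <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("malformed edge line ", idx[bad[1L]], ": '", lines[idx[bad[1L]]],
         "'", call. = FALSE)
  m <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 2L,
                               byrow = TRUE))
  nai <- which(is.na(m[, 1L]) | is.na(m[, 2L]))
  if (length(nai))
    stop("malformed edge line ", idx[nai[1L]], ": '", lines[idx[nai[1L]]],
         "'", call. = FALSE)
  loop <- which(m[, 1L] == m[, 2L])
  if (length(loop))
    stop("self-loop at line ", idx[loop[1L]], ": '", lines[idx[loop[1L]]],
         "'", call. = FALSE)
  if (is.null(n_nodes)) n_nodes <- max(m) + 1L
  isvor_graph(n_nodes, m, provenance = list(family = "edgelist",
                                            args = list(path = path)))
}

#' @rdname read_edgelist
#' @param g graph to write.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(is_isvor_graph(g))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# undirected edge list, 0-based node ids",
               paste0("# n_nodes ", g$n_nodes)), con)
  if (nrow(g$edges))
    writeLines(paste(g$edges[, 1L], g$edges[, 2L]), con)
  invisible(path)
}
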