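#' Undirected protein-interaction network
#'
#' A `ppi_network` is a simple undirected graph over opaque molecule
#' identifiers (typically UniProt accessions or miRNA names). Self-loops and
#' duplicate edges are collapsed at construction; edge provenance (which
#' source databases attest an interaction) survives the collapse as the
#' union of the duplicates' provenance sets.
#'
#' @param edges a data.frame (or 2-column matrix) with columns `id_a`,
#'   `id_b` and optionally `provenance` (semicolon-separated source tags).
#'   May be `NULL` for an edgeless network.
#' @param nodes character vector of node identifiers to include even when
#'   they touch no edge (isolated nodes).
#' @param quiet suppress the message reporting collapsed self-loops and
#'   duplicate edges.
#'
#' @return an object of class `ppi_network` with components `nodes` (sorted
#'   identifiers), `edges` (data.frame `id_a`, `id_b`, `provenance`, with
#'   `id_a < id_b`), `adj` (adjacency list of integer node indices) and
#'   `node_attrs` (data.frame of per-node annotations, one row per node).
#' @export
ppi_network <- function(edges = NULL, nodes = character(), quiet = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(id_a = character(), id_b = character(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) {
    edges <- data.frame(id_a = edges[, 1], id_b = edges[, 2],
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id_a", "id_b") %in% names(edges)))
  if (!"provenance" %in% names(edges)) {
    edges$provenance <- rep("", nrow(edges))
  }
  edges$id_a <- as.character(edges$id_a)
  edges$id_b <- as.character(edges$id_b)
  if (any(!nzchar(edges$id_a)) || any(!nzchar(edges$id_b))) {
    stop("edge endpoints must be non-empty identifiers")
  }

  loops <- edges$id_a == edges$id_b
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]

  # canonical orientation id_a < id_b so duplicates collapse regardless of
  # the order a source reported the pair in
  flip <- edges$id_a > edges$id_b
  tmp <- edges$id_a[flip]
  edges$id_a[flip] <- edges$id_b[flip]
  edges$id_b[flip] <- tmp

  key <- paste(edges$id_a, edges$id_b, sep = "\r")
  n_dups <- sum(duplicated(key))
  if (n_dups > 0 || n_loops > 0) {
    prov <- split(edges$provenance, key)
    prov <- vapply(prov, function(p) {
      p <- unlist(strsplit(p[nzchar(p)], ";", fixed = TRUE))
      paste(sort(unique(p)), collapse = ";")
    }, character(1))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$provenance <- unname(prov[paste(edges$id_a, edges$id_b, sep = "\r")])
    if (!quiet) {
      message(sprintf("ppi_network: collapsed %d self-loop(s) and %d duplicate edge(s)",
                      n_loops, n_dups))
    }
  }

  all_nodes <- sort(unique(c(as.character(nodes), edges$id_a, edges$id_b)))
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  rownames(edges) <- NULL

  net <- list(
    nodes = all_nodes,
    edges = edges,
    adj = build_adjacency(all_nodes, edges),
    node_attrs = data.frame(row.names = all_nodes)
  )
  class(net) <- "ppi_network"
  net
}

build_adjacency <- function(nodes, edges) {
  n <- length(nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges)) {
    ia <- match(edges$id_a, nodes)
    ib <- match(edges$id_b, nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (ncol(x$node_attrs)) {
    cat("node attributes:", paste(names(x$node_attrs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `ppi_network`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

node_index <- function(net, v) {
  i <- match(v, net$nodes)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(v[is.na(i)], collapse = ", "))
  }
  i
}

#' Node degrees
#'
#' Degree centrality: the number of edges incident to each node.
#'
#' @param net a `ppi_network`
#' @param v optional node identifiers (default: all nodes)
#' @return named integer vector
#' @export
node_degree <- function(net, v = NULL) {
  deg <- vapply(net$adj, length, integer(1))
  names(deg) <- net$nodes
  if (!is.null(v)) deg <- deg[net$nodes[node_index(net, v)]]
  deg
}

#' Set a per-node attribute
#'
#' @param net a `ppi_network`
#' @param name attribute name
#' @param values vector named by node identifier, or a scalar recycled to
#'   all nodes; unnamed vectors must match the node count and order.
#' @return the modified network
#' @export
set_node_attr <- function(net, name, values) {
  n <- length(net$nodes)
  if (is.null(names(values))) {
    if (length(values) == 1) values <- rep(values, n)
    stopifnot(length(values) == n)
    net$node_attrs[[name]] <- values
  } else {
    i <- node_index(net, names(values))
    col <- rep(NA, n)
    storage.mode(col) <- storage.mode(values)
    col[i] <- values
    net$node_attrs[[name]] <- col
  }
  net
}

# BFS from node index `src`; returns integer distances (NA = unreachable)
bfs_distances <- function(net, src) {
  n <- length(net$nodes)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- integer(n)
  queue[1] <- src
  head <- 1L; tail <- 1L
  adj <- net$adj
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    du <- dist[u]
    for (w in adj[[u]]) {
      if (is.na(dist[w])) {
        dist[w] <- du + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

#' Connected components
#'
#' @param net a `ppi_network`
#' @return a list with `membership` (integer component id per node, named),
#'   `sizes` (component sizes) and `components` (list of node-identifier
#'   vectors, largest first, ties broken by smallest member identifier).
#' @export
connected_components <- function(net) {
  n <- length(net$nodes)
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(membership[s])) next
    comp <- comp + 1L
    reach <- !is.na(bfs_distances(net, s))
    membership[reach & is.na(membership)] <- comp
  }
  names(membership) <- net$nodes
  comps <- split(net$nodes, membership)
  ord <- order(-vapply(comps, length, integer(1)),
               vapply(comps, min, character(1)))
  comps <- unname(comps[ord])
  relabel <- match(membership, as.integer(names(split(seq_len(n), membership))[ord]))
  membership <- relabel
  names(membership) <- net$nodes
  list(membership = membership,
       sizes = vapply(comps, length, integer(1)),
       components = comps)
}

#' Topology summary
#'
#' Node and edge counts, number of connected components, size of the
#' largest connected component (LCC), and the mean shortest-path length
#' averaged over connected unordered node pairs only (pairs in different
#' components are excluded from both numerator and denominator). A network
#' with no connected pair has `avg_path_length = NA`.
#'
#' @param net a `ppi_network`
#' @return a one-row data.frame with columns `n_nodes`, `n_edges`,
#'   `n_components`, `lcc_size`, `avg_path_length`
#' @export
topology_summary <- function(net) {
  n <- length(net$nodes)
  if (n == 0) {
    return(data.frame(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                      lcc_size = 0L, avg_path_length = NA_real_))
  }
  cc <- connected_components(net)
  total <- 0
  npairs <- 0
  for (s in seq_len(n)) {
    d <- bfs_distances(net, s)
    d <- d[!is.na(d)]
    total <- total + sum(as.numeric(d))
    npairs <- npairs + (length(d) - 1L)
  }
  npairs <- npairs / 2
  total <- total / 2
  data.frame(
    n_nodes = n,
    n_edges = nrow(net$edges),
    n_components = length(cc$sizes),
    lcc_size = max(cc$sizes),
    avg_path_length = if (npairs > 0) total / npairs else NA_real_
  )
}

#' Induced subgraph
#'
#' @param net a `ppi_network`
#' @param keep node identifiers to retain
#' @return the induced `ppi_network` (edges with both endpoints kept);
#'   node attributes are carried over.
#' @export
induced_subnetwork <- function(net, keep) {
  i <- node_index(net, keep)       # validates
  keep <- net$nodes[sort(i)]
  e <- net$edges[net$edges$id_a %in% keep & net$edges$id_b %in% keep, ,
                 drop = FALSE]
  sub <- ppi_network(e, nodes = keep, quiet = TRUE)
  sub$node_attrs <- net$node_attrs[sub$nodes, , drop = FALSE]
  sub
}

#' Remove one node (and its incident edges)
#'
#' @param net a `ppi_network`
#' @param v a node identifier present in the network
#' @return the depleted `ppi_network`
#' @export
remove_node <- function(net, v) {
  stopifnot(length(v) == 1)
  node_index(net, v)
  induced_subnetwork(net, setdiff(net$nodes, v))
}

#' Ego network around a seed node
#'
#' Induced subgraph on all nodes within geodesic distance `radius` of the
#' seed, each labelled with its ring level (0 = seed, 1 = first neighbours,
#' 2 = second neighbours, ...) in the node attribute `ring`.
#'
#' @param net a `ppi_network`
#' @param seed node identifier
#' @param radius maximum geodesic distance (default 2)
#' @return a `ppi_network` with integer node attribute `ring`
#' @export
ego_network <- function(net, seed, radius = 2L) {
  stopifnot(radius >= 0)
  s <- node_index(net, seed)
  d <- bfs_distances(net, s)
  keep <- which(!is.na(d) & d <= radius)
  sub <- induced_subnetwork(net, net$nodes[keep])
  ring <- d[keep]
  names(ring) <- net$nodes[keep]
  set_node_attr(sub, "ring", ring)
}

#' Convert to igraph
#'
#' @param net a `ppi_network`
#' @return an undirected `igraph` graph carrying node attributes and the
#'   edge `provenance` attribute
#' @export
as_igraph <- function(net) {
  vertices <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  for (a in names(net$node_attrs)) vertices[[a]] <- net$node_attrs[[a]]
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = vertices)
}

#' Write a network as GraphML
#'
#' @param net a `ppi_network`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  # igraph refuses logical NA attributes in graphml; coerce to character
  for (a in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, a)
    if (is.logical(v)) g <- igraph::set_vertex_attr(g, a, value = as.character(v))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
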