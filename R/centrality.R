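#' Betweenness centrality
#'
#' Cb(v) = sum over unordered pairs {s, t} (s != v != t) of
#' sigma_st(v) / sigma_st, where sigma_st is the number of shortest s-t
#' paths and sigma_st(v) the number of those passing through v. Each
#' unordered pair is counted once; endpoints are excluded; pairs in
#' different components contribute nothing. Computed with Brandes'
#' dependency accumulation (one BFS per source), which for an undirected
#' graph double-counts each pair, hence the final division by two.
#'
#' @param net a `ppi_network`
#' @return named numeric vector of Cb(v) over all nodes
#' @export
betweenness_centrality <- function(net) {
  n <- length(net$nodes)
  cb <- numeric(n)
  adj <- net$adj
  for (s in seq_len(n)) {
    # BFS from s recording predecessor lists and path counts
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L; nv <- 0L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      nv <- nv + 1L
      order_visited[nv] <- u
      for (w in adj[[u]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[u] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[u] + 1L) {
          sigma[w] <- sigma[w] + sigma[u]
          preds[[w]] <- c(preds[[w]], u)
        }
      }
    }
    # accumulate dependencies in reverse BFS order
    delta <- numeric(n)
    for (k in rev(seq_len(nv))) {
      w <- order_visited[k]
      coeff <- (1 + delta[w]) / sigma[w]
      for (u in preds[[w]]) delta[u] <- delta[u] + sigma[u] * coeff
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb <- cb / 2
  names(cb) <- net$nodes
  cb
}

#' Closeness centrality
#'
#' Cc(v) = (n - 1) / sum of d(v, u) over nodes u in v's connected
#' component, where n is the size of that component. An isolated node has
#' closeness 0 by convention.
#'
#' @param net a `ppi_network`
#' @param v optional node identifiers (default: all nodes)
#' @return named numeric vector of raw closeness values in [0, 1]
#' @export
closeness_centrality <- function(net, v = NULL) {
  idx <- if (is.null(v)) seq_along(net$nodes) else node_index(net, v)
  cc <- vapply(idx, function(i) {
    d <- bfs_distances(net, i)
    d <- d[!is.na(d)]
    if (length(d) <= 1) return(0)
    (length(d) - 1) / sum(as.numeric(d))
  }, numeric(1))
  names(cc) <- net$nodes[idx]
  cc
}

#' Centrality report
#'
#' Degree, betweenness and closeness for a set of nodes. `closeness_norm`
#' is raw closeness divided by the maximum raw closeness over *all* nodes
#' of the network (so the network-wide maximum is 1 even when reporting a
#' subset).
#'
#' @param net a `ppi_network`
#' @param nodes node identifiers to report (default: every node, in sorted
#'   order so reports are byte-stable)
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness_raw`, `closeness_norm`
#' @export
centrality_report <- function(net, nodes = NULL) {
  if (is.null(nodes)) nodes <- net$nodes else node_index(net, nodes)
  bt <- betweenness_centrality(net)
  cl <- closeness_centrality(net)
  cmax <- max(cl, 0)
  out <- data.frame(
    node = nodes,
    degree = unname(node_degree(net)[nodes]),
    betweenness = unname(bt[nodes]),
    closeness_raw = unname(cl[nodes]),
    closeness_norm = if (cmax > 0) unname(cl[nodes]) / cmax else 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a centrality report as TSV
#'
#' @param report data.frame from [centrality_report()]
#' @param path output file path
#' @param header_comment optional character vector of comment lines
#'   (written prefixed with `#`)
#' @return `path`, invisibly
#' @export
write_centrality_tsv <- function(report, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
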