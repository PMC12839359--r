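# Brute-force oracles kept deliberately independent of the package's
# BFS/Brandes code paths: distances via Floyd-Warshall on the adjacency
# matrix, path counts via the d(s,v) + d(v,t) = d(s,t) combinatorial
# identity.

adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    ia <- match(net$edges$id_a, net$nodes)
    ib <- match(net$edges$id_b, net$nodes)
    A[cbind(ia, ib)] <- 1L
    A[cbind(ib, ia)] <- 1L
  }
  A
}

brute_distances <- function(net) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      better <- nd < D[i, ]
      D[i, better] <- nd[better]
    }
  }
  D
}

# sigma[s, t] = number of shortest s-t paths, filled in order of distance
brute_sigma <- function(net, D = brute_distances(net)) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  S <- matrix(0, n, n)
  diag(S) <- 1
  maxd <- max(D[is.finite(D)])
  for (d in seq_len(max(maxd, 1))) {
    idx <- which(D == d, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      s <- idx[r, 1]; t <- idx[r, 2]
      pred <- which(A[, t] == 1L & D[s, ] == d - 1)
      S[s, t] <- sum(S[s, pred])
    }
  }
  dimnames(S) <- dimnames(A)
  S
}

brute_betweenness <- function(net) {
  D <- brute_distances(net)
  S <- brute_sigma(net, D)
  n <- nrow(D)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t <= s || !is.finite(D[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          cb[v] <- cb[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  names(cb) <- net$nodes
  cb
}

brute_summary <- function(net) {
  D <- brute_distances(net)
  n <- nrow(D)
  finite <- is.finite(D)
  # components: union of reachability rows
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- finite[i, ]
    sizes <- c(sizes, sum(comp))
    seen <- seen | comp
  }
  off <- finite & upper.tri(D)
  list(n_components = length(sizes),
       lcc_size = if (n) max(sizes) else 0L,
       avg_path_length = if (any(off)) mean(D[off]) else NA_real_)
}

brute_closeness <- function(net, v) {
  D <- brute_distances(net)
  d <- D[v, is.finite(D[v, ])]
  if (length(d) <= 1) return(0)
  (length(d) - 1) / sum(d)
}

# seeded Erdos-Renyi ppi_network over n nodes
random_net <- function(n, p, isolated_ok = TRUE) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  pick <- stats::runif(ncol(pairs)) < p
  ppi_network(data.frame(id_a = nodes[pairs[1, pick]],
                         id_b = nodes[pairs[2, pick]],
                         stringsAsFactors = FALSE),
              nodes = nodes, quiet = TRUE)
}

# random tree on n nodes: node i attaches to a random earlier node
random_tree <- function(n) {
  nodes <- sprintf("T%02d", seq_len(n))
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1))
  ppi_network(data.frame(id_a = nodes[parent], id_b = nodes[2:n],
                         stringsAsFactors = FALSE), quiet = TRUE)
}

path_net <- function(ids) {
  ppi_network(data.frame(id_a = ids[-length(ids)], id_b = ids[-1],
                         stringsAsFactors = FALSE), quiet = TRUE)
}

star_net <- function(center, leaves) {
  ppi_network(data.frame(id_a = center, id_b = leaves,
                         stringsAsFactors = FALSE), quiet = TRUE)
}

# 7-node barbell: two triangles joined through bridge node X
barbell_net <- function() {
  ppi_network(rbind(
    data.frame(id_a = c("A1", "A1", "A2"), id_b = c("A2", "A3", "A3")),
    data.frame(id_a = c("B1", "B1", "B2"), id_b = c("B2", "B3", "B3")),
    data.frame(id_a = c("X", "X"), id_b = c("A1", "B1"))
  ), quiet = TRUE)
}

# one PSI-MITAB 2.5 line with controllable taxon, score and type
mitab_line <- function(id_a, id_b, tax_a = "taxid:9606(human)",
                       tax_b = tax_a, score = 0.8,
                       type = "psi-mi:\"MI:0407\"(direct interaction)",
                       pub = "pubmed:12345",
                       confidence = sprintf("intact-miscore:%.2f", score)) {
  paste(sprintf("uniprotkb:%s", id_a), sprintf("uniprotkb:%s", id_b),
        "-", "-", "-", "-", "psi-mi:\"MI:0018\"(two hybrid)", "-", pub,
        tax_a, tax_b, type, "psi-mi:\"MI:0469\"(IntAct)", "-",
        confidence, sep = "\t")
}

mirna_row <- function(mirna, gene, method = "Luciferase reporter assay",
                      pmid, species = 9606L) {
  data.frame(mirna_id = admod::normalize_mirna_id(mirna),
             target_gene = gene, method = method,
             pmid = as.character(pmid), species = species,
             strong_evidence = FALSE, stringsAsFactors = FALSE)
}
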