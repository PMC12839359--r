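#' In silico depletion of one node
#'
#' Removes the node and its incident edges, recomputes the topology
#' summary, and reports deltas against the undepleted baseline, signed as
#' (after - before): a fragmenting knock-out shows a positive
#' `delta_components` and a negative `delta_lcc`. When either the baseline
#' or the depleted network has no connected pair, the corresponding
#' average path length is undefined and `delta_path` is `NA`.
#'
#' @param net a `ppi_network`
#' @param v node identifier to remove
#' @param baseline optional precomputed [topology_summary()] of `net`
#'   (recomputed when omitted; pass it when scanning many nodes)
#' @return one-row data.frame: `node`, `components_after`, `lcc_after`,
#'   `avg_path_after`, `delta_components`, `delta_lcc`, `delta_path`
#' @export
deplete_node <- function(net, v, baseline = NULL) {
  node_index(net, v)
  if (is.null(baseline)) baseline <- topology_summary(net)
  after <- topology_summary(remove_node(net, v))
  data.frame(
    node = v,
    components_after = after$n_components,
    lcc_after = after$lcc_size,
    avg_path_after = after$avg_path_length,
    delta_components = after$n_components - baseline$n_components,
    delta_lcc = after$lcc_size - baseline$lcc_size,
    delta_path = after$avg_path_length - baseline$avg_path_length,
    stringsAsFactors = FALSE
  )
}

#' Single-node depletion scan
#'
#' Depletes each listed node independently from the pristine baseline
#' (never cumulatively) and collects the per-node topology deltas.
#'
#' @param net a `ppi_network`
#' @param nodes node identifiers to scan (default: all nodes)
#' @return a list with `baseline` (the undepleted [topology_summary()])
#'   and `results` (data.frame of [deplete_node()] rows in the order
#'   given)
#' @export
depletion_scan <- function(net, nodes = NULL) {
  if (is.null(nodes)) nodes <- net$nodes
  missing <- setdiff(nodes, net$nodes)
  if (length(missing)) {
    stop("depletion_scan: unknown node(s): ", paste(missing, collapse = ", "))
  }
  baseline <- topology_summary(net)
  rows <- lapply(nodes, function(v) deplete_node(net, v, baseline))
  list(baseline = baseline, results = do.call(rbind, rows))
}

#' Rank nodes by fragmentation impact
#'
#' Orders depletion results by decreasing `delta_components`, breaking
#' ties by the most negative `delta_lcc` (a removal that detaches a whole
#' submodule outranks one that merely clips a short pendant chain), then
#' by node identifier for byte-stable output.
#'
#' @param results data.frame from [depletion_scan()]`$results`
#' @return the data.frame reordered, most disruptive first
#' @export
rank_fragmentation <- function(results) {
  ord <- order(-results$delta_components, results$delta_lcc, results$node)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Role-classification configuration
#'
#' Thresholds for [classify_roles()]. `top_fraction` is the fraction of
#' the assessed node universe counted as "top-ranked" for the bottleneck
#' tests; `peripheral_degree` is the maximum degree of a peripheral node.
#' All thresholds are echoed in the classification output.
#'
#' @param top_fraction fraction in (0, 1] (default 0.10)
#' @param peripheral_degree non-negative integer (default 3)
#' @return a list of class `role_config`
#' @export
role_config <- function(top_fraction = 0.10, peripheral_degree = 3L) {
  stopifnot(top_fraction > 0, top_fraction <= 1, peripheral_degree >= 0)
  structure(list(top_fraction = top_fraction,
                 peripheral_degree = as.integer(peripheral_degree)),
            class = "role_config")
}

#' Classify node roles from centrality and depletion evidence
#'
#' Rule-based assignment of exactly one label per node:
#' \describe{
#'   \item{peripheral}{degree <= `peripheral_degree` and closeness below
#'     the median over the assessed universe - the signature of a node on
#'     a peripheral branch, far from the network core.}
#'   \item{bottleneck}{(betweenness rank and degree rank both within the
#'     top `top_fraction`) or (the removal fragments the network,
#'     `delta_components > 0`, and the absolute path-length change ranks
#'     within the top `top_fraction`).}
#'   \item{local_hub}{everything else: well-embedded nodes whose loss
#'     neither fragments the network nor lengthens communication much.}
#' }
#' The peripheral test runs first: a pendant-chain node is an articulation
#' point and inherits all the traffic of its subtree, so its betweenness
#' and path impact can look bottleneck-like even though the branch it
#' guards is topologically marginal.
#'
#' @param centrality data.frame from [centrality_report()]
#' @param depletion data.frame from [depletion_scan()]`$results` over the
#'   same node universe
#' @param config a [role_config()]
#' @return data.frame `node`, `role`, plus the supporting ranks
#'   (`degree_rank`, `betweenness_rank`, `delta_path_rank`) and the
#'   thresholds used; attribute `config` carries the configuration.
#' @export
classify_roles <- function(centrality, depletion, config = role_config()) {
  if (!setequal(centrality$node, depletion$node)) {
    stop("classify_roles: centrality and depletion cover different node universes")
  }
  depletion <- depletion[match(centrality$node, depletion$node), , drop = FALSE]
  n <- nrow(centrality)
  k_top <- max(1L, ceiling(config$top_fraction * n))

  # rank 1 = largest; ties share the better (minimum) rank so a tied pair
  # straddling the cutoff is treated symmetrically
  rank_desc <- function(x) rank(-x, ties.method = "min", na.last = "keep")
  deg_rank <- rank_desc(centrality$degree)
  btw_rank <- rank_desc(centrality$betweenness)
  dpath <- abs(depletion$delta_path)
  dpath[is.na(dpath)] <- 0
  dpath_rank <- rank_desc(dpath)

  med_clo <- stats::median(centrality$closeness_raw)
  peripheral <- centrality$degree <= config$peripheral_degree &
    centrality$closeness_raw < med_clo
  bottleneck <- (deg_rank <= k_top & btw_rank <= k_top) |
    (depletion$delta_components > 0 & dpath_rank <= k_top)

  role <- ifelse(peripheral, "peripheral",
                 ifelse(bottleneck, "bottleneck", "local_hub"))
  out <- data.frame(
    node = centrality$node,
    role = role,
    degree_rank = deg_rank,
    betweenness_rank = btw_rank,
    delta_path_rank = dpath_rank,
    top_fraction = config$top_fraction,
    peripheral_degree = config$peripheral_degree,
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  out
}

#' Write a depletion scan as TSV
#'
#' Layout mirrors the published knock-out tables: a baseline row (node
#' `none`) followed by one row per depleted node with absolute values and
#' signed deltas.
#'
#' @param scan list from [depletion_scan()]
#' @param path output file path
#' @param header_comment optional comment lines (prefixed `#`)
#' @return `path`, invisibly
#' @export
write_depletion_tsv <- function(scan, path, header_comment = NULL) {
  base <- scan$baseline
  rows <- data.frame(
    node = c("none", scan$results$node),
    components = c(base$n_components, scan$results$components_after),
    lcc = c(base$lcc_size, scan$results$lcc_after),
    avg_path = c(base$avg_path_length, scan$results$avg_path_after),
    delta_components = c(NA, scan$results$delta_components),
    delta_lcc = c(NA, scan$results$delta_lcc),
    delta_path = c(NA, scan$results$delta_path),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
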