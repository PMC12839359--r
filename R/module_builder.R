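#' Build a seed-based disease module
#'
#' Retains, from each pre-filtered source, every interaction with at least
#' one seed endpoint (the first-neighbourhood rule: edges between two
#' non-seed neighbours are excluded), merges the survivors across sources
#' into one deduplicated network, and reports per-source and final
#' node/edge counts. Seeds with no surviving interaction stay in the
#' module as isolated nodes - they are the biological anchors of the
#' analysis - and a warning names them.
#'
#' @param sources named list of interaction-record data.frames, one per
#'   source database (already filtered by their per-database policies)
#' @param seeds character vector of seed accessions (normalized like all
#'   identifiers)
#' @return a list with `network` (a `ppi_network` carrying the logical
#'   node attribute `seed`) and `summary` (data.frame: source, n_nodes,
#'   n_edges, with a final deduplicated row)
#' @export
build_disease_module <- function(sources, seeds) {
  stopifnot(length(seeds) > 0)
  seeds <- normalize_accession(seeds)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- vapply(sources, function(r) {
      if (nrow(r)) r$source_db[1] else "unknown"
    }, character(1))
  }
  kept <- lapply(sources, function(rec) {
    rec[rec$id_a %in% seeds | rec$id_b %in% seeds, , drop = FALSE]
  })
  seen <- unique(unlist(lapply(kept, function(r) c(r$id_a, r$id_b))))
  absent <- setdiff(seeds, seen)
  if (length(absent) == length(seeds)) {
    stop("build_disease_module: no seed has any surviving interaction (",
         paste(seeds, collapse = ", "), ")")
  }
  if (length(absent)) {
    warning("build_disease_module: seed(s) with no surviving interaction kept as isolated nodes: ",
            paste(absent, collapse = ", "))
  }
  net <- merge_records(kept)
  if (length(absent)) {
    net <- ppi_network(net$edges, nodes = c(net$nodes, absent), quiet = TRUE)
  }
  flag <- net$nodes %in% seeds
  names(flag) <- net$nodes
  net <- set_node_attr(net, "seed", flag)

  per_source <- do.call(rbind, lapply(names(kept), function(s) {
    n <- merge_records(kept[s])
    data.frame(source = s, n_nodes = n_nodes(n), n_edges = n_edges(n),
               stringsAsFactors = FALSE)
  }))
  summary <- rbind(per_source,
                   data.frame(source = "merged (duplications deleted)",
                              n_nodes = n_nodes(net), n_edges = n_edges(net),
                              stringsAsFactors = FALSE))
  rownames(summary) <- NULL
  list(network = net, summary = summary)
}

#' Read a disease-gene association list
#'
#' TSV with a gene identifier column and an association-score column
#' (an Open Targets style export). Rows with an unparsable score are
#' skipped with a warning.
#'
#' @param path path to a tab-separated file with a header
#' @param columns mapping from fields to file column names
#' @return data.frame with columns `gene`, `score`
#' @export
read_disease_list <- function(path, columns = c(gene = "gene",
                                                score = "score")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(columns %in% names(df)))
  score <- suppressWarnings(as.numeric(df[[columns[["score"]]]]))
  bad <- is.na(score)
  if (any(bad)) {
    warning(sprintf("read_disease_list: %d row(s) with unparsable score skipped",
                    sum(bad)))
  }
  data.frame(gene = normalize_accession(df[[columns[["gene"]]]][!bad]),
             score = score[!bad], stringsAsFactors = FALSE)
}

#' Flag disease-associated genes in a network
#'
#' Sets the logical node attribute `disease` for every node present in
#' the disease list with an association score *strictly* above the
#' cutoff.
#'
#' @param net a `ppi_network`
#' @param disease_list data.frame with columns `gene`, `score` (see
#'   [read_disease_list()])
#' @param score_cutoff association-score cutoff (default 0.38; strict
#'   inequality, so a gene scoring exactly 0.38 is not flagged)
#' @return the network with node attribute `disease`; the number of
#'   flagged nodes is reported in attribute `n_flagged`
#' @export
annotate_disease_genes <- function(net, disease_list, score_cutoff = 0.38) {
  hits <- normalize_accession(disease_list$gene[disease_list$score > score_cutoff])
  flag <- net$nodes %in% hits
  names(flag) <- net$nodes
  net <- set_node_attr(net, "disease", flag)
  attr(net, "n_flagged") <- sum(flag)
  net
}

#' Write a module provenance summary as TSV
#'
#' Per-source node/edge counts plus the merged total, the layout of the
#' published source-breakdown table.
#'
#' @param summary data.frame from [build_disease_module()]`$summary`
#' @param path output file path
#' @param header_comment optional comment lines (prefixed `#`)
#' @return `path`, invisibly
#' @export
write_module_summary_tsv <- function(summary, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
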