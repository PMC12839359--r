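#' Normalize a mature miRNA name
#'
#' Lowercases and adds the `hsa-` species prefix when the name starts
#' with a bare `miR`/`let`/`lin` stem, so "miR-34a-5p" and
#' "hsa-miR-34a-5p" unify. Names already carrying another species prefix
#' are left alone (apart from case).
#'
#' @param x character vector of miRNA names
#' @return normalized names
#' @export
normalize_mirna_id <- function(x) {
  x <- tolower(trimws(x))
  bare <- grepl("^(mir|let|lin)", x)
  x[bare] <- paste0("hsa-", x[bare])
  x
}

#' Read a miRNA-target evidence table
#'
#' miRTarBase-like TSV with one row per supporting experiment: mature
#' miRNA name, target gene, assay method, publication id, species taxid.
#' An optional `strong_evidence` column (logical) marks rows curated as
#' strong even when the publication id is missing.
#'
#' @param path path to a tab-separated file with a header
#' @param columns mapping from fields to file column names
#' @return data.frame with columns `mirna_id` (normalized),
#'   `target_gene`, `method`, `pmid`, `species`, `strong_evidence`
#' @export
read_mirna_table <- function(path, columns = c(mirna = "mirna",
                                               gene = "gene",
                                               method = "method",
                                               pmid = "pmid",
                                               species = "species")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(columns %in% names(df)))
  out <- data.frame(
    mirna_id = normalize_mirna_id(df[[columns[["mirna"]]]]),
    target_gene = toupper(trimws(df[[columns[["gene"]]]])),
    method = df[[columns[["method"]]]],
    pmid = trimws(as.character(df[[columns[["pmid"]]]])),
    species = suppressWarnings(as.integer(df[[columns[["species"]]]])),
    stringsAsFactors = FALSE
  )
  out$strong_evidence <- if ("strong_evidence" %in% names(df)) {
    as.logical(df$strong_evidence)
  } else {
    FALSE
  }
  out
}

#' Filter miRNA-target evidence by assay method and publication support
#'
#' Keeps human (taxid 9606) miRNA-gene claims whose assay method matches
#' `method_label` (case-insensitive substring) in at least `min_papers`
#' *distinct* publications. Duplicate (miRNA, gene) rows - e.g. merged
#' source files - are pooled by publication-id union before thresholding.
#' Rows lacking a publication id but flagged `strong_evidence` count as
#' one paper. Per-gene `overrides` lower the threshold where a curator
#' decided the published support warrants it; overrides only ever relax
#' the default, never tighten it.
#'
#' @param records data.frame from [read_mirna_table()]
#' @param min_papers minimum distinct supporting publications (default 2)
#' @param method_label substring the assay method must contain
#'   (default "luciferase")
#' @param overrides named integer vector, gene symbol -> per-gene
#'   minimum paper count
#' @param taxid species restriction (default 9606)
#' @return data.frame with columns `mirna_id`, `target_gene`,
#'   `n_papers`, `pmids` (semicolon-joined)
#' @export
filter_mirna_evidence <- function(records, min_papers = 2L,
                                  method_label = "luciferase",
                                  overrides = NULL, taxid = 9606L) {
  hit <- records$species == taxid &
    grepl(tolower(method_label), tolower(records$method), fixed = TRUE)
  rec <- records[hit & !is.na(hit), , drop = FALSE]
  if (!nrow(rec)) {
    return(data.frame(mirna_id = character(), target_gene = character(),
                      n_papers = integer(), pmids = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(rec$mirna_id, rec$target_gene, sep = "\r")
  grp <- split(seq_len(nrow(rec)), key)
  rows <- lapply(grp, function(i) {
    pm <- unique(rec$pmid[i])
    pm <- pm[nzchar(pm) & pm != "-"]
    n <- length(pm)
    # undocumented-PMID rows curated as strong evidence count once
    if (any(rec$strong_evidence[i] & (!nzchar(rec$pmid[i]) | rec$pmid[i] == "-"))) {
      n <- n + 1L
    }
    data.frame(mirna_id = rec$mirna_id[i[1]],
               target_gene = rec$target_gene[i[1]],
               n_papers = n,
               pmids = paste(sort(pm), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- rep(as.integer(min_papers), nrow(out))
  if (!is.null(overrides)) {
    ov <- overrides[out$target_gene]
    use <- !is.na(ov)
    thr[use] <- pmin(thr[use], as.integer(ov[use]))
  }
  out <- out[out$n_papers >= thr, , drop = FALSE]
  out <- out[order(out$target_gene, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach a miRNA regulatory layer to a disease module
#'
#' Keeps only evidence records whose target maps onto a module node -
#' either directly (the target is already a node identifier) or through
#' the supplied gene-symbol/accession mapping table - and summarises the
#' bipartite layer: which nodes are regulated, by how many miRNAs, and
#' which miRNAs hit several module nodes at once (the multi-target
#' property that makes a mimic potent). Unmappable targets are logged
#' and skipped, never fatal.
#'
#' @param net the disease-module `ppi_network`
#' @param records filtered evidence from [filter_mirna_evidence()]
#' @param mapping data.frame with columns `symbol`, `accession`
#' @return a list of class `regulatory_layer`: `edges` (data.frame
#'   `mirna_id`, `node`, `gene_symbol`), `regulated_fraction`,
#'   `per_mirna_targets` and `per_node_regulators` (named counts),
#'   `n_module_nodes`
#' @export
attach_regulators <- function(net, records, mapping = NULL) {
  sym2acc <- character(0)
  if (!is.null(mapping)) {
    stopifnot(all(c("symbol", "accession") %in% names(mapping)))
    sym2acc <- stats::setNames(normalize_accession(mapping$accession),
                               toupper(trimws(mapping$symbol)))
  }
  node <- ifelse(records$target_gene %in% net$nodes,
                 records$target_gene,
                 unname(sym2acc[records$target_gene]))
  unmapped <- is.na(node)
  if (any(unmapped)) {
    message(sprintf("attach_regulators: %d record(s) with unmappable target skipped (%s)",
                    sum(unmapped),
                    paste(unique(records$target_gene[unmapped]), collapse = ", ")))
  }
  keep <- !unmapped & node %in% net$nodes
  edges <- data.frame(mirna_id = records$mirna_id[keep],
                      node = node[keep],
                      gene_symbol = records$target_gene[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$node, edges$mirna_id), , drop = FALSE]
  rownames(edges) <- NULL
  per_node <- table(factor(edges$node, levels = net$nodes))
  layer <- list(
    edges = edges,
    regulated_fraction = if (length(net$nodes)) {
      sum(per_node > 0) / length(net$nodes)
    } else 0,
    per_mirna_targets = sort(table(edges$mirna_id), decreasing = TRUE),
    per_node_regulators = per_node[per_node > 0],
    n_module_nodes = length(net$nodes)
  )
  class(layer) <- "regulatory_layer"
  layer
}

#' @export
print.regulatory_layer <- function(x, ...) {
  cat(sprintf("regulatory_layer: %d miRNA->node edges, %d/%d module nodes regulated (%.1f%%)\n",
              nrow(x$edges), length(x$per_node_regulators),
              x$n_module_nodes, 100 * x$regulated_fraction))
  multi <- x$per_mirna_targets[x$per_mirna_targets >= 2]
  if (length(multi)) {
    cat("multi-target miRNAs:",
        paste(sprintf("%s (%d)", names(multi), multi), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Overlap contingency table for two miRNA sets
#'
#' Builds the 2x2 table (in both sets / layer only / literature only /
#' neither) over a stated background of mature miRNAs, ready for
#' [fisher_exact()]. Both sets are name-normalized first.
#'
#' @param layer_mirnas miRNA names found in the regulatory layer
#' @param literature_mirnas miRNA names from the literature survey
#' @param background_n total background count; must be at least the size
#'   of the union of the two sets
#' @return a `contingency_table`
#' @export
overlap_enrichment <- function(layer_mirnas, literature_mirnas, background_n) {
  s1 <- unique(normalize_mirna_id(layer_mirnas))
  s2 <- unique(normalize_mirna_id(literature_mirnas))
  u <- length(union(s1, s2))
  if (background_n < u) {
    stop(sprintf("background (%d) smaller than the union of the two sets (%d)",
                 background_n, u))
  }
  a <- length(intersect(s1, s2))
  contingency_table(a, length(s1) - a, length(s2) - a, background_n - u)
}

#' Write a regulator table as TSV
#'
#' One row per regulated gene with its semicolon-joined, sorted miRNA
#' list - the layout of the published module-regulator table.
#'
#' @param layer a `regulatory_layer` from [attach_regulators()]
#' @param path output file path
#' @param header_comment optional comment lines (prefixed `#`)
#' @return `path`, invisibly
#' @export
write_regulator_tsv <- function(layer, path, header_comment = NULL) {
  by_gene <- split(layer$edges$mirna_id, layer$edges$gene_symbol)
  rows <- data.frame(
    gene = names(by_gene),
    mirnas = vapply(by_gene, function(m) paste(sort(unique(m)), collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$gene), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export module plus regulatory layer as a bipartite GraphML overlay
#'
#' Protein-protein edges keep their provenance; miRNA nodes enter as a
#' second partition with `node_type = "mirna"` (rendered as diamonds in
#' the usual visualisations) linked to the module nodes they regulate.
#'
#' @param net the disease-module `ppi_network`
#' @param layer a `regulatory_layer`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_layer_graphml <- function(net, layer, path) {
  bip_edges <- data.frame(id_a = layer$edges$mirna_id,
                          id_b = layer$edges$node,
                          provenance = "mirna_evidence",
                          stringsAsFactors = FALSE)
  all_edges <- rbind(net$edges, bip_edges)
  g <- ppi_network(all_edges, nodes = net$nodes, quiet = TRUE)
  typ <- ifelse(g$nodes %in% unique(layer$edges$mirna_id), "mirna", "protein")
  names(typ) <- g$nodes
  g <- set_node_attr(g, "node_type", typ)
  for (a in names(net$node_attrs)) {
    v <- net$node_attrs[[a]]
    names(v) <- rownames(net$node_attrs)
    g <- set_node_attr(g, a, v)
  }
  write_graphml(g, path)
}
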