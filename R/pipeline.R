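#' Load and validate a pipeline run configuration
#'
#' The whole analysis is driven by one declarative YAML file so the
#' thresholds behind a result are archived with it. Recognised blocks:
#' \describe{
#'   \item{out_dir}{output directory (created if absent).}
#'   \item{rng_seed}{integer seed for the synthetic generator.}
#'   \item{sources}{named blocks `intact`, `string`, `biogrid`, each with
#'     a `path` and optional policy overrides (`min_mi_score`,
#'     `string_min_score`, `min_publications`, `allowed_types`, `taxid`).}
#'   \item{seeds}{seed-protein accessions for module construction.}
#'   \item{mirna}{`evidence`, `mapping`, optional `min_papers`,
#'     `overrides` (gene: count), `literature` (TSV of miRNA names),
#'     `background_n`.}
#'   \item{disease}{`path`, optional `score_cutoff`, `background_n`.}
#'   \item{depletion_nodes}{node list to scan, or `all`.}
#'   \item{roles}{optional `top_fraction`, `peripheral_degree`.}
#' }
#'
#' @param path path to a YAML file
#' @return a list of class `run_config`; `$config_hash` is the MD5 of the
#'   file, echoed into every report header for provenance
#' @export
run_config <- function(path) {
  if (!file.exists(path)) stop("run_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_hash <- unname(tools::md5sum(path))
  cfg$config_path <- path
  if (is.null(cfg$out_dir)) stop("run_config: out_dir is required")
  for (src in names(cfg$sources)) {
    p <- cfg$sources[[src]]$path
    if (is.null(p) || !file.exists(p)) {
      stop("run_config: sources$", src, " path missing or does not exist: ", p)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

report_header <- function(cfg, what) {
  c(sprintf("%s | admod %s | config %s", what,
            as.character(utils::packageVersion("admod")),
            if (is.null(cfg$config_hash)) "-" else cfg$config_hash))
}

source_policy <- function(cfg, src) {
  blk <- cfg$sources[[src]]
  pol <- filter_policy()
  for (f in intersect(names(blk), c("taxid", "min_mi_score", "allowed_types",
                                    "min_publications",
                                    "require_low_throughput",
                                    "string_min_score"))) {
    pol[[f]] <- blk[[f]]
  }
  pol
}

#' Build the disease module from configured sources
#'
#' Reads every configured interaction source with its per-database
#' policy, keeps seed-incident records, merges them, and writes the
#' module as GraphML, the edge list as TSV, and the per-source
#' provenance summary. If a `disease` block is configured the module
#' nodes are flagged against the disease-gene list and the enrichment
#' test is run and written alongside.
#'
#' @param cfg a [run_config()]
#' @return invisibly, the [build_disease_module()] result (plus
#'   `enrichment` when computed)
#' @export
run_build_module <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  readers <- list(intact = read_mitab, string = read_string_table,
                  biogrid = read_biogrid_table)
  sources <- list()
  for (src in names(cfg$sources)) {
    reader <- readers[[src]]
    if (is.null(reader)) stop("run_build_module: unknown source kind: ", src)
    sources[[src]] <- reader(cfg$sources[[src]]$path, source_policy(cfg, src))
    message(sprintf("run_build_module: %s -> %d filtered record(s)",
                    src, nrow(sources[[src]])))
  }
  if (is.null(cfg$seeds)) stop("run_build_module: seeds are required")
  mod <- build_disease_module(sources, unlist(cfg$seeds))
  net <- mod$network

  if (!is.null(cfg$disease)) {
    cutoff <- if (is.null(cfg$disease$score_cutoff)) 0.38 else cfg$disease$score_cutoff
    dl <- read_disease_list(cfg$disease$path)
    net <- annotate_disease_genes(net, dl, cutoff)
    k <- sum(net$node_attrs$disease)
    disease_n <- sum(dl$score > cutoff)
    bg <- cfg$disease$background_n
    if (!is.null(bg)) {
      tab <- contingency_from_counts(n_nodes(net), k, disease_n, bg)
      fe <- fisher_exact(tab)
      mod$enrichment <- fe
      write_enrichment_tsv(
        data.frame(dataset = "disease module", n = n_nodes(net), overlap = k,
                   disease_n = disease_n, background = bg,
                   odds_ratio = fe$odds_ratio_cmle, p = fe$p_label),
        file.path(cfg$out_dir, "enrichment.tsv"),
        report_header(cfg, "disease-gene enrichment"))
    }
    mod$network <- net
  }
  write_graphml(net, file.path(cfg$out_dir, "module.graphml"))
  write_edges_tsv(net, file.path(cfg$out_dir, "module_edges.tsv"),
                  report_header(cfg, "module edge list"))
  write_module_summary_tsv(mod$summary,
                           file.path(cfg$out_dir, "module_summary.tsv"),
                           report_header(cfg, "module provenance summary"))
  invisible(mod)
}

#' Overlay the miRNA regulatory layer
#'
#' Reads the configured evidence table, applies the luciferase /
#' distinct-paper filter (with per-gene overrides), attaches survivors to
#' the module, and writes the regulator table and the bipartite GraphML
#' overlay. With a configured literature miRNA list and background, the
#' layer-vs-literature overlap enrichment is written too.
#'
#' @param cfg a [run_config()]
#' @param net the module `ppi_network` (from [run_build_module()]); when
#'   `NULL` the module edge list written by the build step is reloaded
#' @return invisibly, the `regulatory_layer`
#' @export
run_mirna <- function(cfg, net = NULL) {
  if (is.null(cfg$mirna)) stop("run_mirna: no mirna block configured")
  if (is.null(net)) {
    edges <- utils::read.delim(file.path(cfg$out_dir, "module_edges.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE)
    net <- ppi_network(edges, quiet = TRUE)
  }
  rec <- read_mirna_table(cfg$mirna$evidence)
  min_papers <- if (is.null(cfg$mirna$min_papers)) 2L else cfg$mirna$min_papers
  overrides <- NULL
  if (!is.null(cfg$mirna$overrides)) {
    overrides <- unlist(cfg$mirna$overrides)
  }
  surv <- filter_mirna_evidence(rec, min_papers = min_papers,
                                overrides = overrides)
  if (!nrow(surv)) warning("run_mirna: no evidence record survives the filter")
  mapping <- if (is.null(cfg$mirna$mapping)) NULL else
    utils::read.delim(cfg$mirna$mapping, stringsAsFactors = FALSE)
  layer <- attach_regulators(net, surv, mapping)
  write_regulator_tsv(layer, file.path(cfg$out_dir, "module_regulators.tsv"),
                      report_header(cfg, "module regulator table"))
  write_layer_graphml(net, layer, file.path(cfg$out_dir, "module_layer.graphml"))

  if (!is.null(cfg$mirna$literature) && !is.null(cfg$mirna$background_n)) {
    lit <- utils::read.delim(cfg$mirna$literature, stringsAsFactors = FALSE)
    tab <- overlap_enrichment(unique(layer$edges$mirna_id), lit[[1]],
                              cfg$mirna$background_n)
    fe <- fisher_exact(tab)
    write_enrichment_tsv(
      data.frame(dataset = "layer vs literature miRNAs",
                 n = tab$a + tab$b, overlap = tab$a,
                 disease_n = tab$a + tab$c,
                 background = cfg$mirna$background_n,
                 odds_ratio = fe$odds_ratio_cmle, p = fe$p_label),
      file.path(cfg$out_dir, "mirna_enrichment.tsv"),
      report_header(cfg, "miRNA overlap enrichment"))
  }
  invisible(layer)
}

#' Centrality, depletion and role analysis
#'
#' Computes the centrality report, runs the single-node depletion scan
#' over the configured node list (default: every node), classifies node
#' roles, and writes the three report TSVs.
#'
#' @param cfg a [run_config()]
#' @param net the `ppi_network` to analyze; when `NULL` the module edge
#'   list written by the build step is reloaded
#' @return invisibly, a list: `centrality`, `scan`, `roles`
#' @export
run_analyze <- function(cfg, net = NULL) {
  if (is.null(net)) {
    edges <- utils::read.delim(file.path(cfg$out_dir, "module_edges.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE)
    net <- ppi_network(edges, quiet = TRUE)
  }
  nodes <- cfg$depletion_nodes
  if (is.null(nodes) || identical(nodes, "all")) nodes <- net$nodes
  nodes <- unlist(nodes)
  cent <- centrality_report(net, nodes)
  scan <- depletion_scan(net, nodes)
  rc <- role_config()
  if (!is.null(cfg$roles$top_fraction)) rc$top_fraction <- cfg$roles$top_fraction
  if (!is.null(cfg$roles$peripheral_degree)) {
    rc$peripheral_degree <- as.integer(cfg$roles$peripheral_degree)
  }
  roles <- classify_roles(cent, scan$results, rc)
  write_centrality_tsv(cent, file.path(cfg$out_dir, "centrality.tsv"),
                       report_header(cfg, "centrality report"))
  write_depletion_tsv(scan, file.path(cfg$out_dir, "depletion.tsv"),
                      report_header(cfg, "single-node depletion scan"))
  write_centrality_tsv(roles, file.path(cfg$out_dir, "roles.tsv"),
                       report_header(cfg, "node role classification"))
  invisible(list(centrality = cent, scan = scan, roles = roles))
}

#' Generate the full synthetic input bundle
#'
#' Writes a complete, self-consistent set of pipeline inputs (MITAB
#' interactome, miRNA evidence and mapping tables, disease-gene list)
#' under `cfg$out_dir/synthetic/`, driven by `cfg$rng_seed`, together
#' with a `ground_truth.json` sidecar. Regeneration under the same seed
#' is byte-identical.
#'
#' @param cfg a [run_config()] (only `out_dir` and `rng_seed` are used,
#'   plus an optional `synthetic` block forwarded to [synthetic_spec()])
#' @return invisibly, a list of the generator ground truths and paths
#' @export
run_simulate <- function(cfg) {
  if (is.null(cfg$rng_seed)) stop("run_simulate: rng_seed is required")
  dir <- file.path(cfg$out_dir, "synthetic")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  args <- if (is.null(cfg$synthetic)) list() else cfg$synthetic
  args$rng_seed <- cfg$rng_seed
  spec <- do.call(synthetic_spec, args)

  inter <- generate_interactome(spec, file.path(dir, "interactome.mitab"))
  module_nodes <- sort(unique(unlist(inter$truth$modules)))
  mir <- generate_mirna_table(spec, module_nodes,
                              file.path(dir, "mirna_evidence.tsv"),
                              file.path(dir, "mirna_mapping.tsv"))
  dis <- generate_disease_list(module_nodes,
                               background_n = 2000L, disease_n = 40L,
                               planted_or = spec$planted_or,
                               rng_seed = child_seed(spec$rng_seed, 3L),
                               path = file.path(dir, "disease_genes.tsv"))
  truth <- list(interactome = inter$truth, mirna = mir$truth,
                disease = dis$truth)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(spec = spec, truth = truth,
                 paths = list(interactome = inter$path,
                              mirna = mir$path, mapping = mir$mapping_path,
                              disease = dis$path)))
}
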