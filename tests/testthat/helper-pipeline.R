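# Shared scaffolding for end-to-end runs over a synthetic bundle:
# simulate -> build-module -> mirna -> analyze, driven by one YAML config.

make_pipeline_config <- function(dir, seed = 77) {
  cfg0 <- list(out_dir = dir, rng_seed = seed)
  class(cfg0) <- "run_config"
  sim <- run_simulate(cfg0)
  truth <- sim$truth
  seeds <- sort(c(unlist(truth$interactome$modules),
                  truth$interactome$bridges,
                  unlist(truth$interactome$chains)))
  # literature miRNA list overlapping the planted survivors
  lit <- file.path(dir, "literature_mirnas.tsv")
  surv_mirnas <- unique(truth$mirna$survivors$mirna_id)
  writeLines(c("mirna", utils::head(surv_mirnas, 3), "hsa-mir-9999-5p"), lit)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    out_dir = dir,
    rng_seed = seed,
    sources = list(intact = list(path = file.path(dir, "synthetic", "interactome.mitab"),
                                 min_mi_score = 0.65)),
    seeds = as.list(seeds),
    mirna = list(evidence = file.path(dir, "synthetic", "mirna_evidence.tsv"),
                 mapping = file.path(dir, "synthetic", "mirna_mapping.tsv"),
                 min_papers = 2,
                 literature = lit,
                 background_n = 500),
    disease = list(path = file.path(dir, "synthetic", "disease_genes.tsv"),
                   score_cutoff = 0.38,
                   background_n = 2000),
    depletion_nodes = "all"
  ), cfg_path)
  list(config = run_config(cfg_path), truth = truth)
}

run_all_steps <- function(cfg) {
  mod <- suppressMessages(run_build_module(cfg))
  layer <- run_mirna(cfg, mod$network)
  ana <- run_analyze(cfg, mod$network)
  list(mod = mod, layer = layer, ana = ana)
}

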