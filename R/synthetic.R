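#' Specification for the synthetic interactome generator
#'
#' Describes a planted-topology benchmark: dense within-module
#' communities joined by dedicated bridge nodes (the only inter-module
#' connectors that survive confidence filtering), pendant chains hanging
#' off the first module (peripheral branches), low-confidence inter-module
#' noise edges, non-target-species contaminant rows, and a handful of
#' rows with a non-qualifying interaction type. Signal and noise
#' confidence scores are drawn from disjoint ranges straddling the usual
#' MI-score cutoffs, so a 0.65 threshold recovers exactly the planted
#' signal edges while relaxing the cutoff lets noise in.
#'
#' @param n_modules number of dense modules
#' @param module_sizes integer vector of module sizes (recycled to
#'   `n_modules`)
#' @param p_intra within-module edge probability
#' @param n_bridges number of bridge nodes; bridge i joins modules i and
#'   i + 1, attached to `bridge_stubs` nodes on each side
#' @param bridge_stubs attachments per module side of each bridge (2 keeps
#'   single module nodes from becoming articulation points themselves)
#' @param pendant_chain_lengths lengths of pendant chains attached to
#'   module 1
#' @param signal_score_range,noise_score_range MI-score ranges for planted
#'   and noise edges
#' @param n_noise_edges number of low-confidence inter-module noise edges
#' @param n_offtype_edges rows with a non-qualifying interaction type
#'   ("colocalization") at signal-level scores
#' @param contaminant_taxa_fraction fraction of extra rows from a
#'   non-target species (mouse, taxid 10090)
#' @param seed_proteins designated hub accessions used as disease-module
#'   seeds; `NULL` picks the lexicographically first node of each module
#' @param mirna_plan list: `n_heavy` (nodes regulated by many miRNAs),
#'   `heavy_range` (regulator count range for those),
#'   `p_regulated` (probability an ordinary node has any regulator),
#'   `luciferase_fraction` (fraction of claims assayed by luciferase
#'   reporter), `multi_target_mirna` (name of a planted miRNA given
#'   `multi_target_n` module targets)
#' @param planted_or true enrichment odds ratio planted in the disease
#'   list
#' @param rng_seed integer seed; mandatory - every draw is reproducible
#' @return a list of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_modules = 3L,
                           module_sizes = 8L,
                           p_intra = 0.8,
                           n_bridges = 2L,
                           bridge_stubs = 2L,
                           pendant_chain_lengths = 3L,
                           signal_score_range = c(0.70, 0.95),
                           noise_score_range = c(0.30, 0.62),
                           n_noise_edges = 10L,
                           n_offtype_edges = 3L,
                           contaminant_taxa_fraction = 0.10,
                           seed_proteins = NULL,
                           mirna_plan = list(n_heavy = 3L,
                                             heavy_range = c(4L, 7L),
                                             p_regulated = 0.15,
                                             luciferase_fraction = 0.6,
                                             multi_target_mirna = "hsa-mir-34a-5p",
                                             multi_target_n = 4L),
                           planted_or = 15,
                           rng_seed = NULL) {
  if (is.null(rng_seed)) stop("synthetic_spec: rng_seed is mandatory")
  module_sizes <- rep_len(as.integer(module_sizes), n_modules)
  stopifnot(p_intra > 0, p_intra <= 1, all(module_sizes >= 3),
            n_bridges <= n_modules - 1 || n_modules == 1,
            contaminant_taxa_fraction >= 0, contaminant_taxa_fraction <= 1,
            planted_or > 0)
  structure(list(n_modules = as.integer(n_modules),
                 module_sizes = module_sizes,
                 p_intra = p_intra,
                 n_bridges = as.integer(n_bridges),
                 bridge_stubs = as.integer(bridge_stubs),
                 pendant_chain_lengths = as.integer(pendant_chain_lengths),
                 signal_score_range = signal_score_range,
                 noise_score_range = noise_score_range,
                 n_noise_edges = as.integer(n_noise_edges),
                 n_offtype_edges = as.integer(n_offtype_edges),
                 contaminant_taxa_fraction = contaminant_taxa_fraction,
                 seed_proteins = seed_proteins,
                 mirna_plan = mirna_plan,
                 planted_or = planted_or,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

# evaluate `code` under a local RNG state derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic child seed so each sub-generator owns an independent
# stream and adding one never perturbs the draws of another
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

syn_module_nodes <- function(spec) {
  lapply(seq_len(spec$n_modules), function(m) {
    sprintf("P%02d%03d", m, seq_len(spec$module_sizes[m]))
  })
}

# Erdos-Renyi edges among `nodes`, resampled until connected
syn_connected_er <- function(nodes, p, retries = 50L) {
  n <- length(nodes)
  pairs <- utils::combn(n, 2)
  for (try in seq_len(retries)) {
    pick <- stats::runif(ncol(pairs)) < p
    e <- data.frame(id_a = nodes[pairs[1, pick]], id_b = nodes[pairs[2, pick]],
                    stringsAsFactors = FALSE)
    g <- ppi_network(e, nodes = nodes, quiet = TRUE)
    if (length(connected_components(g)$sizes) == 1) return(e)
    warning(sprintf("synthetic module of size %d disconnected at p=%.2f, resampling (%d/%d)",
                    n, p, try, retries))
  }
  stop("synthetic module generation failed: p_intra too small for module size")
}

#' Generate a synthetic interactome as PSI-MITAB 2.5
#'
#' Emits a MITAB 2.5 file realising the planted topology of a
#' [synthetic_spec()], in shuffled row order, plus the ground truth
#' needed to verify every downstream stage. Signal rows (module, bridge
#' and chain edges) carry high `intact-miscore` values and qualifying
#' interaction types; noise rows carry low scores; off-type rows carry a
#' "colocalization" term; contaminant rows carry mouse taxon ids.
#'
#' @param spec a [synthetic_spec()]
#' @param path output file path for the MITAB stream
#' @return invisibly, a list: `path`, and `truth` with `modules` (list of
#'   node vectors), `bridges`, `chains` (list of chain-node vectors),
#'   `chain_nodes`, `seed_proteins`, `signal_edges` / `noise_edges`
#'   (data.frames `id_a`, `id_b`), `n_rows`
#' @export
generate_interactome <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- with_seed(child_seed(spec$rng_seed, 1L), {
    modules <- syn_module_nodes(spec)
    signal <- list()
    for (m in seq_len(spec$n_modules)) {
      signal[[length(signal) + 1L]] <- syn_connected_er(modules[[m]], spec$p_intra)
    }
    bridges <- character(0)
    if (spec$n_bridges > 0 && spec$n_modules > 1) {
      for (i in seq_len(spec$n_bridges)) {
        b <- sprintf("B%02d001", i)
        bridges <- c(bridges, b)
        left <- sample(modules[[i]], spec$bridge_stubs)
        right <- sample(modules[[i + 1L]], spec$bridge_stubs)
        signal[[length(signal) + 1L]] <- data.frame(
          id_a = b, id_b = c(left, right), stringsAsFactors = FALSE)
      }
    }
    chains <- list()
    for (ci in seq_along(spec$pendant_chain_lengths)) {
      len <- spec$pendant_chain_lengths[ci]
      if (len < 1) next
      cn <- sprintf("C%02d%03d", ci, seq_len(len))
      anchor <- sample(modules[[1L]], 1)
      signal[[length(signal) + 1L]] <- data.frame(
        id_a = c(anchor, cn[-len]), id_b = cn, stringsAsFactors = FALSE)
      chains[[ci]] <- cn
    }
    signal <- do.call(rbind, signal)
    # canonical order + dedup (two modules could not collide, but ER
    # sampling may re-pick a bridge stub pair)
    swap <- signal$id_a > signal$id_b
    tmp <- signal$id_a[swap]; signal$id_a[swap] <- signal$id_b[swap]
    signal$id_b[swap] <- tmp
    signal <- unique(signal)

    all_nodes <- c(unlist(modules), bridges, unlist(chains))
    # low-confidence inter-module noise, never duplicating a signal pair
    noise <- data.frame(id_a = character(), id_b = character(),
                        stringsAsFactors = FALSE)
    sig_key <- paste(signal$id_a, signal$id_b)
    guard <- 0L
    while (nrow(noise) < spec$n_noise_edges && guard < 1000L) {
      guard <- guard + 1L
      ms <- sample(spec$n_modules, 2)
      u <- sample(modules[[ms[1]]], 1); v <- sample(modules[[ms[2]]], 1)
      if (u > v) { t <- u; u <- v; v <- t }
      if (paste(u, v) %in% c(sig_key, paste(noise$id_a, noise$id_b))) next
      noise <- rbind(noise, data.frame(id_a = u, id_b = v,
                                       stringsAsFactors = FALSE))
    }
    offtype <- noise[0, ]
    guard <- 0L
    while (nrow(offtype) < spec$n_offtype_edges && guard < 1000L) {
      guard <- guard + 1L
      uv <- sort(sample(all_nodes, 2))
      if (paste(uv[1], uv[2]) %in% sig_key) next
      offtype <- rbind(offtype, data.frame(id_a = uv[1], id_b = uv[2],
                                           stringsAsFactors = FALSE))
    }

    seeds <- spec$seed_proteins
    if (is.null(seeds)) seeds <- vapply(modules, min, character(1))

    rows <- c(
      mitab_rows(signal, stats::runif(nrow(signal),
                                      spec$signal_score_range[1],
                                      spec$signal_score_range[2]),
                 taxid = 9606L, type = "signal"),
      mitab_rows(noise, stats::runif(nrow(noise),
                                     spec$noise_score_range[1],
                                     spec$noise_score_range[2]),
                 taxid = 9606L, type = "signal"),
      mitab_rows(offtype, stats::runif(nrow(offtype),
                                       spec$signal_score_range[1],
                                       spec$signal_score_range[2]),
                 taxid = 9606L, type = "colocalization")
    )
    n_contam <- round(spec$contaminant_taxa_fraction * length(rows))
    if (n_contam > 0) {
      ce <- data.frame(id_a = sprintf("Q%05d", seq_len(n_contam)),
                       id_b = sprintf("Q%05d", seq_len(n_contam) + 500L),
                       stringsAsFactors = FALSE)
      rows <- c(rows, mitab_rows(ce, stats::runif(n_contam,
                                                  spec$signal_score_range[1],
                                                  spec$signal_score_range[2]),
                                 taxid = 10090L, type = "signal"))
    }
    rows <- sample(rows)
    writeLines(rows, path)
    list(modules = modules, bridges = bridges, chains = chains,
         chain_nodes = unlist(chains), seed_proteins = seeds,
         signal_edges = signal[order(signal$id_a, signal$id_b), ],
         noise_edges = noise, n_rows = length(rows))
  })
  invisible(list(path = path, truth = truth))
}

# format MITAB 2.5 rows (15 tab-separated columns)
mitab_rows <- function(edges, scores, taxid, type) {
  if (!nrow(edges)) return(character(0))
  organism <- if (taxid == 9606L) "taxid:9606(human)" else
    sprintf("taxid:%d(mouse)", taxid)
  itype <- switch(type,
    signal = ifelse(stats::runif(nrow(edges)) < 0.5,
                    "psi-mi:\"MI:0407\"(direct interaction)",
                    "psi-mi:\"MI:0915\"(physical association)"),
    colocalization = rep("psi-mi:\"MI:0403\"(colocalization)", nrow(edges)))
  pub <- sprintf("pubmed:%d", sample(10000000:39999999, nrow(edges),
                                     replace = TRUE))
  sprintf(paste(
    "uniprotkb:%s", "uniprotkb:%s", "-", "-",
    "psi-mi:%s(gene name)", "psi-mi:%s(gene name)",
    "psi-mi:\"MI:0018\"(two hybrid)", "-", "%s",
    "%s", "%s", "%s", "psi-mi:\"MI:0469\"(IntAct)", "-",
    "intact-miscore:%.4f", sep = "\t"),
    edges$id_a, edges$id_b, edges$id_a, edges$id_b, pub,
    organism, organism, itype, scores)
}

#' Generate a synthetic miRNA-target evidence table
#'
#' Emulates the skewed regulator distribution seen in curated disease
#' modules: a few heavily regulated nodes, a minority of nodes with one
#' or two regulators, most with none, and one planted multi-target miRNA
#' hitting several module nodes. Assay methods mix luciferase reporter
#' assays with non-qualifying methods, and publication counts straddle
#' the two-paper threshold, so the evidence filter has real work to do.
#' Targets are written as gene symbols with a companion
#' symbol-to-accession mapping table.
#'
#' @param spec a [synthetic_spec()]
#' @param module_nodes accessions of the module the miRNAs act on
#' @param path output path for the evidence TSV
#' @param mapping_path output path for the symbol/accession mapping TSV
#' @return invisibly, a list: `path`, `mapping_path`, `truth` with
#'   `survivors` (data.frame `mirna_id`, `node`: the records that pass a
#'   luciferase >= 2 distinct-paper filter) and `regulated_nodes`
#' @export
generate_mirna_table <- function(spec, module_nodes, path,
                                 mapping_path = file.path(dirname(path),
                                                          "mirna_mapping.tsv")) {
  stopifnot(length(module_nodes) > 0)
  plan <- spec$mirna_plan
  res <- with_seed(child_seed(spec$rng_seed, 2L), {
    symbol <- paste0("G", module_nodes)
    names(symbol) <- module_nodes
    pool <- sprintf("hsa-mir-%d-5p", 100 + seq_len(3 * length(module_nodes)))

    n_heavy <- min(plan$n_heavy, length(module_nodes))
    heavy <- sample(module_nodes, n_heavy)
    n_reg <- stats::setNames(integer(length(module_nodes)), module_nodes)
    n_reg[heavy] <- sample(plan$heavy_range[1]:plan$heavy_range[2],
                           n_heavy, replace = TRUE)
    rest <- setdiff(module_nodes, heavy)
    light <- rest[stats::runif(length(rest)) < plan$p_regulated]
    n_reg[light] <- sample(1:2, length(light), replace = TRUE)

    claims <- list()
    used <- 0L
    for (node in names(n_reg)[n_reg > 0]) {
      k <- n_reg[[node]]
      claims[[node]] <- data.frame(mirna_id = pool[used + seq_len(k)],
                                   node = node, stringsAsFactors = FALSE)
      used <- used + k
    }
    claims <- do.call(rbind, c(claims, list(data.frame(
      mirna_id = character(), node = character(), stringsAsFactors = FALSE))))
    # planted multi-target miRNA
    mt_targets <- sample(module_nodes, min(plan$multi_target_n,
                                           length(module_nodes)))
    claims <- rbind(claims, data.frame(mirna_id = plan$multi_target_mirna,
                                       node = mt_targets,
                                       stringsAsFactors = FALSE))
    claims <- unique(claims)

    lucif <- stats::runif(nrow(claims)) < plan$luciferase_fraction
    lucif[claims$mirna_id == plan$multi_target_mirna] <- TRUE
    n_pap <- ifelse(lucif, sample(1:3, nrow(claims), replace = TRUE), 1L)
    n_pap[claims$mirna_id == plan$multi_target_mirna] <- 2L
    survivors <- claims[lucif & n_pap >= 2, , drop = FALSE]

    rows <- list()
    for (i in seq_len(nrow(claims))) {
      method <- if (lucif[i]) "Luciferase reporter assay" else
        sample(c("Western blot", "qRT-PCR", "Microarray"), 1)
      pmids <- sample(10000000:39999999, n_pap[i])
      rows[[i]] <- data.frame(
        mirna = claims$mirna_id[i],
        gene = symbol[[claims$node[i]]],
        method = method,
        pmid = pmids,
        species = 9606L,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    # contaminant species rows (filtered out downstream)
    tab <- rbind(tab, data.frame(mirna = "mmu-mir-1-3p", gene = symbol[[1]],
                                 method = "Luciferase reporter assay",
                                 pmid = sample(10000000:39999999, 2),
                                 species = 10090L, stringsAsFactors = FALSE))
    tab <- tab[sample(nrow(tab)), , drop = FALSE]
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(symbol = unname(symbol),
                                  accession = module_nodes),
                       mapping_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    survivors <- survivors[order(survivors$node, survivors$mirna_id), ]
    rownames(survivors) <- NULL
    list(survivors = survivors,
         regulated_nodes = sort(unique(survivors$node)))
  })
  invisible(list(path = path, mapping_path = mapping_path, truth = res))
}

#' Sample from Fisher's noncentral hypergeometric distribution
#'
#' Number of "marked" items in a draw of `k` from `m1` marked and `m2`
#' unmarked items when each marked item's odds of inclusion are inflated
#' by `or`. `or = 1` recovers the central hypergeometric. Sampling is by
#' inverse CDF on the log-space probability mass over the support.
#'
#' @param n number of draws
#' @param m1 marked population size
#' @param m2 unmarked population size
#' @param k sample size
#' @param or odds ratio (> 0)
#' @return integer vector of length `n`
#' @export
rnchyper <- function(n, m1, m2, k, or) {
  stopifnot(or > 0, k <= m1 + m2)
  lo <- max(0L, k - m2); hi <- min(k, m1)
  x <- lo:hi
  lw <- lchoose(m1, x) + lchoose(m2, k - x) + x * log(or)
  w <- exp(lw - max(lw))
  x[sample.int(length(x), n, replace = TRUE, prob = w)]
}

#' Generate a synthetic disease-gene association list
#'
#' Plants a true enrichment odds ratio: the overlap between the module
#' and the "disease set" (genes scoring above the association cutoff) is
#' drawn from Fisher's noncentral hypergeometric distribution at the
#' requested margins. Association scores straddle the cutoff - disease
#' genes score above it, decoy rows (module and background) at or below
#' it - so the strict-inequality filter is exercised.
#'
#' @param module_nodes accessions forming the network margin
#' @param background_n background gene count
#' @param disease_n disease-set size (genes above the cutoff)
#' @param planted_or true odds ratio (capped at 1e6; at the cap the
#'   overlap saturates at the smaller margin)
#' @param rng_seed integer seed
#' @param path output TSV path (columns `gene`, `score`)
#' @param score_cutoff association-score cutoff the scores straddle
#' @return invisibly, a list: `path`, `truth` with `overlap_n`,
#'   `overlap_genes`, `disease_n`, `background_n`
#' @export
generate_disease_list <- function(module_nodes, background_n = 19435L,
                                  disease_n = 292L, planted_or = 15,
                                  rng_seed, path, score_cutoff = 0.38) {
  m1 <- length(module_nodes)
  stopifnot(disease_n <= background_n - m1 + min(m1, disease_n),
            background_n >= m1 + disease_n)
  planted_or <- min(planted_or, 1e6)
  res <- with_seed(rng_seed, {
    a <- rnchyper(1, m1, background_n - m1, disease_n, planted_or)
    overlap <- sort(sample(module_nodes, a))
    n_bg <- disease_n - a
    bg_genes <- sprintf("BG%05d", seq_len(n_bg))
    disease <- data.frame(
      gene = c(overlap, bg_genes),
      score = round(stats::runif(disease_n, score_cutoff + 0.005, 0.95), 3),
      stringsAsFactors = FALSE
    )
    # decoys at or below the cutoff: module nodes and extra background
    decoy_mod <- setdiff(module_nodes, overlap)
    decoy_mod <- decoy_mod[seq_len(min(3, length(decoy_mod)))]
    decoys <- data.frame(
      gene = c(decoy_mod, sprintf("BG9%04d", 1:5)),
      score = round(c(rep(score_cutoff, length(decoy_mod)),
                      stats::runif(5, 0.05, score_cutoff - 0.01)), 3),
      stringsAsFactors = FALSE
    )
    tab <- rbind(disease, decoys)
    tab <- tab[sample(nrow(tab)), , drop = FALSE]
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(overlap_n = a, overlap_genes = overlap,
         disease_n = disease_n, background_n = background_n)
  })
  invisible(list(path = path, truth = res))
}
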