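test_that("mirna names normalize to lowercase hsa- prefixed forms", {
  expect_equal(normalize_mirna_id(c("miR-34a-5p", "hsa-miR-34a-5p",
                                    "HSA-MIR-34A-5P", "let-7b", "mmu-miR-1")),
               c("hsa-mir-34a-5p", "hsa-mir-34a-5p", "hsa-mir-34a-5p",
                 "hsa-let-7b", "mmu-mir-1"))
})

test_that("evidence filter demands the assay method and distinct papers", {
  rec <- rbind(
    mirna_row("miR-1-3p", "GENE1", pmid = 1),
    mirna_row("miR-1-3p", "GENE1", pmid = 2),           # 2 distinct -> kept
    mirna_row("miR-2-5p", "GENE2", method = "Western blot", pmid = 3),
    mirna_row("miR-2-5p", "GENE2", method = "Western blot", pmid = 4),
    mirna_row("miR-2-5p", "GENE2", method = "Western blot", pmid = 5),
    mirna_row("miR-2-5p", "GENE2", method = "Western blot", pmid = 6),
    mirna_row("miR-2-5p", "GENE2", method = "Western blot", pmid = 7),
    mirna_row("miR-3-3p", "GENE3", pmid = 9),
    mirna_row("miR-3-3p", "GENE3", pmid = 9),           # same PMID twice
    mirna_row("miR-4-5p", "GENE4", pmid = 10, species = 10090L)
  )
  out <- filter_mirna_evidence(rec)
  expect_equal(out$mirna_id, "hsa-mir-1-3p")
  expect_equal(out$n_papers, 2L)
})

test_that("per-gene overrides relax but never tighten the paper threshold", {
  rec <- rbind(mirna_row("miR-650", "APOE", pmid = 1),
               mirna_row("miR-9-5p", "CDH1", pmid = 2))
  # APOE accepted on a single study, as a curated exception
  out <- filter_mirna_evidence(rec, min_papers = 2, overrides = c(APOE = 1))
  expect_equal(out$target_gene, "APOE")
  # an override above the default must not tighten
  rec2 <- rbind(mirna_row("miR-1", "G1", pmid = 1),
                mirna_row("miR-1", "G1", pmid = 2))
  out2 <- filter_mirna_evidence(rec2, min_papers = 2, overrides = c(G1 = 5))
  expect_equal(nrow(out2), 1)
})

test_that("the filter is monotone in min_papers", {
  set.seed(44)
  rec <- do.call(rbind, lapply(1:30, function(i) {
    k <- sample(1:4, 1)
    do.call(rbind, lapply(seq_len(k), function(j) {
      mirna_row(sprintf("miR-%d", i), sprintf("G%d", i), pmid = 1000 + j)
    }))
  }))
  kept <- vapply(1:5, function(m) nrow(filter_mirna_evidence(rec, m)),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("duplicate (miRNA, gene) rows pool their PMIDs before thresholding", {
  rec <- rbind(mirna_row("miR-7-5p", "SNCA", pmid = 1),
               mirna_row("hsa-miR-7-5p", "SNCA", pmid = 2))
  out <- filter_mirna_evidence(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$pmids, "1;2")
})

test_that("strong-evidence rows without a PMID count as one paper", {
  rec <- rbind(mirna_row("miR-5-3p", "G5", pmid = 77),
               within(mirna_row("miR-5-3p", "G5", pmid = "-"),
                      strong_evidence <- TRUE))
  out <- filter_mirna_evidence(rec)
  expect_equal(out$n_papers, 2L)
})

test_that("attaching regulators reports fractions and multi-target counts", {
  nodes <- sprintf("P%02d", 1:10)
  net <- ppi_network(data.frame(id_a = nodes[1], id_b = nodes[-1]),
                     quiet = TRUE)
  rec <- data.frame(mirna_id = c("hsa-mir-34a-5p", "hsa-mir-34a-5p",
                                 "hsa-mir-34a-5p", "hsa-mir-34a-5p",
                                 "hsa-mir-107"),
                    target_gene = c("G1", "G2", "G3", "G4", "G1"),
                    n_papers = 2L, pmids = "1;2", stringsAsFactors = FALSE)
  mapping <- data.frame(symbol = c("G1", "G2", "G3", "G4"),
                        accession = nodes[1:4])
  layer <- attach_regulators(net, rec, mapping)
  expect_equal(nrow(layer$edges), 5)
  expect_equal(unname(layer$per_mirna_targets[["hsa-mir-34a-5p"]]), 4L)
  expect_equal(layer$regulated_fraction, 0.4)
  expect_true(all(layer$edges$node %in% net$nodes))

  # 2 regulated nodes out of 10 -> fraction 0.2
  layer2 <- attach_regulators(net, rec[c(1, 2), ], mapping)
  expect_equal(layer2$regulated_fraction, 0.2)

  # unmappable targets are skipped, not fatal
  rec_bad <- rbind(rec, data.frame(mirna_id = "hsa-mir-9-5p",
                                   target_gene = "NOPE", n_papers = 2L,
                                   pmids = "9"))
  expect_message(layer3 <- attach_regulators(net, rec_bad, mapping),
                 "unmappable target")
  expect_equal(nrow(layer3$edges), 5)

  # empty evidence -> empty layer, fraction 0
  empty <- attach_regulators(net, rec[0, ], mapping)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$regulated_fraction, 0)
})

test_that("overlap contingency tables follow set algebra", {
  tab <- overlap_enrichment(c("miR-a", "miR-b", "miR-c"),
                            c("miR-b", "miR-c", "miR-d"), 10)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 2L, b = 1L, c = 1L, d = 6L))
  dis <- overlap_enrichment(c("miR-a"), c("miR-b"), 10)
  expect_equal(dis$a, 0L)
  expect_error(overlap_enrichment(sprintf("miR-%d", 1:8),
                                  sprintf("miR-%d", 6:12), 10),
               "background .* smaller")
  # prefix variants unify before counting
  tab2 <- overlap_enrichment(c("miR-34a-5p"), c("hsa-miR-34a-5p"), 5)
  expect_equal(tab2$a, 1L)
})

test_that("regulator table and bipartite overlay export correctly", {
  net <- ppi_network(data.frame(id_a = "P01", id_b = c("P02", "P03")),
                     quiet = TRUE)
  rec <- data.frame(mirna_id = c("hsa-mir-1", "hsa-mir-2"),
                    target_gene = c("G1", "G1"),
                    n_papers = 2L, pmids = "1;2", stringsAsFactors = FALSE)
  mapping <- data.frame(symbol = "G1", accession = "P02")
  layer <- attach_regulators(net, rec, mapping)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_regulator_tsv(layer, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(tab$gene, "G1")
  expect_equal(tab$mirnas, "hsa-mir-1;hsa-mir-2")

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_layer_graphml(net, layer, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 5)  # 3 proteins + 2 miRNAs
  types <- igraph::V(g)$node_type
  expect_equal(sum(types == "mirna"), 2)
})
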