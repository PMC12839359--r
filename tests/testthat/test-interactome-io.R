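write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("mitab reader applies taxon, score and type filters row by row", {
  pol <- filter_policy(min_mi_score = 0.65)
  keep <- mitab_line("P00001", "P00002", score = 0.70)
  f <- write_lines_tmp(keep)
  rec <- read_mitab(f, pol)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$id_a, "P00001")
  expect_equal(rec$mi_score, 0.70)

  low <- mitab_line("P00001", "P00002", score = 0.60)
  expect_equal(nrow(read_mitab(write_lines_tmp(low), pol)), 0)
})

test_that("a 20-row mitab fixture keeps exactly the qualifying rows", {
  mouse <- "taxid:10090(mouse)"
  coloc <- "psi-mi:\"MI:0403\"(colocalization)"
  rows <- c(
    vapply(1:11, function(i) mitab_line(sprintf("P%05d", i),
                                        sprintf("P%05d", i + 100),
                                        score = 0.66 + i / 100),
           character(1)),
    mitab_line("P90001", "P90002", tax_a = mouse, tax_b = mouse, score = 0.9),
    mitab_line("P90003", "P90004", tax_a = mouse, score = 0.9),
    mitab_line("P90005", "P90006", tax_b = mouse, score = 0.9),
    vapply(1:4, function(i) mitab_line(sprintf("P%05d", 200 + i),
                                       sprintf("P%05d", 300 + i),
                                       score = 0.30), character(1)),
    mitab_line("P90007", "P90008", score = 0.9, type = coloc),
    mitab_line("P90009", "P90010", score = 0.9, type = coloc)
  )
  expect_length(rows, 20)
  rec <- read_mitab(write_lines_tmp(rows), filter_policy(min_mi_score = 0.65))
  expect_equal(nrow(rec), 11)
  # every kept record satisfies the policy predicates
  expect_true(all(rec$mi_score >= 0.65))
  expect_true(all(rec$taxid_a == 9606 & rec$taxid_b == 9606))
  expect_true(all(rec$interaction_type %in%
                    c("direct interaction", "physical association")))
})

test_that("malformed and ambiguous mitab lines are skipped with a warning", {
  rows <- c(mitab_line("P00001", "P00002", score = 0.9),
            "too\tfew\tcolumns",
            mitab_line("P00003", "P00004", score = 0.9,
                       tax_a = "taxid:9606(human)|taxid:10090(mouse)"))
  f <- write_lines_tmp(rows)
  expect_warning(expect_warning(rec <- read_mitab(f, filter_policy()),
                                "line 2 has 3 columns"),
                 "conflicting taxon")
  expect_equal(nrow(rec), 1)
  # records with no parsable miscore are dropped under a positive threshold
  noscore <- mitab_line("P00005", "P00006", confidence = "author-score:high")
  expect_equal(nrow(read_mitab(write_lines_tmp(noscore),
                               filter_policy(min_mi_score = 0.1))), 0)
})

test_that("mitab identifiers are normalized (isoforms stripped, uppercased)", {
  rows <- mitab_line("p05067-2", "q12345", score = 0.9)
  rec <- read_mitab(write_lines_tmp(rows), filter_policy())
  expect_equal(rec$id_a, "P05067")
  expect_equal(rec$id_b, "Q12345")
})

test_that("string reader auto-detects the score dialect and applies the 0.9 cutoff", {
  tab_1000 <- c("protein1\tprotein2\tcombined_score",
                "P1\tP2\t950", "P3\tP4\t899", "P5\tP6\t900")
  rec <- read_string_table(write_lines_tmp(tab_1000), filter_policy())
  expect_equal(nrow(rec), 2)
  expect_equal(rec$mi_score, c(0.950, 0.900))

  tab_unit <- c("protein1\tprotein2\tcombined_score",
                "P1\tP2\t0.95", "P3\tP4\t0.85")
  rec <- read_string_table(write_lines_tmp(tab_unit), filter_policy())
  expect_equal(nrow(rec), 1)

  fixture <- c("protein1\tprotein2\tcombined_score",
               sprintf("A%d\tB%d\t%d", 1:10, 1:10,
                       c(950, 980, 920, 910, 905, 901, 880, 850, 400, 899)))
  expect_equal(nrow(read_string_table(write_lines_tmp(fixture),
                                      filter_policy())), 6)

  bad <- c("protein1\tprotein2\tcombined_score", "P1\tP2\thigh", "P3\tP4\t950")
  expect_warning(rec <- read_string_table(write_lines_tmp(bad), filter_policy()),
                 "non-numeric score")
  expect_equal(nrow(rec), 1)
})

test_that("biogrid reader counts distinct publications on physical low-throughput rows", {
  hdr <- "interactor_a\tinteractor_b\tsystem_type\tthroughput\tpmid"
  fixture <- c(hdr,
    # pair 1: two distinct PMIDs, physical LTP -> kept
    "P1\tP2\tphysical\tLow Throughput\t101",
    "P2\tP1\tphysical\tLow Throughput\t102",      # reversed orientation
    # pair 2: one PMID repeated on 3 rows -> dropped (distinctness)
    "P3\tP4\tphysical\tLow Throughput\t201",
    "P3\tP4\tphysical\tLow Throughput\t201",
    "P3\tP4\tphysical\tLow Throughput\t201",
    # pair 3: two PMIDs but genetic -> dropped
    "P5\tP6\tgenetic\tLow Throughput\t301",
    "P5\tP6\tgenetic\tLow Throughput\t302",
    # pair 4: two PMIDs but high throughput -> dropped
    "P7\tP8\tphysical\tHigh Throughput\t401",
    "P7\tP8\tphysical\tHigh Throughput\t402",
    # pair 5: two distinct PMIDs -> kept
    "P9\tPA\tphysical\tLow Throughput\t501",
    "P9\tPA\tphysical\tLow Throughput\t502")
  rec <- read_biogrid_table(write_lines_tmp(fixture), filter_policy())
  expect_equal(nrow(rec), 2)
  expect_setequal(paste(rec$id_a, rec$id_b), c("P1 P2", "P9 PA"))
  expect_equal(rec$n_publications, c(2L, 2L))

  # rows missing the publication id never count, with a warning
  nopub <- c(hdr, "P1\tP2\tphysical\tLow Throughput\t-",
             "P1\tP2\tphysical\tLow Throughput\t101")
  expect_warning(rec <- read_biogrid_table(write_lines_tmp(nopub),
                                           filter_policy()),
                 "lack a publication id")
  expect_equal(nrow(rec), 0)
})

test_that("merge deduplicates pairs and unions provenance", {
  r_intact <- data.frame(id_a = "A", id_b = "B", taxid_a = 9606L,
                         taxid_b = 9606L, interaction_type = "direct interaction",
                         mi_score = 0.8, n_publications = 1L,
                         detection_class = "unknown", source_db = "intact")
  r_biogrid <- r_intact
  r_biogrid$source_db <- "biogrid"
  net <- merge_records(r_intact, r_biogrid)
  expect_equal(n_edges(net), 1)
  expect_equal(net$edges$provenance, "biogrid;intact")

  # disjoint 3 + 4 edges -> 7
  mk <- function(ids_a, ids_b, db) {
    data.frame(id_a = ids_a, id_b = ids_b, taxid_a = 9606L, taxid_b = 9606L,
               interaction_type = "direct interaction", mi_score = 0.8,
               n_publications = 1L, detection_class = "unknown", source_db = db)
  }
  l1 <- mk(c("A", "B", "C"), c("D", "E", "F"), "intact")
  l2 <- mk(c("G", "H", "I", "J"), c("K", "L", "M", "N"), "string")
  expect_equal(n_edges(merge_records(l1, l2)), 7)

  # idempotent and order-independent
  m1 <- merge_records(l1, l2, r_intact, r_biogrid)
  m2 <- merge_records(r_biogrid, l2, r_intact, l1)
  expect_identical(m1$edges, m2$edges)
  # merging an already-merged edge set again changes nothing
  again <- mk(m1$edges$id_a, m1$edges$id_b, m1$edges$provenance)
  expect_identical(merge_records(again)$edges, m1$edges)
})

test_that("mi-score filtering is monotone across a threshold grid", {
  spec <- synthetic_spec(rng_seed = 7)
  f <- withr::local_tempfile(fileext = ".mitab")
  generate_interactome(spec, f)
  kept <- vapply(c(0.0, 0.3, 0.56, 0.65, 0.8, 0.95), function(thr) {
    nrow(read_mitab(f, filter_policy(min_mi_score = thr)))
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
  # relaxing 0.65 to 0.56 admits extra (noisier) records, as intended
  expect_gt(kept[3], kept[4])
})
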