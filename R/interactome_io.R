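#' Filtering policy for interaction sources
#'
#' Thresholds applied while reading the three interaction dialects:
#' species restriction, minimum IntAct MI confidence score, allowed
#' interaction-type CV labels, minimum distinct supporting publications
#' (BioGRID-like), whether only low-throughput evidence counts, and the
#' minimum STRING combined score.
#'
#' @param taxid NCBI taxonomy id both interactors must carry (9606 = human)
#' @param min_mi_score minimum IntAct MI score in [0, 1]
#' @param allowed_types interaction-type labels (CV names or MI ids) kept
#' @param min_publications minimum distinct publications per pair
#' @param require_low_throughput only count low-throughput rows towards
#'   the publication threshold
#' @param string_min_score minimum STRING combined score in [0, 1]
#' @return a list of class `filter_policy`
#' @export
filter_policy <- function(taxid = 9606L,
                          min_mi_score = 0.60,
                          allowed_types = c("direct interaction",
                                            "physical association"),
                          min_publications = 2L,
                          require_low_throughput = TRUE,
                          string_min_score = 0.9) {
  stopifnot(min_mi_score >= 0, min_mi_score <= 1,
            string_min_score >= 0, string_min_score <= 1,
            min_publications >= 0)
  structure(list(taxid = as.integer(taxid),
                 min_mi_score = min_mi_score,
                 allowed_types = tolower(allowed_types),
                 min_publications = as.integer(min_publications),
                 require_low_throughput = isTRUE(require_low_throughput),
                 string_min_score = string_min_score),
            class = "filter_policy")
}

#' Normalize a molecule accession
#'
#' Uppercases and strips UniProt isoform suffixes ("P05067-2" becomes
#' "P05067") so the same gene product merges across databases.
#'
#' @param x character vector of accessions
#' @return normalized character vector
#' @export
normalize_accession <- function(x) {
  sub("-[0-9]+$", "", toupper(trimws(x)))
}

empty_records <- function() {
  data.frame(id_a = character(), id_b = character(),
             taxid_a = integer(), taxid_b = integer(),
             interaction_type = character(), mi_score = numeric(),
             n_publications = integer(), detection_class = character(),
             source_db = character(), stringsAsFactors = FALSE)
}

# "uniprotkb:P05067|intact:EBI-77613" -> "P05067" (first entry's value)
mitab_primary_id <- function(field) {
  first <- sub("\\|.*$", "", field)
  sub("^[^:]*:", "", first)
}

# all distinct taxids in a MITAB organism field; NA when absent ("-")
mitab_taxids <- function(field) {
  if (field == "-" || !nzchar(field)) return(integer(0))
  m <- regmatches(field, gregexpr("taxid:-?[0-9]+", field))[[1]]
  unique(as.integer(sub("taxid:", "", m)))
}

# 'psi-mi:"MI:0407"(direct interaction)' -> c("mi:0407", "direct interaction")
mitab_type_labels <- function(field) {
  mi <- regmatches(field, regexpr("MI:[0-9]{4}", field))
  nm <- regmatches(field, regexpr("\\(([^)]*)\\)", field))
  nm <- sub("^\\(", "", sub("\\)$", "", nm))
  tolower(c(mi, nm))
}

# "author score:high|intact-miscore:0.73" -> 0.73, NA when unparsable
mitab_miscore <- function(field) {
  m <- regmatches(field, regexpr("intact-miscore:[0-9.eE+-]+", field))
  if (!length(m)) return(NA_real_)
  suppressWarnings(as.numeric(sub("intact-miscore:", "", m)))
}

#' Read and filter a PSI-MITAB 2.5 interaction file
#'
#' Parses the 15-column tab-separated PSI-MITAB 2.5 format and keeps a
#' record iff both interactors carry the policy's taxon, the
#' `intact-miscore` confidence is at least `min_mi_score`, and the
#' interaction-type CV term (matched by MI identifier or lowercased name)
#' is among `allowed_types`. Rows with the wrong column count, with
#' conflicting taxon annotations, or with no parsable MI score are
#' skipped with a logged warning naming the line.
#'
#' @param path path to a MITAB 2.5 file (lines starting `#` are ignored)
#' @param policy a [filter_policy()]
#' @return data.frame of interaction records (`id_a`, `id_b`, `taxid_a`,
#'   `taxid_b`, `interaction_type`, `mi_score`, `n_publications`,
#'   `detection_class`, `source_db`)
#' @export
read_mitab <- function(path, policy = filter_policy()) {
  lines <- readLines(path)
  keep_line <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep_line)
  lines <- lines[keep_line]
  out <- vector("list", length(lines))
  dropped <- c(malformed = 0L, taxon = 0L, score = 0L, type = 0L)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 15) {
      warning(sprintf("read_mitab: line %d has %d columns (expected 15), skipped",
                      line_no[i], length(f)))
      dropped["malformed"] <- dropped["malformed"] + 1L
      next
    }
    tax_a <- mitab_taxids(f[10])
    tax_b <- mitab_taxids(f[11])
    if (length(tax_a) != 1 || length(tax_b) != 1) {
      if (length(tax_a) > 1 || length(tax_b) > 1) {
        warning(sprintf("read_mitab: line %d has conflicting taxon annotations, skipped",
                        line_no[i]))
      }
      dropped["taxon"] <- dropped["taxon"] + 1L
      next
    }
    if (tax_a != policy$taxid || tax_b != policy$taxid) {
      dropped["taxon"] <- dropped["taxon"] + 1L
      next
    }
    score <- mitab_miscore(f[15])
    if (is.na(score) || score < policy$min_mi_score) {
      dropped["score"] <- dropped["score"] + 1L
      next
    }
    labels <- mitab_type_labels(f[12])
    if (!any(labels %in% policy$allowed_types)) {
      dropped["type"] <- dropped["type"] + 1L
      next
    }
    pubs <- unique(strsplit(f[9], "|", fixed = TRUE)[[1]])
    pubs <- pubs[pubs != "-" & nzchar(pubs)]
    out[[i]] <- data.frame(
      id_a = normalize_accession(mitab_primary_id(f[1])),
      id_b = normalize_accession(mitab_primary_id(f[2])),
      taxid_a = tax_a, taxid_b = tax_b,
      interaction_type = labels[length(labels)],
      mi_score = score,
      n_publications = length(pubs),
      detection_class = "unknown",
      source_db = "intact",
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, c(list(empty_records()), out[!vapply(out, is.null, logical(1))]))
  attr(rec, "dropped") <- dropped
  rec
}

#' Read and filter a STRING-like interaction table
#'
#' Tabular export with two protein identifiers and a combined score. The
#' score dialect is auto-detected: when any score exceeds 1 the column is
#' treated as 0-1000 and divided by 1000. Rows with a non-numeric score
#' are skipped with a warning. Rows with score below
#' `policy$string_min_score` are dropped.
#'
#' @param path path to a tab-separated file with a header
#' @param policy a [filter_policy()]
#' @param columns mapping from record fields to file column names
#' @return data.frame of interaction records (see [read_mitab()])
#' @export
read_string_table <- function(path, policy = filter_policy(),
                              columns = c(id_a = "protein1",
                                          id_b = "protein2",
                                          score = "combined_score")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(columns %in% names(df)))
  score_raw <- df[[columns[["score"]]]]
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- is.na(score)
  if (any(bad)) {
    warning(sprintf("read_string_table: %d row(s) with non-numeric score skipped",
                    sum(bad)))
  }
  df <- df[!bad, , drop = FALSE]
  score <- score[!bad]
  if (length(score) && max(score) > 1) score <- score / 1000
  keep <- score >= policy$string_min_score
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(empty_records())
  data.frame(
    id_a = normalize_accession(df[[columns[["id_a"]]]]),
    id_b = normalize_accession(df[[columns[["id_b"]]]]),
    taxid_a = policy$taxid, taxid_b = policy$taxid,
    interaction_type = "physical association",
    mi_score = score[keep],
    n_publications = NA_integer_,
    detection_class = "unknown",
    source_db = "string",
    stringsAsFactors = FALSE
  )
}

#' Read and filter a BioGRID-like interaction table
#'
#' Tabular export with one row per supporting experiment. Rows are grouped
#' by unordered interactor pair; a pair survives iff it accumulates at
#' least `policy$min_publications` *distinct* publication identifiers on
#' physical rows (low-throughput only when
#' `policy$require_low_throughput`). Rows with a missing publication id do
#' not count towards the threshold and are logged.
#'
#' @param path path to a tab-separated file with a header
#' @param policy a [filter_policy()]
#' @param columns mapping from record fields to file column names
#' @return data.frame of interaction records (see [read_mitab()]);
#'   `n_publications` holds the distinct qualifying publication count
#' @export
read_biogrid_table <- function(path, policy = filter_policy(),
                               columns = c(id_a = "interactor_a",
                                           id_b = "interactor_b",
                                           system_type = "system_type",
                                           throughput = "throughput",
                                           pmid = "pmid")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(columns %in% names(df)))
  physical <- grepl("physical", tolower(df[[columns[["system_type"]]]]), fixed = TRUE)
  ltp <- if (policy$require_low_throughput) {
    grepl("low", tolower(df[[columns[["throughput"]]]]), fixed = TRUE)
  } else {
    rep(TRUE, nrow(df))
  }
  pmid <- trimws(as.character(df[[columns[["pmid"]]]]))
  no_pmid <- !nzchar(pmid) | pmid == "-" | is.na(pmid)
  if (any(no_pmid & physical & ltp)) {
    warning(sprintf("read_biogrid_table: %d qualifying row(s) lack a publication id and were not counted",
                    sum(no_pmid & physical & ltp)))
  }
  use <- physical & ltp & !no_pmid
  if (!any(use)) return(empty_records())
  a <- normalize_accession(df[[columns[["id_a"]]]][use])
  b <- normalize_accession(df[[columns[["id_b"]]]][use])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  counts <- vapply(split(pmid[use], key), function(p) length(unique(p)),
                   integer(1))
  keep <- names(counts)[counts >= policy$min_publications]
  if (!length(keep)) return(empty_records())
  pair <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
  data.frame(
    id_a = pair[, 1], id_b = pair[, 2],
    taxid_a = policy$taxid, taxid_b = policy$taxid,
    interaction_type = "physical association",
    mi_score = NA_real_,
    n_publications = unname(counts[keep]),
    detection_class = if (policy$require_low_throughput) "low_throughput" else "unknown",
    source_db = "biogrid",
    stringsAsFactors = FALSE
  )
}

#' Merge filtered interaction records into one deduplicated network
#'
#' One edge per unordered accession pair regardless of how many sources
#' attest it; the edge `provenance` attribute lists the contributing
#' source databases.
#'
#' @param ... interaction-record data.frames (or a single list of them)
#' @return a `ppi_network`
#' @export
merge_records <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]]) && !is.data.frame(lists[[1]])) {
    lists <- lists[[1]]
  }
  rec <- do.call(rbind, c(list(empty_records()), lists))
  edges <- data.frame(id_a = rec$id_a, id_b = rec$id_b,
                      provenance = rec$source_db, stringsAsFactors = FALSE)
  ppi_network(edges, quiet = TRUE)
}

#' Write a network edge list as TSV
#'
#' @param net a `ppi_network`
#' @param path output file path
#' @param header_comment optional comment lines (prefixed `#`)
#' @return `path`, invisibly
#' @export
write_edges_tsv <- function(net, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
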