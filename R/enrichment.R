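#' Build a 2x2 contingency table from overlap counts
#'
#' The table underlying the disease-gene enrichment test:
#' `a` = genes both in the network and in the disease set, `b` = network
#' only, `c` = disease set only, `d` = background genes in neither.
#'
#' @param network_n number of genes in the network
#' @param overlap_k number of genes in both sets
#' @param disease_n number of genes in the disease set
#' @param background_n total background (e.g. all protein-coding genes)
#' @return object of class `contingency_table`: list with integer cells
#'   `a`, `b`, `c`, `d`
#' @export
contingency_from_counts <- function(network_n, overlap_k, disease_n,
                                    background_n) {
  if (overlap_k > min(network_n, disease_n)) {
    stop(sprintf("overlap (%d) exceeds the smaller margin (network %d, disease %d)",
                 overlap_k, network_n, disease_n))
  }
  if (background_n < network_n + disease_n - overlap_k) {
    stop(sprintf("background (%d) smaller than the union of the two sets (%d)",
                 background_n, network_n + disease_n - overlap_k))
  }
  contingency_table(overlap_k, network_n - overlap_k,
                    disease_n - overlap_k,
                    background_n - network_n - disease_n + overlap_k)
}

#' @rdname contingency_from_counts
#' @param a,b,c,d non-negative integer cell counts
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency table cells must be non-negative integers")
  }
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("in set 1", "not in set 1"),
                              c("in set 2", "not in set 2")))
  print(m)
  invisible(x)
}

# log hypergeometric probability of cell a given margins (m1 = a+b row,
# k = a+c column, N total), via log-gamma
lhyper <- function(a, m1, m2, k) {
  lchoose(m1, a) + lchoose(m2, k - a) - lchoose(m1 + m2, k)
}

#' Fisher's exact test and odds-ratio estimates for a 2x2 table
#'
#' The two-sided p-value follows the probability-mass rule: it is the sum
#' of hypergeometric probabilities of every table with the observed
#' margins whose probability does not exceed that of the observed table
#' (with a relative slack of 1e-7 when comparing masses, the convention of
#' the reference implementations). All masses are computed in log space
#' via log-gamma and combined by log-sum-exp, so the log p-value is exact
#' even when `p_value` underflows; in that case `p_label` reports an upper
#' bound instead of 0.
#'
#' Two odds-ratio estimates are returned: the raw cross-product
#' `ad / bc` (with an `Inf` sentinel when `bc = 0`) and the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric
#' distribution, solved numerically until the expected first cell matches
#' the observed one to within 1e-8.
#'
#' @param tab a `contingency_table`
#' @return list with `p_value`, `log10_p`, `p_label`,
#'   `odds_ratio_sample`, `odds_ratio_cmle`
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  support <- lo:hi
  lp <- lhyper(support, m1, m2, k)
  lp_obs <- lp[support == a]
  sel <- lp <= lp_obs + log1p(1e-07)
  log_p <- logsumexp(lp[sel])
  log_p <- min(log_p, 0)   # guard rounding above 1
  p <- exp(log_p)
  list(
    p_value = p,
    log10_p = log_p / log(10),
    p_label = if (p > 0) format(p, digits = 4) else
      sprintf("< 1e%d", ceiling(log_p / log(10))),
    odds_ratio_sample = odds_ratio_sample(a, b, c, d),
    odds_ratio_cmle = odds_ratio_cmle(a, m1, m2, k)
  )
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

odds_ratio_sample <- function(a, b, c, d) {
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
}

# expected first cell of Fisher's noncentral hypergeometric with log-odds
# `theta`, margins (m1, m2, k); weights in log space for stability
nchg_mean <- function(theta, m1, m2, k) {
  lo <- max(0L, k - m2); hi <- min(k, m1)
  x <- lo:hi
  lw <- lchoose(m1, x) + lchoose(m2, k - x) + x * theta
  w <- exp(lw - max(lw))
  sum(x * w) / sum(w)
}

odds_ratio_cmle <- function(a, m1, m2, k) {
  lo <- max(0L, k - m2); hi <- min(k, m1)
  if (lo == hi) return(NaN)           # degenerate margin: OR not identifiable
  if (a == hi) return(Inf)
  if (a == lo) return(0)
  f <- function(theta) nchg_mean(theta, m1, m2, k) - a
  bracket <- c(-1, 1)
  while (f(bracket[1]) > 0) bracket[1] <- bracket[1] * 2
  while (f(bracket[2]) < 0) bracket[2] <- bracket[2] * 2
  sol <- stats::uniroot(f, bracket, tol = .Machine$double.eps^0.75)
  theta <- sol$root
  # polish until the expected cell matches the observed one tightly
  for (i in 1:100) {
    err <- f(theta)
    if (abs(err) < 1e-08) break
    # Newton step using the conditional variance as the derivative
    lo_hi <- lo:hi
    lw <- lchoose(m1, lo_hi) + lchoose(m2, k - lo_hi) + lo_hi * theta
    w <- exp(lw - max(lw)); w <- w / sum(w)
    mu <- sum(lo_hi * w)
    v <- sum((lo_hi - mu)^2 * w)
    theta <- theta - err / v
  }
  exp(theta)
}

#' Write an enrichment report as TSV
#'
#' One row per tested dataset in the layout (dataset, n, overlap,
#' background, odds ratio, p).
#'
#' @param rows data.frame with columns `dataset`, `n`, `overlap`,
#'   `disease_n`, `background`, `odds_ratio`, `p`
#' @param path output file path
#' @param header_comment optional comment lines (prefixed `#`)
#' @return `path`, invisibly
#' @export
write_enrichment_tsv <- function(rows, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
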