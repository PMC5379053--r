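# Subfamily-level enrichment of multi-TF binding: base-2 log odds ratios on
# the {subfamily j vs other TEs} x {bound by i TFs vs not} 2x2 table, with
# hypergeometric upper-tail significance and a minimum-element reporting
# filter.

#' Base-2 log odds ratio for subfamily enrichment
#'
#' For `k` TEs of subfamily j bound by i TFs, out of `N_j` subfamily copies,
#' `K_i` bound TEs genome-wide and `N` TEs total, forms the 2x2 table
#' `a = k`, `b = N_j - k`, `c = K_i - k`, `d = N - N_j - K_i + k` and returns
#' `log2(a*d / (b*c))`. When any cell is 0 the Haldane-Anscombe correction
#' adds 0.5 to every cell of that table, keeping the estimate finite. Base 2
#' makes the enrichment scale read directly in folds: LOR 6 = 64-fold.
#'
#' @param k,N_j,K_i,N Integer vectors (recycled) satisfying
#'   `0 <= k <= min(N_j, K_i)` and `N_j + K_i - k <= N`.
#' @return Numeric vector of log odds ratios (bits of enrichment).
#' @export
log_odds_ratio <- function(k, N_j, K_i, N) {
  a <- as.numeric(k)
  b <- as.numeric(N_j) - a
  c <- as.numeric(K_i) - a
  d <- as.numeric(N) - as.numeric(N_j) - as.numeric(K_i) + a
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stopf("invalid 2x2 table: derived cell is negative (check k <= min(N_j, K_i) and N_j + K_i - k <= N)")
  }
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a[zero] <- a[zero] + 0.5
  b[zero] <- b[zero] + 0.5
  c[zero] <- c[zero] + 0.5
  d[zero] <- d[zero] + 0.5
  log2(a * d / (b * c))
}

#' Hypergeometric upper-tail p-value for subfamily enrichment
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K_i, N_j)`: drawing the `N_j`
#' copies of subfamily j from the `N` annotated TEs of which `K_i` are bound
#' by i TFs. Computed with the exact tail of [stats::phyper()].
#'
#' @inheritParams log_odds_ratio
#' @return Numeric vector of p-values in (0, 1].
#' @export
hypergeom_upper <- function(k, N_j, K_i, N) {
  if (any(k < 0 | k > pmin(N_j, K_i) | N_j > N | K_i > N)) {
    stopf("invalid hypergeometric arguments")
  }
  stats::phyper(k - 1, K_i, N - K_i, N_j, lower.tail = FALSE)
}

#' Scan all TE subfamilies for enrichment of multi-TF binding
#'
#' Bins TEs by the number of distinct TFs bound (1..5 exactly, plus a `"2+"`
#' aggregate) and, per (subfamily, bin), computes the log odds ratio and
#' hypergeometric upper-tail p-value over the universe of all annotated TE
#' copies. The full table is returned; `passes_min` marks rows with at least
#' `min_elements` bound copies (the reporting filter), and `flagged` marks
#' rows that additionally reach the LOR and p-value cutoffs. A
#' Benjamini-Hochberg FDR column is emitted as supplementary output alongside
#' the raw p-values.
#'
#' @param n_tfs Integer vector from [assign_clusters_to_tes()], one value per
#'   annotation row.
#' @param annotation TE annotation data.frame with a `repName` column.
#' @param min_elements Minimum bound copies for a row to be reportable
#'   (default 10).
#' @param lor_threshold LOR cutoff for flagging (default 4.5).
#' @param p_threshold p-value cutoff for flagging (default 0.001).
#' @return data.frame with columns `repName`, `i`, `k`, `N_j`, `K_i`, `N`,
#'   `lor`, `pvalue`, `bh_fdr`, `passes_min`, `flagged`.
#' @export
enrichment_scan <- function(n_tfs, annotation, min_elements = 10,
                            lor_threshold = 4.5, p_threshold = 0.001) {
  if (!nrow(annotation)) {
    warnf("empty TE annotation: returning empty enrichment table")
    return(data.frame(repName = character(), i = character(), k = integer(),
                      N_j = integer(), K_i = integer(), N = integer(),
                      lor = numeric(), pvalue = numeric(), bh_fdr = numeric(),
                      passes_min = logical(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  if (length(n_tfs) != nrow(annotation)) {
    stopf("n_tfs must have one value per annotation row")
  }
  N <- nrow(annotation)
  subfam <- as.character(annotation$repName)
  fams <- sort(unique(subfam))
  N_j <- table(factor(subfam, levels = fams))
  bins <- c(as.character(1:5), "2+")
  rows <- lapply(bins, function(b) {
    in_bin <- if (b == "2+") n_tfs >= 2 else n_tfs == as.integer(b)
    K_i <- sum(in_bin)
    k <- tapply(in_bin, factor(subfam, levels = fams), sum)
    data.frame(repName = fams, i = b, k = as.integer(k),
               N_j = as.integer(N_j), K_i = K_i, N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$lor <- log_odds_ratio(out$k, out$N_j, out$K_i, out$N)
  out$pvalue <- hypergeom_upper(out$k, out$N_j, out$K_i, out$N)
  out$bh_fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$passes_min <- out$k >= min_elements
  out$flagged <- out$passes_min & out$lor >= lor_threshold &
    out$pvalue < p_threshold
  rownames(out) <- NULL
  out
}
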