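# TE dating: Jukes-Cantor correction of consensus divergence, pairing of
# flanking LTRs, inter-LTR divergence from global alignment, and
# insertion-time estimation under mutation-rate bounds.

#' Jukes-Cantor corrected substitutions per site
#'
#' `K = -(3/4) * ln(1 - (4/3) p)` for an observed divergence proportion `p`.
#' The correction accounts for multiple substitutions at one site under the
#' one-parameter model; it saturates at `p = 0.75`, beyond which the distance
#' is undefined.
#'
#' @param p Observed proportion of differing sites, in `[0, 0.75)`.
#' @return Substitutions per site, `K >= p`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    stopf("divergence p must lie in [0, 0.75): Jukes-Cantor distance saturates at 0.75")
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pair adjacent same-subfamily LTR copies into candidate proviruses
#'
#' The two LTRs flanking an intact endogenous retrovirus are identical at
#' insertion; finding such pairs is the first step of insertion dating.
#' Pairing is greedy nearest-neighbor per chromosome: among coordinate-
#' adjacent copies of the same subfamily on the same strand whose inter-LTR
#' gap is at most `max_span`, the closest pairs are taken first and each copy
#' is used at most once (an ambiguous triple resolves to its closest duo).
#'
#' @param ltrs Annotation data.frame of LTR copies (`chrom`, `start`, `end`,
#'   `strand`, `repName`).
#' @param max_span Maximum bp between the inner ends of the two LTRs
#'   (default 7,000).
#' @return data.frame with one row per pair: indices `idx5`/`idx3` into
#'   `ltrs`, coordinates of both copies, `repName`, `strand`, `span`.
#' @export
pair_ltrs <- function(ltrs, max_span = 7000) {
  empty <- data.frame(idx5 = integer(), idx3 = integer(), chrom = character(),
                      start5 = integer(), end5 = integer(),
                      start3 = integer(), end3 = integer(),
                      repName = character(), strand = character(),
                      span = integer(), stringsAsFactors = FALSE)
  if (nrow(ltrs) < 2) return(empty)
  key <- paste(ltrs$chrom, ltrs$repName, ltrs$strand, sep = "\r")
  cand <- NULL
  for (grp in split(seq_len(nrow(ltrs)), key)) {
    if (length(grp) < 2) next
    grp <- grp[order(ltrs$start[grp])]
    a <- grp[-length(grp)]
    b <- grp[-1]
    gap <- ltrs$start[b] - ltrs$end[a]
    keep <- gap >= 0 & gap <= max_span
    if (any(keep)) {
      cand <- rbind(cand, data.frame(a = a[keep], b = b[keep],
                                     gap = gap[keep]))
    }
  }
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$gap), , drop = FALSE]
  used <- logical(nrow(ltrs))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$a[r]; j <- cand$b[r]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      idx5 = i, idx3 = j, chrom = ltrs$chrom[i],
      start5 = ltrs$start[i], end5 = ltrs$end[i],
      start3 = ltrs$start[j], end3 = ltrs$end[j],
      repName = ltrs$repName[i], strand = ltrs$strand[i],
      span = cand$gap[r], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start5), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site divergence between two LTR sequences
#'
#' Globally aligns the pair (match +1, mismatch -1, gap open -4, gap extend
#' -1) and returns mismatches divided by aligned non-gap columns. The caller
#' is responsible for orienting the sequences; antiparallel input yields a
#' divergence near the random expectation 0.75 and triggers a warning.
#'
#' @param seqA,seqB Character or `DNAString` sequences (non-empty).
#' @return Proportion of differing aligned sites, in `[0, 1)`.
#' @export
ltr_divergence <- function(seqA, seqB) {
  a <- toupper(as.character(seqA))
  b <- toupper(as.character(seqB))
  if (!nchar(a) || !nchar(b)) stopf("both sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa != "-" & sa != "-"
  if (!any(ok)) stopf("alignment has no non-gap columns: divergence undefined")
  d <- sum(pa[ok] != sa[ok]) / sum(ok)
  if (d > 0.5) {
    warnf("inter-LTR divergence %.2f is near the random expectation; check sequence orientation", d)
  }
  d
}

#' Insertion time from inter-LTR divergence
#'
#' The two LTRs are identical at insertion and then evolve independently, so
#' divergence accrues at twice the per-lineage rate: `T = d / (2 r)`.
#'
#' @param d Per-site divergence between the paired LTRs.
#' @param r Mutation rate, substitutions per site per million years.
#' @return Time since insertion in million years.
#' @export
insertion_time <- function(d, r) {
  if (any(d < 0)) stopf("divergence must be >= 0")
  if (any(r <= 0)) stopf("mutation rate must be > 0")
  d / (2 * r)
}

#' Box-plot statistics of insertion times per subfamily and rate bound
#'
#' Summarizes insertion-time estimates per subfamily under each supplied
#' mutation rate (default: the fast/slow mouse-rat bounds of 1.2% and 0.05%
#' per site per Myr). The faster rate gives the smaller times.
#'
#' @param pairs data.frame from [pair_ltrs()] with a `d` divergence column
#'   added (see [ltr_divergence()]).
#' @param rates Named numeric vector of rates (per site per Myr).
#' @return data.frame with `repName`, `rate_label`, `rate`, `n_pairs`,
#'   `min`, `q25`, `median`, `q75`, `max` of the insertion time (Myr).
#' @export
subfamily_age_summary <- function(pairs,
                                  rates = c(fast = 0.012, slow = 0.0005)) {
  if (!nrow(pairs)) {
    warnf("no LTR pairs supplied: empty age summary")
    return(data.frame(repName = character(), rate_label = character(),
                      rate = numeric(), n_pairs = integer(), min = numeric(),
                      q25 = numeric(), median = numeric(), q75 = numeric(),
                      max = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(pairs$d)) stopf("pairs must carry a divergence column 'd'")
  out <- list()
  for (fam in sort(unique(pairs$repName))) {
    dd <- pairs$d[pairs$repName == fam]
    for (ri in seq_along(rates)) {
      tt <- insertion_time(dd, rates[ri])
      q <- stats::quantile(tt, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        repName = fam, rate_label = names(rates)[ri] %||% as.character(ri),
        rate = unname(rates[ri]), n_pairs = length(tt),
        min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
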