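# Reporter-assay quantification: luciferase fold changes, barcoded reporter
# (CRE-seq / MPRA) expression, mutant-versus-wild-type effects, and qPCR
# delta-delta-Ct relative expression.

#' Regulatory potential from dual-luciferase measurements
#'
#' Per record, expression is the firefly/renilla ratio. Technical replicates
#' are averaged within each experiment first; experiment-level means are then
#' averaged across experiments. The fold change is the construct value
#' divided by the empty-vector value computed the same way; the reported sd
#' is across experiment-level fold changes. Constructs are classified as
#' `inactive`, `enhancer` (fold change > 2) or `strong_enhancer` (> 10).
#'
#' @param records data.frame with `construct`, `firefly`, `renilla`,
#'   `experiment`, `technical`.
#' @param empty_records Same layout, for the empty/basal vector.
#' @return data.frame per construct: `fold_change`, `sd`, `n_experiments`,
#'   `class`.
#' @export
luciferase_fold_change <- function(records, empty_records) {
  clean <- function(df, what) {
    bad <- df$renilla <= 0
    if (any(bad)) {
      warnf("dropping %d %s record(s) with renilla <= 0", sum(bad), what)
      df <- df[!bad, , drop = FALSE]
    }
    if (!nrow(df)) stopf("all %s records dropped (renilla <= 0)", what)
    df$ratio <- df$firefly / df$renilla
    df
  }
  records <- clean(records, "construct")
  empty_records <- clean(empty_records, "empty-vector")
  exp_means <- function(df) {
    agg <- stats::aggregate(ratio ~ construct + experiment, df, mean)
    agg
  }
  emp <- exp_means(empty_records)
  empty_value <- mean(tapply(emp$ratio, emp$experiment, mean))
  agg <- exp_means(records)
  out <- do.call(rbind, lapply(split(agg, agg$construct), function(g) {
    fc_exp <- g$ratio / empty_value
    data.frame(construct = g$construct[1],
               fold_change = mean(fc_exp),
               sd = if (length(fc_exp) > 1) stats::sd(fc_exp) else NA_real_,
               n_experiments = length(fc_exp),
               stringsAsFactors = FALSE)
  }))
  out$class <- classify_potential(out$fold_change)
  rownames(out) <- NULL
  out
}

classify_potential <- function(fc, enhancer = 2, strong = 10) {
  ifelse(fc > strong, "strong_enhancer",
         ifelse(fc > enhancer, "enhancer", "inactive"))
}

# per-barcode cDNA/DNA ratios with low-depth filtering
barcode_ratios <- function(counts, min_dna = 10, pseudocount = 0.5) {
  keep <- counts$dna_count >= min_dna
  ratio <- (counts$cdna_count + pseudocount) / (counts$dna_count + pseudocount)
  data.frame(construct = counts$construct, barcode = counts$barcode,
             replicate = counts$replicate, ratio = ratio, retained = keep,
             stringsAsFactors = FALSE)
}

#' Regulatory potential from barcoded reporter (CRE-seq) counts
#'
#' Per barcode and replicate, expression is the pseudocounted cDNA/DNA read
#' ratio; barcodes with DNA depth below `min_dna` are excluded. A construct's
#' expression is the mean over its retained barcode-replicate ratios, and its
#' fold change is that expression divided by the mean expression of the basal
#' constructs. Constructs whose barcodes are all excluded are reported with
#' `NA` and a warning.
#'
#' @param counts data.frame with `construct`, `barcode`, `replicate`,
#'   `dna_count`, `cdna_count`.
#' @param basal_ids Construct id(s) of the basal/empty reference.
#' @param min_dna Minimum DNA reads for a barcode to count (default 10).
#' @param pseudocount Added to both counts before the ratio (default 0.5).
#' @return data.frame per construct: `expression`, `fold_change`, `sd`
#'   (across replicate-level expressions), `n_barcodes`, `class`.
#' @export
cre_expression <- function(counts, basal_ids, min_dna = 10, pseudocount = 0.5) {
  if (!length(basal_ids) || !any(counts$construct %in% basal_ids)) {
    stopf("at least one basal construct is required")
  }
  br <- barcode_ratios(counts, min_dna, pseudocount)
  kept <- br[br$retained, , drop = FALSE]
  all_ids <- unique(counts$construct)
  expr <- vapply(all_ids, function(id) {
    x <- kept$ratio[kept$construct == id]
    if (!length(x)) NA_real_ else mean(x)
  }, numeric(1))
  missing <- all_ids[is.na(expr)]
  if (length(missing)) {
    warnf("construct(s) with no retained barcode: %s",
          paste(missing, collapse = ", "))
  }
  basal <- mean(expr[all_ids %in% basal_ids], na.rm = TRUE)
  rep_expr <- stats::aggregate(ratio ~ construct + replicate, kept, mean)
  out <- data.frame(construct = all_ids,
                    expression = unname(expr),
                    fold_change = unname(expr) / basal,
                    sd = vapply(all_ids, function(id) {
                      x <- rep_expr$ratio[rep_expr$construct == id] / basal
                      if (length(x) > 1) stats::sd(x) else NA_real_
                    }, numeric(1)),
                    n_barcodes = vapply(all_ids, function(id) {
                      sum(kept$construct == id)
                    }, integer(1)),
                    stringsAsFactors = FALSE)
  out$class <- classify_potential(out$fold_change)
  rownames(out) <- NULL
  out
}

#' Mutant effect on regulatory potential
#'
#' Normalizes a mutant construct's expression to its matched wild-type
#' construct and tests the replicate-level expression values with a Welch
#' two-sided t-test.
#'
#' @inheritParams cre_expression
#' @param mutant,wildtype Construct ids of the matched pair.
#' @return List with `ratio` (mutant fold change / wild-type fold change),
#'   `pvalue`, `mutant_fold_change`, `wildtype_fold_change`.
#' @export
mutant_effect <- function(counts, mutant, wildtype, basal_ids,
                          min_dna = 10, pseudocount = 0.5) {
  present <- c(mutant, wildtype) %in% counts$construct
  if (!all(present)) {
    stopf("missing construct(s): %s",
          paste(c(mutant, wildtype)[!present], collapse = ", "))
  }
  res <- cre_expression(counts, basal_ids, min_dna, pseudocount)
  fc <- function(id) res$fold_change[res$construct == id]
  br <- barcode_ratios(counts, min_dna, pseudocount)
  kept <- br[br$retained, , drop = FALSE]
  rep_vals <- function(id) {
    g <- kept[kept$construct == id, , drop = FALSE]
    as.numeric(tapply(g$ratio, g$replicate, mean))
  }
  x <- rep_vals(mutant)
  y <- rep_vals(wildtype)
  p <- if (length(x) > 1 && length(y) > 1 &&
           (stats::var(x) > 0 || stats::var(y) > 0)) {
    stats::t.test(x, y)$p.value
  } else if (isTRUE(all.equal(mean(x), mean(y)))) {
    1
  } else {
    NA_real_
  }
  list(ratio = fc(mutant) / fc(wildtype), pvalue = p,
       mutant_fold_change = fc(mutant), wildtype_fold_change = fc(wildtype))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each condition, `ddCt = mean(dCt
#' mutant) - mean(dCt wild type)`, and relative expression `2^(-ddCt)`, so a
#' value of 0.5 means the mutant expresses the target at half the wild-type
#' level. A Welch t-test compares the replicate-level dCt values.
#'
#' @param ct_target_wt,ct_ref_wt Replicate Ct values of target and reference
#'   gene in the wild-type condition.
#' @param ct_target_mut,ct_ref_mut Same for the mutant condition.
#' @return List with `relative_expression`, `ddct`, `sd` (of replicate-level
#'   relative expression), `pvalue`.
#' @export
ddct <- function(ct_target_wt, ct_ref_wt, ct_target_mut, ct_ref_mut) {
  if (any(c(ct_target_wt, ct_ref_wt, ct_target_mut, ct_ref_mut) <= 0)) {
    stopf("Ct values must be positive")
  }
  dct_wt <- ct_target_wt - ct_ref_wt
  dct_mut <- ct_target_mut - ct_ref_mut
  dd <- mean(dct_mut) - mean(dct_wt)
  rel_reps <- 2^(-(dct_mut - mean(dct_wt)))
  p <- if (length(dct_wt) > 1 && length(dct_mut) > 1 &&
           (stats::var(dct_wt) > 0 || stats::var(dct_mut) > 0)) {
    stats::t.test(dct_mut, dct_wt)$p.value
  } else if (isTRUE(all.equal(mean(dct_mut), mean(dct_wt)))) {
    1
  } else {
    NA_real_
  }
  list(relative_expression = 2^(-dd), ddct = dd,
       sd = if (length(rel_reps) > 1) stats::sd(rel_reps) else NA_real_,
       pvalue = p)
}
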