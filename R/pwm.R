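# Position weight matrices: construction, information content, exact
# score-distribution p-values (patser-style), scanning, module detection and
# information-content-guided mutagenesis design.

#' Construct a position weight matrix object
#'
#' @param name TF name (e.g. `"Sox2"`).
#' @param probs 4 x L matrix of base probabilities; rows A, C, G, T. Each
#'   column must sum to 1 (tolerance 1e-9) and L must be at least 4.
#' @param background Base frequencies of the null model (sums to 1). Default
#'   uniform.
#' @param pseudocount Additive constant applied to probabilities (and to the
#'   background) before taking log odds, guarding against `-Inf` scores.
#'   Information content, by contrast, is computed on the raw probabilities.
#' @return An object of class `pwm` with fields `name`, `probs`, `background`,
#'   `pseudocount` and `consensus` (majority base where its probability
#'   exceeds 0.5, else `N`).
#' @export
pwm <- function(name, probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) rownames(probs) <- DNA_BASES4
  probs <- probs[DNA_BASES4, , drop = FALSE]
  if (ncol(probs) < 4) stopf("PWM '%s': motif length must be >= 4", name)
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stopf("PWM '%s': columns must each sum to 1", name)
  }
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  structure(list(name = name, probs = probs,
                 background = as.numeric(background),
                 pseudocount = pseudocount,
                 consensus = pwm_consensus(probs)),
            class = "pwm")
}

pwm_consensus <- function(probs) {
  paste(vapply(seq_len(ncol(probs)), function(j) {
    i <- which.max(probs[, j])
    if (probs[i, j] > 0.5) DNA_BASES4[i] else "N"
  }, ""), collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (length %d, consensus %s)\n",
              x$name, ncol(x$probs), x$consensus))
  print(round(x$probs, 3))
  invisible(x)
}

motif_length <- function(pwm) ncol(pwm$probs)

#' Log-odds score matrix of a PWM
#'
#' `log2((p + pc) / (bg + pc))` per cell, so a column identical to the
#' background scores 0 everywhere.
#' @param pwm A [pwm()] object.
#' @return 4 x L numeric matrix (bits).
#' @export
score_matrix <- function(pwm) {
  log2((pwm$probs + pwm$pseudocount) /
         (pwm$background + pwm$pseudocount))
}

#' Highest-scoring site of a motif
#'
#' The sequence maximizing the log-odds score (per-column argmax); used for
#' planting exact sites in simulations and as the wild-type site in
#' mutagenesis design.
#' @param pwm A [pwm()] object.
#' @return Character string of the motif length.
#' @export
best_site <- function(pwm) {
  S <- score_matrix(pwm)
  paste(DNA_BASES4[apply(S, 2, which.max)], collapse = "")
}

#' Per-position information content of a motif
#'
#' `IC_l = 2 + sum_b p_bl * log2(p_bl)` against a uniform background, with
#' `0 * log(0) := 0`. Values lie in `[0, 2]` bits.
#'
#' @param pwm A [pwm()] object (or a bare 4 x L probability matrix).
#' @return Numeric vector of length L.
#' @export
info_content <- function(pwm) {
  p <- if (inherits(pwm, "pwm")) pwm$probs else as.matrix(pwm)
  t <- p * log2(p)
  t[p == 0] <- 0
  as.numeric(2 + colSums(t))
}

#' Exact null distribution of the motif score
#'
#' Convolves the per-column score distributions under the background base
#' model on a discretized score grid. This reproduces patser-style exact
#' p-values without enumerating all 4^L sequences.
#'
#' @param pwm A [pwm()] object.
#' @param binwidth Score discretization (bits); default 0.01.
#' @return List with `scores` (bin centers, bits), `probs` (summing to 1) and
#'   `binwidth`.
#' @export
score_distribution <- function(pwm, binwidth = 0.01) {
  S <- score_matrix(pwm)
  B <- round(S / binwidth)
  bg <- pwm$background
  dist <- 1
  offset <- 0L
  for (l in seq_len(ncol(B))) {
    cb <- as.integer(B[, l])
    lo <- min(cb)
    new <- numeric(length(dist) + max(cb) - lo)
    for (b in 1:4) {
      sh <- cb[b] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + bg[b] * dist
    }
    dist <- new
    offset <- offset + lo
  }
  list(scores = (offset + seq_along(dist) - 1) * binwidth,
       probs = dist, binwidth = binwidth)
}

#' Score threshold at a target exact p-value
#'
#' The smallest attainable score `s` with `P(score >= s) <= p` under the
#' background model. Returns `Inf` with a warning when no attainable score is
#' rare enough (e.g. a PWM identical to the background, whose every sequence
#' scores 0).
#'
#' @param pwm A [pwm()] object.
#' @param p Target p-value in (0, 1].
#' @param binwidth Score discretization (bits).
#' @return Scalar threshold in bits (possibly `Inf`).
#' @export
score_threshold <- function(pwm, p = 0.001, binwidth = 0.01) {
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    stopf("p must be a single value in (0, 1]")
  }
  d <- score_distribution(pwm, binwidth)
  tail <- rev(cumsum(rev(d$probs)))
  cand <- which(tail <= p + 1e-12 & d$probs > 0)
  if (!length(cand)) {
    warnf("PWM '%s': no attainable score reaches p <= %g; threshold is Inf",
          pwm$name, p)
    return(Inf)
  }
  d$scores[cand[1]]
}

# tail probability of an observed score, from a score_distribution()
score_pvalue <- function(dist, score) {
  tail <- rev(cumsum(rev(dist$probs)))
  minpos <- min(tail[tail > 0])
  bin <- round(score / dist$binwidth) - round(dist$scores[1] / dist$binwidth) + 1
  bin <- pmin(pmax(bin, 1L), length(tail))
  p <- tail[bin]
  p[score > dist$scores[length(dist$scores)] + dist$binwidth / 2] <- minpos
  pmin(pmax(p, minpos), 1)
}

#' Scan a sequence for motif hits with exact p-values
#'
#' Slides the PWM over both strands and reports windows whose log-odds score
#' meets [score_threshold()] at the requested p-value. Windows containing any
#' non-ACGT base are skipped. Minus-strand hits are reported in forward
#' coordinates: `offset` is the 0-based start of the matched window on the
#' given sequence.
#'
#' @param sequence Character string or `DNAString` over A/C/G/T/N.
#' @param pwm A [pwm()] object.
#' @param p Exact p-value cutoff (default 0.001).
#' @param require_consensus_match If `TRUE`, the window must additionally
#'   agree with the consensus at every majority-base position (probability
#'   > 0.5).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @param binwidth Score discretization for the null distribution.
#' @param seqname Optional sequence identifier carried into the output.
#' @return data.frame with columns `seqname`, `offset`, `strand`, `score`,
#'   `pvalue`, `tf`; zero rows when nothing passes (or the sequence is shorter
#'   than the motif).
#' @export
scan_pwm <- function(sequence, pwm, p = 0.001, require_consensus_match = FALSE,
                     both_strands = TRUE, binwidth = 0.01, seqname = NA_character_) {
  v <- dna_to_int(sequence)
  L <- motif_length(pwm)
  empty <- data.frame(seqname = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), tf = character(),
                      stringsAsFactors = FALSE)
  if (length(v) < L) return(empty)
  dist <- score_distribution(pwm, binwidth)
  thr <- {
    tail <- rev(cumsum(rev(dist$probs)))
    cand <- which(tail <= p + 1e-12 & dist$probs > 0)
    if (!length(cand)) Inf else dist$scores[cand[1]]
  }
  if (!is.finite(thr)) return(empty)
  S <- score_matrix(pwm)
  cons_idx <- which(apply(pwm$probs, 2, max) > 0.5)
  cons_base <- apply(pwm$probs, 2, which.max)

  scan_strand <- function(vv) {
    nw <- length(vv) - L + 1L
    sc <- numeric(nw)
    for (l in 0:(L - 1L)) {
      idx <- vv[(1L + l):(nw + l)]
      sc <- sc + S[cbind(idx, l + 1L)]  # NA (from N) propagates
    }
    keep <- !is.na(sc) & sc >= thr - 1e-12
    if (require_consensus_match && any(keep)) {
      for (l in cons_idx) {
        m <- vv[(0L + l):(nw + l - 1L)] == cons_base[l]
        m[is.na(m)] <- FALSE
        keep <- keep & m
      }
    }
    list(offset = which(keep) - 1L, score = sc[keep])
  }

  fwd <- scan_strand(v)
  res <- data.frame(seqname = rep(seqname, length(fwd$offset)),
                    offset = fwd$offset, strand = rep("+", length(fwd$offset)),
                    score = fwd$score, stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- scan_strand(revcomp_int(v))
    if (length(rev$offset)) {
      res <- rbind(res, data.frame(seqname = rep(seqname, length(rev$offset)),
                                   offset = length(v) - rev$offset - L,
                                   strand = "-", score = rev$score,
                                   stringsAsFactors = FALSE))
    }
  }
  if (!nrow(res)) return(empty)
  res$pvalue <- score_pvalue(dist, res$score)
  res$tf <- pwm$name
  res[order(res$offset, res$strand), , drop = FALSE]
}

#' Scan a sequence against a library of PWMs
#'
#' @inheritParams scan_pwm
#' @param pwm_library Named list of [pwm()] objects.
#' @return Row-bound data.frame of [scan_pwm()] results.
#' @export
scan_pwm_library <- function(sequence, pwm_library, p = 0.001,
                             require_consensus_match = FALSE,
                             both_strands = TRUE, seqname = NA_character_) {
  do.call(rbind, lapply(pwm_library, function(m) {
    scan_pwm(sequence, m, p = p,
             require_consensus_match = require_consensus_match,
             both_strands = both_strands, seqname = seqname)
  }))
}

#' Detect an Esrrb/Klf4/Sox2 (EKS) motif module in a TE
#'
#' A module is called present when the element carries at least one hit for
#' each required TF and those hits all start within the upstream part of the
#' element. "Upstream" is taken strand-aware: the 5' fraction of the element
#' on its annotated strand.
#'
#' @param hits data.frame from [scan_pwm_library()] computed on the element's
#'   own sequence (forward = element orientation).
#' @param element_length Element length in bp.
#' @param element_strand `"+"` or `"-"`; for `"-"` the upstream region is the
#'   right-hand fraction in the coordinates of `hits`.
#' @param upstream_fraction Fraction of the element counted as upstream
#'   (default 0.5, i.e. the 5' half).
#' @param required_tfs TF names that must all be present (default EKS).
#' @return List with `present` (logical) and `members` (the qualifying hits).
#' @export
detect_eks_module <- function(hits, element_length, element_strand = "+",
                              upstream_fraction = 0.5,
                              required_tfs = c("Esrrb", "Klf4", "Sox2")) {
  if (is.null(hits) || !nrow(hits)) {
    return(list(present = FALSE, members = hits))
  }
  cutoff <- upstream_fraction * element_length
  in_up <- if (identical(element_strand, "-")) {
    hits$offset >= element_length - cutoff
  } else {
    hits$offset < cutoff
  }
  members <- hits[in_up & hits$tf %in% required_tfs, , drop = FALSE]
  list(present = all(required_tfs %in% members$tf), members = members)
}

#' Design motif-disrupting mutations guided by information content
#'
#' Selects the `max_mutations` highest-information-content positions of the
#' motif (ties broken leftmost) and replaces the site base at each with the
#' least informative nucleotide of that column (ties broken alphabetically
#' A < C < G < T); if the site already carries that base, the next-least
#' informative one is used, so every replacement differs from the original.
#'
#' @param pwm A [pwm()] object.
#' @param site_sequence The bound site, same length as the motif.
#' @param max_mutations Maximum substitutions to introduce (default 4).
#' @return An object of class `mutation_plan`: list with `tf`, `positions`
#'   (data.frame of 0-based `position`, `original`, `replacement`, in order of
#'   decreasing information content), `original_sequence`,
#'   `mutated_sequence`.
#' @export
design_mutations <- function(pwm, site_sequence, max_mutations = 4) {
  L <- motif_length(pwm)
  site <- toupper(as.character(site_sequence))
  if (nchar(site) != L) {
    stopf("site sequence length (%d) must equal motif length (%d)",
          nchar(site), L)
  }
  if (max_mutations < 0) stopf("max_mutations must be >= 0")
  ic <- info_content(pwm)
  plan <- data.frame(position = integer(), original = character(),
                     replacement = character(), stringsAsFactors = FALSE)
  mutated <- site
  if (max_mutations > 0) {
    if (all(ic <= 1e-9)) {
      stopf("PWM '%s' is uniform at every position: no informative position to mutate",
            pwm$name)
    }
    sel <- order(-ic, seq_len(L))[seq_len(min(max_mutations, L))]
    chars <- strsplit(site, "")[[1]]
    repl <- character(length(sel))
    for (i in seq_along(sel)) {
      col <- pwm$probs[, sel[i]]
      ord <- order(col, seq_len(4))  # ascending probability, then A<C<G<T
      least <- DNA_BASES4[ord[1]]
      if (identical(chars[sel[i]], least)) least <- DNA_BASES4[ord[2]]
      repl[i] <- least
    }
    plan <- data.frame(position = sel - 1L, original = chars[sel],
                       replacement = repl, stringsAsFactors = FALSE)
    chars[sel] <- repl
    mutated <- paste(chars, collapse = "")
  }
  structure(list(tf = pwm$name, positions = plan,
                 original_sequence = site, mutated_sequence = mutated),
            class = "mutation_plan")
}

#' @export
print.mutation_plan <- function(x, ...) {
  cat(sprintf("mutation plan for %s: %s -> %s (%d substitution(s))\n",
              x$tf, x$original_sequence, x$mutated_sequence,
              nrow(x$positions)))
  if (nrow(x$positions)) print(x$positions)
  invisible(x)
}

#' Check that designed mutations create no new TF-binding motif
#'
#' Rescans the mutated sequence against a whole motif library and fails if a
#' hit overlapping a mutated position appears that was absent at the same
#' (offset, strand, TF) in the original sequence. This is the self-contained
#' replacement for an external motif-comparison step: it tests the property
#' that matters, namely that the designed substitutions do not gain a binding
#' site.
#'
#' @param original,mutated Equal-length sequences before/after mutation.
#' @param mutated_positions 0-based positions (on the full sequence) where
#'   bases were changed; an empty vector passes vacuously.
#' @param pwm_library Named list of [pwm()] objects.
#' @param p Scan p-value cutoff (default 0.001).
#' @return List with `pass` (logical) and `offending_hits` (data.frame).
#' @export
verify_no_new_motif <- function(original, mutated, mutated_positions,
                                pwm_library, p = 0.001) {
  if (!length(pwm_library)) stopf("pwm_library must be non-empty")
  if (!length(mutated_positions)) {
    return(list(pass = TRUE, offending_hits = NULL))
  }
  offending <- NULL
  for (m in pwm_library) {
    h0 <- scan_pwm(original, m, p = p)
    h1 <- scan_pwm(mutated, m, p = p)
    if (!nrow(h1)) next
    key0 <- paste(h0$tf, h0$strand, h0$offset)
    key1 <- paste(h1$tf, h1$strand, h1$offset)
    new <- h1[!key1 %in% key0, , drop = FALSE]
    if (!nrow(new)) next
    L <- motif_length(m)
    touches <- vapply(new$offset, function(o) {
      any(mutated_positions >= o & mutated_positions < o + L)
    }, logical(1))
    offending <- rbind(offending, new[touches, , drop = FALSE])
  }
  list(pass = is.null(offending) || nrow(offending) == 0,
       offending_hits = offending)
}
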