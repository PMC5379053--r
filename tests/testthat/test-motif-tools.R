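# PWM machinery: information content, exact score distributions, scanning,
# EKS-module detection, mutagenesis design and no-new-motif verification.

test_that("information content reproduces closed-form column values", {
  m <- make_pwm("ic", list(uniform_col(),
                           c(1, 0, 0, 0),
                           c(0.5, 0.5, 0, 0),
                           dom_col("T", 0.7)))
  ic <- info_content(m)
  expect_equal(ic[1], 0)
  expect_equal(ic[2], 2)
  expect_equal(ic[3], 1)
  expect_true(ic[4] > 0 && ic[4] < 2)
})

test_that("exact score distribution is a proper distribution", {
  for (m in c(tf_library, list(small_pwm(4)))) {
    d <- score_distribution(m)
    expect_equal(sum(d$probs), 1, tolerance = 1e-9)
    expect_true(all(d$probs >= 0))
  }
})

test_that("score threshold is monotone non-increasing in p", {
  m <- tf_library$Sox2
  ps <- c(0.5, 0.1, 0.01, 0.001, 1e-4)
  thr <- vapply(ps, function(p) score_threshold(m, p), numeric(1))
  expect_true(all(diff(thr) >= 0))  # smaller p -> higher threshold
})

test_that("convolution distribution agrees with brute-force enumeration", {
  m <- small_pwm(4)
  bf <- brute_force_scores(m)
  thr <- score_threshold(m, 0.01)
  # brute-force tail at the reported threshold honors the cutoff
  expect_lte(sum(bf$probs[bf$scores >= thr - 1e-9]), 0.01 + 1e-9)
  # the convolution tail matches the enumerated tail at every exact score
  d <- score_distribution(m)
  for (s in sample(unique(bf$scores), 20)) {
    exact <- sum(bf$probs[bf$scores >= s - 1e-9])
    conv <- sum(d$probs[d$scores >= s - d$binwidth / 2 - 1e-9])
    expect_equal(conv, exact, tolerance = 2e-3)
  }
})

test_that("degenerate background-equal PWM has no attainable threshold", {
  m <- make_pwm("null", rep(list(uniform_col()), 4))
  expect_warning(thr <- score_threshold(m, 0.001), "Inf")
  expect_identical(thr, Inf)
})

test_that("p = 1 returns the minimum attainable score", {
  m <- small_pwm(4)
  bf <- brute_force_scores(m)
  expect_equal(score_threshold(m, 1), min(bf$scores), tolerance = 0.011)
})

test_that("scanning recovers a planted site on both strands", {
  set.seed(7)
  m <- tf_library$Klf4
  site <- best_site(m)
  seq <- paste0(rand_seq(40), site, rand_seq(40))
  hits <- scan_pwm(seq, m, p = 0.001)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))
  planted <- hits[hits$offset == 40 & hits$strand == "+", ]
  # reverse complement: same hit, minus strand, identical score
  rc_hits <- scan_pwm(revcomp_chr_test(seq), m, p = 0.001)
  off_rc <- nchar(seq) - 40 - nchar(site)
  match_rc <- rc_hits[rc_hits$offset == off_rc & rc_hits$strand == "-", ]
  expect_equal(nrow(match_rc), 1)
  expect_equal(match_rc$score, planted$score, tolerance = 1e-9)
})

test_that("all-N and too-short sequences give zero hits", {
  m <- tf_library$Sox2
  expect_equal(nrow(scan_pwm(strrep("N", 50), m)), 0)
  expect_equal(nrow(scan_pwm("ACG", m)), 0)
})

test_that("the consensus-best site attains the maximum possible score", {
  for (m in tf_library) {
    hits <- scan_pwm(best_site(m), m, p = 1, both_strands = FALSE)
    expect_equal(max(hits$score), sum(apply(score_matrix(m), 2, max)),
                 tolerance = 1e-9)
  }
})

test_that("consensus-match filtering discards near-threshold mismatches", {
  m <- tf_library$Oct4
  site <- best_site(m)
  # corrupt one strong consensus position; keep the rest intact
  chars <- strsplit(site, "")[[1]]
  chars[1] <- setdiff(c("A", "C", "G", "T"), chars[1])[1]
  mm <- paste(chars, collapse = "")
  h <- scan_pwm(mm, m, p = 0.05, require_consensus_match = TRUE,
                both_strands = FALSE)
  expect_false(any(h$offset == 0))
})

test_that("EKS module detection requires all three TFs in the upstream part", {
  hits <- function(...) {
    df <- data.frame(...)
    df$seqname <- NA; df$score <- 10; df$pvalue <- 1e-5
    df
  }
  h1 <- hits(tf = c("Esrrb", "Klf4", "Sox2"), offset = c(10, 40, 80),
             strand = "+")
  expect_true(detect_eks_module(h1, 300)$present)
  h2 <- hits(tf = c("Esrrb", "Klf4", "Sox2"), offset = c(10, 40, 200),
             strand = "+")
  expect_false(detect_eks_module(h2, 300)$present)
  h3 <- hits(tf = c("Klf4", "Sox2"), offset = c(10, 40), strand = "+")
  expect_false(detect_eks_module(h3, 300)$present)
  # minus-strand element: upstream is the right-hand half
  h4 <- hits(tf = c("Esrrb", "Klf4", "Sox2"), offset = c(160, 200, 280),
             strand = "+")
  expect_true(detect_eks_module(h4, 300, element_strand = "-")$present)
  expect_false(detect_eks_module(h4, 300, element_strand = "+")$present)
})

test_that("mutation design selects the top-IC positions with stated ties", {
  # IC ordering col1 > col4 > col3 > col6 > col2 > col5
  m <- make_pwm("ictest", list(c(1, 0, 0, 0),
                               dom_col("C", 0.55),
                               dom_col("G", 0.90),
                               dom_col("T", 0.97),
                               c(0.30, 0.24, 0.23, 0.23),
                               dom_col("A", 0.80)))
  plan <- design_mutations(m, best_site(m), max_mutations = 4)
  expect_setequal(plan$positions$position, c(0L, 3L, 2L, 5L))
  # order of selection follows decreasing IC
  expect_equal(plan$positions$position, c(0L, 3L, 2L, 5L))
  expect_true(all(plan$positions$replacement != plan$positions$original))
})

test_that("replacement is the least-informative base, alphabetical ties", {
  m <- make_pwm("rep", list(dom_col("A", 0.7), dom_col("A", 0.7),
                            dom_col("T", 0.7), dom_col("G", 0.7)))
  plan <- design_mutations(m, "AATG", max_mutations = 4)
  # site base A, least-informative tie C/G/T -> C
  expect_equal(plan$positions$replacement[plan$positions$position == 0], "C")
  # site base T at a T-dominant column: least of the tied A/C/G is A
  expect_equal(plan$positions$replacement[plan$positions$position == 2], "A")
})

test_that("ties in information content break to the leftmost position", {
  m <- make_pwm("tie", list(dom_col("A", 0.8), dom_col("C", 0.8),
                            dom_col("G", 0.8), dom_col("T", 0.8)))
  plan <- design_mutations(m, best_site(m), max_mutations = 2)
  expect_equal(plan$positions$position, c(0L, 1L))
})

test_that("degenerate designs are rejected; empty plans pass through", {
  uni <- make_pwm("uni", rep(list(uniform_col()), 4))
  expect_error(design_mutations(uni, "ACGT"), "uniform")
  m <- tf_library$Nanog
  plan0 <- design_mutations(m, best_site(m), max_mutations = 0)
  expect_equal(nrow(plan0$positions), 0)
  expect_equal(plan0$mutated_sequence, best_site(m))
})

test_that("no-new-motif verification passes destroy-only designs and catches gains", {
  set.seed(11)
  m <- tf_library$Sox2
  flank <- rand_seq(30)
  seq0 <- paste0(flank, best_site(m), rand_seq(30))
  plan <- design_mutations(m, best_site(m), max_mutations = 4)
  mut_site <- plan$mutated_sequence
  seq1 <- paste0(flank, mut_site, substr(seq0, 30 + nchar(mut_site) + 1, nchar(seq0)))
  chk <- verify_no_new_motif(seq0, seq1, 30 + plan$positions$position,
                             tf_library, p = 0.001)
  expect_true(chk$pass)
  # vacuous pass with an empty plan
  expect_true(verify_no_new_motif(seq0, seq0, integer(), tf_library)$pass)

  # adversarial design: the "mutations" complete a Klf4 site
  k <- tf_library$Klf4
  broken <- strsplit(best_site(k), "")[[1]]
  broken[c(2, 5, 7)] <- c("A", "C", "C")
  pre <- paste0("AAATTTAAAT", paste(broken, collapse = ""), "TTTAAATTTA")
  stopifnot(nrow(scan_pwm(pre, k, p = 0.001)) == 0)  # precondition
  post <- paste0("AAATTTAAAT", best_site(k), "TTTAAATTTA")
  chk2 <- verify_no_new_motif(pre, post, c(11, 14, 16), tf_library, p = 0.001)
  expect_false(chk2$pass)
  expect_true("Klf4" %in% chk2$offending_hits$tf)
})
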