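# Shared fixtures and independent oracles used across the suite.

tf_library <- load_pwm_library()

# build a PWM from probability columns given as a list of 4-vectors (A,C,G,T)
make_pwm <- function(name, cols, background = rep(0.25, 4),
                     pseudocount = 0.01) {
  probs <- do.call(cbind, cols)
  rownames(probs) <- c("A", "C", "G", "T")
  pwm(name, probs, background = background, pseudocount = pseudocount)
}

# dominant-base column with the remainder spread evenly
dom_col <- function(base, p) {
  v <- rep((1 - p) / 3, 4)
  v[match(base, c("A", "C", "G", "T"))] <- p
  v
}

uniform_col <- function() rep(0.25, 4)

# small non-uniform PWM for exhaustive-enumeration tests
small_pwm <- function(L = 4, name = "toy") {
  cols <- list(c(0.70, 0.10, 0.10, 0.10),
               c(0.05, 0.55, 0.25, 0.15),
               c(0.25, 0.25, 0.40, 0.10),
               c(0.10, 0.10, 0.10, 0.70),
               c(0.30, 0.30, 0.20, 0.20),
               c(0.15, 0.05, 0.60, 0.20))
  make_pwm(name, cols[seq_len(L)])
}

# ORACLE: brute-force enumeration of the motif-score distribution over all
# 4^L windows; returns exact scores and their background probabilities
brute_force_scores <- function(pwm) {
  S <- score_matrix(pwm)
  L <- ncol(S)
  grid <- do.call(expand.grid, rep(list(1:4), L))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (l in seq_len(L)) {
    scores <- scores + S[cbind(grid[[l]], l)]
    probs <- probs * pwm$background[grid[[l]]]
  }
  list(scores = scores, probs = probs)
}

# ORACLE: hypergeometric upper tail by exhaustive enumeration of all
# choose(N, n) draws (feasible for N <= 12)
hyper_enum <- function(k, n_draw, K_succ, N) {
  if (n_draw == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n_draw)
  succ <- colSums(subsets <= K_succ)  # items 1..K_succ are the successes
  mean(succ >= k)
}

# independent reverse complement (not the package's own helper)
revcomp_chr_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random sequence helper
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# tiny simulation config for fast tests
tiny_sim_config <- function(seed, n_subfamilies = 3L, copies = 30L,
                            genome_length = 3e5, fraction = 0.5,
                            ltr_n = 10L, rate = 0.05, ...) {
  sim_config(seed = seed, genome_length = genome_length,
             n_subfamilies = n_subfamilies, copies_per_subfamily = copies,
             substitution_rate = rate,
             planted_module = list(subfamily = "simLTR1",
                                   pwms = c("Esrrb", "Klf4", "Sox2"),
                                   fraction = fraction),
             ltr_pairs = list(n = ltr_n, time_myr = 13, rate = 5e-4,
                              internal_span = 2000L, ltr_length = 300L),
             pwm_library = tf_library, ...)
}
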