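# The synthetic-data generator: determinism, realized divergence, planted
# modules, LTR pairs, coverage and reporter outputs.

test_that("zero substitution rate reproduces the consensus exactly", {
  cfg <- tiny_sim_config(seed = 1, rate = 0, ltr_n = 0L, fraction = 0,
                         copies = 10L, genome_length = 1e5)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$truth$te_truth$divergence_p == 0))
  expect_true(all(sim$annotation$milliDiv == 0))
  # the placed copy really is the consensus (or its reverse complement)
  a <- sim$annotation[1, ]
  placed <- as.character(Biostrings::subseq(sim$genome[[a$chrom]],
                                            a$start + 1, a$end))
  if (a$strand == "-") placed <- revcomp_chr_test(placed)
  cons <- cfg$subfamilies[[1]]$consensus
  expect_equal(placed, cons)
})

test_that("realized divergence matches the binomial expectation", {
  cfg <- sim_config(seed = 2, genome_length = 2e6, n_subfamilies = 1L,
                    copies_per_subfamily = 200L, substitution_rate = 0.1,
                    planted_module = NULL, ltr_pairs = NULL,
                    pwm_library = tf_library)
  sim <- simulate_genome(cfg, materialize_sequence = FALSE)
  p_bar <- mean(sim$truth$te_truth$divergence_p)
  # binomial mean 0.1 with 3 SE over 200 copies x 300 sites
  expect_true(p_bar > 0.085 && p_bar < 0.115)
})

test_that("identical config and seed give byte-identical FASTA output", {
  cfg <- tiny_sim_config(seed = 3, copies = 10L, genome_length = 1e5,
                         ltr_n = 2L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(simulate_genome(cfg)$genome, f1)
  Biostrings::writeXStringSet(simulate_genome(cfg)$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("annotation rows = planted copies + 2 x LTR pairs", {
  cfg <- tiny_sim_config(seed = 4, copies = 15L, ltr_n = 7L,
                         genome_length = 2e5)
  sim <- simulate_genome(cfg, materialize_sequence = FALSE)
  expect_equal(nrow(sim$annotation), 3 * 15 + 2 * 7)
  expect_equal(nrow(sim$truth$ltr_truth), 7)
  # every planted entity lies within the genome
  expect_true(all(sim$annotation$start >= 0))
  expect_true(all(sim$annotation$end <= sim$seqlengths[sim$annotation$chrom]))
  # placements never overlap
  gr <- GenomicRanges::GRanges(sim$annotation$chrom,
                               IRanges::IRanges(sim$annotation$start + 1,
                                                sim$annotation$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr, gr) > 1), 0)
})

test_that("an overfull genome raises a capacity error", {
  cfg <- tiny_sim_config(seed = 5, copies = 30L, genome_length = 1000,
                         ltr_n = 0L)
  expect_error(simulate_genome(cfg, materialize_sequence = FALSE),
               "genome too small")
})

test_that("peaks: planted-only at rate 0; background varies with seed", {
  sim <- simulate_genome(tiny_sim_config(seed = 6), materialize_sequence = FALSE)
  p0 <- simulate_peaks(sim, background_rate = 0)
  expect_equal(nrow(p0), nrow(sim$truth$motif_truth))
  expect_true(all(p0$planted))
  pa <- simulate_peaks(sim, background_rate = 20, seed = 1)
  pb <- simulate_peaks(sim, background_rate = 20, seed = 2)
  strip <- function(df) { rownames(df) <- NULL; df }
  expect_false(identical(strip(pa[!pa$planted, c("start", "tf")]),
                         strip(pb[!pb$planted, c("start", "tf")])))
  expect_identical(strip(pa[pa$planted, ]), strip(pb[pb$planted, ]))
  # module carriers overlap peaks of 3 distinct TFs
  carriers <- sim$truth$te_truth[sim$truth$te_truth$module_carrier, ]
  for (i in seq_len(min(5, nrow(carriers)))) {
    ov <- p0$chrom == carriers$chrom[i] & p0$start < carriers$end[i] &
      p0$end > carriers$start[i]
    expect_equal(sort(unique(p0$tf[ov])), c("Esrrb", "Klf4", "Sox2"))
  }
})

test_that("simulated LTR pairs diverge as 2rT at low divergence", {
  spec <- list(n = 100, time_myr = 13, rate = 5e-4, ltr_length = 300)
  sim <- simulate_ltr_pairs(spec, seed = 31)
  d_bar <- mean(sim$truth$d_realized)
  expect_true(abs(d_bar - 2 * 5e-4 * 13) < 3 * sqrt(0.013 * 0.987 / (100 * 300)))
  # T = 0: the pair is identical
  sim0 <- simulate_ltr_pairs(list(n = 5, time_myr = 0, rate = 5e-4,
                                  ltr_length = 200), seed = 1)
  expect_true(all(sim0$truth$d_realized == 0))
  expect_equal(sim0$pairs[[1]]$ltr5, sim0$pairs[[1]]$ltr3)
})

test_that("LTR pairs placed in the genome pass the downstream 7-kb window", {
  cfg <- tiny_sim_config(seed = 7, ltr_n = 8L, genome_length = 3e5,
                         copies = 5L)
  sim <- simulate_genome(cfg, materialize_sequence = FALSE)
  ltrs <- sim$annotation[sim$annotation$repName == "simERV-LTR", ]
  pairs <- pair_ltrs(ltrs, max_span = 7000)
  expect_equal(nrow(pairs), 8)
  expect_true(all(pairs$span == 2000))
})

test_that("coverage is Poisson at background and boosted over carriers", {
  sim <- simulate_genome(tiny_sim_config(seed = 8, genome_length = 2e5,
                                         copies = 20L, ltr_n = 0L),
                         materialize_sequence = FALSE)
  # null: enrichment 1 -> flat Poisson everywhere
  tr1 <- simulate_coverage(sim, background = 20, enrichment = 1, seed = 1)
  w <- tr1$depth$chrS1[50001:53000]
  expect_lt(abs(mean(w) - 20), 4 * sqrt(20 / 3000))
  # enrichment 5 over a carrier TE
  tr5 <- simulate_coverage(sim, background = 20, enrichment = 5, seed = 1)
  carrier <- sim$truth$te_truth[sim$truth$te_truth$module_carrier, ][1, ]
  m <- mean(tr5$depth[[carrier$chrom]][(carrier$start + 1):carrier$end])
  expect_true(m > 4 * 20 && m < 6 * 20)
  # zero background -> all-zero track
  tr0 <- simulate_coverage(sim, background = 0, enrichment = 5, seed = 1)
  expect_true(all(tr0$depth$chrS1 == 0))
  expect_equal(tr0$library_size, 0)
})

test_that("reporter tables have the promised shape and recover fold changes", {
  constructs <- data.frame(construct = paste0("c", 1:5), class = "wt",
                           fold_change = c(1, 1, 1, 1, 1))
  sim <- simulate_reporter(list(basal = 1, depth = 1000, dispersion = 0.1,
                                barcodes = 8, replicates = 3,
                                fold_changes = c(wildtype = 1)),
                           constructs = constructs, seed = 55)
  # 5 constructs + basal reference, 8 barcodes x 3 replicates each
  expect_equal(nrow(sim$barcodes), 6 * 8 * 3)
  expect_true(all(sim$barcodes$dna_count >= 0))
  res <- cre_expression(sim$barcodes, "basal")
  fc <- res$fold_change[res$construct %in% constructs$construct]
  expect_true(all(fc > 0.9 & fc < 1.1))
  # dispersion 0 at high depth: per-barcode ratio ~ basal x fold change
  hi <- simulate_reporter(list(basal = 2, depth = 1e5, dispersion = 0,
                               barcodes = 8, replicates = 3,
                               fold_changes = c(wildtype = 3)), seed = 56)
  wt <- hi$barcodes[hi$barcodes$construct == "wildtype", ]
  ratios <- wt$cdna_count / wt$dna_count
  expect_true(all(abs(ratios - 2 * 3) / 6 < 0.01))
})

test_that("simulation respects config invariants", {
  expect_error(sim_config(), "seed")
  expect_error(tiny_sim_config(seed = 1, rate = 1.5), "rate")
  expect_error(sim_config(seed = 1, coverage = list(background = 10,
                                                    enrichment = 0.5),
                          pwm_library = tf_library), "enrichment")
})
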