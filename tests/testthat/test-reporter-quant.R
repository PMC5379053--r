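# Luciferase, barcoded reporter (CRE-seq) and delta-delta-Ct quantification.

luc_records <- function(construct, firefly, renilla, nexp = 3, ntech = 3) {
  grid <- expand.grid(experiment = seq_len(nexp), technical = seq_len(ntech))
  data.frame(construct = construct, firefly = firefly, renilla = renilla,
             experiment = grid$experiment, technical = grid$technical,
             stringsAsFactors = FALSE)
}

test_that("luciferase fold change is the F/R ratio normalized by empty", {
  rec <- luc_records("te1", 30, 3)
  empty <- luc_records("empty", 4, 2)
  out <- luciferase_fold_change(rec, empty)
  expect_equal(out$fold_change, 5)  # (30/3) / (4/2)
  # construct identical to empty -> fold change 1
  null <- luciferase_fold_change(luc_records("te2", 4, 2), empty)
  expect_equal(null$fold_change, 1)
})

test_that("fold change is invariant to rescaling both channels", {
  set.seed(12)
  rec <- luc_records("te1", stats::runif(9, 20, 40), stats::runif(9, 2, 4))
  empty <- luc_records("empty", stats::runif(9, 3, 5), stats::runif(9, 1, 2))
  base <- luciferase_fold_change(rec, empty)
  rec2 <- rec; rec2$firefly <- rec2$firefly * 7
  empty2 <- empty; empty2$firefly <- empty2$firefly * 7
  rec2$renilla <- rec2$renilla * 3; empty2$renilla <- empty2$renilla * 3
  scaled <- luciferase_fold_change(rec2, empty2)
  expect_equal(scaled$fold_change, base$fold_change, tolerance = 1e-12)
})

test_that("enhancer classification follows the >2 and >10 tiers", {
  empty <- luc_records("empty", 1, 1)
  fc <- function(x) luciferase_fold_change(luc_records("c", x, 1), empty)$class
  expect_equal(fc(1.2), "inactive")
  expect_equal(fc(2.5), "enhancer")
  expect_equal(fc(15), "strong_enhancer")
})

test_that("zero-renilla records are dropped with a warning", {
  rec <- luc_records("te1", 30, 3)
  rec$renilla[1] <- 0
  expect_warning(out <- luciferase_fold_change(rec, luc_records("empty", 2, 1)),
                 "renilla")
  expect_equal(out$fold_change, 5)
  allbad <- luc_records("te1", 30, 0)
  expect_error(suppressWarnings(
    luciferase_fold_change(allbad, luc_records("empty", 2, 1))), "dropped")
})

barcode_table <- function(construct, dna, cdna, nbar = 8, nrep = 3) {
  grid <- expand.grid(barcode = paste0("bc", seq_len(nbar)),
                      replicate = seq_len(nrep), stringsAsFactors = FALSE)
  data.frame(construct = construct, barcode = grid$barcode,
             replicate = grid$replicate, dna_count = dna, cdna_count = cdna,
             stringsAsFactors = FALSE)
}

test_that("CRE expression uses pseudocounted cDNA/DNA ratios over basal", {
  counts <- rbind(barcode_table("te1", 50, 100),
                  barcode_table("basal", 100, 50))
  out <- cre_expression(counts, basal_ids = "basal")
  expect_equal(out$fold_change[out$construct == "te1"],
               (100.5 / 50.5) / (50.5 / 100.5), tolerance = 1e-12)
  # cdna == dna for construct and basal -> fold change 1
  counts2 <- rbind(barcode_table("te1", 80, 80),
                   barcode_table("basal", 40, 40))
  out2 <- cre_expression(counts2, basal_ids = "basal")
  expect_equal(out2$fold_change[out2$construct == "te1"], 1)
})

test_that("low-DNA barcodes are excluded; empty constructs become missing", {
  counts <- rbind(barcode_table("te1", c(5, rep(50, 23)), 100),
                  barcode_table("basal", 100, 100))
  out <- cre_expression(counts, basal_ids = "basal", min_dna = 10)
  expect_equal(out$n_barcodes[out$construct == "te1"], 23L)
  gone <- rbind(barcode_table("te2", 2, 100), barcode_table("basal", 100, 100))
  expect_warning(out2 <- cre_expression(gone, basal_ids = "basal"),
                 "no retained barcode")
  expect_true(is.na(out2$fold_change[out2$construct == "te2"]))
})

test_that("CRE expression is invariant to row order", {
  set.seed(8)
  counts <- rbind(barcode_table("te1", stats::rpois(24, 100), stats::rpois(24, 300)),
                  barcode_table("basal", stats::rpois(24, 100), stats::rpois(24, 100)))
  a <- cre_expression(counts, "basal")
  b <- cre_expression(counts[sample.int(nrow(counts)), ], "basal")
  expect_equal(a$fold_change[order(a$construct)],
               b$fold_change[order(b$construct)], tolerance = 1e-12)
})

test_that("mutant effect pairs constructs and tests replicate expressions", {
  set.seed(10)
  sim <- simulate_reporter(list(basal = 1, depth = 1000, dispersion = 0.05,
                                barcodes = 8, replicates = 3,
                                fold_changes = c(wildtype = 4, mutant = 1.2)),
                           seed = 77)
  me <- mutant_effect(sim$barcodes, "mutant", "wildtype", "basal")
  expect_lt(abs(me$ratio - 0.3), 0.1)
  expect_lt(me$pvalue, 0.05)
  expect_error(mutant_effect(sim$barcodes, "nope", "wildtype", "basal"),
               "missing construct")
  # identical replicate sets: ratio 1, p ~ 1
  counts <- rbind(barcode_table("m", rep(c(90, 100, 110), each = 8), 200),
                  barcode_table("w", rep(c(90, 100, 110), each = 8), 200),
                  barcode_table("basal", 100, 100))
  same <- mutant_effect(counts, "m", "w", "basal")
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_gt(same$pvalue, 0.99)
})

test_that("delta-delta-Ct relative expression follows 2^(-ddCt)", {
  out <- ddct(24, 18, 25, 18)
  expect_equal(out$ddct, 1)
  expect_equal(out$relative_expression, 0.5)
  expect_equal(ddct(24, 18, 23, 18)$relative_expression, 2)
  # identical conditions -> 1 for any inputs
  expect_equal(ddct(21.3, 17.2, 21.3, 17.2)$relative_expression, 1)
  expect_equal(ddct(c(24, 25), c(18, 19), c(24, 25), c(18, 19))$relative_expression, 1)
  expect_error(ddct(-1, 18, 25, 18), "positive")
})
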