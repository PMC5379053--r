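# End-to-end orchestration on synthetic data: simulate -> cluster -> enrich
# -> scan -> age -> profile -> reporter, with a machine-readable manifest.

pipeline_defaults <- function() {
  list(seed = NULL,
       peak_extension = 200,      # bp, symmetric about the peak center
       cluster_gap = 100,         # bp between reference points
       motif_pvalue = 0.001,      # exact scan p-value cutoff
       min_elements = 10,         # reporting filter for enrichment rows
       lor_threshold = 4.5,       # flagging tier (bits)
       lor_strong = 6,            # 64-fold tier (bits)
       p_threshold = 0.001,       # hypergeometric cutoff
       max_span = 7000,           # bp between paired LTRs
       rate_fast = 0.012,         # substitutions/site/Myr (upper bound)
       rate_slow = 0.0005,        # substitutions/site/Myr (lower bound)
       gene_window = 50000,       # bp for TE-to-gene association
       profile_flank = 1500,      # bp either side of the TE center
       profile_bin = 50,          # bp per profile bin
       background_peak_rate = 10, # background peaks per Mb per TF
       min_dna = 10,              # barcode DNA-depth filter
       pseudocount = 0.5)         # barcode ratio pseudocount
}

#' Read a pipeline configuration file
#'
#' Plain `key: value` text; `#` starts a comment. Unknown keys are rejected.
#' See [run_pipeline()] for the keys and their defaults.
#'
#' @param file Path to the config file.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl(":", lines, fixed = TRUE)]
  out <- list()
  for (l in lines) {
    key <- trimws(sub(":.*$", "", l))
    val <- trimws(sub("^[^:]*:", "", l))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stopf("config must set a seed")
  chk <- function(cond, msg) if (!cond) stopf("invalid config: %s", msg)
  chk(config$cluster_gap >= 0, "cluster_gap must be >= 0")
  chk(config$peak_extension > 0 && config$peak_extension %% 2 == 0,
      "peak_extension must be even and positive")
  chk(config$motif_pvalue > 0 && config$motif_pvalue < 1,
      "motif_pvalue must be in (0, 1)")
  chk(config$min_elements >= 1, "min_elements must be >= 1")
  chk(config$p_threshold > 0 && config$p_threshold < 1,
      "p_threshold must be in (0, 1)")
  chk(config$max_span > 0, "max_span must be > 0")
  chk(config$rate_fast > 0 && config$rate_slow > 0 &&
        config$rate_fast >= config$rate_slow,
      "rates must be positive with rate_fast >= rate_slow")
  chk(config$gene_window >= 0, "gene_window must be >= 0")
  chk((2 * config$profile_flank) %% config$profile_bin == 0,
      "2*profile_flank must be a multiple of profile_bin")
  chk(config$background_peak_rate >= 0, "background_peak_rate must be >= 0")
  config
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic genome with known ground truth, then executes the
#' analysis stages in order: site clustering, subfamily enrichment, motif
#' scanning with EKS-module detection on the flagged subfamily, LTR-pair
#' insertion dating, epigenomic metaprofiles by TF-occupancy category, and
#' reporter quantification. Each stage writes a TSV under `out_dir`; a
#' `manifest.json` records the package version, seed, settings and row
#' counts, and suffices to reproduce the run bit-identically.
#'
#' @param config Named list of settings, or a path parsed by
#'   [read_pipeline_config()]. `seed` is mandatory; all other keys default to
#'   the values listed in the package configuration (200-bp peak extension,
#'   100-bp cluster gap, motif p < 0.001, >= 10-element filter, LOR tiers
#'   4.5 and 6, 7-kb LTR span, rate bounds 1.2%/0.05% per site per Myr,
#'   50-kb gene window, 50-bp bins with 1.5-kb flanks).
#' @param out_dir Output directory (created if needed).
#' @param sim_cfg Optional [sim_config()] overriding the default synthetic
#'   conditions (its seed is taken from the pipeline config).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, sim_cfg = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  config <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  # -- simulate ---------------------------------------------------------
  if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = seed)
  sim <- simulate_genome(sim_cfg)
  Biostrings::writeXStringSet(sim$genome, file.path(out_dir, "genome.fa"))
  write_rmsk(sim$annotation, file.path(out_dir, "te_annotation.tsv"))
  write_tsv(sim$truth$te_truth, file.path(out_dir, "truth_te.tsv"))
  peaks <- simulate_peaks(sim, background_rate = config$background_peak_rate,
                          peak_width = config$peak_extension,
                          seed = seed + 1L)
  write_tsv(peaks, file.path(out_dir, "peaks.tsv"))
  log_stage("simulate", "%d TE rows, %d peaks", nrow(sim$annotation),
            nrow(peaks))

  # -- cluster ----------------------------------------------------------
  sites <- tf_sites(peaks[, c("chrom", "start", "end", "tf")], "peak")
  sites <- extend_to_length(sites, config$peak_extension,
                            seqlengths = sim$seqlengths)
  clusters <- cluster_sites(sites, gap = config$cluster_gap)
  write_tsv(clusters[, setdiff(names(clusters), "members")],
            file.path(out_dir, "clusters.tsv"))
  log_stage("cluster", "%d sites -> %d clusters", nrow(sites), nrow(clusters))

  # -- enrich -----------------------------------------------------------
  n_tfs <- assign_clusters_to_tes(sim$annotation, clusters)
  enr <- enrichment_scan(n_tfs, sim$annotation,
                         min_elements = config$min_elements,
                         lor_threshold = config$lor_threshold,
                         p_threshold = config$p_threshold)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
  flagged <- unique(enr$repName[enr$flagged])
  log_stage("enrich", "%d/%d rows flagged (subfamilies: %s)",
            sum(enr$flagged), nrow(enr),
            if (length(flagged)) paste(flagged, collapse = ",") else "none")

  # -- scan (EKS modules on the flagged subfamily) ----------------------
  eks <- NULL
  if (length(flagged)) {
    focal <- sim$annotation$repName == flagged[1]
    idx <- which(focal)
    rows <- lapply(idx, function(i) {
      a <- sim$annotation[i, ]
      s <- as.character(Biostrings::subseq(sim$genome[[a$chrom]],
                                           a$start + 1, a$end))
      if (a$strand == "-") s <- revcomp_chr(s)
      hits <- scan_pwm_library(s, sim_cfg$pwm_library, p = config$motif_pvalue,
                               require_consensus_match = TRUE)
      mod <- detect_eks_module(hits, nchar(s), element_strand = "+")
      data.frame(chrom = a$chrom, start = a$start, end = a$end,
                 repName = a$repName, n_hits = if (is.null(hits)) 0L else nrow(hits),
                 eks_present = mod$present, stringsAsFactors = FALSE)
    })
    eks <- do.call(rbind, rows)
    write_tsv(eks, file.path(out_dir, "eks_modules.tsv"))
    log_stage("scan", "%d/%d elements of %s carry an EKS module",
              sum(eks$eks_present), nrow(eks), flagged[1])
  }

  # -- age --------------------------------------------------------------
  ages <- NULL
  ltr_rows <- sim$annotation[sim$annotation$repName == "simERV-LTR", ,
                             drop = FALSE]
  if (nrow(ltr_rows) >= 2) {
    pairs <- pair_ltrs(ltr_rows, max_span = config$max_span)
    pairs$d <- vapply(seq_len(nrow(pairs)), function(i) {
      g <- sim$genome[[pairs$chrom[i]]]
      ltr_divergence(
        as.character(Biostrings::subseq(g, pairs$start5[i] + 1, pairs$end5[i])),
        as.character(Biostrings::subseq(g, pairs$start3[i] + 1, pairs$end3[i])))
    }, numeric(1))
    pairs$T_fast <- insertion_time(pairs$d, config$rate_fast)
    pairs$T_slow <- insertion_time(pairs$d, config$rate_slow)
    write_tsv(pairs, file.path(out_dir, "ltr_pairs.tsv"))
    ages <- subfamily_age_summary(pairs, rates = c(fast = config$rate_fast,
                                                   slow = config$rate_slow))
    write_tsv(ages, file.path(out_dir, "insertion_ages.tsv"))
    log_stage("age", "%d pairs dated; median d = %.4f", nrow(pairs),
              stats::median(pairs$d))
  }

  # -- profile ----------------------------------------------------------
  track <- simulate_coverage(sim, seed = seed + 2L)
  write_bedgraph(track, file.path(out_dir, "coverage.bedgraph"))
  profiles <- category_profiles(sim$annotation, n_tfs, track,
                                mark = "simMark", cell_type = "simCell",
                                flank = config$profile_flank,
                                binsize = config$profile_bin)
  write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  log_stage("profile", "%d profile rows", nrow(profiles))

  # -- reporter ---------------------------------------------------------
  rep_sim <- simulate_reporter(sim_cfg, seed = seed + 3L)
  write_tsv(rep_sim$luciferase, file.path(out_dir, "luciferase.tsv"))
  write_tsv(rep_sim$barcodes, file.path(out_dir, "barcode_counts.tsv"))
  luc <- luciferase_fold_change(
    rep_sim$luciferase[rep_sim$luciferase$construct != "empty", ],
    rep_sim$luciferase[rep_sim$luciferase$construct == "empty", ])
  cre <- cre_expression(rep_sim$barcodes, basal_ids = "basal",
                        min_dna = config$min_dna,
                        pseudocount = config$pseudocount)
  write_tsv(luc, file.path(out_dir, "luciferase_potential.tsv"))
  write_tsv(cre, file.path(out_dir, "cre_potential.tsv"))
  effects <- NULL
  if (all(c("single_mutant", "wildtype") %in% rep_sim$barcodes$construct)) {
    me <- mutant_effect(rep_sim$barcodes, "single_mutant", "wildtype",
                        basal_ids = "basal", min_dna = config$min_dna,
                        pseudocount = config$pseudocount)
    effects <- data.frame(mutant = "single_mutant", wildtype = "wildtype",
                          ratio = me$ratio, pvalue = me$pvalue)
    write_tsv(effects, file.path(out_dir, "mutant_effects.tsv"))
  }
  log_stage("reporter", "%d constructs quantified", nrow(cre))

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    package = "tecrm",
    version = as.character(utils::packageVersion("tecrm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    settings = config,
    pwm_library = names(sim_cfg$pwm_library),
    rows = list(annotation = nrow(sim$annotation), peaks = nrow(peaks),
                clusters = nrow(clusters), enrichment = nrow(enr),
                flagged = sum(enr$flagged)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, peaks = peaks, clusters = clusters,
                 n_tfs = n_tfs, enrichment = enr, eks = eks, ages = ages,
                 profiles = profiles, luciferase = luc, cre = cre,
                 mutant_effects = effects, manifest = manifest))
}
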