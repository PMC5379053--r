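# Synthetic-data generator: a toy genome carrying TE subfamily copies mutated
# from a consensus, planted multi-TF motif modules in a chosen subfamily,
# paired LTRs diverged from a known insertion time, coverage enriched over
# module carriers, and reporter measurements with planted fold changes.
# Every output is accompanied by a ground-truth table.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the study conditions used throughout the package's tests:
#' a 5-Mb single-chromosome genome carrying six LTR-like subfamilies of 100
#' copies each (300-bp consensus, 5% per-site divergence), one subfamily with
#' an Esrrb/Klf4/Sox2 module planted in half of its copies, 100 LTR pairs
#' inserted 13 Myr ago at 5e-4 substitutions per site per Myr with a 6.5-kb
#' internal span, Poisson coverage at depth 20 with 5-fold enrichment over
#' module carriers, and reporter constructs measured at depth 1,000 with 8
#' barcodes and 3 replicates.
#'
#' Subfamily consensus sequences are drawn reproducibly from `seed`.
#'
#' @param seed Mandatory integer seed; the same config and seed reproduce all
#'   downstream outputs exactly.
#' @param genome_length Chromosome length in bp.
#' @param n_chromosomes Number of chromosomes (each `genome_length` bp).
#' @param subfamilies Optional list of subfamily specs, each a list with
#'   `name`, `consensus` (A/C/G/T string), `copies`, `rate` (per-site
#'   substitution probability in `[0, 1]`). When `NULL`, `n_subfamilies`
#'   random consensus sequences are generated.
#' @param n_subfamilies,copies_per_subfamily,consensus_length,substitution_rate
#'   Used to build the default subfamily specs.
#' @param planted_module List: `subfamily`, `pwms` (ordered TF names from
#'   `pwm_library`), `fraction` of copies carrying the module.
#' @param ltr_pairs List: `n`, `time_myr`, `rate` (substitutions per site per
#'   Myr), `internal_span` (bp between the paired LTRs), `ltr_length`.
#' @param coverage List: `background` (mean per-base depth), `enrichment`
#'   (multiplier over module carriers, `>= 1`).
#' @param reporter List: `basal` (mean cDNA/DNA ratio of the basal
#'   construct), `depth` (mean DNA reads per barcode), `dispersion` (log-
#'   normal sdlog of the biological noise), `barcodes`, `replicates`,
#'   `fold_changes` (named vector of planted fold changes per variant class).
#' @param pwm_library Named list of [pwm()] objects; defaults to the bundled
#'   synthetic library.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 5e6,
                       n_chromosomes = 1L,
                       subfamilies = NULL,
                       n_subfamilies = 6L,
                       copies_per_subfamily = 100L,
                       consensus_length = 300L,
                       substitution_rate = 0.05,
                       planted_module = list(subfamily = "simLTR1",
                                             pwms = c("Esrrb", "Klf4", "Sox2"),
                                             fraction = 0.5),
                       ltr_pairs = list(n = 100L, time_myr = 13,
                                        rate = 5e-4, internal_span = 6500L,
                                        ltr_length = 300L),
                       coverage = list(background = 20, enrichment = 5),
                       reporter = list(basal = 1, depth = 1000,
                                       dispersion = 0.1, barcodes = 8L,
                                       replicates = 3L,
                                       fold_changes = c(wildtype = 4,
                                                        single_mutant = 1.2,
                                                        triple_mutant = 1.2,
                                                        negative_control = 1)),
                       pwm_library = NULL) {
  if (missing(seed) || is.null(seed)) stopf("a seed is mandatory")
  if (genome_length < 1000) stopf("genome_length must be >= 1000 bp")
  if (n_chromosomes < 1) stopf("n_chromosomes must be >= 1")
  if (is.null(subfamilies)) {
    subfamilies <- with_preserved_seed(seed, {
      lapply(seq_len(n_subfamilies), function(i) {
        list(name = paste0("simLTR", i),
             consensus = int_to_dna(random_int_seq(consensus_length)),
             copies = as.integer(copies_per_subfamily),
             rate = substitution_rate)
      })
    })
  }
  for (sf in subfamilies) {
    if (!nzchar(sf$consensus) || grepl("[^ACGT]", sf$consensus)) {
      stopf("subfamily '%s': consensus must be non-empty A/C/G/T", sf$name)
    }
    if (sf$copies < 1) stopf("subfamily '%s': copies must be >= 1", sf$name)
    if (sf$rate < 0 || sf$rate > 1) stopf("subfamily '%s': rate must be in [0, 1]", sf$name)
  }
  if (!is.null(planted_module)) {
    if (!planted_module$subfamily %in% vapply(subfamilies, `[[`, "", "name")) {
      stopf("planted module subfamily '%s' is not a simulated subfamily",
            planted_module$subfamily)
    }
    if (planted_module$fraction < 0 || planted_module$fraction > 1) {
      stopf("planted module fraction must be in [0, 1]")
    }
  }
  if (!is.null(ltr_pairs) && ltr_pairs$n > 0) {
    if (ltr_pairs$time_myr < 0) stopf("LTR insertion time must be >= 0")
    if (ltr_pairs$rate <= 0) stopf("LTR mutation rate must be > 0")
  }
  if (coverage$enrichment < 1) stopf("coverage enrichment must be >= 1")
  if (any(reporter$fold_changes <= 0)) stopf("planted fold changes must be > 0")
  if (reporter$depth <= 0) stopf("reporter depth must be > 0")
  if (is.null(pwm_library)) pwm_library <- load_pwm_library()
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_chromosomes = as.integer(n_chromosomes),
                 subfamilies = subfamilies, planted_module = planted_module,
                 ltr_pairs = ltr_pairs, coverage = coverage,
                 reporter = reporter, pwm_library = pwm_library),
            class = "sim_config")
}

#' Simulate a toy genome with TE copies and ground truth
#'
#' Each TE copy is its subfamily consensus with i.i.d. per-site substitutions
#' (uniform over the three alternative bases), placed uniformly without
#' overlap by rejection sampling (at most 1,000 retries per copy; a genome
#' too small to host all copies raises a capacity error). Module-carrier
#' copies of the planted subfamily additionally contain one exact
#' best-scoring site per planted PWM, in order, in the upstream half of the
#' element (strand-aware). When LTR pairs are configured, each provirus
#' contributes two LTR annotation rows separated by the internal span.
#'
#' The annotation records the realized divergence of every placed copy
#' against its consensus (`milliDiv`, substitutions per 1,000 sites).
#'
#' @param config A [sim_config()].
#' @param materialize_sequence Build the genome sequence (`TRUE`); `FALSE`
#'   skips it for annotation-only workflows.
#' @return Object of class `te_simulation`: list with `genome`
#'   (`DNAStringSet` or `NULL`), `seqlengths`, `annotation` (rmsk-style
#'   data.frame), `truth` (list of `te_truth`, `motif_truth`, `ltr_truth`,
#'   `ltr_sequences`) and `config`.
#' @export
simulate_genome <- function(config, materialize_sequence = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(config$seed, simulate_genome_impl(config, materialize_sequence))
}

simulate_genome_impl <- function(config, materialize_sequence) {
  chroms <- paste0("chrS", seq_len(config$n_chromosomes))
  seqlengths <- stats::setNames(rep(config$genome_length, length(chroms)), chroms)
  genome <- if (materialize_sequence) {
    stats::setNames(lapply(seqlengths, random_int_seq), chroms)
  } else {
    NULL
  }
  occ <- stats::setNames(rep(list(matrix(numeric(0), ncol = 2)), length(chroms)),
                         chroms)

  # guard > 0 keeps a clear margin around the placed interval (used for
  # proviruses so that distinct insertions never fall within the downstream
  # LTR-pairing window of each other)
  place <- function(len, guard = 0L) {
    for (try in seq_len(1000L)) {
      chrom <- chroms[[sample.int(length(chroms), 1L)]]
      start <- sample.int(seqlengths[[chrom]] - len, 1L) - 1L  # 0-based
      m <- occ[[chrom]]
      lo <- max(0L, start - guard)
      hi <- min(seqlengths[[chrom]], start + len + guard)
      if (!nrow(m) || !any(lo < m[, 2] & hi > m[, 1])) {
        occ[[chrom]] <<- rbind(m, c(lo, hi))
        return(list(chrom = chrom, start = start, end = start + len))
      }
    }
    stopf("could not place a %d-bp element after 1000 retries: genome too small for the configured copies", len)
  }

  ann <- list()
  te_truth <- list()
  motif_truth <- list()

  pm <- config$planted_module
  planted_sites <- if (!is.null(pm)) {
    lapply(pm$pwms, function(tf) {
      m <- config$pwm_library[[tf]]
      if (is.null(m)) stopf("planted PWM '%s' missing from pwm_library", tf)
      list(tf = tf, site = best_site(m))
    })
  } else {
    NULL
  }

  # reserve the large guarded provirus blocks before the genome gets
  # fragmented by the scattered subfamily copies
  lp <- config$ltr_pairs
  ltr_locs <- NULL
  if (!is.null(lp) && lp$n > 0) {
    block <- 2L * lp$ltr_length + lp$internal_span
    ltr_locs <- lapply(seq_len(lp$n), function(i) place(block, guard = 7000L))
  }

  te_id <- 0L
  for (sf in config$subfamilies) {
    cons <- dna_to_int(sf$consensus)
    L <- length(cons)
    is_module_family <- !is.null(pm) && identical(sf$name, pm$subfamily)
    carriers <- if (is_module_family) {
      sort(sample.int(sf$copies, round(pm$fraction * sf$copies)))
    } else {
      integer()
    }
    for (cp in seq_len(sf$copies)) {
      te_id <- te_id + 1L
      id <- sprintf("te%05d", te_id)
      strand <- sample(c("+", "-"), 1L)
      v <- mutate_int(cons, sf$rate)
      carrier <- cp %in% carriers
      site_rows <- NULL
      if (carrier) {
        off <- 10L
        for (ps in planted_sites) {
          sv <- dna_to_int(ps$site)
          v[(off + 1):(off + length(sv))] <- sv
          site_rows <- rbind(site_rows,
                             data.frame(tf = ps$tf, offset = off,
                                        len = length(sv),
                                        stringsAsFactors = FALSE))
          off <- off + length(sv) + 25L
        }
        if (off > floor(L / 2)) {
          stopf("planted module does not fit the upstream half of a %d-bp consensus", L)
        }
      }
      p_real <- mean(v != cons)
      loc <- place(L)
      placed <- if (identical(strand, "-")) revcomp_int(v) else v
      if (!is.null(genome)) {
        genome[[loc$chrom]][(loc$start + 1):(loc$end)] <- placed
      }
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = loc$chrom, start = loc$start, end = loc$end, strand = strand,
        repName = sf$name, repClass = "LTR", repFamily = "simERVK",
        milliDiv = round(1000 * p_real), stringsAsFactors = FALSE)
      te_truth[[length(te_truth) + 1L]] <- data.frame(
        te_id = id, chrom = loc$chrom, start = loc$start, end = loc$end,
        strand = strand, repName = sf$name, module_carrier = carrier,
        divergence_p = p_real, stringsAsFactors = FALSE)
      if (!is.null(site_rows)) {
        # element offset -> genomic coordinates (strand-aware)
        gstart <- if (identical(strand, "+")) {
          loc$start + site_rows$offset
        } else {
          loc$end - site_rows$offset - site_rows$len
        }
        motif_truth[[length(motif_truth) + 1L]] <- data.frame(
          te_id = id, tf = site_rows$tf, chrom = loc$chrom, start = gstart,
          end = gstart + site_rows$len, strand = strand,
          element_offset = site_rows$offset, stringsAsFactors = FALSE)
      }
    }
  }

  ltr_truth <- NULL
  ltr_sequences <- NULL
  if (!is.null(lp) && lp$n > 0) {
    sim_pairs <- simulate_ltr_pairs(lp)
    ltr_sequences <- sim_pairs$pairs
    rows <- list()
    for (i in seq_len(lp$n)) {
      loc <- ltr_locs[[i]]
      s5 <- loc$start
      s3 <- loc$start + lp$ltr_length + lp$internal_span
      if (!is.null(genome)) {
        genome[[loc$chrom]][(s5 + 1):(s5 + lp$ltr_length)] <-
          dna_to_int(sim_pairs$pairs[[i]]$ltr5)
        genome[[loc$chrom]][(s3 + 1):(s3 + lp$ltr_length)] <-
          dna_to_int(sim_pairs$pairs[[i]]$ltr3)
      }
      for (s in c(s5, s3)) {
        ann[[length(ann) + 1L]] <- data.frame(
          chrom = loc$chrom, start = s, end = s + lp$ltr_length,
          strand = "+", repName = "simERV-LTR", repClass = "LTR",
          repFamily = "simERVK", milliDiv = NA_integer_,
          stringsAsFactors = FALSE)
      }
      rows[[i]] <- data.frame(pair = i, chrom = loc$chrom,
                              start5 = s5, end5 = s5 + lp$ltr_length,
                              start3 = s3, end3 = s3 + lp$ltr_length,
                              time_myr = lp$time_myr, rate = lp$rate,
                              d_realized = sim_pairs$truth$d_realized[i],
                              stringsAsFactors = FALSE)
    }
    ltr_truth <- do.call(rbind, rows)
  }

  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  genome_set <- NULL
  if (!is.null(genome)) {
    genome_set <- Biostrings::DNAStringSet(
      vapply(genome, int_to_dna, character(1)))
    names(genome_set) <- chroms
  }
  structure(list(genome = genome_set, seqlengths = seqlengths,
                 annotation = annotation,
                 truth = list(te_truth = do.call(rbind, te_truth),
                              motif_truth = if (length(motif_truth)) {
                                do.call(rbind, motif_truth)
                              } else {
                                NULL
                              },
                              ltr_truth = ltr_truth,
                              ltr_sequences = ltr_sequences),
                 config = config),
            class = "te_simulation")
}

#' @export
print.te_simulation <- function(x, ...) {
  cat(sprintf("te_simulation: %d chromosome(s) x %g bp, %d annotation rows (%d planted copies, %d LTR-pair rows)\n",
              length(x$seqlengths), x$seqlengths[[1]], nrow(x$annotation),
              nrow(x$truth$te_truth),
              if (is.null(x$truth$ltr_truth)) 0L else 2L * nrow(x$truth$ltr_truth)))
  invisible(x)
}

#' Simulate paired LTR sequences diverged from a known insertion time
#'
#' Each pair starts as one random ancestral LTR; the two copies then
#' independently accumulate i.i.d. substitutions with per-site probability
#' `rate * time_myr` (uniform over the three alternative bases), so the
#' expected pairwise difference is about `2 * rate * time_myr` at low
#' divergence.
#'
#' @param spec List with `n`, `time_myr`, `rate`, `ltr_length` (and
#'   `internal_span`, carried through for placement by [simulate_genome()]).
#' @param seed Optional seed (standalone use); inside [simulate_genome()] the
#'   config seed governs.
#' @return List with `pairs` (list of `list(ltr5, ltr3)` character sequences)
#'   and `truth` (data.frame with per-pair realized divergence `d_realized`).
#' @export
simulate_ltr_pairs <- function(spec, seed = NULL) {
  with_preserved_seed(seed, {
    q <- spec$rate * spec$time_myr
    if (q > 0.75) stopf("rate * time implies per-site substitution probability > 0.75")
    pairs <- vector("list", spec$n)
    d <- numeric(spec$n)
    for (i in seq_len(spec$n)) {
      anc <- random_int_seq(spec$ltr_length)
      a <- mutate_int(anc, q)
      b <- mutate_int(anc, q)
      d[i] <- mean(a != b)
      pairs[[i]] <- list(ltr5 = int_to_dna(a), ltr3 = int_to_dna(b))
    }
    list(pairs = pairs,
         truth = data.frame(pair = seq_len(spec$n), time_myr = spec$time_myr,
                            rate = spec$rate, d_realized = d))
  })
}

#' Simulate per-TF peak tables over a synthetic genome
#'
#' One peak is centered on every planted motif instance (for the TF of that
#' PWM); these planted peaks are deterministic given the simulation. Uniform
#' background peaks are added per TF at `background_rate` peaks per Mb,
#' governed by `seed`. All peaks are clipped to chromosome bounds.
#'
#' @param sim A `te_simulation` from [simulate_genome()].
#' @param background_rate Background peaks per Mb per TF (default 0).
#' @param peak_width Peak width in bp (default 200).
#' @param tfs TF names receiving background peaks; defaults to the PWM
#'   library of the simulation config.
#' @param seed Seed for the background component.
#' @return data.frame with `chrom`, `start`, `end`, `tf`, `planted`.
#' @export
simulate_peaks <- function(sim, background_rate = 0, peak_width = 200,
                           tfs = NULL, seed = NULL) {
  stopifnot(inherits(sim, "te_simulation"))
  tfs <- tfs %||% names(sim$config$pwm_library)
  half <- peak_width %/% 2
  planted <- NULL
  mt <- sim$truth$motif_truth
  if (!is.null(mt) && nrow(mt)) {
    center <- floor((mt$start + mt$end) / 2)
    lim <- sim$seqlengths[mt$chrom]
    planted <- data.frame(chrom = mt$chrom,
                          start = pmax(0, center - half),
                          end = pmin(as.numeric(lim), center + half),
                          tf = mt$tf, planted = TRUE,
                          stringsAsFactors = FALSE)
  }
  background <- NULL
  if (background_rate > 0) {
    background <- with_preserved_seed(seed, {
      rows <- list()
      for (tf in tfs) {
        for (chrom in names(sim$seqlengths)) {
          len <- sim$seqlengths[[chrom]]
          n <- stats::rpois(1, background_rate * len / 1e6)
          if (n > 0) {
            center <- sample.int(len, n, replace = TRUE) - 1L
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, start = pmax(0, center - half),
              end = pmin(len, center + half), tf = tf, planted = FALSE,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    })
  }
  out <- rbind(planted, background)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), tf = character(), planted = logical(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an epigenomic coverage track over a synthetic genome
#'
#' Per-base Poisson depth at the background mean everywhere, with the mean
#' multiplied by the enrichment factor across module-carrier TEs. The track's
#' library size is the total of generated read-equivalents, for
#' reads-per-million normalization downstream.
#'
#' @param sim A `te_simulation`.
#' @param background Mean background depth; default from the sim config.
#' @param enrichment Multiplier over module carriers (`>= 1`); default from
#'   the sim config.
#' @param seed Optional seed.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(sim, background = NULL, enrichment = NULL,
                              seed = NULL) {
  stopifnot(inherits(sim, "te_simulation"))
  background <- background %||% sim$config$coverage$background
  enrichment <- enrichment %||% sim$config$coverage$enrichment
  if (enrichment < 1) stopf("enrichment must be >= 1")
  with_preserved_seed(seed, {
    depth <- lapply(sim$seqlengths, function(n) {
      if (background <= 0) numeric(n) else as.numeric(stats::rpois(n, background))
    })
    names(depth) <- names(sim$seqlengths)
    tt <- sim$truth$te_truth
    carriers <- tt[tt$module_carrier, , drop = FALSE]
    if (background > 0 && enrichment > 1 && nrow(carriers)) {
      for (i in seq_len(nrow(carriers))) {
        ix <- (carriers$start[i] + 1):carriers$end[i]
        depth[[carriers$chrom[i]]][ix] <-
          as.numeric(stats::rpois(length(ix), background * enrichment))
      }
    }
    coverage_track(depth)
  })
}

#' Simulate luciferase and barcoded reporter measurements
#'
#' Luciferase: renilla values are log-normal around 100; firefly equals
#' renilla times the basal ratio, the construct's planted fold change and
#' log-normal noise at the configured dispersion, so the construct's
#' firefly/renilla ratio over the empty vector equals the planted fold change
#' in expectation. Barcoded counts: per barcode and replicate, DNA reads are
#' Poisson at the sequencing depth and cDNA reads Poisson at `depth * basal *
#' fold change * lognormal(0, dispersion)`.
#'
#' @param spec Reporter spec list (see [sim_config()]) or a full
#'   `sim_config` (its `$reporter` is used).
#' @param constructs data.frame with `construct`, `class`, `fold_change`;
#'   defaults to one construct per configured variant class. An `empty`
#'   (luciferase) and `basal` (barcode) reference construct with fold change
#'   1 is always added.
#' @param seed Optional seed.
#' @return List with `luciferase`, `barcodes` and `truth` data.frames.
#' @export
simulate_reporter <- function(spec, constructs = NULL, seed = NULL) {
  if (inherits(spec, "sim_config")) spec <- spec$reporter
  if (any(spec$fold_changes <= 0)) stopf("fold changes must be > 0")
  if (spec$depth <= 0) stopf("depth must be > 0")
  if (is.null(constructs)) {
    constructs <- data.frame(construct = names(spec$fold_changes),
                             class = names(spec$fold_changes),
                             fold_change = unname(spec$fold_changes),
                             stringsAsFactors = FALSE)
  }
  with_preserved_seed(seed, {
    nrep <- spec$replicates %||% 3L
    nbar <- spec$barcodes %||% 8L
    ntech <- 3L
    all_luc <- rbind(constructs,
                     data.frame(construct = "empty", class = "empty",
                                fold_change = 1))
    luc <- do.call(rbind, lapply(seq_len(nrow(all_luc)), function(i) {
      fc <- all_luc$fold_change[i]
      grid <- expand.grid(experiment = seq_len(nrep),
                          technical = seq_len(ntech))
      ren <- stats::rlnorm(nrow(grid), meanlog = log(100), sdlog = 0.1)
      # the basal scale is shared by every construct (incl. the empty
      # vector), so the ratio over empty is the planted fold change
      fire <- ren * spec$basal * fc *
        stats::rlnorm(nrow(grid), meanlog = 0, sdlog = spec$dispersion)
      data.frame(construct = all_luc$construct[i],
                 firefly = fire, renilla = ren,
                 experiment = grid$experiment, technical = grid$technical,
                 stringsAsFactors = FALSE)
    }))
    all_bar <- rbind(constructs,
                     data.frame(construct = "basal", class = "basal",
                                fold_change = 1))
    bar <- do.call(rbind, lapply(seq_len(nrow(all_bar)), function(i) {
      fc <- all_bar$fold_change[i]
      grid <- expand.grid(barcode = paste0("bc", seq_len(nbar)),
                          replicate = seq_len(nrep),
                          stringsAsFactors = FALSE)
      mu <- spec$depth * spec$basal * fc *
        stats::rlnorm(nrow(grid), meanlog = 0, sdlog = spec$dispersion)
      data.frame(construct = all_bar$construct[i], barcode = grid$barcode,
                 replicate = grid$replicate,
                 dna_count = stats::rpois(nrow(grid), spec$depth),
                 cdna_count = stats::rpois(nrow(grid), mu),
                 stringsAsFactors = FALSE)
    }))
    list(luciferase = luc, barcodes = bar, truth = constructs)
  })
}
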