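# Coverage tracks and binned metaprofiles around TE centers.

#' Construct a per-base coverage track
#'
#' @param depth Named list of numeric vectors, one per chromosome, giving
#'   per-base read depth (position 1 = genomic position 0).
#' @param library_size Total read-equivalents for normalization; defaults to
#'   the sum of the track.
#' @return Object of class `coverage_track`.
#' @export
coverage_track <- function(depth, library_size = NULL) {
  if (is.null(names(depth)) || any(!nzchar(names(depth)))) {
    stopf("depth must be a named list of per-chromosome vectors")
  }
  if (any(vapply(depth, function(x) any(x < 0), logical(1)))) {
    stopf("coverage depth must be >= 0")
  }
  structure(list(depth = lapply(depth, as.numeric),
                 library_size = library_size %||% sum(unlist(depth))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosome(s), %d bp, library size %g\n",
              length(x$depth), sum(lengths(x$depth)), x$library_size))
  invisible(x)
}

#' Write a coverage track as bedGraph (+ library-size sidecar)
#'
#' Runs of constant depth are collapsed into bedGraph intervals. The library
#' size used for normalization is written next to the track as
#' `<file>.library.tsv`.
#'
#' @param track A [coverage_track()].
#' @param file Output bedGraph path.
#' @export
write_bedgraph <- function(track, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (chrom in names(track$depth)) {
    r <- rle(track$depth[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  write_tsv(data.frame(library_size = track$library_size),
            paste0(file, ".library.tsv"))
  invisible(file)
}

#' Read a bedGraph coverage track
#'
#' @param file bedGraph path.
#' @param seqlengths Named vector of chromosome lengths (zero-depth tails are
#'   restored from it).
#' @param library_size Optional; when `NULL`, read from the
#'   `<file>.library.tsv` sidecar if present, else the track sum.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(file, seqlengths, library_size = NULL) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  depth <- lapply(seqlengths, function(n) numeric(n))
  names(depth) <- names(seqlengths)
  for (i in seq_len(nrow(df))) {
    depth[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- df$value[i]
  }
  if (is.null(library_size)) {
    sidecar <- paste0(file, ".library.tsv")
    library_size <- if (file.exists(sidecar)) {
      read_tsv(sidecar)$library_size[1]
    } else {
      NULL
    }
  }
  coverage_track(depth, library_size)
}

#' Binned normalized coverage around a genomic point
#'
#' Splits the window `[center - flank, center + flank)` into `2*flank/binsize`
#' bins and returns the mean per-base depth of each, scaled to reads per
#' million by the track's library size. Bins falling outside the chromosome
#' are `NA`.
#'
#' @param track A [coverage_track()].
#' @param chrom Chromosome name.
#' @param center 0-based center position (for TEs, use
#'   `floor((start + end) / 2)`).
#' @param flank Half-window in bp (default 1,500).
#' @param binsize Bin width in bp (default 50).
#' @param normalize Scale to reads per million (`TRUE`); set `FALSE` for
#'   tracks that are already ratios (e.g. methylation levels).
#' @return Numeric vector of length `2*flank/binsize` (default 60).
#' @export
binned_profile <- function(track, chrom, center, flank = 1500, binsize = 50,
                           normalize = TRUE) {
  if ((2 * flank) %% binsize != 0) stopf("2*flank must be a multiple of binsize")
  depth <- track$depth[[as.character(chrom)]]
  if (is.null(depth)) stopf("chromosome '%s' not in track", chrom)
  n <- length(depth)
  if (center < 0 || center >= n) stopf("center %d is off chromosome '%s'", center, chrom)
  nb <- as.integer(2 * flank / binsize)
  scale <- if (normalize) 1e6 / track$library_size else 1
  vapply(seq_len(nb) - 1L, function(b) {
    s <- center - flank + b * binsize      # 0-based inclusive
    e <- s + binsize                       # exclusive
    if (s < 0 || e > n) return(NA_real_)
    mean(depth[(s + 1):e]) * scale
  }, numeric(1))
}

#' Mean metaprofiles by TF-occupancy category
#'
#' Groups TEs into the categories 0, 1 and 2+ bound TFs and averages
#' [binned_profile()] element-wise within each category (missing bins from
#' chromosome-edge truncation are excluded from the mean and reflected in the
#' per-bin `n`). Empty categories are omitted with a warning.
#'
#' @param tes TE annotation data.frame.
#' @param n_tfs Integer vector from [assign_clusters_to_tes()].
#' @param track A [coverage_track()].
#' @param mark,cell_type Labels carried into the output.
#' @inheritParams binned_profile
#' @return Long data.frame: `mark`, `cell_type`, `category`, `bin` (1-based),
#'   `offset_bp` (bin start relative to the TE center), `mean_density`, `n`
#'   (elements contributing to the bin), `n_elements` (category size).
#' @export
category_profiles <- function(tes, n_tfs, track, mark = "mark",
                              cell_type = "cell", flank = 1500, binsize = 50,
                              normalize = TRUE) {
  if (length(n_tfs) != nrow(tes)) stopf("n_tfs must match the TE table")
  category <- ifelse(n_tfs >= 2, "2+", as.character(n_tfs))
  centers <- as.integer(floor((tes$start + tes$end) / 2))
  nb <- as.integer(2 * flank / binsize)
  out <- list()
  for (cat in c("0", "1", "2+")) {
    ix <- which(category == cat)
    if (!length(ix)) {
      warnf("category '%s' has no elements; omitted", cat)
      next
    }
    mat <- t(vapply(ix, function(i) {
      binned_profile(track, tes$chrom[i], centers[i], flank = flank,
                     binsize = binsize, normalize = normalize)
    }, numeric(nb)))
    out[[length(out) + 1L]] <- data.frame(
      mark = mark, cell_type = cell_type, category = cat,
      bin = seq_len(nb),
      offset_bp = -flank + (seq_len(nb) - 1L) * binsize,
      mean_density = colMeans(mat, na.rm = TRUE),
      n = colSums(!is.na(mat)),
      n_elements = length(ix),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
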