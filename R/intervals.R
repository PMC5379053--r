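# Interval operations: peak extension, reference points, single-linkage
# clustering of TF-binding sites, TE overlap assignment, TE-to-gene
# association. All coordinates are 0-based half-open (BED convention).

#' Build a TF-binding-site table from peaks or motif hits
#'
#' Attaches the reference point used for clustering: the peak center
#' (`floor((start + end) / 2)`) for ChIP-seq peaks, or the motif start for
#' predicted binding motifs.
#'
#' @param df data.frame with `chrom`, `start`, `end`, `tf` (BED-style
#'   coordinates).
#' @param kind `"peak"` or `"motif"`.
#' @return The input with `kind` and `reference_point` columns added.
#' @export
tf_sites <- function(df, kind = c("peak", "motif")) {
  kind <- match.arg(kind)
  stopifnot(all(c("chrom", "start", "end", "tf") %in% names(df)))
  if (any(df$start >= df$end)) stopf("sites must satisfy start < end")
  df$kind <- kind
  df$reference_point <- if (kind == "peak") {
    as.integer(floor((df$start + df$end) / 2))
  } else {
    as.integer(df$start)
  }
  df
}

#' Extend binding sites symmetrically to a fixed width
#'
#' Each site becomes a window of `target_length` bp centered on its reference
#' point, clipped at position 0 and (when `seqlengths` is supplied) at the
#' chromosome end. Clipping does not re-center, so edge windows can be
#' shorter than `target_length`; such rows are flagged `truncated`.
#'
#' @param sites data.frame from [tf_sites()] (must carry `reference_point`).
#' @param target_length Even positive width in bp (default 200).
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return `sites` with updated `start`/`end` and a `truncated` flag; the
#'   reference point is unchanged.
#' @export
extend_to_length <- function(sites, target_length = 200, seqlengths = NULL) {
  if (target_length <= 0 || target_length %% 2 != 0) {
    stopf("target_length must be even and positive")
  }
  half <- target_length %/% 2
  ref <- sites$reference_point
  if (is.null(ref)) stopf("sites must carry a reference_point (see tf_sites())")
  start <- pmax(0L, as.integer(ref - half))
  end <- as.integer(ref + half)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[as.character(sites$chrom)]
    end <- pmin(end, as.integer(lim))
  }
  sites$start <- start
  sites$end <- end
  sites$truncated <- (end - start) < target_length
  sites
}

#' Cluster TF-binding sites within a reference-point distance
#'
#' Single-linkage chaining per chromosome on sorted reference points:
#' consecutive points at distance `<= gap` (boundary inclusive) join one
#' cluster. Singletons are returned too. `n_tfs` counts distinct TF names in
#' the cluster.
#'
#' @param sites data.frame from [tf_sites()].
#' @param gap Maximum distance between consecutive reference points
#'   (default 100 bp).
#' @return data.frame with one row per cluster: `cluster`, `chrom`, `start`,
#'   `end` (half-open span of the member reference points), `n_sites`,
#'   `n_tfs`, `tfs` (comma-joined sorted distinct names), and a list-column
#'   `members` of row indices into `sites`.
#' @export
cluster_sites <- function(sites, gap = 100) {
  if (gap < 0) stopf("gap must be >= 0")
  if (!nrow(sites)) {
    return(data.frame(cluster = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      n_sites = integer(), n_tfs = integer(),
                      tfs = character(), stringsAsFactors = FALSE))
  }
  ord <- order(sites$chrom, sites$reference_point)
  chrom <- sites$chrom[ord]
  ref <- sites$reference_point[ord]
  new_cluster <- c(TRUE, chrom[-1] != chrom[-length(chrom)] |
                     diff(ref) > gap)
  id <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_along(id), id), function(ix) {
    orig <- ord[ix]
    data.frame(chrom = chrom[ix[1]],
               start = min(ref[ix]),
               end = max(ref[ix]) + 1L,
               n_sites = length(ix),
               n_tfs = length(unique(sites$tf[orig])),
               tfs = paste(sort(unique(sites$tf[orig])), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$cluster <- seq_len(nrow(out))
  out$members <- unname(lapply(split(seq_along(id), id),
                               function(ix) ord[ix]))
  rownames(out) <- NULL
  out[, c("cluster", "chrom", "start", "end", "n_sites", "n_tfs", "tfs",
          "members")]
}

#' Count TFs bound on each TE from overlapping site clusters
#'
#' A TE is "bound by i TFs" when a cluster with `n_tfs = i` overlaps it by at
#' least 1 bp (half-open semantics). A TE overlapped by several clusters takes
#' the maximum `n_tfs`; TEs with no overlapping cluster get 0.
#'
#' @param tes TE annotation data.frame (`chrom`, `start`, `end`, ...).
#' @param clusters data.frame from [cluster_sites()].
#' @return Integer vector of length `nrow(tes)`.
#' @export
assign_clusters_to_tes <- function(tes, clusters) {
  n_tfs <- integer(nrow(tes))
  if (!nrow(clusters) || !nrow(tes)) return(n_tfs)
  gr_te <- df_to_granges(tes[, c("chrom", "start", "end")])
  gr_cl <- df_to_granges(clusters[, c("chrom", "start", "end")])
  hits <- GenomicRanges::findOverlaps(gr_te, gr_cl, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    agg <- tapply(clusters$n_tfs[s], q, max)
    n_tfs[as.integer(names(agg))] <- as.integer(agg)
  }
  n_tfs
}

#' Associate TEs with their closest gene within a distance cutoff
#'
#' Distance is 0 for overlapping features, otherwise the bp gap between the
#' nearest ends. Associations farther than `max_dist` are dropped (reported
#' as `NA`); ties are broken by the smaller gene start coordinate.
#'
#' @param tes TE annotation data.frame.
#' @param genes data.frame with `chrom`, `start`, `end`, `name`.
#' @param max_dist Maximum association distance in bp (default 50,000).
#' @return data.frame with one row per TE: `nearest_gene` and `distance`
#'   (`NA` when nothing is within `max_dist`).
#' @export
closest_gene <- function(tes, genes, max_dist = 50000) {
  if (!nrow(genes)) stopf("gene list must be non-empty")
  gr_te <- df_to_granges(tes[, c("chrom", "start", "end")])
  gr_gn <- df_to_granges(genes[, c("chrom", "start", "end")])
  gene <- rep(NA_character_, nrow(tes))
  dist <- rep(NA_real_, nrow(tes))
  for (i in seq_len(nrow(tes))) {
    on_chrom <- which(genes$chrom == tes$chrom[i])
    if (!length(on_chrom)) next
    d <- GenomicRanges::distance(gr_te[i], gr_gn[on_chrom],
                                 ignore.strand = TRUE)
    ok <- which(!is.na(d) & d <= max_dist)
    if (!length(ok)) next
    # minimal distance; ties resolve toward the smaller gene start
    best <- ok[order(d[ok], genes$start[on_chrom][ok])][1]
    gene[i] <- genes$name[on_chrom[best]]
    dist[i] <- d[best]
  }
  data.frame(nearest_gene = gene, distance = dist, stringsAsFactors = FALSE)
}
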