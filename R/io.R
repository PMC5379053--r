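# Readers/writers for the plain-text formats the pipeline exchanges:
# BED, rmsk-style TE annotation, bedGraph coverage, JASPAR matrices, TSV.

#' Read a BED3/BED6 file
#'
#' Coordinates are kept in BED convention: 0-based, half-open.
#'
#' @param file Path to a BED file (no header).
#' @return A data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:max(3, count_fields(file))],
                          fill = TRUE)
  df
}

count_fields <- function(file) {
  first <- readLines(file, n = 1L)
  if (!length(first)) return(3L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (0-based half-open).
#' @param file Output path.
#' @export
write_bed <- function(df, file) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: stop at the first missing one
  keep <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name", "score",
                                      "strand") %in% cols, nomatch = 7) - 1)]
  utils::write.table(df[, keep, drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read an rmsk-style TE annotation table
#'
#' Expects a TSV with header columns `chrom`, `genoStart`, `genoEnd`,
#' `strand`, `repName`, `repClass`, `repFamily`, `milliDiv`. `genoStart` is
#' treated as 0-based and `genoEnd` as half-open exclusive, matching both the
#' UCSC rmsk dump and BED semantics.
#'
#' @param file Path to the annotation TSV.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `repName`, `repClass`, `repFamily`, `milliDiv`.
#' @export
read_rmsk <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "genoStart", "genoEnd", "strand", "repName", "repClass",
            "repFamily", "milliDiv")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("rmsk file '%s' lacks column(s): %s", file,
          paste(missing, collapse = ", "))
  }
  data.frame(chrom = df$chrom, start = df$genoStart, end = df$genoEnd,
             strand = df$strand, repName = df$repName, repClass = df$repClass,
             repFamily = df$repFamily, milliDiv = df$milliDiv,
             stringsAsFactors = FALSE)
}

#' Write a TE annotation table in rmsk-style TSV
#'
#' @param tes data.frame as returned by [read_rmsk()] or [simulate_genome()].
#' @param file Output path.
#' @export
write_rmsk <- function(tes, file) {
  out <- data.frame(chrom = tes$chrom, genoStart = tes$start,
                    genoEnd = tes$end, strand = tes$strand,
                    repName = tes$repName, repClass = tes$repClass,
                    repFamily = tes$repFamily, milliDiv = tes$milliDiv)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the four-row bracketed JASPAR text format, e.g.
#' \preformatted{
#' >MA0001.1 TFname
#' A  [ 10  2 80 ... ]
#' C  [ ... ]
#' }
#' Counts (or probabilities) are normalized column-wise into a position
#' probability matrix.
#'
#' @param file Path to a JASPAR `.jaspar`/`.pfm` file (may contain several
#'   matrices).
#' @param background,pseudocount Passed to [pwm()].
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(file, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) stopf("no '>' header found in '%s'", file)
  out <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    last <- if (i < length(headers)) headers[i + 1] - 1L else length(lines)
    block <- lines[(h + 1):last]
    toks <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    name <- if (length(toks) >= 2) toks[2] else toks[1]
    rows <- lapply(block[1:4], function(l) {
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", l)
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l))
      list(base = toupper(base),
           vals = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- vapply(rows, `[[`, "", "base")
    mat <- mat[DNA_BASES4, , drop = FALSE]
    probs <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- pwm(name, probs, background = background,
                       pseudocount = pseudocount)
  }
  out
}

#' Load a directory of JASPAR matrices as a PWM library
#'
#' With no argument, loads the synthetic motif library bundled with the
#' package (`inst/extdata/pwms_synthetic`): hand-constructed stand-ins for the
#' five pluripotency factors (Esrrb, Klf4, Sox2, Oct4, Nanog), not curated
#' database matrices.
#'
#' @param dir Directory containing `.jaspar` files.
#' @return Named list of [pwm()] objects.
#' @export
load_pwm_library <- function(dir = system.file("extdata", "pwms_synthetic",
                                               package = "tecrm")) {
  files <- list.files(dir, pattern = "\\.(jaspar|pfm)$", full.names = TRUE)
  if (!length(files)) stopf("no JASPAR files under '%s'", dir)
  out <- list()
  for (f in files) out <- c(out, read_jaspar(f))
  out
}
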