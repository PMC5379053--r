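# Internal helpers shared across modules.

DNA_BASES4 <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulations do not perturb
#' unrelated randomness. A `NULL` seed evaluates the expression as-is.
#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# DNA as integer codes 1..4 == A,C,G,T; NA for anything else (N etc.)
dna_to_int <- function(x) {
  match(strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]], DNA_BASES4)
}

int_to_dna <- function(v) paste(DNA_BASES4[v], collapse = "")

# reverse complement on integer codes (A<->T, C<->G)
revcomp_int <- function(v) rev(5L - v)

revcomp_chr <- function(x) int_to_dna(revcomp_int(dna_to_int(x)))

#' i.i.d. substitutions on an integer-coded sequence
#'
#' Each site mutates independently with probability `rate`; the replacement is
#' uniform over the three alternative bases (Jukes-Cantor generative model).
#' @keywords internal
#' @noRd
mutate_int <- function(v, rate) {
  if (rate <= 0) return(v)
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- ((v[hit] - 1L + shift) %% 4L) + 1L
  }
  v
}

# random integer-coded sequence under a base composition
random_int_seq <- function(n, prob = rep(0.25, 4)) {
  sample.int(4L, n, replace = TRUE, prob = prob)
}

# 0-based half-open data.frame -> GRanges (1-based closed internally)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) {
      s <- df$strand
      s[!s %in% c("+", "-")] <- "*"
      s
    } else {
      "*"
    }
  )
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
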