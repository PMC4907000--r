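#' @importFrom stats rhyper rbinom rmultinom rpois runif setNames phyper
#'   fisher.test optim coef pbinom
#' @importFrom utils head modifyList
NULL

# Canonical row order used everywhere: count descending, then CDR3 nucleotide
# sequence lexicographic (C locale) so equal-count ties are reproducible.
canonical_order <- function(count, cdr3nt) {
  order(-count, cdr3nt, method = "radix")
}

#' Translate a CDR3 nucleotide sequence
#'
#' Standard-genetic-code translation of the first `floor(L/3)` codons from the
#' 5' end; a trailing incomplete codon is dropped and stop codons are rendered
#' `*`. Out-of-frame sequences are translated the same way for display.
#'
#' @param cdr3nt character vector of uppercase A/C/G/T sequences.
#' @return character vector of amino-acid sequences (may be `""` for inputs
#'   shorter than one codon).
#' @examples
#' translate_cdr3("TGTGCCAGCTTT")   # "CASF"
#' translate_cdr3("TGTGCCAGCTTTA")  # incomplete codon dropped
#' @export
translate_cdr3 <- function(cdr3nt) {
  if (length(cdr3nt) == 0L) return(character(0))
  if (any(is.na(cdr3nt)) || any(!nzchar(cdr3nt)))
    stop("cdr3nt must be non-empty")
  bad <- grepl("[^ACGT]", cdr3nt)
  if (any(bad))
    stop("invalid sequence (non-ACGT character): ",
         paste(utils::head(cdr3nt[bad], 3L), collapse = ", "))
  trimmed <- substr(cdr3nt, 1L, 3L * (nchar(cdr3nt) %/% 3L))
  out <- character(length(cdr3nt))
  nz <- nchar(trimmed) > 0L
  if (any(nz)) {
    aa <- Biostrings::translate(Biostrings::DNAStringSet(trimmed[nz]),
                                no.init.codon = TRUE)
    out[nz] <- as.character(aa)
  }
  out
}

#' Classify reading frame and functionality of CDR3 sequences
#'
#' A clonotype is out-of-frame iff its CDR3 nucleotide length is not a
#' multiple of 3; it is functional iff it is in-frame and its translation
#' contains no stop codon.
#'
#' @param cdr3nt character vector of CDR3 nucleotide sequences.
#' @param cdr3aa optional matching amino-acid sequences; translated from
#'   `cdr3nt` when missing.
#' @return data.frame with columns `frame` (`"in"`/`"out"`) and `functional`.
#' @export
classify_frame <- function(cdr3nt, cdr3aa = NULL) {
  frame <- ifelse(nchar(cdr3nt) %% 3L == 0L, "in", "out")
  if (is.null(cdr3aa)) cdr3aa <- translate_cdr3(cdr3nt)
  functional <- frame == "in" & !grepl("*", cdr3aa, fixed = TRUE)
  data.frame(frame = frame, functional = functional,
             stringsAsFactors = FALSE)
}

#' Construct a clonotype table
#'
#' The central container: one row per clonotype (read or UMI count, frequency,
#' CDR3 nucleotide/amino-acid sequence, V/D/J calls, optional V-(D)-J markup
#' within the CDR3 and per-base Phred+33 quality), held in canonical order
#' (count descending, CDR3nt lexicographic) with sample metadata attached as
#' attributes.
#'
#' Markup coordinates (`v_end`, `d_start`, `d_end`, `j_start`) are 0-based,
#' half-open positions within `cdr3nt`; `-1` encodes absence. Frame and
#' functionality are always derived from the sequence, never trusted from
#' input.
#'
#' @param x data.frame with at least `count` and `cdr3nt`; optional columns
#'   `cdr3aa`, `v`, `d`, `j`, `v_end`, `d_start`, `d_end`, `j_start`,
#'   `quality`.
#' @param sample_id sample identifier stored with the table.
#' @param source_format dialect the table was read from (metadata only).
#' @param normalize recompute `freq = count / sum(count)` (default `TRUE`).
#' @param sort reorder rows canonically (default `TRUE`).
#' @return object of class `clonotype_table` (a data.frame).
#' @export
clonotype_table <- function(x, sample_id = "sample",
                            source_format = "internal",
                            normalize = TRUE, sort = TRUE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(x$count) || is.null(x$cdr3nt))
    stop("clonotype table needs at least 'count' and 'cdr3nt' columns")
  n <- nrow(x)
  count <- x$count
  if (n > 0L) {
    if (any(is.na(count)) || any(count < 1) || any(count != round(count)))
      stop("counts must be positive integers")
    if (any(grepl("[^ACGT]", x$cdr3nt)))
      stop("cdr3nt must contain only A/C/G/T")
  }
  tbl <- data.frame(
    count   = as.numeric(count),
    freq    = if (!is.null(x$freq)) as.numeric(x$freq) else rep(NA_real_, n),
    cdr3nt  = as.character(x$cdr3nt),
    cdr3aa  = if (!is.null(x$cdr3aa)) as.character(x$cdr3aa) else
      translate_cdr3(x$cdr3nt),
    v       = norm_segment(if (!is.null(x$v)) x$v else rep(".", n)),
    d       = norm_segment(if (!is.null(x$d)) x$d else rep(".", n)),
    j       = norm_segment(if (!is.null(x$j)) x$j else rep(".", n)),
    v_end   = mk_markup(x$v_end, n),
    d_start = mk_markup(x$d_start, n),
    d_end   = mk_markup(x$d_end, n),
    j_start = mk_markup(x$j_start, n),
    quality = if (!is.null(x$quality)) as.character(x$quality) else
      rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (any(grepl("[^ACGT]", tbl$cdr3nt)))
      stop("cdr3nt must contain only A/C/G/T")
    len <- nchar(tbl$cdr3nt)
    qok <- is.na(tbl$quality) | nchar(tbl$quality) == len
    if (!all(qok))
      stop("quality string length must equal CDR3 length (rows ",
           paste(which(!qok), collapse = ","), ")")
    check_markup(tbl, len)
    cf <- classify_frame(tbl$cdr3nt, tbl$cdr3aa)
    tbl$frame <- cf$frame
    tbl$functional <- cf$functional
  } else {
    tbl$frame <- character(0)
    tbl$functional <- logical(0)
  }
  if (sort && n > 0L) tbl <- tbl[canonical_order(tbl$count, tbl$cdr3nt), ,
                                 drop = FALSE]
  rownames(tbl) <- NULL
  attr(tbl, "sample_id") <- sample_id
  attr(tbl, "source_format") <- source_format
  attr(tbl, "total_count") <- sum(tbl$count)
  class(tbl) <- c("clonotype_table", "data.frame")
  if (normalize && n > 0L) tbl <- normalize_frequencies(tbl)
  tbl
}

norm_segment <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "-", ".")] <- "."
  x
}

mk_markup <- function(x, n) {
  if (is.null(x)) return(rep(-1L, n))
  x <- as.integer(x)
  x[is.na(x)] <- -1L
  x
}

check_markup <- function(tbl, len) {
  m <- cbind(tbl$v_end, tbl$d_start, tbl$d_end, tbl$j_start, len)
  for (i in seq_len(nrow(m))) {
    v <- m[i, 1:4]
    v <- c(v[v >= 0L], m[i, 5])
    if (is.unsorted(v))
      stop("markup coordinates out of order in row ", i)
  }
  invisible(NULL)
}

#' @export
print.clonotype_table <- function(x, n = 6L, ...) {
  cat(sprintf("clonotype_table '%s': %d clonotypes, %d reads (%s)\n",
              attr(x, "sample_id"), nrow(x), attr(x, "total_count"),
              attr(x, "source_format")))
  if (nrow(x) > 0L)
    print(utils::head(as.data.frame(x)[, c("count", "freq", "cdr3nt",
                                           "cdr3aa", "v", "j")], n))
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Recompute clonotype frequencies from counts
#'
#' Sets `freq = count / total_count` leaving row order unchanged; idempotent.
#'
#' @param table a [clonotype_table()].
#' @return the table with frequencies recomputed.
#' @export
normalize_frequencies <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  total <- sum(table$count)
  table$freq <- table$count / total
  attr(table, "total_count") <- total
  table
}

# Rebuild a clonotype_table from a row subset, keeping metadata.
rebuild_table <- function(table, rows, normalize = TRUE) {
  df <- as.data.frame(table)[rows, , drop = FALSE]
  clonotype_table(df, sample_id = attr(table, "sample_id"),
                  source_format = attr(table, "source_format"),
                  normalize = normalize)
}

#' Per-sample repertoire summary
#'
#' Basic statistics of a single repertoire: read and clonotype totals,
#' out-of-frame read/clonotype fractions, the non-functional (out-of-frame or
#' stop-containing) read fraction, and the frequency-weighted mean CDR3
#' nucleotide length.
#'
#' @param table a normalized [clonotype_table()].
#' @return object of class `sample_summary` (a list).
#' @export
summarize_sample <- function(table) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  table <- normalize_frequencies(table)
  oof <- table$frame == "out"
  out <- list(
    sample_id = attr(table, "sample_id"),
    n_reads = sum(table$count),
    n_clonotypes = nrow(table),
    oof_read_fraction = sum(table$freq[oof]),
    oof_clonotype_fraction = mean(oof),
    nonfunctional_read_fraction = sum(table$freq[!table$functional]),
    mean_cdr3_length_weighted = sum(table$freq * nchar(table$cdr3nt))
  )
  class(out) <- "sample_summary"
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample '%s': %d reads, %d clonotypes\n", x$sample_id,
              x$n_reads, x$n_clonotypes))
  cat(sprintf("  out-of-frame: %.4f of reads, %.4f of clonotypes\n",
              x$oof_read_fraction, x$oof_clonotype_fraction))
  cat(sprintf("  non-functional read fraction: %.4f\n",
              x$nonfunctional_read_fraction))
  cat(sprintf("  mean CDR3 length (freq-weighted): %.2f nt\n",
              x$mean_cdr3_length_weighted))
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded by `seed` (NULL = use the
# current stream). Restores .Random.seed afterwards so callers' streams are
# unaffected.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Down-sample a clonotype table to a fixed read count
#'
#' Draws `m` reads without replacement (multivariate hypergeometric over the
#' clonotype counts), the sampling model for uniquely labeled cDNA molecules.
#' Clonotypes drawn zero times are removed; the output total is exactly `m`.
#'
#' @param table a [clonotype_table()].
#' @param m target read count, `1 <= m <= total_count`.
#' @param seed optional integer seed for reproducibility.
#' @return a down-sampled `clonotype_table`.
#' @export
downsample_table <- function(table, m, seed = NULL) {
  stopifnot(inherits(table, "clonotype_table"))
  if (nrow(table) == 0L) stop("empty clonotype table")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer")
  counts <- table$count
  n <- sum(counts)
  if (m > n) stop("sampling depth m = ", m, " exceeds total count ", n)
  drawn <- with_seed(seed, rmvhyper(counts, m))
  keep <- drawn > 0
  df <- as.data.frame(table)[keep, , drop = FALSE]
  df$count <- drawn[keep]
  clonotype_table(df, sample_id = attr(table, "sample_id"),
                  source_format = attr(table, "source_format"))
}

# One multivariate hypergeometric draw via sequential conditionals.
rmvhyper <- function(counts, m) {
  k <- length(counts)
  drawn <- numeric(k)
  left_n <- sum(counts)
  left_m <- m
  for (i in seq_len(k)) {
    if (left_m == 0) break
    other <- left_n - counts[i]
    x <- if (other == 0) left_m else rhyper(1L, counts[i], other, left_m)
    drawn[i] <- x
    left_m <- left_m - x
    left_n <- other
  }
  drawn
}
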