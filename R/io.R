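# Dialect adapters for clonotype tables exported by common Rep-Seq
# post-processing tools. Header signatures are frozen from each tool's public
# documentation; detection requires the signature to be a subset of the
# file's header columns, and signatures are mutually exclusive on real
# headers (MiTCR says "Read count" where MIGEC says "Count", etc.).

dialect_registry <- function() {
  list(
    internal = list(
      name = "internal",
      header_signature = c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j"),
      count_semantics = "reads"
    ),
    mitcr = list(
      name = "mitcr",
      header_signature = c("Read count", "Percentage",
                           "CDR3 nucleotide sequence",
                           "CDR3 amino acid sequence",
                           "V segments", "J segments"),
      count_semantics = "reads"
    ),
    migec = list(
      name = "migec",
      header_signature = c("Count", "Percentage",
                           "CDR3 nucleotide sequence",
                           "CDR3 amino acid sequence",
                           "V segments", "J segments"),
      count_semantics = "umi"
    ),
    mixcr = list(
      name = "mixcr",
      header_signature = c("cloneCount", "cloneFraction",
                           "nSeqCDR3", "aaSeqCDR3"),
      count_semantics = "reads"
    ),
    igblast_airr = list(
      name = "igblast_airr",
      header_signature = c("v_call", "j_call", "junction", "junction_aa"),
      count_semantics = "reads"
    ),
    imgt_hvq = list(
      name = "imgt_hvq",
      header_signature = c("Sequence ID", "V-GENE and allele",
                           "J-GENE and allele", "JUNCTION"),
      count_semantics = "reads"
    ),
    immunoseq = list(
      name = "immunoseq",
      header_signature = c("nucleotide", "aminoAcid",
                           "vGeneName", "jGeneName"),
      count_semantics = "templates"
    )
  )
}

#' Detect the dialect of a clonotype table from its header line
#'
#' Matches the tab-separated header against the frozen signatures of the
#' supported formats (internal, MiTCR, MIGEC, MiXCR, IgBlast/AIRR,
#' IMGT HighV-QUEST, ImmunoSEQ).
#'
#' @param header_line first non-comment line of the file.
#' @return a dialect identifier string.
#' @export
detect_format <- function(header_line) {
  cols <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  reg <- dialect_registry()
  hits <- names(reg)[vapply(reg, function(d)
    all(d$header_signature %in% cols), logical(1))]
  if (length(hits) == 0L)
    stop("unsupported format; observed columns: ",
         paste(cols, collapse = ", "))
  if (length(hits) > 1L)
    stop("ambiguous format; header matches dialects: ",
         paste(hits, collapse = ", "))
  hits
}

read_table_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

first_token <- function(x) {
  # "TRBV9*01(1024.5),TRBV9-2*01(...)" -> "TRBV9*01"; "Homsap TRBV9*01 F" -> "TRBV9*01"
  x <- sub("^Homsap ", "", x)
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*$", "", x)
  x <- sub(" .*$", "", x)
  x
}

col_or <- function(df, ...) {
  for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
  NULL
}

# Map a parsed dialect data.frame onto internal clonotype fields.
map_dialect <- function(df, dialect) {
  g <- function(nm) if (nm %in% names(df)) df[[nm]] else NULL
  switch(dialect,
    internal = list(count = g("count"), cdr3nt = g("cdr3nt"),
                    cdr3aa = g("cdr3aa"), v = g("v"), d = g("d"), j = g("j"),
                    v_end = g("VEnd"), d_start = g("DStart"),
                    d_end = g("DEnd"), j_start = g("JStart"),
                    quality = g("cdr3ntQuality")),
    mitcr = ,
    migec = list(count = col_or(df, "Read count", "Count"),
                 cdr3nt = g("CDR3 nucleotide sequence"),
                 cdr3aa = g("CDR3 amino acid sequence"),
                 v = first_token(g("V segments")),
                 d = first_token(g("D segments")),
                 j = first_token(g("J segments")),
                 v_end = mitcr_pos(g("Last V nucleotide position"), 1L),
                 d_start = mitcr_pos(g("First D nucleotide position"), 0L),
                 d_end = mitcr_pos(g("Last D nucleotide position"), 1L),
                 j_start = mitcr_pos(g("First J nucleotide position"), 0L),
                 quality = g("CDR3 nucleotide quality")),
    mixcr = list(count = g("cloneCount"),
                 cdr3nt = g("nSeqCDR3"), cdr3aa = g("aaSeqCDR3"),
                 v = first_token(col_or(df, "bestVHit", "allVHitsWithScore")),
                 d = first_token(col_or(df, "bestDHit", "allDHitsWithScore")),
                 j = first_token(col_or(df, "bestJHit", "allJHitsWithScore")),
                 quality = g("qualCDR3")),
    igblast_airr = list(count = col_or(df, "duplicate_count",
                                       "consensus_count"),
                        cdr3nt = g("junction"), cdr3aa = g("junction_aa"),
                        v = first_token(g("v_call")),
                        d = first_token(g("d_call")),
                        j = first_token(g("j_call"))),
    imgt_hvq = list(count = NULL, cdr3nt = g("JUNCTION"),
                    cdr3aa = col_or(df, "AA JUNCTION", "JUNCTION (AA)"),
                    v = first_token(g("V-GENE and allele")),
                    d = first_token(g("D-GENE and allele")),
                    j = first_token(g("J-GENE and allele"))),
    immunoseq = list(count = col_or(df, "count (templates/reads)",
                                    "templates", "count"),
                     cdr3nt = g("nucleotide"), cdr3aa = g("aminoAcid"),
                     v = g("vGeneName"), d = g("dGeneName"),
                     j = g("jGeneName")),
    stop("unknown dialect: ", dialect)
  )
}

# MiTCR/MIGEC markup columns are 0-based inclusive positions; convert "last
# nucleotide of V/D" to half-open ends by adding 1. -1 stays absent.
mitcr_pos <- function(x, add) {
  if (is.null(x)) return(NULL)
  x <- suppressWarnings(as.integer(x))
  x[is.na(x)] <- -1L
  ifelse(x < 0L, -1L, x + add)
}

#' Parse a clonotype table file
#'
#' Reads a tab-delimited clonotype export in any supported dialect
#' (auto-detected from the header unless given), recomputes frequencies from
#' counts, derives frame/functionality from the sequence, and merges duplicate
#' (CDR3nt, V, J) rows with a warning. Non-integer template estimates are
#' rounded half-up with a floor of 1. Gzip-compressed input (`.gz`) is read
#' transparently; `#` comment lines are skipped.
#'
#' @param path input file path.
#' @param dialect optional dialect identifier; auto-detected when `NULL`.
#' @param sample_id sample identifier for the result (default: file base name).
#' @return a [clonotype_table()].
#' @export
parse_clonotype_table <- function(path, dialect = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(txt|tsv)(\\.gz)?$", "", basename(path))
  lines <- read_table_lines(path)
  if (length(lines) == 0L) stop("empty file: ", path)
  if (is.null(dialect)) dialect <- detect_format(lines[1])
  df <- as.data.frame(data.table::fread(text = lines, sep = "\t",
                                        header = TRUE, check.names = FALSE,
                                        colClasses = NULL,
                                        data.table = FALSE))
  m <- map_dialect(df, dialect)
  nrows <- nrow(df)
  if (is.null(m$count)) m$count <- rep(1, nrows)
  count <- suppressWarnings(as.numeric(m$count))
  if (any(is.na(count)))
    stop("non-numeric count at line ",
         paste(which(is.na(count)) + 1L, collapse = ","), " of ", path)
  count <- pmax(1, floor(count + 0.5))  # half-up rounding, floor 1
  cdr3nt <- toupper(as.character(m$cdr3nt))
  keep <- !is.na(cdr3nt) & nzchar(cdr3nt)
  if (!all(keep)) {
    warning(sum(!keep), " rows without a CDR3 sequence dropped")
    df_idx <- which(keep)
  } else df_idx <- seq_len(nrows)
  out <- data.frame(count = count[df_idx], cdr3nt = cdr3nt[df_idx],
                    stringsAsFactors = FALSE)
  for (f in c("cdr3aa", "v", "d", "j", "v_end", "d_start", "d_end",
              "j_start", "quality"))
    if (!is.null(m[[f]])) out[[f]] <- m[[f]][df_idx]
  if (!is.null(out$cdr3aa)) {
    # derive aa when absent/empty rather than trusting blanks
    blank <- is.na(out$cdr3aa) | !nzchar(out$cdr3aa)
    if (any(blank)) out$cdr3aa[blank] <- translate_cdr3(out$cdr3nt[blank])
  }
  out <- merge_duplicate_rows(out)
  clonotype_table(out, sample_id = sample_id, source_format = dialect)
}

merge_duplicate_rows <- function(df) {
  v <- if (!is.null(df$v)) norm_segment(df$v) else rep(".", nrow(df))
  j <- if (!is.null(df$j)) norm_segment(df$j) else rep(".", nrow(df))
  key <- paste(df$cdr3nt, v, j, sep = "\r")
  if (!anyDuplicated(key)) return(df)
  warning("duplicate (cdr3nt, V, J) rows merged with counts summed")
  split_counts <- tapply(df$count, key, sum)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$count <- as.numeric(split_counts[key[first]])
  out
}

#' Write a clonotype table in the internal tab-delimited format
#'
#' Columns: `count freq cdr3nt cdr3aa v d j VEnd DStart DEnd JStart`, plus
#' `cdr3ntQuality` when any quality string is present. Rows are written in
#' canonical order with frequencies at 9 significant digits.
#'
#' @param table a [clonotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_internal <- function(table, path) {
  stopifnot(inherits(table, "clonotype_table"))
  has_q <- nrow(table) > 0L && any(!is.na(table$quality))
  cols <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
            "VEnd", "DStart", "DEnd", "JStart")
  if (has_q) cols <- c(cols, "cdr3ntQuality")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(table) > 0L) {
    rows <- data.frame(
      count = format(table$count, scientific = FALSE, trim = TRUE),
      freq = formatC(table$freq, digits = 9, format = "g"),
      cdr3nt = table$cdr3nt, cdr3aa = table$cdr3aa,
      v = table$v, d = table$d, j = table$j,
      VEnd = table$v_end, DStart = table$d_start,
      DEnd = table$d_end, JStart = table$j_start,
      stringsAsFactors = FALSE)
    if (has_q) rows$cdr3ntQuality <- ifelse(is.na(table$quality), "",
                                            table$quality)
    writeLines(do.call(paste, c(unname(rows), sep = "\t")), con)
  }
  invisible(path)
}

#' Load a collection of samples from a metadata table
#'
#' The metadata file is a TSV with header `sample_id<TAB>file` plus optional
#' free-form annotation columns (e.g. `donor`). File paths are resolved
#' relative to the metadata file's directory.
#'
#' @param metadata_path path to the metadata TSV.
#' @return named list of [clonotype_table()] in metadata order, with the
#'   metadata data.frame attached as attribute `"metadata"`.
#' @export
load_collection <- function(metadata_path) {
  if (!file.exists(metadata_path)) stop("file not found: ", metadata_path)
  md <- as.data.frame(data.table::fread(metadata_path, sep = "\t",
                                        header = TRUE, check.names = FALSE,
                                        data.table = FALSE))
  if (nrow(md) == 0L) {
    out <- list()
    attr(out, "metadata") <- md
    return(out)
  }
  if (!all(c("sample_id", "file") %in% names(md)))
    stop("metadata must have 'sample_id' and 'file' columns")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ","))
  base <- dirname(metadata_path)
  tables <- vector("list", nrow(md))
  for (i in seq_len(nrow(md))) {
    p <- md$file[i]
    if (!file.exists(p)) p <- file.path(base, md$file[i])
    if (!file.exists(p))
      stop("file for sample '", md$sample_id[i], "' not found: ", md$file[i])
    tables[[i]] <- parse_clonotype_table(p, sample_id = md$sample_id[i])
  }
  names(tables) <- md$sample_id
  attr(tables, "metadata") <- md
  tables
}
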