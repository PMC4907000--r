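# Shared fixtures, built in code at test time.

# Toy table T1: counts 12/6/2/1, lengths 12/13/18/12 nt, three TRBV9 clones
# sharing TRBJ2-7 plus one TRBV5-1/TRBJ1-1 singleton; total 21 reads.
toy_table <- function() {
  clonotype_table(data.frame(
    count = c(12, 6, 2, 1),
    cdr3nt = c("TGTGCCAGCTTT", "TGTGCCAGCTTTA",
               "TGTGCCAGCTTTAGCTTT", "TGTGCCTTTTTT"),
    v = c("TRBV9", "TRBV9", "TRBV9", "TRBV5-1"),
    j = c("TRBJ2-7", "TRBJ2-7", "TRBJ2-7", "TRBJ1-1"),
    stringsAsFactors = FALSE), sample_id = "T1")
}

random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small random clonotype table; deterministic under the caller's seed.
random_table <- function(n_clones = 20L, max_count = 50L,
                         sample_id = "rnd", with_quality = FALSE) {
  lens <- sample(9:21, n_clones, replace = TRUE)
  seqs <- vapply(lens, random_nt, character(1))
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(lens[dup], random_nt, character(1))
  }
  df <- data.frame(
    count = sample.int(max_count, n_clones, replace = TRUE),
    cdr3nt = seqs,
    v = sample(c("TRBV9", "TRBV5-1", "TRBV28"), n_clones, replace = TRUE),
    j = sample(c("TRBJ2-7", "TRBJ1-1"), n_clones, replace = TRUE),
    stringsAsFactors = FALSE)
  if (with_quality)
    df$quality <- vapply(lens, function(L)
      paste(intToUtf8(sample(53:74, L, replace = TRUE), multiple = FALSE),
            collapse = ""), character(1))
  clonotype_table(df, sample_id = sample_id)
}

# Dialect fixture writers: one representative file per supported tool layout.
write_mixcr_fixture <- function(path) {
  lines <- c(
    paste("cloneId", "cloneCount", "cloneFraction", "nSeqCDR3", "aaSeqCDR3",
          "allVHitsWithScore", "allDHitsWithScore", "allJHitsWithScore",
          sep = "\t"),
    paste("0", "120", "0.6", "TGTGCCAGCTTT", "CASF",
          "TRBV9*00(1024.5),TRBV9-2*00(900)", "TRBD1*00(55)",
          "TRBJ2-7*00(300)", sep = "\t"),
    paste("1", "80", "0.4", "TGTGCCTTTTTT", "CAFF", "TRBV5-1*00(888)", "",
          "TRBJ1-1*00(250)", sep = "\t"))
  writeLines(lines, path)
  path
}

write_mitcr_fixture <- function(path) {
  lines <- c(
    paste("Read count", "Percentage", "CDR3 nucleotide sequence",
          "CDR3 nucleotide quality", "CDR3 amino acid sequence",
          "V segments", "J segments", "D segments",
          "Last V nucleotide position", "First D nucleotide position",
          "Last D nucleotide position", "First J nucleotide position",
          sep = "\t"),
    paste("30", "0.75", "TGTGCCAGCTTT", "IIIIIIIIIIII", "CASF",
          "TRBV9", "TRBJ2-7", "TRBD1", "5", "7", "8", "10", sep = "\t"),
    paste("10", "0.25", "TGTGCCTTTTTT", "IIIIIIIIIIII", "CAFF",
          "TRBV5-1", "TRBJ1-1", ".", "4", "-1", "-1", "9", sep = "\t"))
  writeLines(lines, path)
  path
}

write_migec_fixture <- function(path) {
  lines <- c(
    paste("Count", "Percentage", "CDR3 nucleotide sequence",
          "CDR3 amino acid sequence", "V segments", "J segments",
          "D segments", sep = "\t"),
    paste("55", "0.55", "TGTGCCAGCTTT", "CASF", "TRBV9", "TRBJ2-7", "TRBD1",
          sep = "\t"),
    paste("45", "0.45", "TGTGCCTTTTTT", "CAFF", "TRBV5-1", "TRBJ1-1", ".",
          sep = "\t"))
  writeLines(lines, path)
  path
}

write_airr_fixture <- function(path) {
  lines <- c(
    paste("sequence_id", "v_call", "d_call", "j_call", "junction",
          "junction_aa", "duplicate_count", sep = "\t"),
    paste("r1", "TRBV9*01", "TRBD1*01", "TRBJ2-7*01", "TGTGCCAGCTTT",
          "CASF", "7", sep = "\t"),
    paste("r2", "TRBV9*01", "", "TRBJ2-7*01", "TGTGCCAGCTTT", "CASF", "3",
          sep = "\t"),
    paste("r3", "TRBV5-1*01", "", "TRBJ1-1*01", "TGTGCCTTTTTT", "CAFF", "5",
          sep = "\t"))
  writeLines(lines, path)
  path
}

write_imgt_fixture <- function(path) {
  lines <- c(
    paste("Sequence number", "Sequence ID", "V-GENE and allele",
          "J-GENE and allele", "D-GENE and allele", "JUNCTION",
          "AA JUNCTION", sep = "\t"),
    paste("1", "seq1", "Homsap TRBV9*01 F", "Homsap TRBJ2-7*01 F",
          "Homsap TRBD1*01 F", "TGTGCCAGCTTT", "CASF", sep = "\t"),
    paste("2", "seq2", "Homsap TRBV5-1*01 F", "Homsap TRBJ1-1*01 F", "",
          "TGTGCCTTTTTT", "CAFF", sep = "\t"))
  writeLines(lines, path)
  path
}

write_immunoseq_fixture <- function(path) {
  lines <- c(
    paste("nucleotide", "aminoAcid", "count (templates/reads)",
          "frequencyCount", "vGeneName", "dGeneName", "jGeneName",
          sep = "\t"),
    paste("TGTGCCAGCTTT", "CASF", "17.4", "0.6", "TRBV9", "TRBD1",
          "TRBJ2-7", sep = "\t"),
    paste("TGTGCCTTTTTT", "CAFF", "12", "0.4", "TRBV5-1", "", "TRBJ1-1",
          sep = "\t"))
  writeLines(lines, path)
  path
}
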