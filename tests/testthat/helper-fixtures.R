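# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except temp files the tests write.

# printed repeat fragments used in worked examples
HUMAN_FRAGMENT <- "YSGGGGYSGGGGCGGGSSGGGGGGGI"
CHICKEN_LOR3_FRAGMENT <- "IIGGGGSSGGSSGCCGGGSSSGGSSGGKIII"
CHICKEN_LOR1_FRAGMENT <- "IIGGGGGSSGGGGGSSHQSQGPICI"

# record with 10 blocks "Y GGGGGGGG Q" (100 residues): termini empty,
# the whole sequence is central; loops are 8 Gs each.
blocky_record <- function(id = "blocky") {
  central <- paste(rep(paste0("Y", strrep("G", 8), "Q"), 10), collapse = "")
  list(record = protein_record(id, central),
       partition = domain_partition(0, 100, 100))
}

# replace the trailing k central residues with X
x_tail <- function(rec, k) {
  L <- nchar(rec$residues)
  protein_record(rec$id, paste0(substring(rec$residues, 1, L - k),
                                strrep("X", k)))
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(lines, tf)
  tf
}

# alignment whose polymorphic columns (defined by the reference rows) give a
# chosen agree/disagree pattern for the focal pair (rows 1 and 2)
patterned_group <- function(pattern) {
  n <- length(pattern)
  r1 <- strrep("A", n)
  r2 <- paste(ifelse(pattern, "A", "C"), collapse = "")
  ref <- strrep("G", n)  # makes every column polymorphic
  aligned_group(c("p1", "p2", "ref"), c(r1, r2, ref))
}
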