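# Shared fixtures built in code at test time.

# Published per-position preference/avoidance lists (residue sets quoted at
# the 1.2 / 0.8 propensity thresholds), used for the consistency check
# between the preference lists and the bundled potential matrices.
published_preferences <- list(
  amyloid = list(
    preferred = list(P1 = c("S", "W", "Y", "H", "M", "N"),
                     P2 = c("C", "F", "I", "Q", "T", "Y"),
                     P3 = c("F", "Q", "V", "W"),
                     P4 = c("I", "L", "N", "W", "Y"),
                     P5 = c("F", "I", "Y"),
                     P6 = c("C", "E", "F", "M", "Q", "S", "Y")),
    avoided = list(P1 = c("D", "T", "R", "E"),
                   P2 = c("D", "A", "N", "S", "G"),
                   P3 = c("A", "G", "D", "I", "Y"),
                   P4 = c("V", "S", "K", "A"),
                   P5 = c("E", "L", "Q", "S", "T"),
                   P6 = c("A", "D", "G", "I", "K"))),
  non_amyloid = list(
    preferred = list(P1 = c("F", "H", "K", "S", "W", "Y"),
                     P2 = c("E", "M", "T", "Y"),
                     P3 = c("C", "E", "F", "N", "V", "W"),
                     P4 = c("F", "I", "L", "Y"),
                     P5 = c("F", "I", "Y"),
                     P6 = c("E", "F", "M", "T", "W")),
    avoided = list(P1 = c("G", "L", "A", "Q", "V"),
                   P2 = c("D", "N", "P", "R"),
                   P3 = c("A", "G", "R", "T", "Y"),
                   P4 = c("A", "M", "V", "D", "W"),
                   P5 = c("A", "G", "M", "R", "S", "T"),
                   P6 = c("A", "V"))))

# write a temporary peptide TSV and return its path
write_peptide_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(rows, path)
  path
}

# random valid hexapeptides, uniform over the alphabet
random_hexapeptides <- function(n) {
  apply(matrix(sample(aa_alphabet(), n * 6, replace = TRUE), ncol = 6),
        1, paste0, collapse = "")
}

# brute-force reference: score one peptide by explicit per-position lookup
naive_phi_total <- function(sequence, pot) {
  res <- strsplit(sequence, "")[[1]]
  tot <- 0
  for (j in 1:6) tot <- tot + unclass(pot)[res[j], j]
  tot
}
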