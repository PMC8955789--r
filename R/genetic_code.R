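# Genetic-code lookup tables built once at install time from the standard
# code (NCBI translation table 1).  All downstream classification and site
# counting indexes into these tables.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
STOP_CODONS <- c("TAA", "TAG", "TGA")

CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
CODONS <- sort(CODONS)

CODON_AA <- Biostrings::GENETIC_CODE[CODONS]
SENSE_CODONS <- CODONS[CODON_AA != "*"]

# Alternative bases for each reference base, in fixed (alphabetical) order.
ALT_BASES <- lapply(setNames(BASES, BASES), function(b) setdiff(BASES, b))

# CHANGE_CLASS[codon, codon position, alt base]: effect of a single-base
# change on the encoded amino acid.  NA where alt == ref or codon is a stop.
CHANGE_CLASS <- array(
  NA_character_, dim = c(64L, 3L, 4L),
  dimnames = list(CODONS, NULL, BASES)
)
for (.codon in SENSE_CODONS) {
  for (.p in 1:3) {
    .ref <- substr(.codon, .p, .p)
    for (.alt in BASES) {
      if (.alt == .ref) next
      .mut <- .codon
      substr(.mut, .p, .p) <- .alt
      CHANGE_CLASS[.codon, .p, .alt] <-
        if (CODON_AA[.mut] == "*") "stopgain"
        else if (CODON_AA[.mut] == CODON_AA[.codon]) "synonymous"
        else "nonsynonymous"
    }
  }
}
rm(.codon, .p, .ref, .alt, .mut)

# Per-codon Nei-Gojobori fractional site counts: each codon position carries
# one site split among its three possible changes; changes creating a stop
# codon contribute to neither class.
NG86_CODON_SITES <- t(vapply(CODONS, function(cd) {
  cls <- CHANGE_CLASS[cd, , ]
  if (all(is.na(cls))) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = sum(cls == "synonymous", na.rm = TRUE) / 3,
    nonsyn = sum(cls == "nonsynonymous", na.rm = TRUE) / 3)
}, numeric(2)))

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
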