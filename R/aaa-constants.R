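# Internal constants shared across modules. This file must collate first.

# The 20 standard residues, alphabetical by one-letter code. All 20x20
# tables in the package are indexed in this order.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Tolerated non-standard letters; retained in sequences, excluded from
# pair counting.
.AA_EXTRA <- c("B", "J", "O", "U", "X", "Z")

.BASES <- c("A", "C", "G", "T")

# All 64 codons in base-4 order (A=0, C=1, G=2, T=3), so that the codon
# with base codes (b1, b2, b3) sits at index 16*b1 + 4*b2 + b3 + 1.
.CODONS <- paste0(rep(.BASES, each = 16L),
                  rep(rep(.BASES, each = 4L), times = 4L),
                  rep(.BASES, times = 16L))

# Standard genetic code, reindexed to .CODONS order ('*' = stop).
.CODON_AA <- unname(Biostrings::GENETIC_CODE[.CODONS])

# Codon index -> protein code (1..20 into .AA20, -1 for stop).
.CODON_PCODE <- {
  p <- match(.CODON_AA, .AA20)
  p[.CODON_AA == "*"] <- -1L
  as.integer(p)
}

# Residue -> synonymous codon indices into .CODONS.
.SYN_CODONS <- lapply(stats::setNames(nm = .AA20),
                      function(a) which(.CODON_AA == a))
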