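DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons.
NON_STOP_CODONS <- setdiff(
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0)),
  STOP_CODONS
)
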