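# Shared base/codon constants (file sorts first so every module can use
# them at load time).

BASES <- c("A", "C", "G", "T")

# The three alternative bases for each reference base, fixed order.
ALT_BASES <- rbind(
  A = c("C", "G", "T"),
  C = c("A", "G", "T"),
  G = c("A", "C", "T"),
  T = c("A", "C", "G")
)

# Class codes used throughout: 1 = synonymous, 2 = non-synonymous, 3 = stop.
CLASS_SYN <- 1L
CLASS_NONSYN <- 2L
CLASS_STOP <- 3L

# For every base, the unique GC-conservative alternative (A<->T, C<->G).
GC_PARTNER <- c(A = "T", C = "G", G = "C", T = "A")

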