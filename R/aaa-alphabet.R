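# Canonical residue order used throughout (AAindex row order).
AA_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

AA_AMBIGUOUS <- c("B", "Z", "X", "U")
AA_GAP <- "-"

aa_alphabet <- function() c(AA_ORDER, AA_GAP, AA_AMBIGUOUS)
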