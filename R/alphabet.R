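# Alphabet definitions shared by the reader, the encoder and the simulator.
# Gap '-' and missing '?' are treated identically (missing data); '?' is
# mapped onto the gap character at read time.

.esl_alphabets <- list(
  nucleotide = list(
    states    = c("A", "C", "G", "T"),
    ambiguity = list(
      R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
      K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
      D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
      N = c("A", "C", "G", "T")
    )
  ),
  amino_acid = list(
    states    = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    ambiguity = list(
      B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
      X = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    )
  )
)

.esl_gap <- "-"

.match_alphabet <- function(alphabet) {
  match.arg(alphabet, c("nucleotide", "amino_acid"))
}

.allowed_chars <- function(alphabet) {
  a <- .esl_alphabets[[alphabet]]
  c(a$states, names(a$ambiguity), .esl_gap)
}
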