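#' The fixed 20-letter amino-acid alphabet
#'
#' All feature vectors and incidence matrices in this package are indexed by
#' the 20 standard amino acids in alphabetical one-letter-code order
#' (A, C, D, E, ..., Y). The ordering is fixed for the life of the package:
#' every downstream vector slot and matrix row/column depends on it, so
#' freezing it once makes all features deterministic and comparable across
#' runs and model versions.
#'
#' @return Character vector of the 20 one-letter codes, in the canonical
#'   order.
#' @examples
#' residue_alphabet()
#' @export
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Map residue letters to alphabet indices
#'
#' @param letters Character vector of one-letter residue codes.
#' @return Integer vector of 1-based indices into [residue_alphabet()];
#'   `NA` for letters outside the alphabet.
#' @export
residue_index <- function(letters) {
  match(letters, residue_alphabet())
}

# Split a residue string into its alphabet indices (internal).
seq_indices <- function(residues) {
  residue_index(strsplit(residues, "", fixed = TRUE)[[1L]])
}
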