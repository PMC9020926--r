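#' Amino-acid frequency vector
#'
#' Counts each of the 20 standard residues in the sequence. This is the
#' purely compositional block of the fused descriptor: 20 non-negative
#' integers that always sum to the sequence length.
#'
#' @param residues Sanitized residue string.
#' @return Named integer vector of length 20 (names = [residue_alphabet()]).
#' @examples
#' frequency_vector("AAC")
#' @export
frequency_vector <- function(residues) {
  idx <- seq_indices(residues)
  stopifnot(!anyNA(idx))
  tab <- tabulate(idx, nbins = 20L)
  names(tab) <- residue_alphabet()
  tab
}

#' Accumulative absolute position incidence vector (AAPIV)
#'
#' For each residue type, sums the 1-based positions at which it occurs.
#' Positions are 1-based so the first residue contributes 1 (a 0-based
#' convention would make it invisible). The 20 entries always sum to
#' k(k+1)/2 for a sequence of length k: each position is attributed to
#' exactly one residue type.
#'
#' @param residues Sanitized residue string.
#' @return Named numeric vector of length 20.
#' @examples
#' aapiv("ACA")  # A occurs at 1 and 3 -> 4; C at 2 -> 2
#' @export
aapiv <- function(residues) {
  idx <- seq_indices(residues)
  stopifnot(!anyNA(idx))
  mu <- vapply(split(seq_along(idx), factor(idx, levels = 1:20)),
               sum, numeric(1))
  names(mu) <- residue_alphabet()
  mu
}

#' Reverse accumulative absolute position incidence vector (RAAPIV)
#'
#' [aapiv()] computed on the reversed sequence, exposing absolute-position
#' information anchored at the C-terminus. Satisfies the exact identity
#' eta_i = (k+1) * tau_i - mu_i, where tau is the frequency vector and mu
#' the forward AAPIV.
#'
#' @param residues Sanitized residue string.
#' @return Named numeric vector of length 20.
#' @export
raapiv <- function(residues) {
  aapiv(reverse_residues(residues))
}

# Reverse a residue string (internal).
reverse_residues <- function(residues) {
  paste(rev(strsplit(residues, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Position-relative incidence matrix (PRIM)
#'
#' A 20x20 matrix capturing residue-order information. Entry (i, j)
#' accumulates, over every occurrence of residue type j at a position p
#' strictly after the first occurrence of type i, the positional offset
#' p - firstpos(i). Rows for residue types absent from the sequence are
#' all zero, keeping the matrix non-negative and its moments finite.
#'
#' @param residues Sanitized residue string.
#' @return 20x20 numeric matrix with dimnames set to the alphabet.
#' @examples
#' prim("ACA")  # Y[A,C] = 1, Y[A,A] = 2, Y[C,A] = 1
#' @export
prim <- function(residues) {
  idx <- seq_indices(residues)
  stopifnot(!anyNA(idx))
  k <- length(idx)
  Y <- matrix(0, 20L, 20L,
              dimnames = list(residue_alphabet(), residue_alphabet()))
  first <- rep(NA_integer_, 20L)
  for (p in seq_len(k)) {
    if (is.na(first[idx[p]])) first[idx[p]] <- p
  }
  pos <- seq_len(k)
  for (i in which(!is.na(first))) {
    sel <- pos > first[i]
    if (!any(sel)) next
    offs <- pos[sel] - first[i]
    acc <- vapply(split(offs, factor(idx[sel], levels = 1:20)),
                  sum, numeric(1))
    Y[i, ] <- acc
  }
  Y
}

#' Reverse position-relative incidence matrix (RPRIM)
#'
#' [prim()] computed on the reversed sequence; exposes order patterns
#' invisible to the forward pass.
#'
#' @param residues Sanitized residue string.
#' @return 20x20 numeric matrix.
#' @export
rprim <- function(residues) {
  prim(reverse_residues(residues))
}

#' Square reshaping of a sequence (row-major)
#'
#' Reshapes the residue-index sequence into the smallest square matrix that
#' holds it, n = ceiling(sqrt(k)), row-major, padding trailing cells with
#' `NA`. Exposed as a utility for inspecting the two-dimensional depiction
#' of a sequence; its moments do not enter the fused 120-feature vector,
#' whose accounting covers only the PRIM/RPRIM moments, AAPIV, RAAPIV and
#' the frequency vector.
#'
#' @param residues Sanitized residue string.
#' @return n x n integer matrix of alphabet indices with `NA` padding.
#' @export
square_seq_matrix <- function(residues) {
  idx <- seq_indices(residues)
  stopifnot(!anyNA(idx))
  k <- length(idx)
  n <- ceiling(sqrt(k))
  cells <- c(idx, rep(NA_integer_, n * n - k))
  matrix(cells, nrow = n, ncol = n, byrow = TRUE)
}
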