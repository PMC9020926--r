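#' Specification of a synthetic two-class sequence dataset
#'
#' Describes a generator for labeled random amino-acid sequences with a
#' controllable class signal: per-class residue-composition weights and an
#' optional k-mer motif planted in positives. With identical compositions
#' and no motif the dataset carries no learnable signal (a null dataset);
#' with disjoint composition supports the classes are separable from
#' composition alone; a planted motif at matched compositions creates a
#' purely positional signal.
#'
#' @param n_pos,n_neg Class sizes. The default 1:4 positive:negative ratio
#'   echoes the class imbalance typical of curated DNA-binding benchmarks.
#' @param length_range Two integers `c(Lmin, Lmax)`, `Lmin >= 4` (the
#'   incidence-matrix moments need a non-trivial support).
#' @param pos_weights,neg_weights Length-20 non-negative composition
#'   weights per class (normalized internally); default uniform.
#' @param motif Optional residue string planted in positives (overwrites a
#'   window at a uniformly drawn offset, so lengths stay in range).
#' @param motif_prob Probability that a positive receives the motif.
#' @param seed Integer seed; the generated dataset is a deterministic
#'   function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pos = 100L, n_neg = 400L,
                           length_range = c(30L, 80L),
                           pos_weights = rep(1, 20), neg_weights = rep(1, 20),
                           motif = NULL, motif_prob = 0, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            length(length_range) == 2, length_range[1] >= 4,
            length_range[1] <= length_range[2],
            length(pos_weights) == 20, length(neg_weights) == 20,
            all(pos_weights >= 0), all(neg_weights >= 0),
            sum(pos_weights) > 0, sum(neg_weights) > 0,
            motif_prob >= 0, motif_prob <= 1)
  if (!is.null(motif)) {
    stopifnot(nchar(motif) >= 1, nchar(motif) <= length_range[1])
    if (anyNA(seq_indices(motif))) stop("motif must use the 20-letter alphabet")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 pos_weights = pos_weights / sum(pos_weights),
                 neg_weights = neg_weights / sum(neg_weights),
                 motif = motif, motif_prob = motif_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic dataset
#'
#' Sequence lengths are uniform on the spec's range; residues are drawn
#' i.i.d. from the class composition; the motif (if any) overwrites a
#' window at a uniform position in the given fraction of positives.
#'
#' @param spec A [synthetic_spec()].
#' @return A [protein_dataset()] with positives first.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  aa <- residue_alphabet()
  gen_class <- function(nseq, w, prefix, plant) {
    lchoices <- seq.int(spec$length_range[1], spec$length_range[2])
    lens <- lchoices[sample.int(length(lchoices), nseq, replace = TRUE)]
    seqs <- vapply(lens, function(k)
      paste(sample(aa, k, replace = TRUE, prob = w), collapse = ""),
      character(1))
    if (plant && !is.null(spec$motif) && spec$motif_prob > 0) {
      m <- nchar(spec$motif)
      gets <- stats::runif(nseq) < spec$motif_prob
      for (i in which(gets)) {
        start <- sample.int(lens[i] - m + 1L, 1L)
        substr(seqs[i], start, start + m - 1L) <- spec$motif
      }
    }
    data.frame(id = sprintf("%s%04d", prefix, seq_len(nseq)),
               residues = seqs, stringsAsFactors = FALSE)
  }
  pos <- gen_class(spec$n_pos, spec$pos_weights, "pos", plant = TRUE)
  neg <- gen_class(spec$n_neg, spec$neg_weights, "neg", plant = FALSE)
  protein_dataset(c(pos$id, neg$id), c(pos$residues, neg$residues),
                  rep(c("positive", "negative"), c(spec$n_pos, spec$n_neg)))
}

#' Observed per-class residue composition
#'
#' Pools all residues of each class and returns their relative
#' frequencies; used to verify generator calibration against the spec's
#' composition weights.
#'
#' @param ds A [protein_dataset()].
#' @return A 2 x 20 matrix with rows `positive`, `negative`.
#' @export
empirical_composition <- function(ds) {
  stopifnot(inherits(ds, "protein_dataset"), nrow(ds) >= 1)
  comp <- function(cls) {
    rows <- ds$residues[ds$label == cls]
    if (length(rows) == 0L) stop("class '", cls, "' is empty")
    counts <- Reduce(`+`, lapply(rows, frequency_vector))
    counts / sum(counts)
  }
  rbind(positive = comp("positive"), negative = comp("negative"))
}
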