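#' Read a FASTA file into raw records
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package's input contract: at least one record, wrapped sequence lines
#' concatenated, record order preserved. No residue validation happens
#' here; see [sanitize_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (full header text up to the first
#'   whitespace) and `seq` (sequence text, whitespace stripped), one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) {
    stop("no FASTA records in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- gsub("[[:space:]]", "", as.character(set))
  data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of residue strings (parallel to `ids`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Sanitize a raw sequence onto the 20-letter alphabet
#'
#' Uppercases the input and resolves characters outside the standard
#' 20-letter amino-acid alphabet according to `policy`:
#' \describe{
#'   \item{`"strict"`}{any non-standard character is an error;}
#'   \item{`"drop"`}{non-standard characters are removed (default policy of
#'     the dataset loaders);}
#'   \item{`"map"`}{ambiguity codes are mapped to a canonical member
#'     (B to D, Z to E, J to L, U to C, O to K); `X` is an error because it
#'     carries no compositional information.}
#' }
#'
#' @param raw Sequence text (whitespace tolerated).
#' @param policy One of `"strict"`, `"drop"`, `"map"`.
#' @return The sanitized residue string (length >= 1 guaranteed).
#' @export
sanitize_sequence <- function(raw, policy = c("drop", "strict", "map")) {
  if (length(policy) == 1L && !policy %in% c("drop", "strict", "map")) {
    stop("unknown sanitization policy: ", policy)
  }
  policy <- match.arg(policy)
  s <- toupper(gsub("[[:space:]]", "", raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  ok <- chars %in% residue_alphabet()
  if (policy == "strict") {
    if (!all(ok)) {
      stop("non-standard residue(s) under strict policy: ",
           paste(unique(chars[!ok]), collapse = ", "))
    }
  } else if (policy == "map") {
    map <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")
    bad <- !ok & !chars %in% names(map)
    if (any(bad)) {
      stop("unmappable residue(s) under map policy: ",
           paste(unique(chars[bad]), collapse = ", "))
    }
    chars[!ok] <- map[chars[!ok]]
  } else {
    chars <- chars[ok]
  }
  if (length(chars) == 0L) {
    stop("sequence empty after sanitization")
  }
  paste(chars, collapse = "")
}

#' Assemble a labeled protein dataset
#'
#' @param id Character vector of identifiers.
#' @param residues Character vector of sanitized residue strings.
#' @param label Character/factor vector with values `"positive"` /
#'   `"negative"`.
#' @return A `protein_dataset`: a data.frame with columns `id`, `residues`,
#'   `label` (factor with levels negative, positive).
#' @export
protein_dataset <- function(id, residues, label) {
  stopifnot(length(id) == length(residues), length(id) == length(label))
  ds <- data.frame(id = as.character(id),
                   residues = as.character(residues),
                   label = factor(as.character(label),
                                  levels = c("negative", "positive")),
                   stringsAsFactors = FALSE)
  if (anyNA(ds$label)) stop("labels must be 'positive' or 'negative'")
  class(ds) <- c("protein_dataset", "data.frame")
  ds
}

#' Load a labeled dataset from two FASTA files
#'
#' Reads a positive (DNA-binding) and a negative (non-binding) FASTA file,
#' sanitizes every record under `policy`, and concatenates positives then
#' negatives. Records that fail sanitization are dropped with a message
#' reporting the per-class rejection counts.
#'
#' @param pos_path FASTA file of positive (DNA-binding) sequences.
#' @param neg_path FASTA file of negative sequences.
#' @param policy Sanitization policy, see [sanitize_sequence()].
#' @return A [protein_dataset()].
#' @export
load_labeled <- function(pos_path, neg_path, policy = "drop") {
  load_one <- function(path, lab) {
    recs <- read_fasta(path)
    clean <- vapply(recs$seq, function(s) {
      tryCatch(sanitize_sequence(s, policy), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    keep <- !is.na(clean)
    if (any(!keep)) {
      message(sum(!keep), " ", lab, " record(s) rejected during sanitization")
    }
    data.frame(id = recs$id[keep], residues = clean[keep],
               label = rep(lab, sum(keep)), stringsAsFactors = FALSE)
  }
  pos <- load_one(pos_path, "positive")
  neg <- load_one(neg_path, "negative")
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("each class must retain at least one sequence after sanitization")
  }
  both <- rbind(pos, neg)
  protein_dataset(both$id, both$residues, both$label)
}

#' Load a labeled dataset from one FASTA plus a two-column label table
#'
#' Alternative input convention: a single FASTA file and a tab-separated
#' table with columns `id` and `label` (1 = DNA-binding, 0 = non-binding).
#'
#' @param fasta_path FASTA file with all sequences.
#' @param label_path TSV file with columns `id`, `label`.
#' @param policy Sanitization policy.
#' @return A [protein_dataset()].
#' @export
load_labeled_tsv <- function(fasta_path, label_path, policy = "drop") {
  recs <- read_fasta(fasta_path)
  lab <- utils::read.delim(label_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(lab))) {
    stop("label table must have columns 'id' and 'label'")
  }
  m <- match(recs$id, lab$id)
  if (anyNA(m)) stop("label table missing id(s): ",
                     paste(utils::head(recs$id[is.na(m)]), collapse = ", "))
  labels <- ifelse(lab$label[m] == 1, "positive", "negative")
  clean <- vapply(recs$seq, function(s) {
    tryCatch(sanitize_sequence(s, policy), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(clean)
  if (any(!keep)) message(sum(!keep), " record(s) rejected during sanitization")
  ds <- protein_dataset(recs$id[keep], clean[keep], labels[keep])
  if (!all(c("negative", "positive") %in% ds$label)) {
    stop("each class must retain at least one sequence after sanitization")
  }
  ds
}

#' Write a labeled dataset back to a pair of FASTA files
#'
#' @param ds A [protein_dataset()].
#' @param pos_path Output FASTA path for positives.
#' @param neg_path Output FASTA path for negatives.
#' @return Invisibly, `c(pos_path, neg_path)`.
#' @export
write_labeled <- function(ds, pos_path, neg_path) {
  pos <- ds[ds$label == "positive", ]
  neg <- ds[ds$label == "negative", ]
  write_fasta(pos$id, pos$residues, pos_path)
  write_fasta(neg$id, neg$residues, neg_path)
  invisible(c(pos_path, neg_path))
}
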