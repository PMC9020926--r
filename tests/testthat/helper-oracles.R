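# Independent oracles and small fixture builders used across the suite.

aa20 <- function() residue_alphabet()

rand_seq <- function(k, prob = NULL) {
  paste(sample(aa20(), k, replace = TRUE, prob = prob), collapse = "")
}

tmp_fasta <- function(ids, seqs, width = 0) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      s <- substring(s, starts, pmin(starts + width - 1, nchar(s)))
    }
    writeLines(s, con)
  }
  close(con)
  path
}

# Triple-loop enumeration oracle for the incidence matrix: for every pair
# of types (i, j) and every position p holding j with p after the first
# occurrence of i, add the offset. Deliberately naive.
brute_prim <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  k <- length(chars)
  Y <- matrix(0, 20, 20, dimnames = list(aa20(), aa20()))
  for (i in seq_len(20)) {
    fp <- NA
    for (p in seq_len(k)) if (chars[p] == aa20()[i]) { fp <- p; break }
    if (is.na(fp)) next
    for (j in seq_len(20)) {
      for (p in seq_len(k)) {
        if (chars[p] == aa20()[j] && p > fp) Y[i, j] <- Y[i, j] + (p - fp)
      }
    }
  }
  Y
}

# Naive double-loop raw and central moments (0-based grid).
brute_raw_moments <- function(mat, x, y) {
  x <- unname(x); y <- unname(y)
  n <- nrow(mat); acc <- 0
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    acc <- acc + i^x * j^y * mat[i + 1, j + 1]
  }
  acc
}

brute_central_moments <- function(mat, x, y) {
  x <- unname(x); y <- unname(y)
  n <- nrow(mat)
  m00 <- brute_raw_moments(mat, 0, 0)
  pc <- brute_raw_moments(mat, 1, 0) / m00
  qc <- brute_raw_moments(mat, 0, 1) / m00
  acc <- 0
  for (p in 0:(n - 1)) for (q in 0:(n - 1)) {
    acc <- acc + (p - pc)^x * (q - qc)^y * mat[p + 1, q + 1]
  }
  acc
}

# Independent construction of the weighted-orthonormal Hahn basis:
# Gram-Schmidt on monomials under the Hahn weight, sign fixed so each
# polynomial is positive at r = 0 (orthonormal polynomial sequences are
# unique up to sign, so this must reproduce the package basis exactly).
gs_hahn_basis <- function(N, a = 0, b = 0, orders = 0:3) {
  Nt <- N - 1
  r <- 0:Nt
  w <- choose(a + r, r) * choose(b + Nt - r, Nt - r)
  V <- sapply(orders, function(n) r^n) * sqrt(w)  # weighted monomials
  B <- matrix(0, N, length(orders))
  for (j in seq_along(orders)) {
    v <- V[, j]
    if (j > 1) for (i in seq_len(j - 1)) v <- v - sum(v * B[, i]) * B[, i]
    v <- v / sqrt(sum(v^2))
    if (v[1] < 0) v <- -v
    B[, j] <- v
  }
  t(B)  # rows = orders, like hahn_basis()$htilde
}

# Composition-compensated motif spec: negatives match the positives'
# expected marginal composition after planting, so the class signal is
# positional (residue order), not compositional.
motif_spec <- function(motif, base_w, n_pos, n_neg, L, seed) {
  m <- nchar(motif)
  w <- base_w / sum(base_w)
  neg_w <- w * (L - m) / L
  tabm <- table(factor(strsplit(motif, "")[[1]], levels = aa20()))
  neg_w <- neg_w + as.numeric(tabm) / L
  synthetic_spec(n_pos = n_pos, n_neg = n_neg, length_range = c(L, L),
                 pos_weights = w, neg_weights = neg_w,
                 motif = motif, motif_prob = 1, seed = seed)
}
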