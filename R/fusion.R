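#' Version tag of the fused feature layout
#'
#' Embedded in exported feature tables and saved models; prediction refuses
#' a model whose layout version differs from the package's.
#'
#' @return A single string.
#' @export
feature_layout_version <- function() "120-v1"

#' Column names of the fused 120-feature vector
#'
#' Layout order: PRIM raw/central/Hahn moments (10 each), RPRIM
#' raw/central/Hahn moments (10 each), AAPIV (20), RAAPIV (20), frequency
#' vector (20).
#'
#' @return Character vector of length 120.
#' @export
feature_names <- function() {
  mo <- moment_orders()
  aa <- residue_alphabet()
  c(paste0("PRIM_raw_M", mo), paste0("PRIM_central_U", mo),
    paste0("PRIM_hahn_H", mo),
    paste0("RPRIM_raw_M", mo), paste0("RPRIM_central_U", mo),
    paste0("RPRIM_hahn_H", mo),
    paste0("AAPIV_", aa), paste0("RAAPIV_", aa), paste0("FV_", aa))
}

#' Fused 120-dimensional feature vector of one sequence
#'
#' Concatenates, in a fixed documented order, the 30 moments of the PRIM,
#' the 30 moments of the RPRIM, the forward and reverse accumulative
#' absolute position incidence vectors (20 each) and the frequency vector
#' (20). The function is pure: identical input gives bit-identical output.
#'
#' @param residues Sanitized residue string.
#' @param basis Optional precomputed 20-point [hahn_basis()]; pass one when
#'   featurizing many sequences to avoid rebuilding it.
#' @return Named numeric vector of length 120 (names = [feature_names()]).
#' @export
featurize <- function(residues, basis = NULL) {
  if (is.null(basis)) basis <- hahn_basis(20L)
  mp <- suppressWarnings(moment_set(prim(residues), basis))
  mr <- suppressWarnings(moment_set(rprim(residues), basis))
  v <- c(mp$raw, mp$central, mp$hahn, mr$raw, mr$central, mr$hahn,
         aapiv(residues), raapiv(residues), frequency_vector(residues))
  names(v) <- feature_names()
  v
}

#' Featurize a labeled dataset into a feature matrix
#'
#' Rows follow dataset order; columns are [feature_names()]. With
#' `scaling = "zscore"` each column is centered and scaled; the fitted
#' means/sds are attached so they can be re-applied to unseen data (the
#' protocol runners always fit scalers on training rows only).
#'
#' @param ds A [protein_dataset()].
#' @param scaling `"none"` (default) or `"zscore"`.
#' @return List with `X` (n x 120 matrix), `y` (factor labels), and
#'   `scaler` (`NULL`, or the list returned by [fit_scaler()]).
#' @export
featurize_dataset <- function(ds, scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(ds, "protein_dataset"), nrow(ds) >= 1)
  basis <- hahn_basis(20L)
  X <- t(vapply(ds$residues, featurize, numeric(120), basis = basis,
                USE.NAMES = FALSE))
  colnames(X) <- feature_names()
  rownames(X) <- ds$id
  scaler <- NULL
  if (scaling == "zscore") {
    scaler <- fit_scaler(X)
    X <- apply_scaler(X, scaler)
  }
  list(X = X, y = ds$label, scaler = scaler)
}

#' Fit a per-column z-score scaler
#'
#' @param X Numeric matrix (training rows only).
#' @return List with `mean` and `sd` vectors; columns with zero spread get
#'   sd 1 (with a message) so scaling never divides by zero.
#' @export
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  const <- !is.finite(sd) | sd == 0
  if (any(const)) {
    message(sum(const), " constant column(s); sd replaced by 1")
    sd[const] <- 1
  }
  list(mean = mu, sd = sd)
}

#' Apply a fitted z-score scaler
#'
#' @param X Numeric matrix.
#' @param scaler Output of [fit_scaler()].
#' @return Scaled matrix of the same shape.
#' @export
apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Write a feature table to CSV
#'
#' The first line is a comment recording the feature-layout version; the
#' table has the 120 feature columns plus a final `label` column.
#'
#' @param feat Output of [featurize_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(feat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# feature_layout=", feature_layout_version()), con)
  df <- as.data.frame(feat$X)
  df$label <- as.character(feat$y)
  utils::write.csv(cbind(id = rownames(feat$X), df), con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return List with `X`, `y` as in [featurize_dataset()].
#' @export
read_feature_csv <- function(path) {
  first <- readLines(path, n = 1)
  ver <- sub("^# feature_layout=", "", first)
  if (!identical(ver, feature_layout_version())) {
    stop("feature layout version mismatch: file has '", ver,
         "', package expects '", feature_layout_version(), "'")
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  X <- as.matrix(df[, feature_names(), drop = FALSE])
  rownames(X) <- df$id
  list(X = X, y = factor(df$label, levels = c("negative", "positive")),
       scaler = NULL)
}
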