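# The fixed order-index set shared by all three moment families.
moment_orders <- function() {
  c("00", "01", "10", "11", "02", "20", "12", "21", "30", "03")
}

order_pairs <- function() {
  o <- moment_orders()
  cbind(x = as.integer(substr(o, 1, 1)), y = as.integer(substr(o, 2, 2)))
}

check_square <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop("a square matrix is required")
  }
  if (any(!is.finite(mat))) stop("matrix entries must be finite")
}

#' Raw moments of a square matrix (orders up to 3)
#'
#' M_xy = sum_i sum_j i^x j^y f(i, j) over 0-based grid coordinates
#' i, j = 0..N-1 (rows are the first coordinate). The 0-based convention
#' matches the support of the discrete Hahn basis. M_00 is the grand sum of
#' the matrix.
#'
#' @param mat Square numeric matrix.
#' @return Named numeric vector of the 10 moments, names `M00`, `M01`, ...
#'   in the fixed order-index set 00, 01, 10, 11, 02, 20, 12, 21, 30, 03.
#' @export
raw_moments <- function(mat) {
  check_square(mat)
  n <- nrow(mat)
  g <- 0:(n - 1)
  op <- order_pairs()
  out <- vapply(seq_len(nrow(op)), function(r) {
    sum((g ^ op[r, "x"]) %o% (g ^ op[r, "y"]) * mat)
  }, numeric(1))
  names(out) <- paste0("M", moment_orders())
  out
}

#' Centroid of a square matrix
#'
#' (p', q') = (M_10 / M_00, M_01 / M_00) in 0-based grid coordinates.
#'
#' @param mat Square numeric matrix with positive grand sum.
#' @return Numeric vector `c(p, q)`.
#' @export
moment_centroid <- function(mat) {
  m <- raw_moments(mat)
  if (m[["M00"]] == 0) stop("degenerate matrix: M00 is zero")
  c(p = m[["M10"]] / m[["M00"]], q = m[["M01"]] / m[["M00"]])
}

#' Central moments of a square matrix (orders up to 3)
#'
#' U_xy = sum_p sum_q (p - p')^x (q - q')^y f(p, q) about the centroid
#' (p', q'). By construction U_00 = M_00 and U_10 = U_01 = 0. For an
#' all-zero matrix the centroid is undefined; the contract is to return
#' all-zero central moments with a warning rather than divide by zero.
#'
#' @param mat Square numeric matrix.
#' @return Named numeric vector of the 10 moments, names `U00` ... `U03`.
#' @export
central_moments <- function(mat) {
  check_square(mat)
  nm <- paste0("U", moment_orders())
  if (sum(mat) == 0) {
    warning("all-zero matrix: central moments set to zero")
    return(stats::setNames(numeric(10), nm))
  }
  ctr <- moment_centroid(mat)
  n <- nrow(mat)
  g <- 0:(n - 1)
  dp <- g - ctr[["p"]]
  dq <- g - ctr[["q"]]
  op <- order_pairs()
  out <- vapply(seq_len(nrow(op)), function(r) {
    sum((dp ^ op[r, "x"]) %o% (dq ^ op[r, "y"]) * mat)
  }, numeric(1))
  names(out) <- nm
  out
}

# Pochhammer (a)_k in log space; a > 0 required (internal).
log_poch <- function(a, k) {
  if (k == 0) return(0)
  lgamma(a + k) - lgamma(a)
}

#' Discrete Hahn polynomial basis
#'
#' Builds the weighted, square-norm-normalized discrete Hahn polynomials
#' h̃_n(r) for orders `orders` on the support r = 0..N-1, with parameters
#' a, b >= 0 (a = b = 0 reduces to the discrete Chebyshev family). The
#' polynomial values come from the terminating hypergeometric sum
#' Q_n(r) = 3F2(-n, n+a+b+1, -r; a+1, -(N-1); 1); each is then scaled by
#' sqrt(weight(r) / norm_n^2) so that sum_r h̃_m(r) h̃_n(r) = delta_mn.
#' Norms and weights are evaluated through log-gamma, so the construction
#' is stable at the N = 20 side used for incidence matrices.
#'
#' @param N Support size (matrix side); must be at least 4 so that orders
#'   up to 3 exist.
#' @param a,b Non-negative Hahn parameters (default 0).
#' @param orders Integer vector of polynomial orders, default `0:3`.
#' @return An object of class `hahn_basis`: list with `N`, `a`, `b`,
#'   `orders`, and `htilde`, a `length(orders) x N` matrix of normalized
#'   polynomial values (row n+1 is order `orders[n+1]`).
#' @export
hahn_basis <- function(N, a = 0, b = 0, orders = 0:3) {
  if (N < 4) stop("N must be at least 4 (orders up to 3 must exist)")
  if (a < 0 || b < 0) stop("Hahn parameters must be non-negative")
  if (any(orders < 0) || any(orders > N - 1)) {
    stop("orders must lie in 0..N-1")
  }
  Nt <- N - 1  # classical Hahn support parameter: x = 0..Nt
  r <- 0:Nt

  # log weight: binom(a+r, r) * binom(b+Nt-r, Nt-r)
  logw <- (lgamma(a + r + 1) - lgamma(a + 1) - lgamma(r + 1)) +
          (lgamma(b + Nt - r + 1) - lgamma(b + 1) - lgamma(Nt - r + 1))

  qn <- function(n, x) {
    # terminating 3F2 sum; term recurrence avoids factorial overflow
    acc <- 1
    term <- 1
    kmax <- min(n, x)
    if (kmax >= 1) {
      for (k in 0:(kmax - 1)) {
        term <- term * (-n + k) * (n + a + b + 1 + k) * (-x + k) /
          ((a + 1 + k) * (-Nt + k) * (k + 1))
        acc <- acc + term
      }
    }
    acc
  }

  htilde <- matrix(0, length(orders), N)
  for (ii in seq_along(orders)) {
    n <- orders[ii]
    # log norm: d_n^2 = poch(n+a+b+1, Nt+1) poch(b+1, n) n! (Nt-n)! /
    #                   [(2n+a+b+1) poch(a+1, n) (Nt!)^2]
    logd2 <- log_poch(n + a + b + 1, Nt + 1) + log_poch(b + 1, n) +
      lfactorial(n) + lfactorial(Nt - n) -
      log(2 * n + a + b + 1) - log_poch(a + 1, n) - 2 * lfactorial(Nt)
    Q <- vapply(r, function(x) qn(n, x), numeric(1))
    htilde[ii, ] <- Q * exp((logw - logd2) / 2)
  }
  structure(list(N = N, a = a, b = b, orders = orders, htilde = htilde),
            class = "hahn_basis")
}

#' Discrete Hahn moments of a square matrix (orders up to 3)
#'
#' H_ij = sum_q sum_p f(p, q) h̃_i(q) h̃_j(p) for the 10 order pairs, where
#' h̃ are the weighted-normalized Hahn polynomials of `basis`. Because the
#' basis is orthonormal, this is an orthogonal projection of the matrix;
#' with the full order set the projection is invertible.
#'
#' @param mat Square numeric matrix.
#' @param basis A [hahn_basis()] with `N` equal to the matrix side and
#'   containing orders 0..3.
#' @return Named numeric vector of the 10 moments, names `H00` ... `H03`.
#' @export
hahn_moments <- function(mat, basis = NULL) {
  check_square(mat)
  if (is.null(basis)) basis <- hahn_basis(nrow(mat))
  if (!inherits(basis, "hahn_basis") || basis$N != nrow(mat)) {
    stop("basis side must match the matrix side")
  }
  if (!all(0:3 %in% basis$orders)) stop("basis must contain orders 0..3")
  Ht <- basis$htilde[match(0:3, basis$orders), , drop = FALSE]
  # full[j+1, i+1] = h_j' %*% mat %*% h_i  ==  H_ij
  full <- Ht %*% mat %*% t(Ht)
  op <- order_pairs()
  out <- vapply(seq_len(nrow(op)), function(r) {
    full[op[r, "y"] + 1L, op[r, "x"] + 1L]
  }, numeric(1))
  names(out) <- paste0("H", moment_orders())
  out
}

#' Full moment set of a square matrix
#'
#' Bundles the 10 raw, 10 central and 10 Hahn moments (orders up to 3) of
#' one matrix in the fixed order-index set. An all-zero matrix yields 30
#' zeros (with a warning from the central-moment path).
#'
#' @param mat Square numeric matrix.
#' @param basis Optional precomputed [hahn_basis()] (reuse it across
#'   matrices of the same side for speed).
#' @return An object of class `moment_set`: list with elements `raw`,
#'   `central`, `hahn` (each a named 10-vector) and `centroid`.
#' @export
moment_set <- function(mat, basis = NULL) {
  check_square(mat)
  raw <- raw_moments(mat)
  if (raw[["M00"]] == 0) {
    warning("all-zero matrix: centroid set to (0, 0), central moments zero")
    ctr <- c(p = 0, q = 0)
    central <- stats::setNames(numeric(10), paste0("U", moment_orders()))
  } else {
    ctr <- moment_centroid(mat)
    central <- central_moments(mat)
  }
  hahn <- hahn_moments(mat, basis)
  structure(list(raw = raw, central = central, hahn = hahn, centroid = ctr),
            class = "moment_set")
}
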