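#' Moment index pairs computed throughout the package
#'
#' The eight (i, j) order pairs used for every moment family, in fixed
#' order: 00, 01, 10, 11, 12, 21, 30, 03.
#'
#' @format Integer matrix with columns `i` and `j`.
#' @export
MOMENT_ORDERS <- matrix(
  c(0L, 0L,  0L, 1L,  1L, 0L,  1L, 1L,
    1L, 2L,  2L, 1L,  3L, 0L,  0L, 3L),
  ncol = 2L, byrow = TRUE,
  dimnames = list(c("00", "01", "10", "11", "12", "21", "30", "03"),
                  c("i", "j")))

moment_names <- function(prefix) paste0(prefix, rownames(MOMENT_ORDERS))

#' Arrange a 1D residue-code sequence as a square 2D grid
#'
#' A k-element sequence is placed row-major into the smallest square
#' matrix that holds it, `n = ceiling(sqrt(k))`; trailing cells are 0.
#' For the 41-mer windows this gives a 7x7 grid with 8 trailing zeros.
#'
#' @param codes Numeric/integer vector (k >= 1), e.g. window codes.
#' @return n x n numeric matrix.
#' @examples
#' reshape_to_grid(1:4)            # 2x2, row-major
#' dim(reshape_to_grid(rep(1, 41)))  # 7 7
#' @export
reshape_to_grid <- function(codes) {
  codes <- as.numeric(as_window_codes(codes))
  k <- length(codes)
  if (k < 1L) stop("cannot grid an empty sequence")
  n <- ceiling(sqrt(k))
  matrix(c(codes, numeric(n * n - k)), nrow = n, ncol = n, byrow = TRUE)
}

#' Raw geometric moments of a 2D grid
#'
#' `M_ij = sum_p sum_q p^i q^j beta[p, q]` with grid coordinates p
#' (row) and q (column) running 1..n.  The eight orders of
#' [MOMENT_ORDERS] are returned.
#'
#' @param grid Square numeric matrix.
#' @return Named numeric vector `m00 ... m03`.
#' @export
raw_moments <- function(grid) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid))
  n <- nrow(grid)
  p <- seq_len(n)
  vals <- vapply(seq_len(nrow(MOMENT_ORDERS)), function(m) {
    i <- MOMENT_ORDERS[m, "i"]; j <- MOMENT_ORDERS[m, "j"]
    sum(outer(p^i, p^j) * grid)
  }, numeric(1))
  names(vals) <- moment_names("m")
  vals
}

#' Centroid of a grid
#'
#' `(x, y) = (M10/M00, M01/M00)`; defined only for grids with nonzero
#' total mass `M00`.
#'
#' @param grid Square numeric matrix.
#' @return Named numeric vector `c(x, y)`.
#' @export
centroid <- function(grid) {
  m <- raw_moments(grid)
  if (m[["m00"]] == 0) {
    stop("centroid undefined: grid has zero total mass (M00 = 0)")
  }
  c(x = m[["m10"]] / m[["m00"]], y = m[["m01"]] / m[["m00"]])
}

#' Central moments of a 2D grid
#'
#' Raw moments taken about the centroid,
#' `eta_ij = sum (p - x)^i (q - y)^j beta[p, q]`, which makes them
#' invariant to translation of the mass pattern within the grid.
#'
#' @param grid Square numeric matrix with nonzero `M00`.
#' @return Named numeric vector `c00 ... c03`.
#' @export
central_moments <- function(grid) {
  ctr <- centroid(grid)
  n <- nrow(grid)
  dp <- seq_len(n) - ctr[["x"]]
  dq <- seq_len(n) - ctr[["y"]]
  vals <- vapply(seq_len(nrow(MOMENT_ORDERS)), function(m) {
    i <- MOMENT_ORDERS[m, "i"]; j <- MOMENT_ORDERS[m, "j"]
    sum(outer(dp^i, dq^j) * grid)
  }, numeric(1))
  names(vals) <- moment_names("c")
  vals
}

# ---- discrete Hahn polynomials ------------------------------------------

# Pochhammer (a)_k as log-magnitude + sign, stable for the N = 20
# incidence-matrix case.  Handles non-positive a (finite product with
# sign tracking and exact zeros).
poch_ls <- function(a, k) {
  if (k == 0L) return(c(logmag = 0, sign = 1))
  f <- a + seq_len(k) - 1
  if (any(f == 0)) return(c(logmag = -Inf, sign = 0))
  c(logmag = sum(log(abs(f))), sign = prod(sign(f)))
}

#' Discrete Hahn polynomial
#'
#' Evaluates the classical Hahn polynomial `h_n^{(u,v)}(r, N)` on the
#' integer support `r = 0..N-1`, in the terminating hypergeometric form
#' `3F2(-n, n+u+v+1, -r; v+1, 1-N; 1)`.  The family is orthogonal on
#' the support with respect to the weight [hahn_weight()].  Pochhammer
#' products are evaluated in log space.
#'
#' @param n Polynomial order, `0 <= n <= N-1`.
#' @param r Evaluation point(s) in `0..N-1` (vectorised).
#' @param N Support size.
#' @param u,v Hahn shape parameters (> -1); `u = v = 0` (the default)
#'   gives the uniform-weight discrete Chebyshev case.
#' @return Numeric vector, one value per `r`.
#' @export
hahn_polynomial <- function(n, r, N, u = 0, v = 0) {
  n <- as.integer(n)
  if (n < 0L || n > N - 1L) stop("order n must lie in 0..N-1")
  if (any(r < 0 | r > N - 1)) stop("argument r must lie in 0..N-1")
  vapply(r, function(ri) {
    total <- 0
    for (k in 0:n) {
      num <- rbind(poch_ls(-n, k), poch_ls(n + u + v + 1, k),
                   poch_ls(-ri, k))
      den <- rbind(poch_ls(v + 1, k), poch_ls(1 - N, k))
      s <- prod(num[, "sign"]) * prod(den[, "sign"])
      if (s == 0 && any(num[, "sign"] == 0)) next
      total <- total + s * exp(sum(num[, "logmag"]) -
                                 sum(den[, "logmag"]) - lgamma(k + 1))
    }
    total
  }, numeric(1))
}

#' Hahn orthogonality weight
#'
#' `rho(r) = Gamma(N+u-r) Gamma(v+1+r) / (Gamma(r+1) Gamma(N-r))` on
#' `r = 0..N-1`; constant (= 1) when `u = v = 0`.
#'
#' @inheritParams hahn_polynomial
#' @return Numeric vector of weights.
#' @export
hahn_weight <- function(r, N, u = 0, v = 0) {
  if (any(r < 0 | r > N - 1)) stop("argument r must lie in 0..N-1")
  exp(lgamma(N + u - r) + lgamma(v + 1 + r) -
        lgamma(r + 1) - lgamma(N - r))
}

.hahn_cache <- new.env(parent = emptyenv())

#' Orthonormal Hahn basis matrix
#'
#' Returns the matrix `Phi` with `Phi[n+1, r+1] = h~_n(r)`, the
#' weighted and norm-scaled polynomials
#' `h~_n(r) = h_n(r) sqrt(rho(r) / d_n^2)`.  The square norm `d_n^2 =
#' sum_r rho(r) h_n(r)^2` is evaluated by exact summation over the
#' finite support, so rows are orthonormal by construction.  Bases are
#' memoised per `(N, u, v, orders)`.
#'
#' @param N Support size (grid dimension).
#' @param u,v Hahn shape parameters (default 0).
#' @param orders Polynomial orders to include (default all, `0..N-1`).
#' @return `length(orders) x N` numeric matrix.
#' @export
hahn_basis <- function(N, u = 0, v = 0, orders = 0:(N - 1)) {
  key <- paste(N, u, v, paste(orders, collapse = ","), sep = "|")
  hit <- .hahn_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- 0:(N - 1)
  rho <- hahn_weight(r, N, u, v)
  phi <- t(vapply(orders, function(n) {
    h <- hahn_polynomial(n, r, N, u, v)
    d2 <- sum(rho * h^2)
    h * sqrt(rho / d2)
  }, numeric(N)))
  rownames(phi) <- as.character(orders)
  .hahn_cache[[key]] <- phi
  phi
}

#' Discrete Hahn moments of a 2D grid
#'
#' Projects the grid onto the orthonormal Hahn basis,
#' `H_ij = sum_p sum_q beta[p, q] h~_i(q) h~_j(p)` with 0-based
#' support coordinates, and returns the eight orders of
#' [MOMENT_ORDERS].
#'
#' @param grid Square numeric matrix (N x N).
#' @param u,v Hahn shape parameters (default 0).
#' @return Named numeric vector `h00 ... h03`.
#' @export
hahn_moments <- function(grid, u = 0, v = 0) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid))
  N <- nrow(grid)
  maxord <- max(MOMENT_ORDERS)
  phi <- hahn_basis(N, u, v, orders = 0:maxord)
  H <- phi %*% t(grid) %*% t(phi)   # H[i+1, j+1] = sum beta_pq phi_i(q) phi_j(p)
  vals <- H[cbind(MOMENT_ORDERS[, "i"] + 1L, MOMENT_ORDERS[, "j"] + 1L)]
  names(vals) <- moment_names("h")
  vals
}

#' Full Hahn transform and its inverse
#'
#' `hahn_transform()` computes the complete N x N array of Hahn
#' moments; `inverse_hahn_transform()` reconstructs the grid from it.
#' Because the basis is orthonormal the round trip is exact up to
#' floating point — the transform conserves the full positional and
#' compositional content of the grid.
#'
#' @param grid Square numeric matrix.
#' @param H N x N Hahn moment matrix.
#' @param u,v Hahn shape parameters (default 0).
#' @return A matrix (moments, or the reconstructed grid).
#' @export
hahn_transform <- function(grid, u = 0, v = 0) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid))
  phi <- hahn_basis(nrow(grid), u, v)
  phi %*% t(grid) %*% t(phi)
}

#' @rdname hahn_transform
#' @export
inverse_hahn_transform <- function(H, u = 0, v = 0) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  phi <- hahn_basis(nrow(H), u, v)
  t(t(phi) %*% H %*% phi)
}
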