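#' The 24-coefficient moment block of a square matrix
#'
#' Raw (8), central (8) and Hahn (8) moments of a square matrix, in the
#' fixed order of [MOMENT_ORDERS].  When the matrix has zero total mass
#' (`M00 = 0`, e.g. an all-zero matrix) the centroid is undefined and
#' the central block is set to zeros by convention.
#'
#' @param mat Square numeric matrix (the 7x7 window grid or a 20x20
#'   incidence matrix).
#' @param prefix Name prefix for the returned coefficients.
#' @return Named numeric vector of length 24.
#' @export
matrix_moment_block <- function(mat, prefix = "") {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop("moment block requires a square matrix")
  }
  raw <- raw_moments(mat)
  ctr <- if (raw[["m00"]] == 0) {
    stats::setNames(numeric(8L), moment_names("c"))
  } else {
    central_moments(mat)
  }
  hah <- hahn_moments(mat)
  out <- c(raw, ctr, hah)
  names(out) <- paste0(prefix, names(out))
  out
}

#' Assemble the full feature vector of a site window
#'
#' Concatenates, in fixed order, the 173 coefficients describing a
#' 41-residue site vicinity window:
#' site vicinity vector (41 integer codes), frequency vector (20),
#' AAPIV (20), RAAPIV (20), then the 24-coefficient moment blocks
#' (raw, central, Hahn) of the 7x7 window grid, of PRIM and of RPRIM.
#'
#' @param window Window-like object of length 41 (see
#'   [as_window_codes()]).
#' @return Named numeric vector of length 173.
#' @export
assemble_feature_vector <- function(window) {
  codes <- as_window_codes(window)
  if (length(codes) != 41L) {
    stop("feature assembly expects a 41-residue window, got ",
         length(codes))
  }
  svv <- stats::setNames(as.numeric(codes), sprintf("svv%02d", 1:41))
  fm <- frequency_vector(codes); names(fm) <- paste0("fm_", AA_LETTERS)
  ap <- aapiv(codes); names(ap) <- paste0("aapiv_", AA_LETTERS)
  rp <- raapiv(codes); names(rp) <- paste0("raapiv_", AA_LETTERS)
  c(svv, fm, ap, rp,
    matrix_moment_block(reshape_to_grid(codes), "grid_"),
    matrix_moment_block(prim(codes), "prim_"),
    matrix_moment_block(rprim(codes), "rprim_"))
}

#' Feature matrix for a window table
#'
#' @param windows Window table (data frame with a `window` column of
#'   41-letter strings) or a list of windows.
#' @return Numeric matrix, one row per window, 173 columns.
#' @export
feature_matrix <- function(windows) {
  wins <- if (is.data.frame(windows)) windows$window else windows
  X <- t(vapply(wins, function(w) assemble_feature_vector(w),
                numeric(173L)))
  rownames(X) <- if (is.data.frame(windows)) windows$id else NULL
  X
}

#' Fit / apply per-feature standardisation
#'
#' `fit_scaler()` estimates per-feature mean and standard deviation on
#' a training feature matrix; `apply_scaler()` centres and scales new
#' rows with those estimates.  Constant features get spread 1 so they
#' pass through unchanged (centred).  Scaling is plumbing for
#' gradient-descent stability — Hahn-moment magnitudes dwarf the raw
#' residue codes — and must be fitted on training data only.
#'
#' @param X Numeric matrix, windows in rows.
#' @return `fit_scaler()`: an object of class `nglyc_scaler`;
#'   `apply_scaler()`: the standardised matrix.
#' @export
fit_scaler <- function(X) {
  if (!is.matrix(X)) X <- rbind(X)
  if (nrow(X) == 0L) stop("cannot fit a scaler on an empty set")
  ctr <- colMeans(X)
  spr <- apply(X, 2L, stats::sd)
  spr[!is.finite(spr) | spr == 0] <- 1
  structure(list(center = ctr, scale = spr), class = "nglyc_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `nglyc_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(scaler, X) {
  if (!inherits(scaler, "nglyc_scaler")) {
    stop("apply_scaler needs params produced by fit_scaler()")
  }
  one <- !is.matrix(X)
  if (one) X <- rbind(X)
  if (ncol(X) != length(scaler$center)) {
    stop("feature count does not match the fitted scaler")
  }
  out <- sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
  if (one) out[1L, ] else out
}
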