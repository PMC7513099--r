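# The regular histogram mapped to the hypersphere: binning, square-root
# parameters, constrained MLE and the (constant) Fisher information.

#' Bin a univariate sample into equal-width intervals
#'
#' Partitions `[min(data), max(data)]` (or an explicit `range`) into `K`
#' equal-width bins, half-open `[a, b)` except for the last bin which is
#' closed so the maximum is counted.  The result carries everything the
#' selection criteria need: counts `v`, sample size `N`, range `R`, bin width
#' `h = R/K` and the bin edges.
#'
#' @param data Numeric vector with at least two finite values.
#' @param K Number of bins (positive integer).
#' @param range Optional length-2 numeric, a known support `c(lo, hi)`
#'   overriding the sample range; all data must fall inside it.
#' @return An object of class `binned_sample`: a list with fields `N`, `K`,
#'   `R`, `h`, `v` (integer counts summing to `N`) and `edges` (length
#'   `K + 1`).
#' @examples
#' bin_counts(c(0, 0.5, 1), K = 2)$v # 1 2
#' @export
bin_counts <- function(data, K, range = NULL) {
  if (!is.numeric(data) || length(data) < 2L) {
    stop("'data' must be a numeric vector with at least 2 values", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("'data' contains missing or non-finite values", call. = FALSE)
  }
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 1 || K != round(K)) {
    stop("'K' must be a single positive integer", call. = FALSE)
  }
  K <- as.integer(K)
  if (is.null(range)) {
    lo <- min(data)
    hi <- max(data)
  } else {
    if (!is.numeric(range) || length(range) != 2L || anyNA(range) ||
        range[1] >= range[2]) {
      stop("'range' must be c(lo, hi) with lo < hi", call. = FALSE)
    }
    lo <- range[1]
    hi <- range[2]
    if (min(data) < lo || max(data) > hi) {
      stop("data fall outside the supplied 'range'", call. = FALSE)
    }
  }
  R <- hi - lo
  if (R <= 0) {
    stop("zero range: all data values are equal, no histogram can be fit",
         call. = FALSE)
  }
  h <- R / K
  idx <- floor((data - lo) / h) + 1
  idx[idx > K] <- K # points at (or rounding onto) the upper edge
  idx[idx < 1L] <- 1L
  v <- tabulate(idx, nbins = K)
  edges <- lo + h * (0:K)
  edges[K + 1L] <- hi
  structure(
    list(N = length(data), K = K, R = R, h = h, v = v, edges = edges),
    class = "binned_sample"
  )
}

#' @export
print.binned_sample <- function(x, ...) {
  cat(sprintf("Binned sample: N = %d, K = %d bins of width %.6g over [%.6g, %.6g]\n",
              x$N, x$K, x$h, x$edges[1], x$edges[x$K + 1L]))
  cat("counts:", x$v, "\n")
  invisible(x)
}

#' Constrained maximum-likelihood estimate on the hypersphere
#'
#' Under the square-root parameterization \eqn{u_k^2 = c_k} the histogram's
#' bin heights sit on the sphere \eqn{\sum_k u_k^2 = 1/h = K/R}.  Maximizing
#' the multinomial likelihood under that constraint gives
#' \deqn{\hat u_k = \sqrt{v_k K / (N R)}, \qquad \hat\lambda = N R / K,}
#' where \eqn{\hat\lambda} is the optimal Lagrange multiplier.  Empty bins
#' land exactly on the coordinate axes (\eqn{\hat u_k = 0}).
#'
#' @param binned A [bin_counts()] result.
#' @return An object of class `sphere_mle`: list with `u_hat` (length `K`)
#'   and `lambda_hat`.
#' @export
sphere_mle <- function(binned) {
  stopifnot(inherits(binned, "binned_sample"))
  structure(
    list(
      u_hat = sqrt(binned$v * binned$K / (binned$N * binned$R)),
      lambda_hat = binned$N * binned$R / binned$K
    ),
    class = "sphere_mle"
  )
}

#' Histogram negative log-likelihood at the constrained MLE
#'
#' Returns \eqn{-\sum_k 2 v_k \ln \hat u_k}, the (un-averaged) negative
#' log-likelihood of the binned data at the sphere MLE, using the convention
#' \eqn{0 \ln 0 = 0} for empty bins.  This is the shared goodness-of-fit
#' term of every criterion in the package.
#'
#' @inheritParams sphere_mle
#' @param mle Optionally a precomputed [sphere_mle()]; recomputed otherwise.
#' @return A single finite number.
#' @export
neg_log_likelihood <- function(binned, mle = sphere_mle(binned)) {
  stopifnot(inherits(binned, "binned_sample"), inherits(mle, "sphere_mle"))
  pos <- binned$v > 0
  if (any(pos & mle$u_hat == 0)) {
    stop("internal error: zero parameter with a non-empty bin", call. = FALSE)
  }
  -sum(2 * binned$v[pos] * log(mle$u_hat[pos]))
}

#' Diagonal of the Lagrange-corrected Hessian
#'
#' At the constrained MLE the Hessian of the Lagrangian (average negative
#' log-likelihood plus the sphere constraint term) is diagonal with every
#' entry equal to \eqn{4h = 4R/K}: the curvature of the constrained problem
#' is identical in all directions, which is what reduces the sphere Laplace
#' integral to a von Mises-Fisher normalizer.
#'
#' @inheritParams sphere_mle
#' @return The common diagonal entry \eqn{4R/K}.
#' @export
hessian_diagonal <- function(binned) {
  stopifnot(inherits(binned, "binned_sample"))
  4 * binned$R / binned$K
}

#' Log square-root determinant of the Fisher information
#'
#' The histogram Fisher information is the constant diagonal matrix
#' \eqn{I_{kk} = 4R/K} (the expectation of the Hessian), independent of the
#' parameters, so \eqn{\ln\sqrt{\det I} = (K/2)\ln(4R/K)}.
#'
#' @inheritParams sphere_surface_log_volume
#' @param R Positive data range.
#' @return \eqn{(K/2)\ln(4R/K)}.
#' @export
fisher_log_det_sqrt <- function(K, R) {
  K <- .check_K(K)
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    stop("'R' must be a single positive number", call. = FALSE)
  }
  (K / 2) * log(4 * R / K)
}

#' Read a univariate sample from a plain-text file
#'
#' Reads one numeric value per line (plain text or single-column CSV, no
#' header).  Blank lines and non-numeric entries are rejected with an error
#' naming the offending line, rather than silently dropped.
#'
#' @param path Path to the file.
#' @return Numeric vector.
#' @export
read_sample <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
  trimmed <- trimws(lines)
  blank <- !nzchar(trimmed)
  if (any(blank)) {
    stop(sprintf("blank line %d in %s; remove it or supply a value",
                 which(blank)[1], path), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(trimmed))
  bad <- is.na(vals)
  if (any(bad)) {
    stop(sprintf("line %d of %s is not a number: '%s'",
                 which(bad)[1], path, trimmed[which(bad)[1]]), call. = FALSE)
  }
  vals
}
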