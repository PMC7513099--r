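# Hypersphere volumes and von Mises-Fisher normalizing constants, all in the
# log domain so that they stay finite for thousands of parameters and
# concentration parameters up to 1e6 and beyond.

.check_K <- function(K) {
  if (!is.numeric(K) || length(K) < 1L || anyNA(K) ||
      any(K < 1) || any(K != round(K))) {
    stop("'K' must be a positive integer (or vector of positive integers)",
         call. = FALSE)
  }
  as.numeric(K)
}

#' Log surface area of the unit hypersphere
#'
#' Natural log of the Riemannian volume (surface area) \eqn{V_M} of the unit
#' \eqn{(K-1)}-sphere embedded in \eqn{R^K}.  Computed through the log-gamma
#' form \eqn{\ln V_M = \ln 2 + (K/2)\ln\pi - \ln\Gamma(K/2)}, which agrees
#' with the familiar parity-split factorial formulas
#' (\eqn{K\pi^{K/2}/(K/2)!} for even \eqn{K},
#' \eqn{2^K \pi^{(K-1)/2} ((K-1)/2)!/(K-1)!} for odd \eqn{K}) but never
#' overflows: it is finite for \eqn{K} well beyond \eqn{10^4}.
#'
#' Over integer dimensions the surface area peaks at \eqn{K = 7}
#' (\eqn{16\pi^3/15 \approx 33.07}) and decreases monotonically toward zero
#' from \eqn{K = 8} on, which is why volume-based complexity penalties treat
#' seven-parameter families as the geometrically "roomiest".
#'
#' @param K Positive integer (vectorized): the embedding dimension, equal to
#'   the number of model parameters.
#' @return \eqn{\ln V_M}, same length as `K`.
#' @seealso [histogram_manifold_log_volume()], [vonmises_log_normalizer()]
#' @examples
#' exp(sphere_surface_log_volume(2)) # 2*pi, the circle
#' which.max(exp(sphere_surface_log_volume(1:50))) # 7
#' @export
sphere_surface_log_volume <- function(K) {
  K <- .check_K(K)
  log(2) + (K / 2) * log(pi) - lgamma(K / 2)
}

#' Log volume of the histogram parameter manifold
#'
#' The square-root parameters of a regular histogram with \eqn{K} bins over a
#' data range \eqn{R} live on the hypersphere of radius \eqn{\sqrt{K/R}}, and
#' the Fisher information contributes a constant metric factor
#' \eqn{(4R/K)^{K/2}}.  Radius and metric combine to a factor \eqn{2^K} that
#' is independent of \eqn{R}, giving manifold volume \eqn{V_H = 2^K V_M}.
#'
#' @inheritParams sphere_surface_log_volume
#' @return \eqn{\ln V_H = K \ln 2 + \ln V_M}, same length as `K`.
#' @export
histogram_manifold_log_volume <- function(K) {
  K <- .check_K(K)
  K * log(2) + sphere_surface_log_volume(K)
}

# Olver's uniform large-order asymptotic expansion of log I_nu(nu z), with
# three correction terms (relative error O(nu^-4); ~1e-10 already at nu = 150).
# Used only where base besselI under/overflows: nu >> x or very large x with
# large nu.
.log_bessel_i_uniform <- function(order, kappa) {
  z <- kappa / order
  s <- sqrt(1 + z^2)
  t <- 1 / s
  eta <- s + log(z / (1 + s))
  u1 <- (3 * t - 5 * t^3) / 24
  u2 <- (81 * t^2 - 462 * t^4 + 385 * t^6) / 1152
  u3 <- (30375 * t^3 - 369603 * t^5 + 765765 * t^7 - 425425 * t^9) / 414720
  order * eta - 0.5 * log(2 * pi * order) - 0.5 * log(s) +
    log1p(u1 / order + u2 / order^2 + u3 / order^3)
}

# Hankel large-argument expansion of log I_nu(x), six correction terms:
# I_nu(x) ~ e^x/sqrt(2 pi x) * sum_k (-1)^k a_k(nu)/x^k,
# a_k = prod_{j<=k} (4 nu^2 - (2j-1)^2) / (k! 8^k).  Engaged only deep in the
# large-argument regime x >> nu^2, where it is accurate to ~1e-12.
.log_bessel_i_hankel <- function(order, kappa) {
  mu <- 4 * order^2
  term <- 1
  s <- 1
  for (k in 1:6) {
    term <- term * -(mu - (2 * k - 1)^2) / (k * 8 * kappa)
    s <- s + term
  }
  kappa - 0.5 * log(2 * pi * kappa) + log(s)
}

.log_bessel_i_scalar <- function(order, kappa) {
  if (kappa < 0) stop("'kappa' must be non-negative", call. = FALSE)
  if (kappa == 0) {
    if (order < 0) {
      stop("at kappa = 0 the order must be non-negative", call. = FALSE)
    }
    return(if (order == 0) 0 else -Inf)
  }
  # exponentially scaled evaluation: ln I_nu(k) = k + ln(e^-k I_nu(k))
  scaled <- suppressWarnings(besselI(kappa, order, expon.scaled = TRUE))
  if (is.finite(scaled) && scaled > 0) {
    return(kappa + log(scaled))
  }
  # base besselI lost the value.  That happens (a) for arguments beyond
  # ~1.4e5, any order -- covered by the Hankel expansion -- and (b) for
  # orders much larger than the argument -- covered by Olver's expansion.
  if (kappa >= 100 * (order^2 + 1)) {
    return(.log_bessel_i_hankel(order, kappa))
  }
  if (order >= 10) {
    return(.log_bessel_i_uniform(order, kappa))
  }
  stop(sprintf("besselI failed for order = %g, kappa = %g", order, kappa),
       call. = FALSE)
}

#' Log modified Bessel function of the first kind
#'
#' Stable evaluation of \eqn{\ln I_\nu(\kappa)}.  The workhorse is the
#' exponentially scaled base Bessel
#' (\eqn{\ln I_\nu(\kappa) = \kappa + \ln(e^{-\kappa} I_\nu(\kappa))}), which
#' keeps arguments up to \eqn{10^6} and beyond inside double range; the
#' unscaled \eqn{I_\nu} already overflows near \eqn{\kappa \approx 700}.
#' Where the scaled routine itself underflows (order much larger than the
#' argument, or very large order and argument together) Olver's uniform
#' large-order expansion takes over.
#'
#' Negative half-integer orders are supported: the criterion for a
#' single-bin histogram needs \eqn{I_{-1/2}(\kappa) =
#' \sqrt{2/(\pi\kappa)}\cosh\kappa}.
#'
#' @param order Real order \eqn{\nu \ge -1/2} (vectorized).
#' @param kappa Non-negative real argument (vectorized); if `kappa` is 0 the
#'   order must be non-negative (\eqn{I_0(0)=1}, \eqn{I_\nu(0)=0} otherwise).
#' @return \eqn{\ln I_\nu(\kappa)} with the usual recycling of arguments.
#' @examples
#' log_bessel_i(0, 0) # 0
#' log_bessel_i(1 / 2, 1) - log(sqrt(2 / pi) * sinh(1)) # ~0
#' @export
log_bessel_i <- function(order, kappa) {
  if (!is.numeric(order) || !is.numeric(kappa) || anyNA(order) || anyNA(kappa)) {
    stop("'order' and 'kappa' must be numeric and non-missing", call. = FALSE)
  }
  if (any(kappa < 0)) stop("'kappa' must be non-negative", call. = FALSE)
  n <- max(length(order), length(kappa))
  order <- rep_len(order, n)
  kappa <- rep_len(kappa, n)
  vapply(seq_len(n), function(i) .log_bessel_i_scalar(order[i], kappa[i]),
         numeric(1))
}

#' Log normalizing constant of the von Mises-Fisher distribution
#'
#' For the density \eqn{\propto \exp(\kappa u^T x)} on the unit
#' \eqn{(K-1)}-sphere, returns \eqn{\ln C_K(\kappa)} where
#' \deqn{C_K(\kappa) = (2\pi/\kappa)^{K/2}\, \kappa\, I_{K/2-1}(\kappa).}
#' At \eqn{\kappa = 0} the distribution is uniform and the constant is the
#' sphere surface area, which is also the continuous limit of the formula;
#' that limit is returned exactly.
#'
#' @inheritParams sphere_surface_log_volume
#' @param kappa Non-negative concentration parameter.
#' @return \eqn{\ln C_K(\kappa)}.
#' @examples
#' # K = 3 has the closed form 4*pi*sinh(kappa)/kappa
#' vonmises_log_normalizer(3, 2) - log(4 * pi * sinh(2) / 2) # ~0
#' @export
vonmises_log_normalizer <- function(K, kappa) {
  K <- .check_K(K)
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0) {
    stop("'kappa' must be a single non-negative number", call. = FALSE)
  }
  if (kappa == 0) {
    return(sphere_surface_log_volume(K))
  }
  (K / 2) * log(2 * pi / kappa) + log(kappa) + log_bessel_i(K / 2 - 1, kappa)
}

#' Large-sample asymptotic form of the Bessel term
#'
#' Truncated large-argument expansion of \eqn{\ln I_{K/2-1}(4N)}:
#' \deqn{I_{K/2-1}(4N) \approx \frac{e^{4N}}{\sqrt{2\pi}}\left[
#'   (4N)^{-1/2} + \frac{4K - 3 - K^2}{8 (4N)^{3/2}}\right],}
#' evaluated in the log domain.  The leading term does not depend on
#' \eqn{K}, which is why the spherical criterion and the ordinary asymptotic
#' MDL converge to the same complexity (up to a \eqn{K}-independent shift) as
#' the sample size grows.
#'
#' @inheritParams sphere_surface_log_volume
#' @param N Positive integer sample size.
#' @return Log of the truncated expansion.
#' @export
log_bessel_asymptotic <- function(K, N) {
  K <- .check_K(K)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != round(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  bracket <- 1 + (4 * K - 3 - K^2) / (32 * N)
  if (any(bracket <= 0)) {
    stop("truncated expansion is not positive here; N is too small for this K",
         call. = FALSE)
  }
  4 * N - 0.5 * log(2 * pi) - 0.5 * log(4 * N) + log1p((4 * K - 3 - K^2) / (32 * N))
}

#' Closed form of the sphere-constrained Laplace integral
#'
#' Log of the Laplace-approximation integral
#' \eqn{\int \exp(-\frac{N}{2}(\theta-\hat\theta)^T H (\theta-\hat\theta))\,
#' d\theta} taken over the radius-\eqn{\sqrt{K/R}} hypersphere carrying the
#' histogram parameters, with the Lagrange-corrected Hessian
#' \eqn{H = 4h\,\mathrm{Id}}.  Expanding the quadratic form under the sphere
#' constraint turns the integrand into a von Mises-Fisher kernel with
#' concentration \eqn{\kappa = 4N}, so the integral collapses to
#' \deqn{(K/R)^{K/2}\, e^{-4N}\, C_K(4N),}
#' independent of where \eqn{\hat\theta} sits on the sphere.  The radius
#' prefactor uses the same \eqn{K}-power scaling convention as
#' [histogram_manifold_log_volume()]; the convention cancels between the two
#' terms of the selection criterion (see the package vignette).
#'
#' @inheritParams log_bessel_asymptotic
#' @param R Positive data range.
#' @return Log of the integral's closed form.
#' @export
laplace_sphere_log_integral <- function(K, R, N) {
  K <- .check_K(K)
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R <= 0) {
    stop("'R' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("'N' must be a positive sample size", call. = FALSE)
  }
  (K / 2) * log(K / R) - 4 * N + vonmises_log_normalizer(K, 4 * N)
}
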