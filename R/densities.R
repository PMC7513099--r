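# The four 1-D Gaussian-mixture benchmark densities (bimodal, skewed
# unimodal, trimodal, claw) as pdf/cdf evaluators and seeded samplers.

#' Construct a Gaussian-mixture specification
#'
#' @param name Identifier for the mixture.
#' @param weights Positive component weights summing to 1.
#' @param means Component means (same length as `weights`).
#' @param sds Positive component standard deviations (same length).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(name, weights, means, sds) {
  if (!is.character(name) || length(name) != 1L) {
    stop("'name' must be a single string", call. = FALSE)
  }
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop("'weights', 'means' and 'sds' must have the same length", call. = FALSE)
  }
  if (any(weights <= 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("'weights' must be positive and sum to 1", call. = FALSE)
  }
  if (any(sds <= 0)) stop("'sds' must be positive", call. = FALSE)
  structure(list(name = name, weights = as.numeric(weights),
                 means = as.numeric(means), sds = as.numeric(sds)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Gaussian mixture '%s' with %d component(s)\n",
              x$name, length(x$weights)))
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Mixture density function
#'
#' @param spec A [mixture_spec()].
#' @param x Numeric vector of evaluation points.
#' @return \eqn{\sum_j w_j \phi((x-\mu_j)/\sigma_j)/\sigma_j}, vectorized
#'   over `x`.
#' @export
mixture_pdf <- function(spec, x) {
  stopifnot(inherits(spec, "mixture_spec"))
  out <- numeric(length(x))
  for (j in seq_along(spec$weights)) {
    out <- out + spec$weights[j] * stats::dnorm(x, spec$means[j], spec$sds[j])
  }
  out
}

#' Mixture cumulative distribution function
#'
#' @inheritParams mixture_pdf
#' @return \eqn{\sum_j w_j \Phi((x-\mu_j)/\sigma_j)}, vectorized over `x`.
#' @export
mixture_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "mixture_spec"))
  out <- numeric(length(x))
  for (j in seq_along(spec$weights)) {
    out <- out + spec$weights[j] * stats::pnorm(x, spec$means[j], spec$sds[j])
  }
  out
}

#' Draw a seeded sample from a Gaussian mixture
#'
#' Each draw picks a component by a weighted categorical draw and then draws
#' from that component's normal.  When `seed` is given the global RNG state
#' is saved and restored, so calls are reproducible without disturbing the
#' caller's random stream.
#'
#' @inheritParams mixture_pdf
#' @param n Number of draws.
#' @param seed Optional integer seed; identical `(spec, n, seed)` give
#'   identical samples.
#' @return Numeric vector of length `n`.
#' @export
mixture_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old_seed)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  comp <- sample.int(length(spec$weights), n, replace = TRUE, prob = spec$weights)
  stats::rnorm(n, spec$means[comp], spec$sds[comp])
}

#' Registry of the four benchmark densities
#'
#' The canonical Marron-Wand parameterizations of the four mixture shapes
#' used throughout the simulation study:
#' \describe{
#'   \item{bimodal}{\eqn{\frac12 N(-1,(2/3)^2) + \frac12 N(1,(2/3)^2)}}
#'   \item{skewed_unimodal}{\eqn{\frac15 N(0,1) + \frac15 N(\frac12,(2/3)^2)
#'     + \frac35 N(\frac{13}{12},(5/9)^2)}}
#'   \item{trimodal}{\eqn{\frac{9}{20} N(-\frac65,(3/5)^2) +
#'     \frac{9}{20} N(\frac65,(3/5)^2) + \frac1{10} N(0,(1/4)^2)}}
#'   \item{claw}{\eqn{\frac12 N(0,1) + \sum_{l=0}^{4} \frac1{10}
#'     N(l/2-1,(1/10)^2)}}
#' }
#' Custom parameterizations can be supplied through
#' [read_mixture_config()].
#'
#' @return Named list of four [mixture_spec()] objects.
#' @export
mixture_registry <- function() {
  list(
    bimodal = mixture_spec("bimodal",
                           weights = c(1 / 2, 1 / 2),
                           means = c(-1, 1),
                           sds = c(2 / 3, 2 / 3)),
    skewed_unimodal = mixture_spec("skewed_unimodal",
                                   weights = c(1 / 5, 1 / 5, 3 / 5),
                                   means = c(0, 1 / 2, 13 / 12),
                                   sds = c(1, 2 / 3, 5 / 9)),
    trimodal = mixture_spec("trimodal",
                            weights = c(9 / 20, 9 / 20, 1 / 10),
                            means = c(-6 / 5, 6 / 5, 0),
                            sds = c(3 / 5, 3 / 5, 1 / 4)),
    claw = mixture_spec("claw",
                        weights = c(1 / 2, rep(1 / 10, 5)),
                        means = c(0, (0:4) / 2 - 1),
                        sds = c(1, rep(1 / 10, 5)))
  )
}

#' Read mixture specifications from a JSON config file
#'
#' The file holds either a single object or an array of objects with fields
#' `name`, `weights`, `means`, `sds`.
#'
#' @param path Path to the JSON file.
#' @return Named list of [mixture_spec()] objects.
#' @export
read_mixture_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.null(raw$name)) raw <- list(raw)
  specs <- lapply(raw, function(m) {
    mixture_spec(m$name, unlist(m$weights), unlist(m$means), unlist(m$sds))
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}
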