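# The five model-selection criteria as interchangeable scores of a binned
# sample.  Every score decomposes as fit + complexity, with the complexity
# term depending only on (K, N) -- never on the observed counts.

.CRITERIA <- c("aic", "bic", "mdl2", "mdl", "spherical")

new_criterion_score <- function(criterion, K, fit_term, complexity_term) {
  structure(
    list(criterion = criterion, K = as.integer(K), score = fit_term + complexity_term,
         fit_term = fit_term, complexity_term = complexity_term),
    class = "criterion_score"
  )
}

#' @export
print.criterion_score <- function(x, ...) {
  cat(sprintf("%s @ K = %d: score = %.6g (fit %.6g + complexity %.6g)\n",
              toupper(x$criterion), x$K, x$score, x$fit_term, x$complexity_term))
  invisible(x)
}

#' Akaike information criterion
#'
#' `2 * neg_loglik + 2K`, on AIC's conventional doubled scale.  The doubling
#' is kept inside the fit term so that `score = fit_term + complexity_term`
#' holds for every criterion.
#'
#' @param neg_loglik Negative log-likelihood at the MLE (natural log), e.g.
#'   from [neg_log_likelihood()].
#' @param K Number of parameters (histogram bins).
#' @return A `criterion_score`.
#' @export
aic <- function(neg_loglik, K) {
  new_criterion_score("aic", K, 2 * neg_loglik, 2 * K)
}

#' Bayesian information criterion
#'
#' `2 * neg_loglik + K * ln N`: like AIC but with a sample-size aware
#' penalty, so ever fewer bins survive as data accumulate.
#'
#' @inheritParams aic
#' @param N Sample size.
#' @return A `criterion_score`.
#' @export
bic <- function(neg_loglik, K, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("'N' must be a positive sample size", call. = FALSE)
  }
  new_criterion_score("bic", K, 2 * neg_loglik, K * log(N))
}

#' Two-part minimum description length
#'
#' Rissanen's original two-part code: `neg_loglik + (K/2) ln(N / 2pi)`.
#' Geometry-blind like AIC/BIC: the penalty sees only the parameter count
#' and sample size.
#'
#' @inheritParams bic
#' @return A `criterion_score`.
#' @export
mdl_two_part <- function(neg_loglik, K, N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("'N' must be a positive sample size", call. = FALSE)
  }
  new_criterion_score("mdl2", K, neg_loglik, (K / 2) * log(N / (2 * pi)))
}

#' Asymptotic (razor) minimum description length
#'
#' The geometric MDL obtained from the negative log of the Bayesian razor:
#' `neg_loglik + (K/2) ln(N / 2pi) + ln V`, where `ln V` is the log
#' Riemannian volume of the parameter manifold -- for the histogram family,
#' [histogram_manifold_log_volume()].  Unlike the two-part code it charges
#' for the size of the model manifold, but its Laplace step still treats the
#' parameter space as flat Euclidean space.
#'
#' @inheritParams bic
#' @param log_manifold_volume Log Riemannian volume of the model manifold.
#' @return A `criterion_score`.
#' @export
mdl_asymptotic <- function(neg_loglik, K, N, log_manifold_volume) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("'N' must be a positive sample size", call. = FALSE)
  }
  new_criterion_score("mdl", K,
                      neg_loglik,
                      (K / 2) * log(N / (2 * pi)) + log_manifold_volume)
}

#' Spherical minimum description length
#'
#' MDL with the Laplace approximation carried out on the hypersphere that
#' actually carries the histogram parameters: the flat Gaussian integral is
#' replaced by the von Mises-Fisher normalizing constant with concentration
#' \eqn{\kappa = 4N}.  The production (`"reduced"`) form, after the constant
#' Fisher determinant cancels, scores
#' \deqn{-\sum_k 2 v_k \ln\hat u_k + \ln V_H(K) + \frac{K}{2}\ln\frac{N}{2\pi}
#'   - \ln I_{K/2-1}(4N).}
#' The `"full"` form keeps every term of the derivation explicitly
#' (\eqn{-\ln\sqrt{\det I}}, \eqn{+\ln V_H}, minus the log of the sphere
#' Laplace integral); it exceeds the reduced form by the
#' \eqn{K}-independent constant \eqn{4N - \ln 4N}, so both select the same
#' bin count.  All Bessel work is done in the log domain: the unscaled
#' \eqn{I_{K/2-1}(4N)} would overflow already near \eqn{N = 180}.
#'
#' @inheritParams sphere_mle
#' @param form `"reduced"` (default, the production criterion) or `"full"`
#'   (term-by-term derivation form, used for consistency checks).
#' @return A `criterion_score` with `criterion = "spherical"`.
#' @export
spherical_mdl <- function(binned, form = c("reduced", "full")) {
  stopifnot(inherits(binned, "binned_sample"))
  form <- match.arg(form)
  K <- binned$K
  N <- binned$N
  nll <- neg_log_likelihood(binned)
  complexity <- if (form == "reduced") {
    histogram_manifold_log_volume(K) + (K / 2) * log(N / (2 * pi)) -
      log_bessel_i(K / 2 - 1, 4 * N)
  } else {
    -fisher_log_det_sqrt(K, binned$R) + histogram_manifold_log_volume(K) -
      laplace_sphere_log_integral(K, binned$R, N)
  }
  if (!is.finite(complexity)) {
    stop("internal error: non-finite spherical complexity", call. = FALSE)
  }
  new_criterion_score("spherical", K, nll, complexity)
}

# Complexity terms for a grid of bin counts, vectorized.  Depends only on
# (criterion, K, N): the counts and the data range never enter, which is
# what makes the decomposition 'fit + complexity' meaningful.
.complexity_grid <- function(criterion, K, N) {
  switch(criterion,
    aic = 2 * K,
    bic = K * log(N),
    mdl2 = (K / 2) * log(N / (2 * pi)),
    mdl = (K / 2) * log(N / (2 * pi)) + histogram_manifold_log_volume(K),
    spherical = histogram_manifold_log_volume(K) + (K / 2) * log(N / (2 * pi)) -
      log_bessel_i(K / 2 - 1, 4 * N),
    stop("unknown criterion: ", criterion, call. = FALSE)
  )
}

#' Score a grid of candidate bin counts
#'
#' Bins the data once per candidate `K` and evaluates the requested criteria
#' on the shared binning, returning one row per (criterion, K).  The fit
#' term is the common histogram negative log-likelihood (doubled for AIC and
#' BIC, which live on the conventional `2x` scale); the complexity term is a
#' function of `K` and `N` only.
#'
#' @inheritParams bin_counts
#' @param k_min,k_max Candidate bin-count range (inclusive).
#' @param criteria Character vector among `"aic"`, `"bic"`, `"mdl2"`,
#'   `"mdl"`, `"spherical"`.
#' @return A data frame with columns `criterion`, `K`, `fit_term`,
#'   `complexity_term`, `score`.
#' @export
histogram_score_table <- function(data, k_min = 1, k_max = min(length(data), 30L),
                                  criteria = .CRITERIA, range = NULL) {
  criteria <- match.arg(criteria, .CRITERIA, several.ok = TRUE)
  if (k_min < 1 || k_min != round(k_min) || k_max != round(k_max)) {
    stop("'k_min' and 'k_max' must be positive integers", call. = FALSE)
  }
  if (k_min > k_max) {
    stop("empty candidate range: k_min > k_max", call. = FALSE)
  }
  N <- length(data)
  if (k_max > N) {
    warning("k_max exceeds the sample size; criteria are still defined but ",
            "most bins will be empty", call. = FALSE)
  }
  Kv <- as.integer(k_min:k_max)
  nll <- vapply(Kv, function(K) neg_log_likelihood(bin_counts(data, K, range)),
                numeric(1))
  out <- lapply(criteria, function(crit) {
    fit <- if (crit %in% c("aic", "bic")) 2 * nll else nll
    comp <- .complexity_grid(crit, Kv, N)
    data.frame(criterion = crit, K = Kv, fit_term = fit,
               complexity_term = comp, score = fit + comp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the number of histogram bins
#'
#' Evaluates one criterion at every candidate bin count and returns the
#' minimizer, with ties broken toward the smaller (more parsimonious) `K`.
#'
#' @inheritParams histogram_score_table
#' @param criterion One of `"aic"`, `"bic"`, `"mdl2"`, `"mdl"`,
#'   `"spherical"`.
#' @return An object of class `bin_selection`: list with `K_star` (chosen
#'   bin count), `criterion` and `scores` (the score table).
#' @examples
#' x <- rnorm(100)
#' sel <- select_bins(x, 1, 20, "spherical")
#' sel$K_star
#' @export
select_bins <- function(data, k_min = 1, k_max = min(length(data), 30L),
                        criterion = "spherical", range = NULL) {
  criterion <- match.arg(criterion, .CRITERIA)
  scores <- histogram_score_table(data, k_min, k_max, criterion, range)
  K_star <- scores$K[which.min(scores$score)] # which.min takes the first tie
  structure(list(K_star = K_star, criterion = criterion, scores = scores),
            class = "bin_selection")
}

#' @export
print.bin_selection <- function(x, ...) {
  cat(sprintf("Bin selection by %s over K in [%d, %d]: K* = %d\n",
              toupper(x$criterion), min(x$scores$K), max(x$scores$K), x$K_star))
  invisible(x)
}
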