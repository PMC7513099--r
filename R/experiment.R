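# The deviation-frequency simulation study: repeated sampling from the
# benchmark mixtures, per-criterion bin selection, and the table counting
# how often each comparator disagrees with spherical MDL.

# Deterministic per-trial seed below 2^31, unique over densities and trials
# (trial indices up to 1e6, up to ~2000 densities), so any single trial can
# be reproduced in isolation.
.trial_seed <- function(master, density_index, trial_index) {
  s <- (as.numeric(master) * 1009 + density_index * 1e6 + trial_index) %%
    2147483646
  as.integer(s) + 1L
}

#' Run one simulation trial
#'
#' Draws one sample of size `n` from the mixture and selects the bin count
#' with every requested criterion on that same sample.
#'
#' @param spec A [mixture_spec()].
#' @param n Sample size per trial.
#' @param k_min,k_max Candidate bin-count range.
#' @param seed Optional integer seed for the draw.
#' @param criteria Criteria to evaluate (always includes the requested set;
#'   defaults to all five).
#' @return Named integer vector of chosen bin counts, one per criterion.
#' @export
run_trial <- function(spec, n = 60, k_min = 1, k_max = min(n, 30L),
                      seed = NULL, criteria = .CRITERIA) {
  criteria <- match.arg(criteria, .CRITERIA, several.ok = TRUE)
  x <- mixture_sample(spec, n, seed)
  scores <- histogram_score_table(x, k_min, k_max, criteria)
  vapply(split(scores, scores$criterion)[criteria], function(s) {
    s$K[which.min(s$score)]
  }, integer(1))
}

#' Deviation-frequency study against spherical MDL
#'
#' For each density, runs `trials` independent trials (each a fresh sample
#' of size `n`, with a deterministic per-trial seed derived from `seed`) and
#' counts, per comparator criterion, the trials in which that criterion's
#' chosen bin count differs from spherical MDL's choice on the same sample.
#'
#' @param specs Named list of [mixture_spec()] objects; defaults to the four
#'   benchmark densities of [mixture_registry()].
#' @param n Sample size per trial (default 60).
#' @param trials Trials per density (default 2500).
#' @param k_min,k_max Candidate bin-count range (default 1..min(n, 30)).
#' @param seed Master seed; the full study is reproducible from it.
#' @param criteria Comparator criteria (default AIC, BIC, two-part MDL,
#'   asymptotic MDL); spherical MDL is always evaluated as the reference.
#' @param detail If `TRUE`, keep the per-trial chosen bin counts for every
#'   density (a `trials x criteria` integer matrix each).
#' @param verbose If `TRUE`, report progress every 100 trials.
#' @return An object of class `deviation_table`: list with `counts` (data
#'   frame, densities as rows plus a `Total` row, comparator criteria as
#'   columns), `meta` (configuration record) and, if requested,
#'   `selections`.
#' @export
deviation_study <- function(specs = mixture_registry(), n = 60, trials = 2500,
                            k_min = 1, k_max = min(n, 30L), seed = 1,
                            criteria = c("aic", "bic", "mdl2", "mdl"),
                            detail = FALSE, verbose = FALSE) {
  if (!is.numeric(trials) || trials < 1) {
    stop("'trials' must be at least 1", call. = FALSE)
  }
  criteria <- match.arg(criteria, setdiff(.CRITERIA, "spherical"),
                        several.ok = TRUE)
  all_crit <- c(criteria, "spherical")
  counts <- matrix(0L, nrow = length(specs), ncol = length(criteria),
                   dimnames = list(names(specs), criteria))
  selections <- if (detail) vector("list", length(specs)) else NULL
  for (d in seq_along(specs)) {
    sel <- matrix(NA_integer_, nrow = trials, ncol = length(all_crit),
                  dimnames = list(NULL, all_crit))
    for (t in seq_len(trials)) {
      ks <- run_trial(specs[[d]], n, k_min, k_max,
                      seed = .trial_seed(seed, d, t), criteria = all_crit)
      sel[t, ] <- ks[all_crit]
      if (verbose && t %% 100 == 0) {
        message(sprintf("density %s: %d/%d trials", names(specs)[d], t, trials))
      }
    }
    counts[d, ] <- colSums(sel[, criteria, drop = FALSE] != sel[, "spherical"])
    if (detail) selections[[d]] <- sel
  }
  tab <- as.data.frame(rbind(counts, Total = colSums(counts)))
  if (detail) names(selections) <- names(specs)
  structure(
    list(counts = tab,
         meta = list(n = n, trials = trials, k_min = k_min, k_max = k_max,
                     seed = seed, densities = names(specs),
                     criteria = criteria),
         selections = selections),
    class = "deviation_table"
  )
}

#' @export
print.deviation_table <- function(x, ...) {
  cat(sprintf(
    "Deviations from spherical MDL over %d trials per density (n = %d, K in [%d, %d], seed %s)\n",
    x$meta$trials, x$meta$n, x$meta$k_min, x$meta$k_max, format(x$meta$seed)))
  print(x$counts)
  invisible(x)
}

#' Write a deviation table to TSV or JSON
#'
#' TSV mirrors the study layout (densities as rows, comparator criteria as
#' columns, plus a `Total` row); JSON carries the counts together with the
#' full configuration metadata.
#'
#' @param x A `deviation_table` from [deviation_study()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_deviation_table <- function(x, path, format = c("tsv", "json")) {
  stopifnot(inherits(x, "deviation_table"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(cbind(density = rownames(x$counts), x$counts),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(counts = cbind(density = rownames(x$counts),
                                             x$counts),
                              meta = x$meta),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
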