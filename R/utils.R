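# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic per-stage sub-seed: offset the global seed by a stable hash
# of the stage name so toggling one stage never shifts another's RNG stream
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 100003L
  (as.integer(seed) + h) %% .Machine$integer.max
}

stop_validation <- function(...) {
  stop(structure(class = c("signedcircles_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("signedcircles_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_format(what, " is missing required column(s): ",
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Summary of a permutation or rewiring null distribution
#'
#' Container used by [rewiring_null()] and [permutation_balance_test()]:
#' the sampled statistic values, their mean, a two-sided percentile
#' confidence interval, and the one-sided exceedance count relative to the
#' observed statistic.
#'
#' @param samples numeric vector of statistic values under the null.
#' @param observed observed value of the statistic.
#' @param conf_level confidence level for the percentile interval.
#' @param seed the seed the samples were generated under.
#' @return An object of class `null_distribution`: a list with elements
#'   `samples`, `n_samples`, `mean`, `ci_level`, `ci_low`, `ci_high`,
#'   `observed`, `exceedance_count` (number of samples greater than or equal
#'   to the observed value) and `seed`.
#' @export
null_distribution <- function(samples, observed, conf_level = 0.95, seed = NA) {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            conf_level > 0, conf_level < 1)
  a <- (1 - conf_level) / 2
  qs <- stats::quantile(samples, c(a, 1 - a), names = FALSE)
  structure(list(
    samples = samples,
    n_samples = length(samples),
    mean = mean(samples),
    ci_level = conf_level,
    ci_low = qs[1],
    ci_high = qs[2],
    observed = observed,
    exceedance_count = sum(samples >= observed),
    seed = seed
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution (%d samples)\n", x$n_samples))
  cat(sprintf("  mean %.4f, %d%% CI (%.4f; %.4f)\n",
              x$mean, round(100 * x$ci_level), x$ci_low, x$ci_high))
  if (!is.na(x$observed)) {
    cat(sprintf("  observed %.4f (%d/%d null samples >= observed)\n",
                x$observed, x$exceedance_count, x$n_samples))
  }
  invisible(x)
}
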