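#' Null-model configuration
#'
#' Shared settings for every standardized effect size in the package.
#' The null scheme is a richness-preserving uniform draw from the regional
#' pool without replacement ("pool draw"), with 999 replicates by default.
#' Significance is the two-sided |SES| > z rule (z = 1.96, P < 0.05);
#' the inequality is strict, so |SES| = 1.96 exactly is not significant.
#'
#' @param n_reps Number of null replicates (>= 1).
#' @param seed Integer seed; every cell and metric derives its own
#'   deterministic substream from it, so results do not depend on the order
#'   in which cells are processed.
#' @param significance_z Two-sided significance threshold on |SES|.
#' @return A list of class `"null_config"`.
#' @export
null_config <- function(n_reps = 999L, seed = 1L, significance_z = 1.96) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("n_reps must be a positive integer")
  structure(list(n_reps = n_reps, seed = as.integer(seed),
                 significance_z = significance_z),
            class = "null_config")
}

#' Read a null-model configuration from a YAML file
#'
#' Recognized keys: `n_reps` (default 999), `seed` (default 1),
#' `significance_z` (default 1.96). Unknown keys are ignored.
#'
#' @param path Path to a YAML (or INI-style `key: value`) file.
#' @return A `"null_config"` list.
#' @export
read_null_config <- function(path) {
  vals <- yaml::read_yaml(path)
  null_config(
    n_reps = if (!is.null(vals$n_reps)) vals$n_reps else 999L,
    seed = if (!is.null(vals$seed)) vals$seed else 1L,
    significance_z = if (!is.null(vals$significance_z)) vals$significance_z else 1.96
  )
}

# Deterministic 31-bit substream seed for a (cell, metric) pair. A rolling
# string hash keeps per-cell results independent of processing order and of
# every other cell's stream.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((h + (as.numeric(seed) %% 2147483647) * 48271) %% 2147483647)
}

#' Draw one null assemblage from a pool
#'
#' Uniform sample of `richness` taxa without replacement. Uses the current
#' RNG state; wrap in [withr::with_seed()] (as [standardized_effect()]
#' does) for reproducible streams.
#'
#' @param pool Character vector of taxon names.
#' @param richness Number of taxa to draw (1 <= richness <= length(pool)).
#' @return Character vector of drawn taxon names.
#' @export
draw_null_assemblage <- function(pool, richness) {
  if (richness <= 0L) stop("richness must be positive")
  if (richness > length(pool)) {
    stop("richness (", richness, ") exceeds pool size (", length(pool), ")")
  }
  pool[sample.int(length(pool), richness)]
}

new_ses_result <- function(observed, null_mean, null_sd, ses, p_rank,
                           n_reps, significance_z) {
  defined <- is.finite(ses)
  significant <- defined && abs(ses) > significance_z
  direction <- if (!defined || ses == 0) "none" else if (ses > 0) "high" else "low"
  structure(list(
    observed = observed, null_mean = null_mean, null_sd = null_sd,
    ses = ses, p_rank = p_rank, n_reps = n_reps,
    significant = significant, direction = direction
  ), class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  cat(sprintf(
    "SES result: observed %.4g, null %.4g +/- %.4g, SES %s, rank P %.4g (%d reps)%s\n",
    x$observed, x$null_mean, x$null_sd,
    if (is.finite(x$ses)) sprintf("%.3f", x$ses) else "undefined",
    x$p_rank, x$n_reps,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Standardized effect size against the pool-draw null
#'
#' Draws `config$n_reps` random assemblages of the given richness from the
#' pool, evaluates `statistic` on each, and standardizes the observed value:
#' `SES = (observed - mean(null)) / sd(null)` with the sample (n-1) s.d.
#' A rank-based P is reported alongside: `(r + 1) / (n_reps + 1)` where `r`
#' counts null values at least as extreme as the observed one, in the tail
#' the SES sign points to. If the null has zero variance (e.g. richness =
#' pool size) the SES is flagged undefined (`NA`) rather than infinite and
#' the result is never significant.
#'
#' The pool is sorted internally before drawing, so the result is invariant
#' to pool ordering.
#'
#' @param observed Observed value of the statistic.
#' @param statistic Function taking a character vector of taxon names and
#'   returning a scalar.
#' @param pool Character vector: the regional pool.
#' @param richness Assemblage size for the null draws.
#' @param config A [null_config()].
#' @param stream_seed Optional integer overriding `config$seed` as this
#'   call's RNG substream (used by per-cell drivers).
#' @return A `"ses_result"` list.
#' @export
standardized_effect <- function(observed, statistic, pool, richness, config,
                                stream_seed = NULL) {
  pool <- sort(pool)
  seed <- if (is.null(stream_seed)) config$seed else stream_seed
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(config$n_reps), function(i) {
      statistic(draw_null_assemblage(pool, richness))
    }, numeric(1L))
  })
  summarize_null(observed, nulls, config)
}

# Turn observed value + null replicate values into a ses_result.
summarize_null <- function(observed, nulls, config) {
  m <- mean(nulls)
  s <- stats::sd(nulls)
  # a degenerate null (e.g. richness = pool size) must flag the SES
  # undefined; summation order makes "constant" statistics differ at the
  # 1e-13 level, so the zero test is relative
  degenerate <- !is.finite(s) || s <= 1e-9 * max(1, abs(m))
  ses <- if (degenerate) NA_real_ else (observed - m) / s
  r <- if (!is.finite(ses) || ses >= 0) {
    sum(nulls >= observed)
  } else {
    sum(nulls <= observed)
  }
  p <- (r + 1) / (length(nulls) + 1)
  new_ses_result(observed, m, s, ses, p, length(nulls), config$significance_z)
}
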