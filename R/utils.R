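# Shared helpers: classed errors, seed fan-out, adjusted Rand index.

tme_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tme_error")))
}

#' @noRd
tme_format_error <- function(msg) tme_error(msg, "tme_format_error")

#' @noRd
tme_config_error <- function(msg) tme_error(msg, "tme_config_error")

#' Derive a stage-specific seed from a run seed
#'
#' A single run seed fans out to per-stage seeds by hashing the stage name,
#' so stages are individually reproducible without seed collisions.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    tme_config_error("seed must be a single finite number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones. Used to score recovery of planted subtypes.
#'
#' @param a,b Vectors of labels of equal length.
#' @return Numeric ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) tme_config_error("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
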