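#' @title Monte-Carlo power for the paired Wilcoxon signed-rank test
#' @description Simulates the power of the exact two-sided Wilcoxon
#'   matched-pairs signed-rank test for paired designs in which the
#'   control proportion of correct diagnoses is Normal(20%, 10%) and the
#'   true control/test difference is a constant shift, so paired
#'   differences are Normal(true_difference, sd). Each replicate draws n
#'   differences, tests them against zero at the configured alpha, and the
#'   power estimate is the rejection fraction.
#' @name power-sim
NULL

#' Power-simulation configuration
#'
#' @param n_range inclusive integer range of sample sizes for
#'   [power_curve()].
#' @param reps Monte-Carlo replicates per sample size.
#' @param mean_control mean control proportion of correct diagnoses, in
#'   percent (descriptive; the paired-difference model depends only on
#'   `true_difference` and `sd`).
#' @param sd standard deviation of the paired differences, in percent.
#' @param true_difference true control/test difference, in percent.
#' @param alpha two-sided significance level.
#' @param seed integer RNG seed.
#' @return a `power_sim_config`.
#' @export
power_sim_config <- function(n_range = 10:25, reps = 10000L,
                             mean_control = 20, sd = 10,
                             true_difference = 10, alpha = 0.01,
                             seed = 1L) {
  stopifnot(reps >= 1, alpha > 0, alpha < 1, sd > 0)
  structure(list(n_range = as.integer(n_range), reps = as.integer(reps),
                 mean_control = mean_control, sd = sd,
                 true_difference = true_difference, alpha = alpha,
                 seed = as.integer(seed)),
            class = "power_sim_config")
}

#' Simulate power at a single sample size
#'
#' Draws `reps` replicates of n paired differences from
#' Normal(true_difference, sd), applies the exact two-sided signed-rank
#' test against zero, and reports the fraction of replicates with
#' p < alpha together with its Monte-Carlo standard error. Continuous
#' draws are tie-free with probability one, so the exact distribution
#' applies throughout n <= 25; larger n fall back to the tie-corrected
#' normal approximation of [wilcoxon_signed_rank()].
#'
#' @param n paired sample size (>= 5; the exact two-sided test cannot
#'   reach alpha = 0.01 below n = 7, so 5-6 draw a warning).
#' @param config a [power_sim_config()].
#' @return list with `n`, `power`, `se`, `reps`, `alpha`.
#' @export
simulate_power <- function(n, config = power_sim_config()) {
  stopifnot(inherits(config, "power_sim_config"))
  if (n < 5) {
    stop("n must be >= 5 (the exact test cannot approach the design ",
         "alpha below that)", call. = FALSE)
  }
  min_p <- 2 / 2^n
  if (min_p >= config$alpha) {
    warning("smallest attainable two-sided p (", format(min_p),
            ") is not below alpha = ", config$alpha,
            "; power is exactly 0 at n = ", n, call. = FALSE)
  }
  rejected <- .with_seed(config$seed + n, function() {
    if (n <= 25L) {
      ptab <- signrank_pvalue_table(n)
      d <- matrix(stats::rnorm(n * config$reps, config$true_difference,
                               config$sd),
                  nrow = n)
      W <- vapply(seq_len(config$reps), function(j) {
        x <- d[, j]
        sum(rank(abs(x))[x > 0])
      }, numeric(1))
      sum(ptab[W + 1L] < config$alpha)
    } else {
      sum(vapply(seq_len(config$reps), function(j) {
        d <- stats::rnorm(n, config$true_difference, config$sd)
        wilcoxon_signed_rank(d)$p_value < config$alpha
      }, logical(1)))
    }
  })
  power <- rejected / config$reps
  list(n = as.integer(n), power = power,
       se = sqrt(power * (1 - power) / config$reps),
       reps = config$reps, alpha = config$alpha)
}

#' Power curve over a range of sample sizes
#'
#' @param config a [power_sim_config()]; `n_range` gives the sample sizes.
#' @return data.frame with columns n, power, se.
#' @export
power_curve <- function(config = power_sim_config()) {
  rows <- lapply(config$n_range, function(n) {
    r <- simulate_power(n, config)
    data.frame(n = r$n, power = r$power, se = r$se)
  })
  do.call(rbind, rows)
}

#' Smallest sample size achieving a target power
#'
#' The estimated power curve is smoothed by isotonic regression before
#' thresholding (the underlying power is nondecreasing in n, so this
#' removes Monte-Carlo flip-flops near the target).
#'
#' @param target target power in (0, 1).
#' @param config a [power_sim_config()].
#' @return list with `n` (smallest sample size whose smoothed power
#'   reaches the target), `curve` (with a `power_smooth` column).
#' @export
min_n_for_power <- function(target, config = power_sim_config()) {
  stopifnot(target > 0, target < 1)
  curve <- power_curve(config)
  iso <- stats::isoreg(curve$n, curve$power)
  curve$power_smooth <- iso$yf
  ok <- which(curve$power_smooth >= target)
  if (length(ok) == 0L) {
    stop("target power ", target, " unreachable in n_range; maximum ",
         "achieved power is ", format(max(curve$power_smooth), digits = 3),
         " at n = ", curve$n[which.max(curve$power_smooth)], call. = FALSE)
  }
  list(n = curve$n[min(ok)], curve = curve)
}
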