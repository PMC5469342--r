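# Event-related synchronization (ERS) and the paired group-comparison
# protocol.

#' Event-related synchronization percentage
#'
#' `ERS(%) = (GBAm - GBAb) / GBAb * 100`: the percentage change of
#' task-related gamma-band power over baseline. Negative values (motor
#' below basal) are event-related desynchronization. The ratio is
#' scale-invariant: a common gain on both powers (e.g. from the shared
#' recording reference) cancels.
#'
#' @param gba_motor Motor-condition band power (microvolts^2), >= 0.
#' @param gba_basal Basal-condition band power (microvolts^2), > 0.
#' @return ERS in percent. Vectorized.
#' @export
#' @examples
#' compute_ers(0.02, 0.01)   # 100
#' compute_ers(0.005, 0.01)  # -50
compute_ers <- function(gba_motor, gba_basal) {
  if (any(gba_basal <= 0))
    stop("basal band power must be strictly positive", call. = FALSE)
  (gba_motor - gba_basal) / gba_basal * 100
}

#' Subject-level ERS from per-trial band powers
#'
#' Per-trial band powers are averaged within each condition first, then
#' the ERS ratio of the two condition means is taken (means-then-ratio,
#' not mean of per-trial ratios).
#'
#' @param basal_gba Per-trial basal band powers: numeric vector or a
#'   [gba_per_trial()] data frame.
#' @param motor_gba Per-trial motor band powers, same forms.
#' @param method Method label (`"original"`, `"imf1"`, `"imf2"`).
#' @param hand `"right"` or `"left"`.
#' @param subject_id Subject identifier.
#' @return An `ers_result`: list with `subject_id`, `method`, `hand`,
#'   `gba_basal`, `gba_motor`, `ers_percent`.
#' @export
subject_ers <- function(basal_gba, motor_gba,
                        method = c("original", "imf1", "imf2"),
                        hand = c("right", "left"),
                        subject_id = "S1") {
  method <- match.arg(method)
  hand <- match.arg(hand)
  bv <- if (is.data.frame(basal_gba)) basal_gba$value_uV2 else
    as.numeric(basal_gba)
  mv <- if (is.data.frame(motor_gba)) motor_gba$value_uV2 else
    as.numeric(motor_gba)
  if (length(bv) == 0 || length(mv) == 0)
    stop("per-trial band power lists must be non-empty", call. = FALSE)
  gb <- mean(bv)
  gm <- mean(mv)
  structure(list(subject_id = subject_id, method = method, hand = hand,
                 gba_basal = gb, gba_motor = gm,
                 ers_percent = compute_ers(gm, gb)),
            class = "ers_result")
}

#' Grand average with 95% confidence interval
#'
#' Arithmetic mean of subject-level ERS values with a t-distribution 95%
#' confidence interval.
#'
#' @param x Numeric vector of subject-level values (percent), or a list
#'   of `ers_result` objects.
#' @return List with `mean`, `ci_lower`, `ci_upper`, `n`.
#' @export
grand_average <- function(x) {
  if (is.list(x) && !is.data.frame(x) && inherits(x[[1]], "ers_result"))
    x <- vapply(x, function(r) r$ers_percent, numeric(1))
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  m <- mean(x)
  half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  list(mean = m, ci_lower = m - half, ci_upper = m + half, n = n)
}

#' Paired comparison of two ERS methods
#'
#' Each sample is tested for normality (by default the Lilliefors-
#' corrected Kolmogorov-Smirnov test, appropriate when the Gaussian
#' parameters are estimated from the data; `lilliefors = FALSE` uses the
#' plain KS test against the fitted normal). If both samples pass at
#' `normality_alpha` the paired Student t-test is used, otherwise the
#' Wilcoxon signed-rank test. Two-sided p-values; identical samples
#' (all-zero differences) report p = 1 by convention.
#'
#' @param a,b Equal-length paired numeric vectors (percent), n >= 5.
#' @param method_a,method_b Labels for reporting.
#' @param normality_alpha Normality-gate significance level.
#' @param lilliefors Use the Lilliefors correction (default `TRUE`).
#' @return A `group_comparison`: list with `method_a`, `method_b`, `n`,
#'   `test_name` (`"paired-t"` or `"wilcoxon"`), `p_value`,
#'   `normality_p_a`, `normality_p_b`.
#' @export
compare_methods <- function(a, b, method_a = "a", method_b = "b",
                            normality_alpha = 0.05, lilliefors = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 5)
    stop("need at least 5 pairs", call. = FALSE)
  norm_p <- function(x) {
    if (stats::sd(x) == 0) return(0)   # degenerate: not Gaussian
    if (lilliefors) nortest::lillie.test(x)$p.value
    else stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
  }
  pa <- norm_p(a)
  pb <- norm_p(b)
  gaussian <- pa >= normality_alpha && pb >= normality_alpha
  d <- a - b
  if (all(d == 0)) {
    test_name <- if (gaussian) "paired-t" else "wilcoxon"
    p <- 1
  } else if (gaussian) {
    test_name <- "paired-t"
    p <- stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    test_name <- "wilcoxon"
    p <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  structure(list(method_a = method_a, method_b = method_b, n = n,
                 test_name = test_name, p_value = p,
                 normality_p_a = pa, normality_p_b = pb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (n = %d): %s, p = %.4g\n",
              x$method_a, x$method_b, x$n, x$test_name, x$p_value))
  invisible(x)
}
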