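#' Normality-gated two-sample test
#'
#' The comparison rule applied throughout the pipeline: a Shapiro-Wilk
#' normality test is run on each sample first; if both pass (p >= 0.05) the
#' samples are compared with a Welch two-sample t-test, otherwise with a
#' two-sided Wilcoxon rank-sum test. The Wilcoxon p-value is exact for
#' group sizes up to 25 (ties permitting) and uses the continuity-corrected
#' normal approximation above that.
#'
#' @param x,y Numeric samples, each with at least 3 values (the Shapiro-Wilk
#'   minimum).
#' @param m Bonferroni family size; `p_corrected = min(1, m * p_raw)`.
#' @param gate_alpha Shapiro-Wilk gate threshold (default 0.05).
#' @return An object of class `gated_test`: list with `test_used` (`"t"` or
#'   `"wilcoxon"`), `statistic`, `p_raw`, `p_corrected`, and
#'   `normality_p` (the two Shapiro-Wilk p-values).
#' @export
gated_two_sample_test <- function(x, y, m = 1, gate_alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L) {
    stop("each sample needs at least 3 values (got ",
         length(x), " and ", length(y), ")")
  }
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  if (px >= gate_alpha && py >= gate_alpha) {
    ht <- stats::t.test(x, y)  # Welch, two-sided
    used <- "t"
  } else {
    exact <- max(length(x), length(y)) <= 25L
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    used <- "wilcoxon"
  }
  structure(list(test_used = used, statistic = unname(ht$statistic),
                 p_raw = ht$p.value,
                 p_corrected = min(1, m * ht$p.value),
                 normality_p = c(x = px, y = py)),
            class = "gated_test")
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4g, p = %.4g (corrected %.4g); Shapiro p = %.3g / %.3g\n",
              if (x$test_used == "t") "Welch t" else "Wilcoxon rank-sum",
              x$statistic, x$p_raw, x$p_corrected,
              x$normality_p[1], x$normality_p[2]))
  invisible(x)
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the family size and caps at 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; must be at least `length(p_values)`. Defaults to
#'   the number of p-values.
#' @return Corrected p-values, same order.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) {
    stop("family size m (", m, ") smaller than the number of p-values (",
         length(p_values), ")")
  }
  pmin(1, m * p_values)
}
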