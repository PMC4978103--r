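#' Mean, SEM and n of a sample
#'
#' @param values Numeric vector; `NA`s dropped. Needs n >= 2 after dropping.
#' @return List with `mean`, `sem` (sample sd with n-1 denominator over
#'   sqrt(n)) and `n`.
#' @examples
#' summarize_values(c(1, 2, 3))  # mean 2, SEM 0.577
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("summary needs at least 2 non-missing values", call. = FALSE)
  }
  list(mean = mean(values),
       sem = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' Two-group comparison with a normality screen
#'
#' Both groups are screened with the Shapiro-Wilk test; if both are
#' consistent with normality (p > `alpha_norm`) the groups are compared with
#' a two-sided pooled-variance independent-samples t-test, otherwise with a
#' two-sided Wilcoxon rank-sum test (exact p for small samples without
#' ties, normal approximation with continuity correction otherwise).
#' Groups with fewer than 3 values cannot be screened and fall back to the
#' rank test with a warning.
#'
#' @param a,b Numeric vectors (sham and burn groups, say); `NA`s dropped.
#' @param alpha Significance level for the comparison. Default 0.05.
#' @param alpha_norm Level for the normality screen. Default 0.05.
#' @param var_equal Pooled-variance t-test (classic independent-samples);
#'   set `FALSE` for Welch. Default `TRUE`.
#' @return List of class `comparison_result`: group means/SEMs/ns,
#'   `normality_p` (per group), `test_used` (`"t_test"` or
#'   `"wilcoxon_rank"`), `p_value`, `significant`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, alpha_norm = 0.05,
                           var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  can_screen <- length(a) >= 3L && length(b) >= 3L
  norm_p <- c(a = NA_real_, b = NA_real_)
  if (can_screen) {
    # shapiro.test errors on zero-variance input; constant data are not normal
    norm_p["a"] <- tryCatch(stats::shapiro.test(a)$p.value, error = function(e) 0)
    norm_p["b"] <- tryCatch(stats::shapiro.test(b)$p.value, error = function(e) 0)
    use_t <- all(norm_p > alpha_norm)
  } else {
    warning("group with n < 3 cannot be screened for normality; ",
            "using rank test", call. = FALSE)
    use_t <- FALSE
  }
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    test_used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
    test_used <- "wilcoxon_rank"
  }
  p <- ht$p.value
  sa <- summarize_values(a); sb <- summarize_values(b)
  structure(
    list(mean_a = sa$mean, sem_a = sa$sem, n_a = sa$n,
         mean_b = sb$mean, sem_b = sb$sem, n_b = sb$n,
         normality_p = norm_p, test_used = test_used,
         p_value = p, significant = (p < alpha)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%.4g +/- %.3g (n=%d) vs %.4g +/- %.3g (n=%d): %s p = %.4g%s\n",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$test_used, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}
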