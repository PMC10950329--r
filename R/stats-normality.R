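#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino's Z of sqrt(b1)) and
#' kurtosis (Anscombe-Glynn's Z of b2) into the omnibus statistic
#' K2 = Z_skew^2 + Z_kurt^2, which is chi-squared with 2 df under normality.
#'
#' @param x Numeric vector, n >= 8.
#' @return A list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @examples
#' dagostino_k2(rnorm(200))
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test requires n >= 8.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) abort("Zero variance; normality test undefined.")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # Skewness: D'Agostino (1970) transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Kurtosis: Anscombe & Glynn (1983) transformation
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  x1 <- (b2 - e_b2) / sqrt(var_b2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + x1 * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality-gated selection of the statistical test
#'
#' Encodes the decision rule used throughout the analysis: when the total
#' sample size n exceeds 100 or the number of independent experiments N
#' exceeds 5, every group is tested for Gaussian distribution with the
#' D'Agostino-Pearson test; if any group rejects normality
#' (p < `alpha_normality`) the nonparametric branch is taken, otherwise the
#' parametric branch. When the gate does not apply (small n and N), the
#' parametric branch is the default. The concrete test follows from the
#' design: unpaired t / Mann-Whitney for two independent groups, one-sample
#' t / one-sample Wilcoxon for values normalized to a reference, one-way
#' ANOVA + Tukey / Kruskal-Wallis + Dunn for three or more groups.
#'
#' @param data A tibble with columns `group` and `value` (for one-sample
#'   designs a single group is enough).
#' @param n_experiments Number of independent experiments N, if the design is
#'   nested (videos within cultures); `NULL` if not applicable.
#' @param design `"auto"` (from the group count), `"two_group"`,
#'   `"one_sample"` or `"multi_group"`.
#' @param alpha_normality Significance level of the normality gate.
#' @param min_n_gate Smallest group size at which the normality test is
#'   valid; if the gate applies but a group is smaller, the gate is skipped
#'   with an explicit flag.
#' @return An object of class `test_plan`: `branch`, `test`, `gate_applied`,
#'   `gate_skipped_small_n`, `normality` (per-group tibble), `design`.
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 60),
#'                     value = rnorm(120))
#' normality_gate(d)
#' @export
normality_gate <- function(data, n_experiments = NULL,
                           design = c("auto", "two_group", "one_sample",
                                      "multi_group"),
                           alpha_normality = 0.05, min_n_gate = 8) {
  design <- match.arg(design)
  dat <- as_tibble(data)
  if (!"value" %in% names(dat)) abort("`data` needs a `value` column.")
  if (!"group" %in% names(dat)) dat$group <- "all"
  groups <- split(dat$value, dat$group)
  k <- length(groups)
  if (design == "auto") {
    design <- if (k == 1) "one_sample" else if (k == 2) "two_group" else
      "multi_group"
  }
  n_total <- nrow(dat)
  gate_applies <- n_total > 100 ||
    (!is.null(n_experiments) && n_experiments > 5)
  gate_skipped <- FALSE
  normality <- tibble(group = names(groups),
                      n = vapply(groups, length, integer(1)),
                      k2 = NA_real_, p = NA_real_)
  branch <- "parametric"
  if (gate_applies) {
    if (any(normality$n < min_n_gate)) {
      gate_skipped <- TRUE
      warn(sprintf(
        "Normality gate applies (n=%d) but a group has fewer than %d values; gate skipped.",
        n_total, min_n_gate))
    } else {
      res <- lapply(groups, dagostino_k2)
      normality$k2 <- vapply(res, `[[`, numeric(1), "statistic")
      normality$p <- vapply(res, `[[`, numeric(1), "p_value")
      if (any(normality$p < alpha_normality)) branch <- "nonparametric"
    }
  }
  test <- switch(design,
    two_group = if (branch == "parametric") "t_unpaired" else "mann_whitney",
    one_sample = if (branch == "parametric") "one_sample_t" else
      "one_sample_wilcoxon",
    multi_group = if (branch == "parametric") "anova_tukey" else
      "kruskal_dunn")
  structure(
    list(branch = branch, test = test,
         gate_applied = gate_applies && !gate_skipped,
         gate_skipped_small_n = gate_skipped,
         normality = normality, design = design,
         alpha_normality = alpha_normality, n_total = n_total,
         n_experiments = n_experiments),
    class = "test_plan"
  )
}

#' @export
print.test_plan <- function(x, ...) {
  cat(sprintf("<test_plan> %s branch -> %s (gate %s)\n", x$branch, x$test,
              if (x$gate_applied) "applied" else
                if (x$gate_skipped_small_n) "skipped (small groups)" else
                  "not required"))
  invisible(x)
}
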