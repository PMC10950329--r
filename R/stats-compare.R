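#' Run the planned group comparison
#'
#' Executes the test selected by [normality_gate()]: unpaired two-tailed
#' Student's t-test, two-sided Mann-Whitney (exact p when the product of the
#' group sizes is at most 400 and no ties are present, normal approximation
#' with tie correction otherwise), one-sample t or one-sample Wilcoxon
#' against `reference_value`, one-way ANOVA with Tukey HSD pairwise adjusted
#' p-values, or Kruskal-Wallis with Dunn's pairwise comparisons
#' (Bonferroni-adjusted by default).
#'
#' @param data A tibble with columns `group` and `value` (one group for
#'   one-sample designs).
#' @param plan A `test_plan`; computed by [normality_gate()] with defaults
#'   when omitted.
#' @param reference_value Reference for one-sample tests (e.g. 100 for
#'   percent-of-control data).
#' @param n_experiments Passed to [normality_gate()] when `plan` is omitted.
#' @param exact_cap Largest product of group sizes for which the exact
#'   Mann-Whitney null distribution is used.
#' @return A tibble of class `stat_result` with one row per comparison
#'   (post-hoc tests add one row per pair after the omnibus row): `test`,
#'   `comparison`, `statistic`, `p_value`, `p_adj`, `n1`, `n2`. The plan is
#'   attached as attribute `"plan"`.
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
#'                     value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
#' compare_groups(d, normality_gate(d))
#' @export
compare_groups <- function(data, plan = NULL, reference_value = NULL,
                           n_experiments = NULL, exact_cap = 400) {
  dat <- as_tibble(data)
  if (!"group" %in% names(dat)) dat$group <- "all"
  dat <- dat[is.finite(dat$value), ]
  groups <- split(dat$value, dat$group)
  if (any(vapply(groups, length, integer(1)) == 0) || length(groups) == 0) {
    abort("Empty groups are not allowed.")
  }
  plan <- plan %||% normality_gate(dat, n_experiments = n_experiments)
  k <- length(groups)
  test <- plan$test

  needs_two <- test %in% c("t_unpaired", "mann_whitney")
  if (needs_two && k != 2) abort("Two-group test planned but k != 2 groups.")
  if (test %in% c("anova_tukey", "kruskal_dunn") && k < 3) {
    abort("Multi-group test planned but fewer than 3 groups.")
  }
  if (test %in% c("one_sample_t", "one_sample_wilcoxon")) {
    if (k != 1) abort("One-sample test planned but more than one group.")
    if (is.null(reference_value)) {
      abort("`reference_value` is required for one-sample tests.")
    }
  }
  if (test %in% c("mann_whitney", "one_sample_wilcoxon", "kruskal_dunn") &&
      length(unique(dat$value)) == 1) {
    abort("All values are identical; rank tests are undefined on tied-only data.")
  }

  rows <- switch(test,
    t_unpaired = {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      result_row(test, paste(names(groups), collapse = " vs "),
                 ht$statistic, ht$p.value,
                 n1 = length(groups[[1]]), n2 = length(groups[[2]]))
    },
    mann_whitney = {
      ties <- anyDuplicated(dat$value) > 0
      exact <- !ties &&
        length(groups[[1]]) * length(groups[[2]]) <= exact_cap
      ht <- suppressWarnings(
        wilcox.test(groups[[1]], groups[[2]], exact = exact,
                    correct = !exact))
      result_row(test, paste(names(groups), collapse = " vs "),
                 ht$statistic, ht$p.value,
                 n1 = length(groups[[1]]), n2 = length(groups[[2]]))
    },
    one_sample_t = {
      ht <- t.test(groups[[1]], mu = reference_value)
      result_row(test, sprintf("%s vs %g", names(groups), reference_value),
                 ht$statistic, ht$p.value, n1 = length(groups[[1]]))
    },
    one_sample_wilcoxon = {
      x <- groups[[1]]
      exact <- !anyDuplicated(x) && !any(x == reference_value) &&
        length(x) <= 50
      ht <- suppressWarnings(
        wilcox.test(x, mu = reference_value, exact = exact))
      result_row(test, sprintf("%s vs %g", names(groups), reference_value),
                 ht$statistic, ht$p.value, n1 = length(x))
    },
    anova_tukey = fit_anova_tukey(dat, groups),
    kruskal_dunn = {
      ht <- kruskal.test(dat$value, factor(dat$group))
      omnibus <- result_row("kruskal_wallis", "omnibus", ht$statistic,
                            ht$p.value, n1 = nrow(dat))
      dplyr::bind_rows(omnibus, dunn_posthoc(dat$value, dat$group))
    })
  structure(rows, class = c("stat_result", class(tibble())), plan = plan)
}

result_row <- function(test, comparison, statistic, p_value,
                       p_adj = NA_real_, n1 = NA_integer_,
                       n2 = NA_integer_) {
  tibble(test = test, comparison = comparison,
         statistic = unname(statistic), p_value = unname(p_value),
         p_adj = p_adj, n1 = n1, n2 = n2)
}

fit_anova_tukey <- function(dat, groups) {
  means <- vapply(groups, mean, numeric(1))
  withinvar <- vapply(groups, function(g) {
    if (length(g) > 1) stats::var(g) else 0
  }, numeric(1))
  if (all(withinvar < .Machine$double.eps)) {
    if (diff(range(means)) < .Machine$double.eps) {
      abort("All groups identical with zero variance; ANOVA is undefined.")
    }
    # Zero within-group variance with distinct means: limiting p of 0
    pairs <- combn(names(groups), 2)
    rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      result_row("tukey_hsd", paste(pairs[, j], collapse = " vs "),
                 Inf, 0, p_adj = 0,
                 n1 = length(groups[[pairs[1, j]]]),
                 n2 = length(groups[[pairs[2, j]]]))
    })
    return(dplyr::bind_rows(
      result_row("anova", "omnibus", Inf, 0, n1 = nrow(dat)), rows))
  }
  dat$group <- factor(dat$group)
  fit <- aov(value ~ group, data = dat)
  s <- summary(fit)[[1]]
  omnibus <- result_row("anova", "omnibus", s[["F value"]][1],
                        s[["Pr(>F)"]][1], n1 = nrow(dat))
  tk <- TukeyHSD(fit)$group
  rows <- tibble(
    test = "tukey_hsd",
    comparison = gsub("-", " vs ", rownames(tk), fixed = TRUE),
    statistic = tk[, "diff"], p_value = tk[, "p adj"],
    p_adj = tk[, "p adj"], n1 = NA_integer_, n2 = NA_integer_)
  dplyr::bind_rows(omnibus, rows)
}

# Dunn's pairwise z-tests on the joint ranks, with tie correction and
# Bonferroni adjustment over all pairs.
dunn_posthoc <- function(value, group, method = "bonferroni") {
  group <- factor(group)
  n <- length(value)
  r <- rank(value)
  tie_tab <- table(value)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  rbar <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  pairs <- combn(levels(group), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[a] + 1 / ns[b]))
    z[j] <- (rbar[a] - rbar[b]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  p_adj <- stats::p.adjust(p, method = method)
  tibble(test = "dunn",
         comparison = apply(pairs, 2, paste, collapse = " vs "),
         statistic = z, p_value = p, p_adj = p_adj,
         n1 = as.integer(ns[pairs[1, ]]), n2 = as.integer(ns[pairs[2, ]]))
}

#' Exact Mann-Whitney p-value by exhaustive enumeration
#'
#' Enumerates every assignment of the pooled observations into groups of the
#' observed sizes, computes the Mann-Whitney U statistic for each, and
#' returns the exact two-sided tail probability
#' P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|). Intended as an independent
#' reference for [compare_groups()]'s exact mode on small samples.
#'
#' @param group_a,group_b Numeric vectors with `length(a) + length(b) <= 12`.
#' @return The exact two-sided p-value.
#' @examples
#' mannwhitney_exact_oracle(c(1, 2), c(3, 4))  # 2/6
#' @export
mannwhitney_exact_oracle <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na + nb > 12) {
    abort("Enumeration oracle is capped at 12 total observations.")
  }
  if (na == 0 || nb == 0) abort("Both groups must be non-empty.")
  pooled <- c(group_a, group_b)
  n <- na + nb
  u_stat <- function(idx_a) {
    a <- pooled[idx_a]; b <- pooled[-idx_a]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(na))
  centre <- na * nb / 2
  labelings <- combn(n, na)
  us <- apply(labelings, 2, u_stat)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}
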