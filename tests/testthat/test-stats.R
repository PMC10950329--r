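test_that("densities are counts per area with order-invariant summaries", {
  rec <- tibble::tibble(synapse_id = 1:3, bouton_area_um2 = c(0.5, 1, 2),
                        svs = c(50L, 100L, 0L))
  d <- density_per_area(rec, "svs")
  expect_equal(d$density, c(100, 100, 0))
  s1 <- density_summary(rec, "svs")
  s2 <- density_summary(rec[c(3, 1, 2), ], "svs")
  expect_equal(s1, s2)
  # all-zero counts: densities and SEM are zero
  rec0 <- tibble::tibble(synapse_id = 1:4, bouton_area_um2 = rep(1, 4),
                         svs = rep(0L, 4))
  s0 <- density_summary(rec0, "svs")
  expect_equal(s0$mean_density, 0)
  expect_equal(s0$sem, 0)
  # zero-area records are rejected with a report
  recz <- tibble::tibble(synapse_id = 1:2, bouton_area_um2 = c(0, 1),
                         svs = c(5L, 5L))
  expect_warning(dz <- density_per_area(recz, "svs"), "rejected")
  expect_equal(nrow(dz), 1)
  expect_error(density_per_area(rec, "nope"), "not present")
})

test_that("the K2 statistic matches a direct evaluation of the formulas", {
  set.seed(31)
  for (x in list(rnorm(150), rlnorm(120), runif(80), rt(200, df = 3))) {
    got <- dagostino_k2(x)
    expect_equal(got$statistic, k2_direct(x), tolerance = 1e-9)
    expect_gte(got$p_value, 0)
    expect_lte(got$p_value, 1)
  }
  expect_error(dagostino_k2(rnorm(5)), "n >= 8")
})

test_that("the normality test rejects lognormal samples with high power", {
  set.seed(8)
  rejected <- sum(replicate(100, dagostino_k2(rlnorm(150))$p_value < 0.05))
  expect_gt(rejected / 100, 0.9)
})

test_that("the gate routes by sample size, experiment count and normality", {
  # small N, two groups: gate not applied, parametric t-test
  set.seed(1)
  small <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                          value = rnorm(8))
  plan <- normality_gate(small, n_experiments = 3)
  expect_false(plan$gate_applied)
  expect_equal(plan$test, "t_unpaired")

  # n > 100 with one lognormal group: nonparametric, Mann-Whitney
  set.seed(2)
  big <- tibble::tibble(group = rep(c("a", "b"), each = 75),
                        value = c(rnorm(75, 10), rlnorm(75)))
  plan2 <- normality_gate(big)
  expect_true(plan2$gate_applied)
  expect_equal(plan2$branch, "nonparametric")
  expect_equal(plan2$test, "mann_whitney")

  # Gaussian data passing the gate stays parametric
  set.seed(3)
  gauss <- tibble::tibble(group = rep(c("a", "b"), each = 75),
                          value = rnorm(150))
  expect_equal(normality_gate(gauss)$test, "t_unpaired")

  # one-group design normalized to a reference: one-sample branch
  set.seed(4)
  one <- tibble::tibble(value = rnorm(150, 110, 20))
  plan3 <- normality_gate(one)
  expect_equal(plan3$design, "one_sample")
  expect_equal(plan3$test, "one_sample_t")

  # N > 5 triggers the gate even at modest n
  set.seed(5)
  mid <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                        value = rnorm(20))
  expect_true(normality_gate(mid, n_experiments = 8)$gate_applied)

  # gate applies but groups too small for the test: skipped with a flag
  tiny <- tibble::tibble(group = rep(c("a", "b"), each = 4), value = rnorm(8))
  expect_warning(plan4 <- normality_gate(tiny, n_experiments = 8), "skipped")
  expect_true(plan4$gate_skipped_small_n)
})

test_that("exact Mann-Whitney enumeration matches hand-counted cases", {
  expect_equal(mannwhitney_exact_oracle(c(1, 2), c(3, 4)), 2 / 6)
  expect_equal(mannwhitney_exact_oracle(1:5, 6:10), 2 / 252)
  # symmetric under group swap
  set.seed(10)
  a <- rnorm(4); b <- rnorm(5)
  expect_equal(mannwhitney_exact_oracle(a, b),
               mannwhitney_exact_oracle(b, a))
  expect_error(mannwhitney_exact_oracle(1:7, 8:14), "capped")
})

test_that("compare_groups' exact Mann-Whitney matches the enumeration oracle", {
  set.seed(20)
  for (i in 1:12) {
    a <- sample(1:50, 5); b <- sample(51:100, 5)
    # shuffle values across groups so U varies
    pool <- sample(c(a, b))
    a <- pool[1:5]; b <- pool[6:10]
    d <- tibble::tibble(group = rep(c("a", "b"), each = 5),
                        value = c(a, b))
    plan <- list(test = "mann_whitney", branch = "nonparametric")
    class(plan) <- "test_plan"
    got <- compare_groups(d, plan)
    expect_equal(got$p_value, mannwhitney_exact_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank tests handle identical groups and reject tied-only data", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                      value = c(1, 2, 3, 1, 2, 3))
  plan <- list(test = "mann_whitney", branch = "nonparametric")
  class(plan) <- "test_plan"
  expect_equal(compare_groups(d, plan)$p_value, 1)
  tied <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                         value = rep(5, 6))
  expect_error(compare_groups(tied, plan), "tied-only")
})

test_that("one-sample tests compare to the normalization reference", {
  set.seed(30)
  d <- tibble::tibble(value = rnorm(30, 120, 15))
  plan <- list(test = "one_sample_t", branch = "parametric")
  class(plan) <- "test_plan"
  got <- compare_groups(d, plan, reference_value = 100)
  ref <- t.test(d$value, mu = 100)
  expect_equal(got$p_value, ref$p.value)
  planw <- list(test = "one_sample_wilcoxon", branch = "nonparametric")
  class(planw) <- "test_plan"
  goty <- compare_groups(d, planw, reference_value = 100)
  expect_lt(goty$p_value, 0.05)
  expect_error(compare_groups(d, planw), "reference_value")
})

test_that("post hoc adjusted p-values never undercut the unadjusted ones", {
  set.seed(40)
  d <- tibble::tibble(group = rep(c("a", "b", "c", "d"), each = 12),
                      value = c(rnorm(12), rnorm(12, 0.5), rnorm(12, 1),
                                rnorm(12, 1.5)))
  plan <- list(test = "kruskal_dunn", branch = "nonparametric")
  class(plan) <- "test_plan"
  kd <- compare_groups(d, plan)
  dunn <- kd[kd$test == "dunn", ]
  expect_equal(nrow(dunn), 6)
  expect_true(all(dunn$p_adj >= dunn$p_value - 1e-15))
  plan2 <- list(test = "anova_tukey", branch = "parametric")
  class(plan2) <- "test_plan"
  at <- compare_groups(d, plan2)
  expect_equal(at$test[1], "anova")
  expect_equal(sum(at$test == "tukey_hsd"), 6)
})

test_that("degenerate multi-group data is flagged or driven to p = 0", {
  plan <- list(test = "anova_tukey", branch = "parametric")
  class(plan) <- "test_plan"
  same <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                         value = rep(5, 12))
  expect_error(compare_groups(same, plan), "undefined")
  sep <- tibble::tibble(group = rep(c("a", "b", "c"), each = 4),
                        value = rep(c(1, 2, 3), each = 4))
  got <- compare_groups(sep, plan)
  expect_equal(got$p_value[1], 0)
  expect_true(all(got$p_adj[got$test == "tukey_hsd"] == 0))
})

test_that("kruskal-wallis omnibus agrees with the base implementation", {
  set.seed(50)
  d <- tibble::tibble(group = rep(c("a", "b", "c"), each = 15),
                      value = c(rlnorm(15), rlnorm(15, 0.4), rlnorm(15, 0.8)))
  plan <- list(test = "kruskal_dunn", branch = "nonparametric")
  class(plan) <- "test_plan"
  got <- compare_groups(d, plan)
  ref <- kruskal.test(d$value, factor(d$group))
  expect_equal(got$p_value[1], ref$p.value)
})
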