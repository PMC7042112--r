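cells_df <- function(values, animal = 1, tech_rep = 1, condition = "a") {
  data.frame(animal = animal, condition = condition, tech_rep = tech_rep,
             peak_amp = values, responder = values > 0)
}

test_that("cells average into technical replicates, then animals", {
  tab <- aggregate_cells(cells_df(c(1, 2, 3)))
  expect_equal(tab$animal_means$value, 2)

  df <- rbind(cells_df(c(0.5, 1.5), tech_rep = 1),
              cells_df(c(1.5, 2.5), tech_rep = 2),
              cells_df(c(2.5, 3.5), tech_rep = 3))
  tab2 <- aggregate_cells(df)
  expect_equal(sort(tab2$tech_rep_means$value), c(1, 2, 3))
  expect_equal(tab2$animal_means$value, 2)
})

test_that("nested aggregation equals a flat nested-loop recomputation", {
  set.seed(9)
  rows <- list()
  for (a in 1:5) for (r in 1:3) {
    rows[[length(rows) + 1L]] <-
      cells_df(rlnorm(30, 0.2, 0.4), animal = a, tech_rep = r)
  }
  df <- do.call(rbind, rows)
  tab <- aggregate_cells(df)
  # oracle: explicit loops
  for (a in 1:5) {
    rep_means <- vapply(1:3, function(r) {
      mean(df$peak_amp[df$animal == a & df$tech_rep == r])
    }, 1)
    expect_equal(tab$animal_means$value[tab$animal_means$animal == a],
                 mean(rep_means), tolerance = 1e-12)
  }
  # order invariance
  tab2 <- aggregate_cells(df[sample(nrow(df)), ])
  expect_equal(tab$animal_means, tab2$animal_means, tolerance = 1e-12)
})

test_that("responders-only filtering drops zero cells before averaging", {
  df <- cells_df(c(0, 0, 2, 4))
  expect_equal(aggregate_cells(df)$animal_means$value, 1.5)
  expect_equal(aggregate_cells(df, responders_only = TRUE)$animal_means$value, 3)
})

test_that("identical paired arms give t = 0, p = 1", {
  df <- rbind(cells_df(c(1, 2), animal = rep(1:4, each = 2), condition = "x"),
              cells_df(c(1, 2), animal = rep(1:4, each = 2), condition = "y"))
  res <- paired_t_log(aggregate_cells(df), "x", "y")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("paired t on log differences matches the textbook formula", {
  # per-animal means chosen so log differences are exactly (1, 1, 2)
  am <- data.frame(
    animal = rep(1:3, 2),
    condition = rep(c("b", "a"), each = 3),
    value = c(exp(1), exp(1), exp(2), 1, 1, 1)
  )
  tb <- structure(list(animal_means = am, metric = "peak_amp"),
                  class = "replicate_table")
  res <- paired_t_log(tb, "b", "a")
  expect_equal(res$statistic, 4, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-4, 2), tolerance = 1e-12)
})

test_that("back-transformed means are geometric means", {
  am <- data.frame(animal = rep(1:2, 2),
                   condition = rep(c("a", "b"), each = 2),
                   value = c(1, exp(2), 2, 2))
  tb <- structure(list(animal_means = am, metric = "peak_amp"),
                  class = "replicate_table")
  res <- paired_t_log(tb, "a", "b")
  expect_equal(res$geometric_mean[1], exp(1), tolerance = 1e-12)
  expect_equal(res$geometric_mean[2], 2, tolerance = 1e-12)
})

test_that("paired test is invariant to common rescaling of both arms", {
  set.seed(3)
  am <- data.frame(animal = rep(1:5, 2),
                   condition = rep(c("a", "b"), each = 5),
                   value = rlnorm(10, 0, 0.3))
  tb <- function(x) structure(list(animal_means = x, metric = "m"),
                              class = "replicate_table")
  r1 <- paired_t_log(tb(am), "a", "b")
  am2 <- am; am2$value <- am2$value * 17.3
  r2 <- paired_t_log(tb(am2), "a", "b")
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
})

test_that("non-positive animal means and broken pairing are errors", {
  am <- data.frame(animal = rep(1:3, 2), condition = rep(c("a", "b"), each = 3),
                   value = c(1, 0, 2, 1, 1, 1))
  tb <- structure(list(animal_means = am, metric = "m"),
                  class = "replicate_table")
  expect_error(paired_t_log(tb, "a", "b"), "non-positive")
  am2 <- data.frame(animal = c(1, 2, 3, 1, 2, 4),
                    condition = rep(c("a", "b"), each = 3),
                    value = rep(1, 6))
  tb2 <- structure(list(animal_means = am2, metric = "m"),
                   class = "replicate_table")
  expect_error(paired_t_log(tb2, "a", "b"), "pairing")
})

test_that("two-way ANOVA: zero SS for constant data, oracle SS otherwise", {
  df0 <- data.frame(value = rep(2, 12),
                    treatment = rep(c("c", "t"), 6),
                    stimulus = rep(c("ip3", "ach"), each = 6))
  res0 <- anova2_tukey(df0, "value", "treatment", "stimulus")
  expect_true(all(res0$anova_table[["Sum Sq"]][1:3] < 1e-20))

  set.seed(14)
  df <- expand.grid(treatment = c("c", "t"), stimulus = c("ip3", "ach"),
                    rep = 1:4)
  df$value <- rlnorm(nrow(df), 0.3, 0.4)
  res <- anova2_tukey(df, "value", "treatment", "stimulus")
  ss <- oracle_anova2_ss(log(df$value), df$treatment, df$stimulus)
  expect_equal(unname(res$anova_table[["Sum Sq"]]), unname(ss),
               tolerance = 1e-10)
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  set.seed(15)
  df <- expand.grid(treatment = c("c", "t"), stimulus = c("ip3", "ach"),
                    rep = 1:5)
  df$value <- rlnorm(nrow(df), 0.3, 0.3)
  res <- anova2_tukey(df, "value", "treatment", "stimulus")
  tuk <- res$tukey$`treatment:stimulus`
  # unadjusted p for each contrast from the same residual MS
  fit <- aov(y ~ treatment * stimulus,
             data = transform(df, y = log(value)))
  mse <- summary(fit)[[1]][["Mean Sq"]][4]
  dfres <- summary(fit)[[1]][["Df"]][4]
  n_per <- 5
  se <- sqrt(2 * mse / n_per)
  p_unadj <- 2 * pt(-abs(tuk[, "diff"]) / se, dfres)
  expect_true(all(tuk[, "p adj"] >= p_unadj - 1e-12))
})

test_that("single-level factors are rejected", {
  df <- data.frame(value = rlnorm(6), a = "x", b = rep(c("u", "v"), 3))
  expect_error(anova2_tukey(df, "value", "a", "b"), "two levels")
})
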