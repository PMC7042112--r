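#' Aggregate per-cell summaries over the replication hierarchy
#'
#' Cells are averaged within each technical replicate, and technical
#' replicates within each animal (biological replicate); both levels are
#' retained. The per-animal means are the unit of all downstream statistics
#' (n = number of animals).
#'
#' @param cell_summaries Data frame with columns `animal`, `condition`,
#'   `tech_rep`, and the metric column (e.g. the output of
#'   [analyze_recording()] with design columns added).
#' @param metric Name of the metric column to aggregate.
#' @param responders_only Drop non-responding cells before averaging
#'   (recommended when aggregating `peak_amp`, whose zeros encode "no
#'   event", and required before log-scale statistics).
#' @return A `replicate_table`: list with `tech_rep_means`, `animal_means`
#'   (data frames) and `metric`.
#' @export
aggregate_cells <- function(cell_summaries, metric = "peak_amp",
                            responders_only = FALSE) {
  need <- c("animal", "condition", "tech_rep", metric)
  missing <- setdiff(need, names(cell_summaries))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  df <- cell_summaries
  if (responders_only) {
    if (!"responder" %in% names(df)) stop("no responder column")
    df <- df[df$responder, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no cells to aggregate")
  tech <- stats::aggregate(
    df[[metric]],
    by = list(animal = df$animal, condition = df$condition,
              tech_rep = df$tech_rep),
    FUN = mean
  )
  names(tech)[4] <- "value"
  animal <- stats::aggregate(
    tech$value,
    by = list(animal = tech$animal, condition = tech$condition),
    FUN = mean
  )
  names(animal)[3] <- "value"
  structure(
    list(tech_rep_means = tech[order(tech$condition, tech$animal, tech$tech_rep), ],
         animal_means = animal[order(animal$condition, animal$animal), ],
         metric = metric),
    class = "replicate_table"
  )
}

#' Paired t test on log-transformed per-animal means
#'
#' The per-animal means of the two conditions are natural-log transformed
#' (they must be positive; zeros should be excluded at aggregation with
#' `responders_only`), compared with a paired two-sided Student's t test,
#' and the condition means back-transformed, i.e. reported as geometric
#' means. Raw-scale means +/- SEM are reported alongside.
#'
#' @param table A `replicate_table` from [aggregate_cells()].
#' @param condition_a,condition_b The two paired conditions; every animal
#'   must appear in both.
#' @return A `stat_result`: test name, statistic, df, p-value, per-condition
#'   geometric means, raw means and SEMs, and n.
#' @export
paired_t_log <- function(table, condition_a, condition_b) {
  stopifnot(inherits(table, "replicate_table"))
  am <- table$animal_means
  a <- am[am$condition == condition_a, ]
  b <- am[am$condition == condition_b, ]
  common <- intersect(a$animal, b$animal)
  if (length(common) < 2) stop("need >= 2 paired animals")
  if (length(common) < length(unique(c(a$animal, b$animal)))) {
    stop("pairing requires every animal in both conditions")
  }
  va <- a$value[match(common, a$animal)]
  vb <- b$value[match(common, b$animal)]
  if (any(va <= 0) || any(vb <= 0)) {
    stop("non-positive per-animal mean: cannot log-transform ",
         "(exclude non-responders before aggregation)")
  }
  d <- log(va) - log(vb)
  if (sd(d) == 0) {
    # degenerate: identical paired differences carry no evidence scale
    stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    tt <- list(statistic = stat, parameter = length(d) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- t.test(log(va), log(vb), paired = TRUE)
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  structure(
    list(
      test = "paired t test on log-transformed per-animal means",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, n = length(common),
      conditions = c(condition_a, condition_b),
      geometric_mean = c(exp(mean(log(va))), exp(mean(log(vb)))),
      raw_mean = c(mean(va), mean(vb)),
      raw_sem = c(sem(va), sem(vb)),
      metric = table$metric
    ),
    class = "stat_result"
  )
}

#' Two-way ANOVA with Tukey contrasts on log-scale per-animal means
#'
#' Classical two-way ANOVA (main effects, interaction, residual) of the
#' natural-log per-animal means over two user-declared factors, followed by
#' Tukey's studentized-range test for all pairwise cell-mean contrasts with
#' family-wise adjusted p values.
#'
#' @param data Data frame of per-animal means.
#' @param value Name of the (positive) response column.
#' @param factor_a,factor_b Names of the two factor columns.
#' @return A `stat_result` with the ANOVA table and a list of Tukey
#'   contrast tables.
#' @export
anova2_tukey <- function(data, value = "value", factor_a, factor_b) {
  need <- c(value, factor_a, factor_b)
  stopifnot(all(need %in% names(data)))
  v <- data[[value]]
  if (any(v <= 0)) stop("non-positive values: cannot log-transform")
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    stop("each factor needs at least two levels")
  }
  df <- data.frame(y = log(v), A = fa, B = fb)
  names(df)[2:3] <- c(factor_a, factor_b)
  fit <- aov(stats::as.formula(
    sprintf("y ~ %s * %s", factor_a, factor_b)), data = df)
  tab <- summary(fit)[[1]]
  tukey <- TukeyHSD(fit)
  structure(
    list(
      test = "two-way ANOVA with Tukey's multiple comparisons",
      anova_table = tab,
      tukey = tukey,
      factors = c(factor_a, factor_b),
      geometric_means = tapply(v, list(fa, fb),
                               function(x) exp(mean(log(x))))
    ),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$test, "\n")
  if (!is.null(x$statistic)) {
    cat(sprintf("  t = %.4g, df = %g, p = %.4g (n = %d)\n",
                x$statistic, x$df, x$p_value, x$n))
    cat(sprintf("  %s: geometric mean %.4g (raw %.4g +/- %.4g SEM)\n",
                x$conditions[1], x$geometric_mean[1], x$raw_mean[1],
                x$raw_sem[1]))
    cat(sprintf("  %s: geometric mean %.4g (raw %.4g +/- %.4g SEM)\n",
                x$conditions[2], x$geometric_mean[2], x$raw_mean[2],
                x$raw_sem[2]))
  } else if (!is.null(x$anova_table)) {
    print(x$anova_table)
  }
  invisible(x)
}
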