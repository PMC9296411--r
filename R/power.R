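#' ANOVA power specification
#'
#' Parameters of an a-priori power computation for a mixed-design ANOVA
#' effect, in the convention of standard power software. Two noncentral-F
#' formulations are available:
#'
#' * `design = "fixed_effects"` (default): the fixed-effects "special"
#'   cell used for higher-order interactions. Noncentrality
#'   `lambda = f^2 * N`; `df1 = df_effect`, `df2 = N - k_groups`. The
#'   default `df_effect = 2` is the Group x Condition x Age three-way
#'   interaction of a 2 x 2 x 3 design (`(2-1)(2-1)(3-1) = 2`) with
#'   `k_groups = 12` cells. This is the cell that reproduces the study
#'   design's published sample-size calculation (see the methods
#'   vignette).
#' * `design = "within_between"`: the repeated-measures within-between
#'   interaction. `lambda = f^2 * N * m / (1 + (m - 1) * rho)`;
#'   `df1 = (k - 1)(m - 1) * epsilon`, `df2 = (N - k)(m - 1) * epsilon`.
#'
#' @param effect_f Cohen's f (> 0); 0.40 is conventionally "large".
#' @param alpha Type-I error rate.
#' @param design `"fixed_effects"` or `"within_between"`.
#' @param k_groups Number of between-subject cells.
#' @param m_measurements Within-subject levels (within-between design).
#' @param rho Assumed repeated-measures correlation (within-between design).
#' @param epsilon Nonsphericity correction in (0, 1].
#' @param df_effect Numerator df of the tested effect (fixed-effects
#'   design).
#' @param n_total Total sample size (may be `NULL` when searching for N).
#' @return A list of class `power_spec`.
#' @export
power_spec <- function(effect_f = 0.40, alpha = 0.05,
                       design = c("fixed_effects", "within_between"),
                       k_groups = NULL, m_measurements = 2, rho = 0.5,
                       epsilon = 1, df_effect = 2, n_total = NULL) {
  design <- match.arg(design)
  if (is.null(k_groups)) k_groups <- if (design == "fixed_effects") 12 else 6
  stopifnot(effect_f > 0, alpha > 0, alpha < 1, k_groups >= 2,
            m_measurements >= 2, rho >= 0, rho < 1,
            epsilon > 0, epsilon <= 1, df_effect >= 1)
  structure(list(effect_f = effect_f, alpha = alpha, design = design,
                 k_groups = k_groups, m_measurements = m_measurements,
                 rho = rho, epsilon = epsilon, df_effect = df_effect,
                 n_total = n_total), class = "power_spec")
}

#' Power of an ANOVA interaction F test
#'
#' Evaluates `P(F'(df1, df2, lambda) > F_crit(df1, df2, 1 - alpha))` with
#' the noncentrality and degrees of freedom determined by the spec's
#' design (see [power_spec]).
#'
#' @param spec A [power_spec].
#' @param n_total Total sample size; defaults to `spec$n_total`.
#' @return Power as a probability.
#' @export
anova_interaction_power <- function(spec = power_spec(),
                                    n_total = spec$n_total) {
  stopifnot(inherits(spec, "power_spec"))
  if (is.null(n_total)) stop("n_total must be given")
  N <- n_total
  if (spec$design == "within_between") {
    m <- spec$m_measurements
    lambda <- spec$effect_f ^ 2 * N * m / (1 + (m - 1) * spec$rho)
    df1 <- (spec$k_groups - 1) * (m - 1) * spec$epsilon
    df2 <- (N - spec$k_groups) * (m - 1) * spec$epsilon
  } else {
    lambda <- spec$effect_f ^ 2 * N
    df1 <- spec$df_effect
    df2 <- N - spec$k_groups
  }
  if (df2 <= 0) stop("nonpositive denominator df: N too small for design")
  fcrit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest N reaching a target power
#'
#' Searches total sample size upward in steps of `step` (default 2, so the
#' two groups stay equal) for the smallest N whose interaction power
#' reaches `target_power`.
#'
#' @param spec A [power_spec] (its `n_total` is ignored).
#' @param target_power Target power in (alpha, 1).
#' @param step Increment of the search (default 2).
#' @param n_max Search cap.
#' @return The smallest qualifying total N.
#' @export
min_n_for_power <- function(spec = power_spec(), target_power = 0.80,
                            step = 2, n_max = 10000) {
  stopifnot(inherits(spec, "power_spec"),
            target_power > spec$alpha, target_power < 1)
  N <- spec$k_groups + step
  while (N <= n_max) {
    if (anova_interaction_power(spec, n_total = N) >= target_power)
      return(N)
    N <- N + step
  }
  stop(sprintf("target power %.2f unreachable below N = %d",
               target_power, n_max))
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation, the nonparametric association
#' measure used throughout threshold-performance analyses (d-prime scores
#' from small trial counts tie often, so the tie-corrected variant is the
#' right one).
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return Kendall's tau-b; `NA` (with a warning) when either input is
#'   constant.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("fewer than 2 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("kendall_tau undefined for a constant sequence")
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Summarize scored results by design cell
#'
#' Mean and SD of a score for every group x age x task x condition cell
#' present in the input, with single-observation cells flagged (SD
#' undefined) and absent cells listed.
#'
#' @param scores Data frame with columns `group`, `age_cohort`, `task`,
#'   `condition`, and the score column named by `value_col`.
#' @param value_col Name of the score column (default `"d_prime"`).
#' @return A list with `table` (data frame: cell columns, `n`, `mean`,
#'   `sd`) and `missing_cells` (data frame of absent combinations).
#' @export
summarize_cohort <- function(scores, value_col = "d_prime") {
  need <- c("group", "age_cohort", "task", "condition", value_col)
  stopifnot(is.data.frame(scores), all(need %in% names(scores)))
  f <- interaction(scores$group, scores$age_cohort, scores$task,
                   scores$condition, drop = TRUE)
  agg <- do.call(rbind, lapply(split(scores, f), function(g) {
    data.frame(group = g$group[1], age_cohort = g$age_cohort[1],
               task = g$task[1], condition = g$condition[1],
               n = nrow(g), mean = mean(g[[value_col]]),
               sd = if (nrow(g) > 1) stats::sd(g[[value_col]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  full <- expand.grid(group = unique(scores$group),
                      age_cohort = unique(scores$age_cohort),
                      task = unique(scores$task),
                      condition = unique(scores$condition),
                      stringsAsFactors = FALSE)
  seen <- paste(agg$group, agg$age_cohort, agg$task, agg$condition)
  missing <- full[!(paste(full$group, full$age_cohort, full$task,
                          full$condition) %in% seen), , drop = FALSE]
  rownames(missing) <- NULL
  list(table = agg, missing_cells = missing)
}
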