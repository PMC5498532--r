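test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, ifelse(is.na(x$df), "-", x$df), x$p_value))
  invisible(x)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; samples
#' censored at an event time are counted at risk at that time.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return A data.frame of class `survival_curve` (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`) over the distinct observed times.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival # 2/3, 1/3, 0
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected number of events in group A is
#' `d * n_A / n`; the statistic `(O_A - E_A)^2 / V` is referred to a
#' chi-square distribution with one degree of freedom (hypergeometric
#' variance, no strata).
#'
#' @param times_a,events_a,times_b,events_b Per-group time and 0/1 event
#'   vectors.
#' @return A `test_result` (`statistic`, `df = 1`, `p_value`).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) >= 1, length(times_b) >= 1)
  if (sum(events_a) + sum(events_b) == 0) {
    warning("no events in either group; log-rank statistic is 0")
    return(test_result(0, 1L, 1, "log-rank"))
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  test_result(sd$chisq, 1L, p, "log-rank")
}

#' ROC-sweep optimal cutoff by Youden's J
#'
#' Sweeps all midpoints between adjacent sorted distinct values; a sample is
#' called positive when its value exceeds the cutoff. Returns the cutoff
#' maximizing `J = sensitivity + specificity - 1` against the binary labels;
#' J ties are broken toward the more balanced sensitivity/specificity pair,
#' then toward the lower cutoff.
#'
#' @param values Continuous marker values.
#' @param labels 0/1 outcome labels (1 = positive class, assumed to sit at
#'   higher values).
#' @return A list of class `cutoff_result` (`cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`).
#' @examples
#' roc_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1)) # cutoff 2.5, J = 1
#' @export
roc_cutoff <- function(values, labels) {
  stopifnot(length(values) == length(labels), all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0)) stop("both label classes must be present")
  v <- sort(unique(values))
  if (length(v) < 3) stop("need >= 3 distinct values to sweep")
  cuts <- (v[-1] + v[-length(v)]) / 2
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  sens <- vapply(cuts, function(ct) sum(values > ct & labels == 1) / n_pos, 0)
  spec <- vapply(cuts, function(ct) sum(values <= ct & labels == 0) / n_neg, 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[order(abs(sens[best] - spec[best]), cuts[best])][1]
  structure(list(cutoff = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best]),
            class = "cutoff_result")
}

#' Fold-change and t-test association of expression with a binary grouping
#'
#' Compares values between two groups (e.g. M0 vs M1, N0 vs N+), reporting
#' the ratio of group means with an explicitly declared numerator and a
#' two-tailed pooled-variance Student's t-test.
#'
#' @param values Numeric vector (typically linear-scale expression).
#' @param groups Grouping vector with exactly two distinct values.
#' @param numerator_group Which group supplies the fold-change numerator.
#' @return A list of class `association_result`: `group_means` (named),
#'   `fold_change`, `numerator`, `denominator`, `test` (a `test_result`).
#' @export
group_association <- function(values, groups, numerator_group) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("`groups` must have exactly 2 distinct values")
  if (!numerator_group %in% lev) stop("numerator_group not among the groups")
  x_num <- values[groups == numerator_group]
  x_den <- values[groups != numerator_group]
  if (length(x_num) < 2 || length(x_den) < 2) stop("each group needs n >= 2")
  tt <- row_t_test(matrix(x_num, 1), matrix(x_den, 1))
  means <- stats::setNames(c(mean(x_num), mean(x_den)),
                           c(numerator_group, setdiff(lev, numerator_group)))
  structure(list(group_means = means,
                 fold_change = means[[1]] / means[[2]],
                 numerator = numerator_group,
                 denominator = setdiff(lev, numerator_group),
                 test = test_result(tt$t, tt$df, tt$p, "Student's t (pooled)")),
            class = "association_result")
}

#' Paired t-test on matched measurements
#'
#' Two-tailed paired Student's t on the within-pair differences (e.g. tumor
#' vs adjacent normal tissue from the same patient).
#'
#' @param values_a,values_b Equal-length paired vectors, n >= 2.
#' @return A `test_result`.
#' @export
paired_association <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(test_result(0, n - 1L, 1, "paired t"))
    warning("constant non-zero paired differences: degenerate t")
    return(test_result(sign(d[1]) * Inf, n - 1L, 0, "paired t"))
  }
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  test_result(t_stat, n - 1L, 2 * stats::pt(-abs(t_stat), n - 1), "paired t")
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; `df = (R - 1)(C - 1)`. Expected counts
#' below 5 trigger a warning (inherited from [stats::chisq.test()]), not a
#' failure; a zero row or column marginal is fatal.
#'
#' @param contingency An R x C matrix of non-negative counts.
#' @return A `test_result`.
#' @export
chisq_association <- function(contingency) {
  contingency <- as.matrix(contingency)
  stopifnot(all(contingency >= 0), nrow(contingency) >= 2, ncol(contingency) >= 2)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("zero row/column marginal in contingency table")
  }
  ct <- stats::chisq.test(contingency, correct = FALSE)
  test_result(ct$statistic, as.integer(ct$parameter), ct$p.value, "chi-square")
}

#' Summarize a score by molecular subtype with a Kruskal-Wallis test
#'
#' Per-subtype n, mean and sd of the score, plus a global Kruskal-Wallis
#' rank test across subtypes. Samples with missing subtype are dropped.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param subtypes Subtype labels aligned with `scores`.
#' @return A list: `table` (data.frame `subtype`, `n`, `mean`, `sd`) and
#'   `test` (a `test_result`).
#' @export
summarize_by_subtype <- function(scores, subtypes) {
  keep <- !is.na(subtypes)
  scores <- scores[keep]
  subtypes <- as.character(subtypes[keep])
  if (length(unique(subtypes)) < 2) stop("need >= 2 subtype groups")
  tab <- do.call(rbind, lapply(sort(unique(subtypes)), function(s) {
    data.frame(subtype = s, n = sum(subtypes == s),
               mean = mean(scores[subtypes == s]),
               sd = stats::sd(scores[subtypes == s]),
               stringsAsFactors = FALSE)
  }))
  kw <- stats::kruskal.test(scores, factor(subtypes))
  list(table = tab,
       test = test_result(kw$statistic, as.integer(kw$parameter), kw$p.value,
                          "Kruskal-Wallis"))
}
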