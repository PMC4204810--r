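# Contingency-table association statistics between latent classes and
# binary/categorical traits: 2x2 odds ratios with Woolf (Wald log-OR)
# confidence intervals against a baseline class, and Pearson chi-square
# comparisons of categorical distributions.

#' Odds ratio with Woolf 95% confidence interval
#'
#' For a 2x2 table comparing a class against a baseline class on a binary
#' trait: `a` trait-positive in the class, `b` trait-negative in the class,
#' `c` trait-positive in the baseline, `d` trait-negative in the baseline.
#' OR = (a*d)/(b*c); the Woolf interval is
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and the p-value comes
#' from the Wald z statistic of log(OR). Any zero cell triggers the
#' Haldane–Anscombe +0.5 continuity correction (applied to all four cells and
#' flagged in the result).
#'
#' @param a,b,c,d non-negative integer cell counts
#' @param conf_level confidence level (default 0.95)
#' @param baseline_label optional label for the reference class
#' @return object of class `odds_ratio_result`: counts, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`, `baseline_label`
#' @export
odds_ratio_woolf <- function(a, b, c, d, conf_level = 0.95,
                             baseline_label = "baseline") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  structure(list(counts = counts, or = unname(or),
                 ci_low = ci[1], ci_high = ci[2], p_value = unname(p),
                 corrected = corrected, conf_level = conf_level,
                 baseline_label = baseline_label),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.1f (%.1f-%.1f), p = %.3g vs %s%s\n",
              round_half_up(x$or, 1), round_half_up(x$ci_low, 1),
              round_half_up(x$ci_high, 1), x$p_value, x$baseline_label,
              if (x$corrected) " [continuity corrected]" else ""))
  invisible(x)
}

#' Per-class odds ratios for a binary trait against a baseline class
#'
#' Children with a missing trait are excluded. Returns one
#' [odds_ratio_woolf()] row per non-baseline class plus a totals row with the
#' overall trait prevalence.
#'
#' @param assignments integer class assignment per child
#' @param trait binary (0/1/NA) trait per child, same length
#' @param baseline_class class index used as the reference
#' @param class_labels optional class label vector
#' @return list: `table` (data.frame with counts, OR, CI, p per class),
#'   `totals` (trait_pos, trait_neg, percent_pos), `baseline_class`
#' @export
class_trait_table <- function(assignments, trait, baseline_class = 1,
                              class_labels = NULL) {
  stopifnot(length(assignments) == length(trait))
  keep <- !is.na(trait) & !is.na(assignments)
  assignments <- assignments[keep]; trait <- trait[keep]
  classes <- sort(unique(assignments))
  if (!baseline_class %in% classes) stop("baseline class is empty")
  cb <- sum(assignments == baseline_class & trait == 1)
  db <- sum(assignments == baseline_class & trait == 0)
  rows <- list()
  for (cl in setdiff(classes, baseline_class)) {
    a <- sum(assignments == cl & trait == 1)
    b <- sum(assignments == cl & trait == 0)
    orr <- odds_ratio_woolf(a, b, cb, db)
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl,
      label = if (is.null(class_labels)) as.character(cl) else class_labels[cl],
      trait_pos = a, trait_neg = b,
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      p_value = orr$p_value, corrected = orr$corrected)
  }
  totals <- data.frame(trait_pos = sum(trait == 1), trait_neg = sum(trait == 0),
                       percent_pos = 100 * mean(trait == 1))
  list(table = do.call(rbind, rows), totals = totals,
       baseline_class = baseline_class,
       baseline_counts = c(trait_pos = cb, trait_neg = db))
}

#' Per-class Pearson chi-square tests of a categorical trait vs baseline
#'
#' For each non-baseline class, tests the 2 x k contingency table of the
#' trait's distribution in that class versus the baseline class with an
#' (uncorrected) Pearson chi-square test.
#'
#' @param assignments integer class assignment per child
#' @param category categorical trait per child (>= 2 levels after NA removal)
#' @param baseline_class reference class index
#' @return data.frame: class, chisq, df, p_value
#' @export
class_categorical_test <- function(assignments, category, baseline_class = 1) {
  stopifnot(length(assignments) == length(category))
  keep <- !is.na(category) & !is.na(assignments)
  assignments <- assignments[keep]; category <- factor(category[keep])
  if (nlevels(category) < 2) stop("category needs at least 2 observed levels")
  classes <- sort(unique(assignments))
  if (!baseline_class %in% classes) stop("baseline class is empty")
  base_counts <- table(category[assignments == baseline_class])
  rows <- list()
  for (cl in setdiff(classes, baseline_class)) {
    cls_counts <- table(category[assignments == cl])
    tab <- rbind(as.numeric(cls_counts), as.numeric(base_counts))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts == 0))
      stop("zero expected count for class ", cl,
           "; merge sparse category levels before testing")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      class = cl, chisq = unname(ct$statistic),
      df = unname(ct$parameter), p_value = unname(ct$p.value))
  }
  do.call(rbind, rows)
}

#' Write a class-trait association table to CSV
#' @param trait_table result of [class_trait_table()]
#' @param path file path
#' @export
write_assoc_csv <- function(trait_table, path) {
  utils::write.csv(trait_table$table, path, row.names = FALSE)
  invisible(path)
}
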