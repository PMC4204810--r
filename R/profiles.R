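# Characterisation of fitted classes: trajectory tables, cross-sectional
# prevalence summaries, assignment-certainty matrices, and confusion matrices
# between two classifications.

#' Per-class trajectory probability table
#'
#' For each class: its size (children assigned by argmax), share of the
#' cohort, the observed per-cell symptom proportions among assigned children
#' (non-missing cells only), and the model-implied emission probabilities.
#' For Markov-family fits the model-implied probabilities are the marginal
#' symptom probabilities obtained by propagating the class's chain forward.
#'
#' @param fit a [fit()] result
#' @param cohort the cohort the model was fitted to
#' @return object of class `class_profile_table`: data.frame with columns
#'   class, size, share, symptom, age, observed_prop, model_prob
#' @export
profile_table <- function(fit, cohort) {
  if (length(fit$assignment) != nrow(cohort))
    stop("fit assignments do not cover the cohort")
  g <- cohort_grid(cohort)
  sy <- cohort_symptoms(cohort)
  Tn <- length(g$ages)
  n <- fit$spec$n_classes
  Y <- panel_matrix(cohort)
  sizes <- tabulate(fit$assignment, n)
  model_p <- model_marginal_prob(fit$params, fit$spec)
  rows <- list()
  for (c in seq_len(n)) {
    sel <- fit$assignment == c
    for (s in seq_along(sy)) for (t in seq_len(Tn)) {
      col <- Y[sel, (s - 1) * Tn + t]
      obs_p <- if (sum(!is.na(col)) > 0) mean(col, na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        class = c, size = sizes[c], share = sizes[c] / nrow(cohort),
        symptom = sy[s], age = g$ages[t],
        observed_prop = obs_p, model_prob = model_p[c, s, t])
    }
  }
  structure(do.call(rbind, rows), class = c("class_profile_table", "data.frame"))
}

# Marginal P(symptom s present at age t | class) for any family, as an
# n x S x T array.
model_marginal_prob <- function(params, spec) {
  Tn <- length(params$grid$ages)
  S <- length(SYMPTOMS)
  n <- spec$n_classes
  if (spec$family == "latent_profile") return(params$prob)
  out <- array(NA_real_, dim = c(n, S, Tn))
  st <- joint_states(S)
  for (c in seq_len(n)) {
    m <- joint_init(params, c)
    Tm <- joint_transition(params, spec$family, c)
    for (t in seq_len(Tn)) {
      if (t > 1) m <- as.vector(m %*% Tm)
      for (s in seq_len(S)) out[c, s, t] <- sum(m[st[, s] == 1])
    }
  }
  out
}

#' Cross-sectional prevalence table
#'
#' Per (symptom, age, cohort): positives, observed N, percent — plus a pooled
#' "joint" column across cohorts. Counts are over non-missing cells; an
#' all-missing cell reports N = 0 and percent NA.
#'
#' @param cohort a [cohort_table()]
#' @return data.frame with columns cohort, symptom, age, n_pos, n_obs, percent
#' @export
prevalence_table <- function(cohort) {
  g <- cohort_grid(cohort)
  sy <- cohort_symptoms(cohort)
  groups <- c(as.list(unique(cohort$cohort)), list(unique(cohort$cohort)))
  labels <- c(unique(cohort$cohort), "joint")
  rows <- list()
  df <- as.data.frame(cohort)
  for (i in seq_along(groups)) {
    sub <- df[df$cohort %in% groups[[i]], , drop = FALSE]
    for (s in sy) for (a in g$ages) {
      v <- sub[[paste(s, a, sep = "_")]]
      n_obs <- sum(!is.na(v)); n_pos <- sum(v == 1, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = labels[i], symptom = s, age = a, n_pos = n_pos, n_obs = n_obs,
        percent = if (n_obs > 0) 100 * n_pos / n_obs else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Assignment-certainty matrix
#'
#' Row `a`, column `b` holds the mean posterior probability of class `b`
#' among children assigned (argmax) to class `a` — the conditional
#' probability of being predicted in class `b` given actual assigned
#' membership `a`. Rows sum to 1; the diagonal measures assignment certainty.
#'
#' @param fit a [fit()] result
#' @return n x n row-stochastic matrix
#' @export
membership_quality <- function(fit) {
  n <- fit$spec$n_classes
  out <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    sel <- fit$assignment == a
    out[a, ] <- if (any(sel)) colMeans(fit$membership[sel, , drop = FALSE])
    else rep(NA_real_, n)
  }
  out
}

#' Cross-tabulate two classifications of the same children
#'
#' Builds the confusion matrix between two hard assignments matched on child
#' id and tests for association with a Pearson chi-square test of
#' independence.
#'
#' @param assignments_a,assignments_b named vectors (names = child ids) or
#'   data.frames with columns `child_id`, `class`
#' @return list: `counts` (matrix), `chisq` (statistic), `p_value`, `n`
#' @export
cross_tabulate <- function(assignments_a, assignments_b) {
  a <- as_assignment(assignments_a)
  b <- as_assignment(assignments_b)
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("assignments share no child ids")
  tab <- table(factor(a[common]), factor(b[common]))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(counts = unclass(tab), chisq = unname(ct$statistic),
       p_value = unname(ct$p.value), n = length(common))
}

as_assignment <- function(x) {
  if (is.data.frame(x)) return(stats::setNames(x$class, x$child_id))
  if (is.null(names(x))) stop("assignments must carry child ids as names")
  x
}

#' Plot per-class trajectory curves
#'
#' One panel per class: fitted emission probability against age, one curve
#' per symptom, with the observed per-class proportions overplotted as
#' points. Draws on the active graphics device; wrap in `png()`/`pdf()` to
#' export.
#'
#' @param x a [profile_table()] result
#' @param ... passed to `matplot`
#' @export
plot.class_profile_table <- function(x, ...) {
  classes <- unique(x$class)
  symptoms <- unique(x$symptom)
  ages <- sort(unique(x$age))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(classes)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (c in classes) {
    sub <- x[x$class == c, ]
    pm <- sapply(symptoms, function(s)
      sub$model_prob[sub$symptom == s][order(sub$age[sub$symptom == s])])
    graphics::matplot(ages, pm, type = "l", lty = 1, lwd = 2, col = 2:4,
                      ylim = c(0, 1), xlab = "age (y)", ylab = "P(symptom)",
                      main = sprintf("class %d (%.1f%%)", c,
                                     100 * sub$share[1]), ...)
    op <- sapply(symptoms, function(s)
      sub$observed_prop[sub$symptom == s][order(sub$age[sub$symptom == s])])
    graphics::matpoints(ages, op, pch = 1, col = 2:4)
  }
  graphics::legend("topleft", legend = symptoms, col = 2:4, lty = 1, bty = "n")
  invisible(x)
}

#' Write a fit's memberships to CSV
#'
#' Columns: child_id, p_class_1..n, assigned_class.
#' @param fit a [fit()] result
#' @param path file path
#' @export
write_membership_csv <- function(fit, path) {
  m <- as.data.frame(fit$membership)
  names(m) <- paste0("p_class_", seq_len(ncol(m)))
  out <- cbind(data.frame(child_id = fit$child_id), m,
               assigned_class = fit$assignment)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
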