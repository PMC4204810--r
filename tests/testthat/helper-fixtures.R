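# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; no stored data.

# --- tiny deterministic cohort builders ------------------------------------

toy_grid <- function() age_grid(c(1, 3))

# Build a cohort table directly from an N x (S*T) panel matrix (symptom-major
# columns), with optional extra columns.
toy_cohort <- function(panels, ages = c(1, 3), cohort = "A", ...) {
  n <- nrow(panels)
  df <- data.frame(child_id = sprintf("t%03d", seq_len(n)),
                   cohort = cohort, sex = rep(0, n))
  colnames(panels) <- symptomLCA:::symptom_cols(symptomLCA:::SYMPTOMS, ages)
  df <- cbind(df, as.data.frame(panels))
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  cohort_table(df, grid = age_grid(ages))
}

# Random small model parameters for a given family (valid, interior).
random_params <- function(spec, ages = c(1, 3), seed = 1) {
  set.seed(seed)
  n <- spec$n_classes
  w <- runif(n, 0.2, 1); w <- w / sum(w)
  if (spec$family == "latent_profile") {
    model_params(spec, w,
                 prob = array(runif(n * 3 * length(ages), 0.05, 0.95),
                              dim = c(n, 3, length(ages))),
                 ages = ages)
  } else {
    trans <- lapply(1:3, function(s) {
      k <- length(symptomLCA:::family_parents(spec$family, s))
      matrix(runif(n * 2^k, 0.05, 0.95), n)
    })
    model_params(spec, w, init = matrix(runif(n * 3, 0.05, 0.95), n),
                 trans = trans, ages = ages)
  }
}

# --- independent oracles ---------------------------------------------------

# Probability of one COMPLETE panel under one class, by naive nested loops.
# Kept deliberately dumb and separate from the package's forward/matrix path.
oracle_complete_prob <- function(panel, c, params, spec) {
  S <- nrow(panel); Tn <- ncol(panel)
  pr <- 1
  if (spec$family == "latent_profile") {
    for (s in 1:S) for (t in 1:Tn) {
      p <- params$prob[c, s, t]
      pr <- pr * if (panel[s, t] == 1) p else 1 - p
    }
    return(pr)
  }
  for (s in 1:S) {
    p <- params$init[c, s]
    pr <- pr * if (panel[s, 1] == 1) p else 1 - p
  }
  parents <- function(s) {
    if (spec$family == "independent_markov") s else list(1L, c(2L, 1L), c(3L, 2L))[[s]]
  }
  for (t in 2:Tn) for (s in 1:S) {
    pa <- parents(s)
    cfg <- 1 + sum(panel[pa, t - 1] * 2^(seq_along(pa) - 1))
    p <- params$trans[[s]][c, cfg]
    pr <- pr * if (panel[s, t] == 1) p else 1 - p
  }
  pr
}

# Class-conditional probability of an OBSERVED (possibly partial) panel by
# enumerating every completion of the missing cells.
oracle_observed_prob <- function(panel, c, params, spec) {
  miss <- which(is.na(panel))
  total <- 0
  for (k in 0:(2^length(miss) - 1)) {
    pp <- panel
    if (length(miss))
      pp[miss] <- (k %/% 2^(seq_along(miss) - 1)) %% 2
    total <- total + oracle_complete_prob(pp, c, params, spec)
  }
  total
}

# Posterior membership by direct Bayes rule on the enumeration oracle.
oracle_membership <- function(panel, params, spec) {
  lik <- vapply(seq_len(spec$n_classes), function(c)
    oracle_observed_prob(panel, c, params, spec), numeric(1))
  post <- params$weights * lik
  post / sum(post)
}

# Marginal log-likelihood of a whole cohort by the enumeration oracle.
oracle_cohort_loglik <- function(cohort, params, spec) {
  total <- 0
  for (i in seq_len(nrow(cohort))) {
    panel <- symptomLCA:::child_panel(cohort, i)
    lik <- vapply(seq_len(spec$n_classes), function(c)
      oracle_observed_prob(panel, c, params, spec), numeric(1))
    total <- total + log(sum(params$weights * lik))
  }
  total
}

# Adjusted Rand index (closed form on the contingency table); independent of
# any package code.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- sum(choose(tab, 2))
  ra <- sum(choose(rowSums(tab), 2))
  cb <- sum(choose(colSums(tab), 2))
  expected <- ra * cb / choose(n, 2)
  (sum_comb - expected) / ((ra + cb) / 2 - expected)
}

# Optimal class matching (exhaustive over permutations; fine for n <= 8).
best_permutation <- function(truth, assigned, n) {
  tab <- table(factor(truth, 1:n), factor(assigned, 1:n))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_v <- -1
  for (p in perms(1:n)) {
    v <- sum(tab[cbind(1:n, p)])
    if (v > best_v) { best_v <- v; best <- p }
  }
  best
}

# The default eight-class two-cohort truth at a reduced size (shares and
# missingness structure preserved; cohort A keeps its real share ~11.6%).
scaled_default_truth <- function(n_total, seed, item_rate = 0.1) {
  n_a <- round(n_total * 1136 / 9801)
  default_truth(seed = seed, cohort_sizes = c(A = n_a, B = n_total - n_a),
                item_rate = item_rate)
}
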