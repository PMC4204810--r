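# MAP expectation-maximisation for all three model families.
#
# The original analysis used expectation propagation; here the engine is EM
# with MAP priors (Gaussian prior on probit scores, Dirichlet prior on class
# weights). The downstream outputs consumed by the rest of the pipeline -
# posterior class memberships, argmax assignments, evidence ranking - are
# engine-agnostic, and all tests target those outputs.
#
# Missing observations are never imputed: in the latent_profile family a
# missing cell simply contributes no Bernoulli term; in the Markov families
# the forward (and, in the M-step, forward-backward) recursions run over the
# 2^S joint symptom state space with missing cells leaving the state
# unconstrained, which is exact marginalisation.

#' EM control settings
#'
#' @param restarts number of initialisations (alternating k-means-style and
#'   random); the best penalised objective wins, ties broken by the lowest
#'   restart index
#' @param max_iter iteration cap per restart
#' @param tol relative stability tolerance for the convergence rule
#' @param window number of consecutive iterations over which the objective
#'   must remain stable (within `tol`, relative) to declare convergence
#' @param n_splits number of random hold-out splits for the hold-out evidence
#' @param holdout_frac fraction of children held out per split
#' @param evidence_restarts restarts for the per-split refits (warm-started
#'   from the full-data fit when available)
#' @return list of class `em_control`
#' @export
em_control <- function(restarts = 10, max_iter = 500, tol = 1e-6, window = 100,
                       n_splits = 100, holdout_frac = 0.1,
                       evidence_restarts = 1) {
  structure(list(restarts = restarts, max_iter = max_iter, tol = tol,
                 window = window, n_splits = n_splits,
                 holdout_frac = holdout_frac,
                 evidence_restarts = evidence_restarts),
            class = "em_control")
}

# ---------------------------------------------------------------------------
# Vectorised likelihood machinery
# ---------------------------------------------------------------------------

# Internal fitting representation of a cohort: observation matrix, mask, and
# cached sufficient structures.
panel_data <- function(cohort) {
  Y <- panel_matrix(cohort)
  obs <- !is.na(Y)
  Y0 <- Y; Y0[!obs] <- 0
  grid <- cohort_grid(cohort)
  list(Y = Y, Y0 = Y0, obs = obs * 1, n = nrow(Y),
       S = length(cohort_symptoms(cohort)), Tn = length(grid$ages),
       grid = grid, child_id = cohort$child_id)
}

safe_log <- function(p) {
  out <- log(p)
  out[p <= 0] <- LOGLIK_FLOOR
  out
}

# N x n matrix of class-conditional log-likelihoods.
loglik_matrix <- function(pd, params, spec) {
  if (spec$family == "latent_profile") {
    # LP: (S*T) x n, column order matching panel_matrix (symptom-major)
    LP <- matrix(aperm(params$prob, c(3, 2, 1)), ncol = spec$n_classes)
    ll <- (pd$Y0 * pd$obs) %*% safe_log(LP) +
      ((1 - pd$Y0) * pd$obs) %*% safe_log(1 - LP)
    return(pmax(ll, LOGLIK_FLOOR))
  }
  E <- markov_evidence(pd)
  ll <- matrix(NA_real_, pd$n, spec$n_classes)
  for (c in seq_len(spec$n_classes)) {
    A <- markov_forward(pd, params, spec, c, E)
    tot <- rowSums(A[[pd$Tn]])
    lc <- safe_log(tot)
    ll[, c] <- pmax(lc, LOGLIK_FLOOR)
  }
  ll
}

# Per-time evidence matrices: E[[t]] is N x 2^S with entry 1 where the joint
# state is consistent with the child's observed cells at time t.
markov_evidence <- function(pd) {
  st <- joint_states(pd$S)
  lapply(seq_len(pd$Tn), function(t) {
    E <- matrix(1, pd$n, nrow(st))
    for (s in seq_len(pd$S)) {
      y <- pd$Y[, (s - 1) * pd$Tn + t]
      nas <- is.na(y)
      for (b in seq_len(nrow(st))) {
        col <- if (st[b, s] == 1) y else 1 - y
        col[nas] <- 1
        E[, b] <- E[, b] * col
      }
    }
    E
  })
}

# Forward messages for class c: list over t of N x 2^S matrices, evidence
# included at each step.
markov_forward <- function(pd, params, spec, c, E) {
  Tm <- joint_transition(params, spec$family, c)
  A <- vector("list", pd$Tn)
  A[[1]] <- sweep(E[[1]], 2, joint_init(params, c), "*")
  for (t in 2:pd$Tn) A[[t]] <- (A[[t - 1]] %*% Tm) * E[[t]]
  A
}

# ---------------------------------------------------------------------------
# E and M steps
# ---------------------------------------------------------------------------

# Responsibilities and total data log-likelihood given current params.
e_step <- function(pd, params, spec) {
  ll <- loglik_matrix(pd, params, spec)
  lw <- sweep(ll, 2, safe_log(params$weights), "+")
  norm <- row_logsumexp(lw)
  R <- exp(lw - norm)
  list(R = R, loglik = sum(norm))
}

# Gaussian prior on all probit scores plus Dirichlet prior on weights
# (additive constants dropped from neither - they cancel in comparisons).
log_prior <- function(params, spec) {
  probs <- if (spec$family == "latent_profile") as.vector(params$prob)
  else c(as.vector(params$init), unlist(lapply(params$trans, as.vector)))
  theta <- stats::qnorm(pmin(pmax(probs, PROB_EPS), 1 - PROB_EPS))
  sum(stats::dnorm(theta, log = TRUE)) +
    (spec$pseudocount - 1) * sum(safe_log(params$weights))
}

WEIGHT_FLOOR <- 1e-6

m_step_weights <- function(R, spec) {
  raw <- colSums(R) + spec$pseudocount - 1
  raw <- pmax(raw, WEIGHT_FLOOR)   # empty classes retained at the floor
  raw / sum(raw)
}

m_step <- function(pd, R, params, spec) {
  w <- m_step_weights(R, spec)
  if (spec$family == "latent_profile") {
    K <- crossprod(R, pd$Y0 * pd$obs)     # n x (S*T) expected successes
    M <- crossprod(R, pd$obs)             # n x (S*T) expected trials
    p <- probit_map_prob(as.vector(K), as.vector(M))
    prob <- aperm(array(matrix(p, nrow = spec$n_classes),
                        dim = c(spec$n_classes, pd$Tn, pd$S)), c(1, 3, 2))
    params$prob <- prob
    params$weights <- w
    return(params)
  }
  # Markov families: expected initial-state and transition counts from
  # forward-backward over the joint state space, per class.
  st <- joint_states(pd$S)
  E <- markov_evidence(pd)
  n <- spec$n_classes
  init_k <- matrix(0, n, pd$S); init_m <- matrix(0, n, pd$S)
  trans_k <- lapply(seq_len(pd$S), function(s)
    matrix(0, n, 2^length(family_parents(spec$family, s))))
  trans_m <- trans_k
  for (c in seq_len(n)) {
    Tm <- joint_transition(params, spec$family, c)
    A <- markov_forward(pd, params, spec, c, E)
    # backward
    B <- vector("list", pd$Tn)
    B[[pd$Tn]] <- matrix(1, pd$n, nrow(st))
    for (t in (pd$Tn - 1):1)
      B[[t]] <- (B[[t + 1]] * E[[t + 1]]) %*% t(Tm)
    L <- rowSums(A[[pd$Tn]])
    wgt <- ifelse(L > 0, R[, c] / L, 0)
    # initial-state marginals
    g1 <- colSums((A[[1]] * B[[1]]) * wgt)          # length 2^S
    for (s in seq_len(pd$S)) {
      init_k[c, s] <- sum(g1[st[, s] == 1])
      init_m[c, s] <- sum(g1)
    }
    # pairwise marginals, pooled over time (time-homogeneous transitions)
    C <- matrix(0, nrow(st), nrow(st))
    for (t in 2:pd$Tn) {
      C <- C + Tm * crossprod(A[[t - 1]] * wgt, E[[t]] * B[[t]])
    }
    for (s in seq_len(pd$S)) {
      pa <- family_parents(spec$family, s)
      cfg_a <- parent_config_index(st, pa)          # config of each source state
      for (g in seq_len(2^length(pa))) {
        rows <- cfg_a == g
        trans_k[[s]][c, g] <- sum(C[rows, st[, s] == 1])
        trans_m[[s]][c, g] <- sum(C[rows, ])
      }
    }
  }
  params$init <- matrix(probit_map_prob(as.vector(init_k), as.vector(init_m)),
                        nrow = n)
  params$trans <- lapply(seq_len(pd$S), function(s)
    matrix(probit_map_prob(as.vector(trans_k[[s]]), as.vector(trans_m[[s]])),
           nrow = n))
  params$weights <- w
  params
}

# ---------------------------------------------------------------------------
# Initialisation
# ---------------------------------------------------------------------------

# Responsibility matrix from a k-means-style partition of the observed panels
# (missing cells imputed by the column mean for clustering only; the EM
# itself never sees imputed values).
init_responsibilities <- function(pd, n, type, seed) {
  with_seed(seed, {
    if (type == "kmeans" && pd$n > n) {
      Yi <- pd$Y
      mu <- colMeans(Yi, na.rm = TRUE)
      mu[is.nan(mu)] <- 0.5
      for (j in seq_len(ncol(Yi))) Yi[is.na(Yi[, j]), j] <- mu[j]
      km <- tryCatch(stats::kmeans(Yi, centers = n, nstart = 5, iter.max = 50),
                     error = function(e) NULL)
      if (!is.null(km)) {
        R <- matrix(0.5 / n, pd$n, n)
        R[cbind(seq_len(pd$n), km$cluster)] <- R[cbind(seq_len(pd$n), km$cluster)] + 0.5
        return(R / rowSums(R))
      }
    }
    R <- matrix(stats::runif(pd$n * n, 0.1, 1), pd$n, n)
    R / rowSums(R)
  })
}

blank_params <- function(spec, grid) {
  n <- spec$n_classes
  S <- length(SYMPTOMS); Tn <- length(grid$ages)
  if (spec$family == "latent_profile") {
    model_params(spec, weights = rep(1 / n, n),
                 prob = array(0.5, dim = c(n, S, Tn)), ages = grid$ages)
  } else {
    trans <- lapply(seq_len(S), function(s)
      matrix(0.5, n, 2^length(family_parents(spec$family, s))))
    model_params(spec, weights = rep(1 / n, n),
                 init = matrix(0.5, n, S), trans = trans, ages = grid$ages)
  }
}

# ---------------------------------------------------------------------------
# Fitting
# ---------------------------------------------------------------------------

#' Fit a latent-class model to a cohort by MAP EM
#'
#' Runs `control$restarts` independent EM runs (alternating seeded
#' k-means-style and random initialisations) and keeps the run with the best
#' penalised objective (data log-likelihood + log Dirichlet prior on weights
#' + log Gaussian prior on probit scores). Convergence follows the stability
#' rule: the objective must remain stable (relative change across the window
#' below `control$tol`) for `control$window` consecutive iterations.
#'
#' @param cohort a [cohort_table()] (already passed through inclusion filters)
#' @param spec a [model_spec()]
#' @param seed master integer seed; every restart derives its own sub-seed
#' @param control an [em_control()]
#' @param init_params optional [model_params()] to warm-start a single run
#'   (used by the hold-out evidence refits)
#' @return object of class `fit_result`: `params`, `membership` (N x n),
#'   `assignment`, `loglik`, `objective`, `trace`, `converged`, `seed`,
#'   `restarts`
#' @export
fit <- function(cohort, spec, seed = 1L, control = em_control(),
                init_params = NULL) {
  pd <- panel_data(cohort)
  n_distinct <- nrow(unique(data.frame(pd$Y)))
  if (spec$n_classes > n_distinct)
    warning("n_classes exceeds the number of distinct observed panels; ",
            "empty classes are likely")
  runs <- if (is.null(init_params)) seq_len(control$restarts) else 0L
  best <- NULL
  for (r in runs) {
    if (r == 0L) {
      params <- init_params
      es <- e_step(pd, params, spec)
      R <- es$R
    } else {
      type <- if (r %% 2 == 1) "kmeans" else "random"
      R <- init_responsibilities(pd, spec$n_classes, type,
                                 derive_seed(seed, "init", r))
      params <- blank_params(spec, pd$grid)
    }
    run <- em_run(pd, R, params, spec, control)
    if (is.null(best) || run$objective > best$objective + 1e-12) best <- run
  }
  es <- e_step(pd, best$params, spec)
  membership <- es$R
  rownames(membership) <- pd$child_id
  assignment <- max.col(membership, ties.method = "first")
  structure(list(params = best$params, membership = membership,
                 assignment = assignment, loglik = es$loglik,
                 objective = best$objective, trace = best$trace,
                 converged = best$converged, seed = seed,
                 restarts = length(runs), spec = spec,
                 child_id = pd$child_id),
            class = "fit_result")
}

em_run <- function(pd, R, params, spec, control) {
  # start from the M-step implied by the initial responsibilities
  params <- m_step(pd, R, params, spec)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    es <- e_step(pd, params, spec)
    obj <- es$loglik + log_prior(params, spec)
    trace <- c(trace, obj)
    if (convergence_check(trace, window = control$window, tol = control$tol)) {
      converged <- TRUE
      break
    }
    params <- m_step(pd, es$R, params, spec)
  }
  list(params = params, objective = trace[length(trace)], trace = trace,
       converged = converged)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: %s, n = %d classes, %d children\n",
              x$spec$family, x$spec$n_classes, length(x$assignment)))
  cat(sprintf("  objective %.3f, converged: %s, restarts: %d\n",
              x$objective, x$converged, x$restarts))
  cat("  class sizes:", paste(tabulate(x$assignment, x$spec$n_classes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Posterior class membership of a single panel
#'
#' `P(class | panel) \propto weights[c] * exp(complete_loglik(...))`. When the
#' panel has zero likelihood under every class, a uniform vector is returned
#' with a warning.
#'
#' @inheritParams complete_loglik
#' @return probability vector of length `n_classes`
#' @export
posterior_membership <- function(panel, params, spec) {
  ll <- vapply(seq_len(spec$n_classes),
               function(c) complete_loglik(panel, c, params, spec), numeric(1))
  if (all(ll <= LOGLIK_FLOOR)) {
    warning("panel has zero likelihood under every class; returning uniform")
    return(rep(1 / spec$n_classes, spec$n_classes))
  }
  lw <- safe_log(params$weights) + ll
  p <- exp(lw - logsumexp(lw))
  p / sum(p)
}

# ---------------------------------------------------------------------------
# Evidence
# ---------------------------------------------------------------------------

#' Model evidence for a fitted specification
#'
#' `method = "holdout"`: mean per-child predictive log-likelihood over
#' `control$n_splits` random train/hold-out splits (default fraction 10%
#' held out). Each split refits on the training children — warm-started from
#' `fit_full` when supplied — and evaluates the held-out children under the
#' refitted MAP parameters. `method = "bic"`: maximised data log-likelihood
#' minus `(p/2) log N`. Both are "higher is better".
#'
#' @param cohort a [cohort_table()]
#' @param spec a [model_spec()]
#' @param seed master seed; split `i` uses a derived sub-seed
#' @param control an [em_control()]
#' @param method `"holdout"` or `"bic"`
#' @param fit_full optional [fit()] result on the full cohort to warm-start
#'   per-split refits (and to reuse for `"bic"`)
#' @return scalar evidence (higher = better fit)
#' @export
evidence <- function(cohort, spec, seed = 1L, control = em_control(),
                     method = c("holdout", "bic"), fit_full = NULL) {
  method <- match.arg(method)
  pd_n <- nrow(cohort)
  if (method == "bic") {
    if (is.null(fit_full)) fit_full <- fit(cohort, spec, seed = seed, control = control)
    p <- n_parameters(spec, cohort_grid(cohort))
    return(fit_full$loglik - 0.5 * p * log(pd_n))
  }
  if (control$holdout_frac >= 1) stop("hold-out split would leave an empty training set")
  warm <- if (!is.null(fit_full)) fit_full$params else NULL
  split_ctrl <- control
  split_ctrl$restarts <- control$evidence_restarts
  # split membership is derived per child id, so the same children are held
  # out whatever the row order (permutation-invariance contract); the derived
  # integer only seeds the RNG, whose initialisation scrambles the nearly
  # collinear id hashes into proper uniforms
  child_u <- function(i) {
    vapply(cohort$child_id, function(id)
      with_seed(derive_seed(seed, "holdout", i, id), stats::runif(1)),
      numeric(1))
  }
  per_split <- vapply(seq_len(control$n_splits), function(i) {
    u <- child_u(i)
    hold <- u < control$holdout_frac
    if (!any(hold)) hold[which.max(u)] <- TRUE
    if (all(hold)) stop("hold-out split would leave an empty training set")
    train <- subset_cohort(cohort, !hold)
    test <- subset_cohort(cohort, hold)
    f <- fit(train, spec, seed = derive_seed(seed, "split_fit", i),
             control = split_ctrl, init_params = warm)
    pd_test <- panel_data(test)
    ll <- loglik_matrix(pd_test, f$params, spec)
    lw <- sweep(ll, 2, safe_log(f$params$weights), "+")
    mean(row_logsumexp(lw))
  }, numeric(1))
  mean(per_split)
}
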