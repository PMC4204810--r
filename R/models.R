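# Model families over a child's longitudinal symptom panel.
#
# Three class-conditional generative laws for the S x T binary panel
# (S symptoms, T grid ages), mixed over n latent classes:
#
#   independent_markov  - per-symptom first-order chains; the probability of a
#                         symptom at time t depends only on the same symptom
#                         at t-1, with chains tied together by the class.
#   atopic_march_markov - adds the hypothesised cross-symptom lags: eczema at
#                         t-1 also conditions wheeze at t, and wheeze at t-1
#                         conditions rhinitis at t; own-symptom lags retained.
#   latent_profile      - unconstrained profile mixture: given the class, all
#                         symptom-by-age indicators are independent Bernoulli
#                         draws with their own probability.
#
# Emission/transition probabilities are parameterised on the probit scale
# (p = Phi(theta)) with a standard Gaussian prior on theta; class weights get
# a symmetric Dirichlet prior with a configurable pseudocount.

MODEL_FAMILIES <- c("independent_markov", "atopic_march_markov", "latent_profile")

#' Specify a latent-class model
#'
#' @param family one of `"independent_markov"`, `"atopic_march_markov"`,
#'   `"latent_profile"`
#' @param n_classes number of latent classes (2..15 in a standard sweep;
#'   1 allowed for degenerate checks)
#' @param pseudocount symmetric Dirichlet pseudocount per class for the class
#'   weight prior; the sensitivity sweep uses {1/n, 2/n, 1, 2}
#' @return object of class `model_spec`
#' @export
model_spec <- function(family = "latent_profile", n_classes = 8, pseudocount = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  stopifnot(n_classes >= 1, pseudocount > 0)
  structure(list(family = family, n_classes = as.integer(n_classes),
                 pseudocount = pseudocount),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model spec: %s, n = %d, Dirichlet pseudocount = %g\n",
              x$family, x$n_classes, x$pseudocount))
  invisible(x)
}

# Parent symptoms (at the previous grid age) of symptom s, by family.
# Symptom indices follow SYMPTOMS = (eczema, wheeze, rhinitis).
family_parents <- function(family, s) {
  if (family == "independent_markov") return(s)
  if (family == "atopic_march_markov")
    return(list(1L, c(2L, 1L), c(3L, 2L))[[s]])
  stop("latent_profile has no Markov parents")
}

#' Parent set of a symptom under the atopic-march Markov model
#'
#' Returns, for a symptom at grid position `t`, the (symptom, time) pairs it
#' is conditioned on: each symptom keeps its own first-order lag, wheeze is
#' additionally conditioned on eczema at the previous time step, and rhinitis
#' on wheeze at the previous time step. At the first grid age there are no
#' parents (initial state).
#'
#' @param symptom one of `"eczema"`, `"wheeze"`, `"rhinitis"`
#' @param t grid position (1-based)
#' @return data.frame with columns `symptom`, `t`; zero rows at `t = 1`
#' @export
atopic_march_parents <- function(symptom, t) {
  s <- match(symptom, SYMPTOMS)
  if (is.na(s)) stop("unknown symptom: ", symptom)
  if (t < 1) stop("t must be >= 1")
  if (t == 1) return(data.frame(symptom = character(0), t = integer(0)))
  pa <- list(1L, c(2L, 1L), c(3L, 2L))[[s]]
  data.frame(symptom = SYMPTOMS[pa], t = t - 1L)
}

# 1-based column index of a parent configuration: first parent is the least
# significant bit. `prev` is an N x S matrix of previous-time values.
parent_config_index <- function(prev, pa) {
  cfg <- rep(1L, nrow(prev))
  for (j in seq_along(pa)) cfg <- cfg + prev[, pa[j]] * 2L^(j - 1L)
  as.integer(cfg)
}

#' Construct model parameters
#'
#' For the `latent_profile` family supply `prob`, an `n x S x T` array of
#' emission probabilities. For the Markov families supply `init` (`n x S`
#' matrix of P(symptom present at first age | class)) and `trans` (list of S
#' matrices, one per symptom, each `n x 2^k` where k is the number of parent
#' symptoms; column `1 + sum(parent_value * 2^(position-1))` holds
#' P(symptom present at t | parents at t-1, class)).
#'
#' @param spec a [model_spec()]
#' @param weights class weights, length `n_classes`, summing to 1
#' @param prob,init,trans family-specific parameter arrays (see Details)
#' @param ages nominal age grid labels (default `c(1, 3, 5, 8, 11)`)
#' @return object of class `model_params`
#' @export
model_params <- function(spec, weights, prob = NULL, init = NULL, trans = NULL,
                         ages = c(1, 3, 5, 8, 11)) {
  out <- structure(list(family = spec$family, n_classes = spec$n_classes,
                        weights = as.numeric(weights) / sum(weights),
                        prob = prob, init = init, trans = trans,
                        grid = age_grid(ages)),
                   class = "model_params")
  validate_params(out, spec)
  out
}

params_grid <- function(params) params$grid

validate_params <- function(params, spec) {
  n <- spec$n_classes
  if (length(params$weights) != n) stop("weights length != n_classes")
  if (abs(sum(params$weights) - 1) > 1e-6) stop("weights must sum to 1")
  if (any(params$weights < 0)) stop("negative class weight")
  Tn <- length(params$grid$ages)
  S <- length(SYMPTOMS)
  chk01 <- function(x, what) {
    if (any(is.na(x)) || any(x < 0 | x > 1)) stop(what, " outside [0, 1]")
  }
  if (spec$family == "latent_profile") {
    if (is.null(params$prob) || !all(dim(params$prob) == c(n, S, Tn)))
      stop("latent_profile needs prob array of dim n x S x T")
    chk01(params$prob, "emission probability")
  } else {
    if (is.null(params$init) || !all(dim(params$init) == c(n, S)))
      stop("Markov family needs init matrix n x S")
    chk01(params$init, "initial-state probability")
    if (!is.list(params$trans) || length(params$trans) != S)
      stop("Markov family needs trans list of length S")
    for (s in seq_len(S)) {
      k <- length(family_parents(spec$family, s))
      if (!all(dim(params$trans[[s]]) == c(n, 2^k)))
        stop("trans[[", s, "]] must be n x ", 2^k)
      chk01(params$trans[[s]], "transition probability")
    }
  }
  invisible(TRUE)
}

# All 2^S joint symptom configurations at one time point (rows), bits in
# symptom order (symptom s = column s), first symptom least significant.
joint_states <- function(S = length(SYMPTOMS)) {
  n_st <- 2^S
  st <- matrix(0L, n_st, S)
  for (s in seq_len(S)) st[, s] <- (seq_len(n_st) - 1L) %/% 2L^(s - 1L) %% 2L
  st
}

# 2^S x 2^S joint transition matrix for class c: T[a, b] = prod_s
# P(y_s(t) = b_s | parents from row a).
joint_transition <- function(params, family, c) {
  st <- joint_states()
  n_st <- nrow(st)
  Tm <- matrix(1, n_st, n_st)
  for (s in seq_len(ncol(st))) {
    pa <- family_parents(family, s)
    cfg <- parent_config_index(st, pa)           # per source state a
    p1 <- params$trans[[s]][c, cfg]              # P(y_s = 1 | a)
    Pm <- outer(p1, st[, s], function(p, b) ifelse(b == 1, p, 1 - p))
    Tm <- Tm * Pm
  }
  Tm
}

# Joint initial distribution over 2^S states for class c.
joint_init <- function(params, c) {
  st <- joint_states()
  p <- rep(1, nrow(st))
  for (s in seq_len(ncol(st)))
    p <- p * ifelse(st[, s] == 1, params$init[c, s], 1 - params$init[c, s])
  p
}

# Evidence vector over joint states for one time point of one child:
# 1 for states consistent with the observed cells, 0 otherwise (missing
# cells constrain nothing - this is exactly the marginalisation contract).
state_evidence <- function(y_t) {
  st <- joint_states()
  ev <- rep(1, nrow(st))
  for (s in seq_along(y_t)) {
    if (!is.na(y_t[s])) ev <- ev * (st[, s] == y_t[s])
  }
  ev
}

#' Class-conditional log-likelihood of one child's panel
#'
#' Log probability of the observed cells of an `S x T` panel (rows in symptom
#' order, `NA` = missing) given the latent class, with missing cells and
#' missing Markov parents marginalised by exact summation. Impossible panels
#' (probability zero under the class) return the documented floor `-1e12`
#' rather than `-Inf`.
#'
#' @param panel `S x T` numeric matrix of 0/1/NA (rows = symptoms in the order
#'   eczema, wheeze, rhinitis)
#' @param c class index (1-based)
#' @param params a [model_params()]
#' @param spec a [model_spec()]
#' @return scalar log-likelihood
#' @export
complete_loglik <- function(panel, c, params, spec) {
  if (c < 1 || c > spec$n_classes) stop("class index out of range")
  Tn <- ncol(panel)
  if (spec$family == "latent_profile") {
    ll <- 0
    for (s in seq_len(nrow(panel))) for (t in seq_len(Tn)) {
      y <- panel[s, t]
      if (is.na(y)) next
      p <- params$prob[c, s, t]
      ll <- ll + if (y == 1) log(p) else log1p(-p)
    }
    return(max(ll, LOGLIK_FLOOR))
  }
  # Markov families: forward pass over the 2^S joint state space
  m <- joint_init(params, c) * state_evidence(panel[, 1])
  Tm <- joint_transition(params, spec$family, c)
  for (t in seq_len(Tn)[-1]) {
    m <- as.vector(m %*% Tm) * state_evidence(panel[, t])
  }
  tot <- sum(m)
  if (tot <= 0) return(LOGLIK_FLOOR)
  max(log(tot), LOGLIK_FLOOR)
}

#' Marginal (mixture) log-likelihood of one child's panel
#'
#' `log sum_c weights[c] * exp(complete_loglik(panel, c, ...))`, computed with
#' log-sum-exp.
#'
#' @inheritParams complete_loglik
#' @return scalar log-likelihood
#' @export
marginal_loglik <- function(panel, params, spec) {
  ll <- vapply(seq_len(spec$n_classes),
               function(c) complete_loglik(panel, c, params, spec), numeric(1))
  logsumexp(log(params$weights) + ll)
}

#' Serialise model parameters to / from flat JSON
#'
#' @param params a [model_params()]
#' @param path file path
#' @return `params_from_json` returns a [model_params()]
#' @export
params_to_json <- function(params, path) {
  x <- list(family = params$family, n_classes = params$n_classes,
            ages = params$grid$ages, weights = params$weights)
  if (params$family == "latent_profile") {
    x$prob <- as.vector(params$prob)
    x$prob_dim <- dim(params$prob)
  } else {
    x$init <- as.vector(params$init)
    x$trans <- lapply(params$trans, as.vector)
    x$trans_cols <- vapply(params$trans, ncol, integer(1))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(x$family, x$n_classes)
  if (x$family == "latent_profile") {
    model_params(spec, weights = x$weights,
                 prob = array(x$prob, dim = x$prob_dim), ages = x$ages)
  } else {
    n <- x$n_classes
    # jsonlite simplifies equal-length per-symptom vectors to a matrix
    tr <- if (is.matrix(x$trans)) lapply(seq_len(nrow(x$trans)),
                                         function(s) x$trans[s, ]) else x$trans
    trans <- lapply(tr, function(v) matrix(v, nrow = n))
    model_params(spec, weights = x$weights,
                 init = matrix(x$init, nrow = n), trans = trans, ages = x$ages)
  }
}

# Number of free parameters (for the BIC evidence approximation).
n_parameters <- function(spec, grid) {
  n <- spec$n_classes
  Tn <- length(grid$ages)
  S <- length(SYMPTOMS)
  if (spec$family == "latent_profile") return((n - 1) + n * S * Tn)
  per_class <- sum(vapply(seq_len(S), function(s)
    1 + 2^length(family_parents(spec$family, s)), numeric(1)))
  (n - 1) + n * per_class
}
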