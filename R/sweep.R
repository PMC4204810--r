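# Class-number and model-family selection.

#' Stability-based convergence check
#'
#' A run is declared converged when the objective has remained stable for
#' `window` consecutive iterations: over the last `window` recorded values,
#' the total relative variation (max - min, relative to the magnitude of the
#' final value) is below `tol`. Traces shorter than the window are not
#' converged.
#'
#' @param trace numeric vector of per-iteration objective values
#' @param window number of consecutive stable iterations required (default 100)
#' @param tol relative stability tolerance (default 1e-6)
#' @return logical flag
#' @export
convergence_check <- function(trace, window = 100, tol = 1e-6) {
  if (!length(trace)) stop("empty trace")
  if (length(trace) < window) return(FALSE)
  tail_vals <- trace[(length(trace) - window + 1):length(trace)]
  scale <- max(abs(tail_vals[window]), 1)
  (max(tail_vals) - min(tail_vals)) / scale < tol
}

#' Sweep model families, class numbers and pseudocounts
#'
#' Fits every requested (family, n, pseudocount) combination, records its
#' evidence and convergence flag, and selects the evidence-maximising
#' combination *among converged fits only* — mirroring an analysis in which
#' families that fail to reach stable convergence are reported but excluded
#' from selection. Per-combination seeds are derived deterministically from
#' the master seed, so execution order (or parallelisation) cannot change the
#' result.
#'
#' @param cohort a [cohort_table()]
#' @param families character vector of model families
#' @param n_range integer vector of class numbers (standard sweep: 2..15)
#' @param pseudocounts numeric vector of Dirichlet pseudocounts
#' @param seed master seed
#' @param control an [em_control()]
#' @param method evidence method, `"holdout"` or `"bic"`
#' @return object of class `sweep_result`: `table` (one row per combination,
#'   with evidence, converged and selected flags), `selected` (list with
#'   family, n_classes, pseudocount), `fits` (list of fit results keyed by
#'   combination label)
#' @export
sweep_models <- function(cohort, families = "latent_profile", n_range = 2:15,
                         pseudocounts = 1, seed = 1L, control = em_control(),
                         method = c("holdout", "bic")) {
  method <- match.arg(method)
  if (!length(n_range)) stop("n_range must be non-empty")
  if (!length(pseudocounts)) stop("pseudocounts must be non-empty")
  combos <- expand.grid(family = families, n_classes = n_range,
                        pseudocount = pseudocounts,
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fam <- combos$family[i]; n <- combos$n_classes[i]; a <- combos$pseudocount[i]
    spec <- model_spec(fam, n_classes = n, pseudocount = a)
    sub_seed <- derive_seed(seed, fam, n, round(a * 1000))
    f <- fit(cohort, spec, seed = sub_seed, control = control)
    ev <- evidence(cohort, spec, seed = sub_seed, control = control,
                   method = method, fit_full = f)
    key <- sprintf("%s_n%d_a%g", fam, n, a)
    fits[[i]] <- f
    names(fits)[i] <- key
    rows[[i]] <- data.frame(family = fam, n_classes = n, pseudocount = a,
                            evidence = ev, converged = f$converged)
  }
  tab <- do.call(rbind, rows)
  tab$selected <- FALSE
  selected <- NULL
  conv <- which(tab$converged)
  if (length(conv)) {
    best <- conv[which.max(tab$evidence[conv])]
    tab$selected[best] <- TRUE
    selected <- list(family = tab$family[best], n_classes = tab$n_classes[best],
                     pseudocount = tab$pseudocount[best],
                     fit = fits[[best]])
  }
  structure(list(table = tab, selected = selected, fits = fits,
                 method = method, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("model sweep (evidence method:", x$method, ")\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$selected))
    cat(sprintf("selected: %s with n = %d (pseudocount %g)\n",
                x$selected$family, x$selected$n_classes, x$selected$pseudocount))
  else cat("no converged fit; nothing selected\n")
  invisible(x)
}

#' Dirichlet-pseudocount prior sensitivity analysis
#'
#' Re-runs the class-number sweep under each pseudocount and reports the
#' selected class number per pseudocount, plus a consistency flag that is
#' `TRUE` when every pseudocount selects the same n.
#'
#' @param cohort a [cohort_table()]
#' @param family model family to sweep
#' @param n_range class numbers to sweep
#' @param pseudocounts pseudocounts to compare; the conventional set for n
#'   classes is `c(1/n, 2/n, 1, 2)`
#' @param seed master seed
#' @param control an [em_control()]
#' @param method evidence method
#' @return list: `table` (pseudocount, selected_n, evidence), `consistent`
#' @export
prior_sensitivity <- function(cohort, family = "latent_profile", n_range = 2:6,
                              pseudocounts, seed = 1L, control = em_control(),
                              method = c("holdout", "bic")) {
  method <- match.arg(method)
  if (missing(pseudocounts) || !length(pseudocounts))
    stop("pseudocounts must be a non-empty numeric vector")
  rows <- lapply(pseudocounts, function(a) {
    sw <- sweep_models(cohort, families = family, n_range = n_range,
                       pseudocounts = a, seed = seed, control = control,
                       method = method)
    sel_n <- if (is.null(sw$selected)) NA_integer_ else sw$selected$n_classes
    sel_ev <- if (is.null(sw$selected)) NA_real_ else
      sw$table$evidence[sw$table$selected]
    data.frame(pseudocount = a, selected_n = sel_n, evidence = sel_ev)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       consistent = length(unique(tab$selected_n)) == 1 && !anyNA(tab$selected_n))
}

#' Write a sweep result to CSV
#' @param sweep a `sweep_result`
#' @param path file path
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}
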