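# Cohort container and derived-variable / inclusion-filter rules.

SYMPTOMS <- c("eczema", "wheeze", "rhinitis")

#' Create an age grid
#'
#' The nominal follow-up ages at which symptoms are recorded. Review-clinic
#' ages in the source cohorts differ slightly from these labels (e.g. 1.5 or
#' 3.5 y); the grid stores nominal labels only and "previous/next time step"
#' always means the adjacent grid position.
#'
#' @param ages strictly increasing numeric vector of nominal ages in years
#' @return object of class `age_grid`
#' @export
age_grid <- function(ages = c(1, 3, 5, 8, 11)) {
  ages <- as.numeric(ages)
  if (length(ages) < 2) stop("age grid needs at least two time points")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  structure(list(ages = ages), class = "age_grid")
}

#' @export
length.age_grid <- function(x) length(x$ages)

#' @export
print.age_grid <- function(x, ...) {
  cat("age grid:", paste(x$ages, collapse = ", "), "years\n")
  invisible(x)
}

symptom_cols <- function(symptoms, ages) {
  as.vector(t(outer(symptoms, ages, paste, sep = "_")))
}

#' Construct a cohort table
#'
#' A cohort table is a wide data frame with one row per child: identifier,
#' cohort label, sex, and one column `<symptom>_<age>` per symptom and age
#' holding 0, 1 or `NA` (explicit missingness; no sentinel values). Auxiliary
#' columns (skin-prick wheals, steroid prescriptions, medication use, asthma
#' diagnosis) may be present. Structural missingness — cells never collected
#' by design, e.g. rhinitis before age 5 in one cohort — is recorded in the
#' `structural` attribute as a data frame (cohort, symptom, age).
#'
#' @param data data.frame with columns `child_id`, `cohort`, `sex` and the
#'   symptom columns
#' @param grid an [age_grid()]
#' @param symptoms character vector of symptom names
#' @param structural optional data.frame (cohort, symptom, age) of
#'   structurally unobserved cells
#' @return object of classes `cohort_table` and `data.frame`
#' @export
cohort_table <- function(data, grid = age_grid(),
                         symptoms = SYMPTOMS, structural = NULL) {
  req <- c("child_id", "cohort", symptom_cols(symptoms, grid$ages))
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(data$child_id)) stop("duplicated child_id")
  for (cl in symptom_cols(symptoms, grid$ages)) {
    v <- data[[cl]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stop("column ", cl, " contains values outside {0, 1, NA}")
  }
  structure(as.data.frame(data),
            grid = grid, symptoms = symptoms, structural = structural,
            class = c("cohort_table", "data.frame"))
}

cohort_grid <- function(cohort) attr(cohort, "grid")
cohort_symptoms <- function(cohort) attr(cohort, "symptoms")

#' @export
print.cohort_table <- function(x, ...) {
  g <- cohort_grid(x)
  cat(sprintf("cohort table: %d children, %d cohort(s), symptoms {%s} at ages {%s}\n",
              nrow(x), length(unique(x$cohort)),
              paste(cohort_symptoms(x), collapse = ", "),
              paste(g$ages, collapse = ", ")))
  NextMethod()
}

# Extract the N x (S*T) observation matrix (0/1/NA), children in row order.
# Column order: symptom-major, i.e. eczema_1..eczema_11, wheeze_1, ...
panel_matrix <- function(cohort) {
  g <- cohort_grid(cohort)
  cols <- symptom_cols(cohort_symptoms(cohort), g$ages)
  y <- as.matrix(as.data.frame(cohort)[, cols])
  storage.mode(y) <- "double"
  rownames(y) <- cohort$child_id
  y
}

# Single-child panel as an S x T matrix (rows = symptoms).
child_panel <- function(cohort, i) {
  g <- cohort_grid(cohort)
  sy <- cohort_symptoms(cohort)
  y <- panel_matrix(cohort)[i, ]
  matrix(y, nrow = length(sy), byrow = TRUE,
         dimnames = list(sy, g$ages))
}

#' Derive current asthma from its three component features
#'
#' Current asthma is defined as the presence of any two of: current wheeze,
#' current use of asthma medication, and physician-diagnosed asthma ever.
#' Missing components propagate to a missing result unless the observed
#' components already decide the outcome (two observed positives give 1; two
#' observed negatives plus the rule make a positive impossible only when the
#' third is also observed, except that two zeros among three already cap the
#' positive count below two when the third is observed — with one unobserved
#' component and fewer than two positives the result is unknown only if the
#' missing component could still tip it).
#'
#' @param wheeze_t,med_use_t,dx_ever_t binary (0/1/NA) vectors, recycled
#' @return binary vector with NA where undecidable
#' @export
derive_asthma <- function(wheeze_t, med_use_t, dx_ever_t) {
  x <- cbind(wheeze_t, med_use_t, dx_ever_t)
  pos <- rowSums(x == 1, na.rm = TRUE)
  obs <- rowSums(!is.na(x))
  out <- ifelse(pos >= 2, 1, ifelse(pos + (3 - obs) < 2, 0, NA))
  as.vector(out)
}

#' Derive atopic sensitisation from skin-prick wheal diameters
#'
#' Sensitised means a wheal diameter at least 3 mm greater than the negative
#' control for at least one allergen.
#'
#' @param wheals_t numeric vector of wheal diameters (mm) across allergens
#' @param neg_control_t negative-control wheal diameter (mm)
#' @param threshold_mm positivity threshold, default 3 mm
#' @return 0/1, or NA for an empty/unmeasured allergen panel
#' @export
derive_sensitised <- function(wheals_t, neg_control_t, threshold_mm = 3) {
  wheals_t <- wheals_t[!is.na(wheals_t)]
  if (!length(wheals_t) || is.na(neg_control_t)) return(NA_real_)
  if (any(wheals_t < 0) || neg_control_t < 0) stop("wheal diameters must be >= 0 mm")
  as.numeric(max(wheals_t - neg_control_t) >= threshold_mm)
}

# Structural (cohort, symptom, age) cells: explicit attribute if present,
# otherwise inferred as per-cohort all-missing columns (matches how a column
# that was never collected presents in the data).
structural_cells <- function(cohort) {
  st <- attr(cohort, "structural")
  if (!is.null(st)) return(st)
  g <- cohort_grid(cohort)
  out <- list()
  for (co in unique(cohort$cohort)) {
    sub <- cohort[cohort$cohort == co, , drop = FALSE]
    for (s in cohort_symptoms(cohort)) for (a in g$ages) {
      cl <- paste(s, a, sep = "_")
      if (all(is.na(sub[[cl]])))
        out[[length(out) + 1L]] <- data.frame(cohort = co, symptom = s, age = a)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Inclusion filter: minimum observed time points per symptom
#'
#' Retains children having at least `k` non-missing observations for every
#' symptom. Ages at which a symptom was never collected for a child's cohort
#' (structural missingness) are by default exempt from the requirement for
#' that symptom — the count is taken over the ages actually collected, and a
#' symptom with fewer than `k` collected ages cannot disqualify a child.
#'
#' @param cohort a [cohort_table()]
#' @param k minimum number of observed time points per symptom (default 2)
#' @param exempt_structural exempt structurally unobserved cells (default TRUE)
#' @return filtered cohort table
#' @export
filter_min_timepoints <- function(cohort, k = 2, exempt_structural = TRUE) {
  stopifnot(k >= 1)
  g <- cohort_grid(cohort)
  sy <- cohort_symptoms(cohort)
  st <- if (exempt_structural) structural_cells(cohort) else NULL
  keep <- rep(TRUE, nrow(cohort))
  for (s in sy) {
    cols <- paste(s, g$ages, sep = "_")
    obs <- rowSums(!is.na(as.data.frame(cohort)[, cols, drop = FALSE]))
    # per-cohort number of collectable ages for this symptom
    need <- rep(k, nrow(cohort))
    if (!is.null(st)) {
      n_struct <- vapply(cohort$cohort, function(co)
        sum(st$cohort == co & st$symptom == s), numeric(1))
      collectable <- length(g$ages) - n_struct
      need <- pmin(k, collectable)
    }
    keep <- keep & (obs >= need)
  }
  subset_cohort(cohort, keep)
}

#' Exclusion filter: drop children with (presumed) mild early eczema
#'
#' Mild eczema is parentally reported eczema with no physician-prescribed
#' topical corticosteroid. Children with reported eczema at age 1 or 3 y and
#' a zero steroid-prescription flag are dropped, as are children with
#' reported early eczema whose prescription flag is missing (severity
#' unconfirmable) and children missing eczema at both early ages.
#'
#' @param cohort a [cohort_table()] with a `steroidrx3` column
#' @param early_ages ages defining "early" eczema (default first two grid ages)
#' @return filtered cohort table
#' @export
filter_mild_eczema <- function(cohort, early_ages = NULL) {
  g <- cohort_grid(cohort)
  if (is.null(early_ages)) early_ages <- g$ages[1:2]
  if (is.null(cohort$steroidrx3))
    stop("filter_mild_eczema needs a steroidrx3 column")
  ecz <- as.data.frame(cohort)[, paste("eczema", early_ages, sep = "_"), drop = FALSE]
  reported <- rowSums(ecz == 1, na.rm = TRUE) > 0
  all_missing <- rowSums(!is.na(ecz)) == 0
  rx <- cohort$steroidrx3
  drop <- (reported & !is.na(rx) & rx == 0) |
    (reported & is.na(rx)) |
    all_missing
  subset_cohort(cohort, !drop)
}

subset_cohort <- function(cohort, keep) {
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            grid = cohort_grid(cohort), symptoms = cohort_symptoms(cohort),
            structural = attr(cohort, "structural"),
            class = c("cohort_table", "data.frame"))
}

#' Replace the wheeze columns with derived current asthma
#'
#' For the analysis variant that models current asthma instead of wheeze:
#' each `wheeze_<age>` column is recomputed as the two-of-three asthma rule
#' from wheeze, medication use and diagnosis columns at that age.
#'
#' @param cohort a cohort table with `meduse_<age>` and `dxasthma_<age>` columns
#' @return cohort table with wheeze columns replaced
#' @export
use_asthma_variant <- function(cohort) {
  g <- cohort_grid(cohort)
  out <- as.data.frame(cohort)
  for (a in g$ages) {
    mu <- out[[paste0("meduse_", a)]]
    dx <- out[[paste0("dxasthma_", a)]]
    if (is.null(mu) || is.null(dx))
      stop("asthma variant needs meduse_<age> and dxasthma_<age> columns")
    out[[paste0("wheeze_", a)]] <-
      derive_asthma(out[[paste0("wheeze_", a)]], mu, dx)
  }
  structure(out,
            grid = g, symptoms = cohort_symptoms(cohort),
            structural = attr(cohort, "structural"),
            class = c("cohort_table", "data.frame"))
}

#' Read / write the wide cohort CSV dialect
#'
#' One row per child; columns `child_id`, `cohort`, `sex`, then
#' `<symptom>_<age>` with values 0/1/NA, plus any auxiliary columns.
#'
#' @param path file path
#' @param grid an [age_grid()]
#' @param symptoms symptom names expected in the header
#' @return a [cohort_table()]
#' @export
read_cohort_csv <- function(path, grid = age_grid(), symptoms = SYMPTOMS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(df, grid = grid, symptoms = symptoms)
}

#' @rdname read_cohort_csv
#' @param cohort a [cohort_table()]
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}
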