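#' Juvenile Arthritis Disease Activity Score (JADAS)
#'
#' JADAS is the sum of four components: physician global assessment (0-10),
#' patient/parent global evaluation (0-10), the active joint count truncated
#' at the variant's cap (10, 27 or 71 joints), and an ESR term transformed
#' as (ESR - 20)/10 clamped to [0, 10]. The ESR-based score is the only
#' variant offered; which joint-count cap to use is left to the caller since
#' all three are in established use.
#'
#' Scores are computed for complete cases only: if any component is missing
#' the result is flagged incomputable, with the missing components named —
#' no silent imputation.
#'
#' @param pga physician global assessment, 0-10.
#' @param pge patient/parent global evaluation, 0-10.
#' @param ajc active joint count, 0-71.
#' @param esr erythrocyte sedimentation rate, mm/h.
#' @param variant `"JADAS-10"`, `"JADAS-27"` or `"JADAS-71"`.
#' @return an object of class `cf_jadas`: `variant`, `value` (`NA` when
#'   incomputable), `components`, `missing_components`.
#' @examples
#' jadas(3.5, 2.0, 5, 40, "JADAS-71") # 12.5
#' @export
jadas <- function(pga, pge, ajc, esr,
                  variant = c("JADAS-71", "JADAS-10", "JADAS-27")) {
  variant <- match.arg(variant)
  cap <- c("JADAS-10" = 10, "JADAS-27" = 27, "JADAS-71" = 71)[[variant]]
  inputs <- list(pga = pga, pge = pge, ajc = ajc, esr = esr)
  missing_ones <- names(inputs)[vapply(inputs, function(x) {
    length(x) != 1L || is.na(x)
  }, logical(1))]
  if (length(missing_ones) > 0) {
    return(structure(
      list(variant = variant, value = NA_real_, components = NULL,
           missing_components = missing_ones),
      class = c("cf_jadas", "list")
    ))
  }
  check_in <- function(x, lo, hi, nm) {
    if (x < lo || x > hi) {
      abort(sprintf("`%s` outside [%g, %g]", nm, lo, hi),
        class = "cohortforge_range_error"
      )
    }
  }
  check_in(pga, 0, 10, "pga"); check_in(pge, 0, 10, "pge")
  check_in(ajc, 0, 71, "ajc"); check_in(esr, 0, Inf, "esr")
  comps <- c(
    pga = pga, pge = pge, ajc = min(ajc, cap),
    esr = min(max((esr - 20) / 10, 0), 10)
  )
  structure(
    list(variant = variant, value = sum(comps), components = comps,
         missing_components = character(0)),
    class = c("cf_jadas", "list")
  )
}

# vectorised JADAS values; NA wherever any component is missing
jadas_values <- function(pga, pge, ajc, esr, variant = "JADAS-71") {
  cap <- c("JADAS-10" = 10, "JADAS-27" = 27, "JADAS-71" = 71)[[variant]]
  pga + pge + pmin(ajc, cap) + pmin(pmax((esr - 20) / 10, 0), 10)
}

#' ACR Pedi 30/50/70 response
#'
#' Response at level L requires at least 3 of the 6 core outcome variables
#' (physician global, patient/parent global, CHAQ, active joint count,
#' limited joint count, ESR) improved by at least L% from baseline, with
#' more than 30% worsening in no more than 1. Percent change is
#' 100 x (follow-up - baseline) / baseline; a zero baseline cannot improve,
#' and counts as worsened iff the follow-up value is positive.
#'
#' @param baseline named numeric vector of the 6 core variables at baseline
#'   (names `pga`, `pge`, `chaq`, `ajc`, `ljc`, `esr`).
#' @param followup same shape, at follow-up.
#' @param level 30, 50 or 70.
#' @return an object of class `cf_acr_pedi`: `level`, `responder`,
#'   `n_improved`, `n_worsened`, `pct_change`, `missing_components`.
#' @export
acr_pedi <- function(baseline, followup, level = 30) {
  stopifnot(level %in% c(30, 50, 70))
  base <- baseline[ACR_CORE]
  fu <- followup[ACR_CORE]
  missing_ones <- ACR_CORE[is.na(base) | is.na(fu)]
  if (length(missing_ones) > 0) {
    return(structure(
      list(level = level, responder = NA, n_improved = NA_integer_,
           n_worsened = NA_integer_, pct_change = NULL,
           missing_components = missing_ones),
      class = c("cf_acr_pedi", "list")
    ))
  }
  pct <- ifelse(base == 0, NA_real_, 100 * (fu - base) / base)
  improved <- !is.na(pct) & pct <= -level          # zero baseline: impossible
  worsened <- ifelse(base == 0, fu > 0, pct > 30)  # zero baseline: iff fu > 0
  structure(
    list(
      level = level,
      responder = sum(improved) >= 3 && sum(worsened) <= 1,
      n_improved = sum(improved), n_worsened = sum(worsened),
      pct_change = setNames(pct, ACR_CORE),
      missing_components = character(0)
    ),
    class = c("cf_acr_pedi", "list")
  )
}

#' Missingness report for a cohort dataset
#'
#' Percentage of missing values per (variable, time point), with the
#' structural share decomposed by source study: a value is structurally
#' missing when the retained record's study never collected the variable,
#' and randomly missing otherwise. Denominator is the cohort size.
#'
#' @param cohort a `cf_cohort_dataset`.
#' @param variables core outcome variables to report at T1/T2; patient-level
#'   variables are always reported once.
#' @param mapping mapping configuration (availability matrix).
#' @return a tibble of class `cf_missingness` with columns `variable`,
#'   `timepoint`, `n`, `n_missing`, `pct_missing`, `n_structural`,
#'   `pct_structural`. With an empty cohort, percentages are `NA` and the
#'   `empty_cohort` attribute is set.
#' @export
missingness_report <- function(cohort, variables = COV_VARS,
                               mapping = load_mapping_config()) {
  stopifnot(inherits(cohort, "cf_cohort_dataset"))
  rows <- cohort$rows
  n <- nrow(rows)
  patient_vars <- c("gender", "ethnicity", "ilar_subtype", "ana", "rf",
                    "hla_b27", "uveitis_ever")
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(variable = variables, timepoint = c("T1", "T2")),
    tibble::tibble(variable = patient_vars, timepoint = "patient")
  )
  unav <- mapping$availability$unavailable
  struct_of <- function(var) {
    studies <- names(unav)[vapply(unav, function(u) var %in% u, logical(1))]
    if (n == 0) 0L else sum(rows$source_study %in% studies)
  }
  out <- purrr::pmap_dfr(grid, function(variable, timepoint) {
    col <- switch(timepoint,
      "T1" = paste0("t1_", variable),
      "T2" = paste0("t2_", variable),
      variable
    )
    x <- if (n == 0) logical(0) else is.na(rows[[col]])
    n_structural <- struct_of(variable)
    tibble::tibble(
      variable = variable, timepoint = timepoint, n = n,
      n_missing = sum(x),
      pct_missing = if (n == 0) NA_real_ else round(100 * sum(x) / n, 1),
      n_structural = n_structural,
      pct_structural = if (n == 0) NA_real_ else round(100 * n_structural / n, 1)
    )
  })
  if (n == 0) attr(out, "empty_cohort") <- TRUE
  class(out) <- c("cf_missingness", class(out))
  out
}

#' Characteristics table for a cohort dataset
#'
#' N (%) for gender, ethnicity, ILAR subtype and uveitis (missing counted as
#' its own category), and mean (SD) for age at JIA onset and the baseline
#' active and limited joint counts. Age at onset is computed from the
#' symptom-onset date where the retained study collected it, falling back to
#' the diagnosis date otherwise.
#'
#' @param cohort a `cf_cohort_dataset`.
#' @return a tibble with columns `characteristic`, `level`, `n`, `pct`,
#'   `mean`, `sd`.
#' @export
characteristics_table <- function(cohort) {
  stopifnot(inherits(cohort, "cf_cohort_dataset"))
  rows <- cohort$rows
  n_total <- nrow(rows)
  cat_block <- function(x, characteristic, levels) {
    x <- as.character(x)
    x[is.na(x)] <- "missing"
    counts <- table(factor(x, levels = c(levels, "missing")))
    tibble::tibble(
      characteristic = characteristic,
      level = names(counts),
      n = as.integer(counts),
      pct = if (n_total == 0) rep(NA_real_, length(counts)) else
        round(100 * as.integer(counts) / n_total, 1),
      mean = NA_real_, sd = NA_real_
    )
  }
  num_block <- function(x, characteristic) {
    tibble::tibble(
      characteristic = characteristic, level = "mean (SD)",
      n = sum(!is.na(x)), pct = NA_real_,
      mean = if (all(is.na(x))) NA_real_ else round(mean(x, na.rm = TRUE), 1),
      sd = if (sum(!is.na(x)) < 2) NA_real_ else round(sd(x, na.rm = TRUE), 1)
    )
  }
  if (n_total == 0) {
    rows <- tibble::tibble(
      gender = character(0), ethnicity = character(0),
      ilar_subtype = character(0), uveitis_ever = character(0),
      date_of_symptom_onset = as.Date(character(0)),
      date_of_diagnosis = as.Date(character(0)),
      date_of_birth = as.Date(character(0)),
      t1_ajc = numeric(0), t1_ljc = numeric(0)
    )
  }
  onset <- dplyr::coalesce(rows$date_of_symptom_onset, rows$date_of_diagnosis)
  age_onset <- as.numeric(onset - rows$date_of_birth) / 365.25
  dplyr::bind_rows(
    cat_block(rows$gender, "gender", c("male", "female")),
    cat_block(rows$ethnicity, "ethnicity", c("Caucasian", "Non-Caucasian")),
    cat_block(rows$ilar_subtype, "ilar_subtype", ILAR_LEVELS),
    cat_block(rows$uveitis_ever, "uveitis", c("yes", "no")),
    num_block(age_onset, "age_at_onset_years"),
    num_block(rows$t1_ajc, "ajc_baseline"),
    num_block(rows$t1_ljc, "ljc_baseline")
  )
}

#' Plot missingness by variable and time point
#'
#' Bar chart of percentage missingness per core outcome variable at T1 and
#' T2, optionally faceted by cohort when given a named list of reports.
#'
#' @param reports a `cf_missingness` tibble or a named list of them.
#' @return a ggplot object.
#' @export
plot_missingness <- function(reports) {
  if (inherits(reports, "cf_missingness")) reports <- list(cohort = reports)
  df <- dplyr::bind_rows(reports, .id = "cohort") |>
    dplyr::filter(.data$timepoint %in% c("T1", "T2"))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$variable, y = .data$pct_missing, fill = .data$timepoint)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = NULL, y = "% missing", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
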