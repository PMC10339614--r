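#' Map one study's extract into the common data model
#'
#' Renames the study dialect's columns to CDM names, decodes its value
#' codings through the configured mapping tables (collapsing granular codes
#' to the most inclusive shared definition, e.g. any detailed non-Caucasian
#' ethnic group to `Non-Caucasian`), coerces types, and materialises every
#' CDM variable: variables the study never collected are present but all
#' missing and flagged structural. Unknown source codes are an error naming
#' the code and study — no silent coercion — and a value present in the
#' source is never invented or dropped.
#'
#' @param extract list with elements `main` (visit-level rows carrying the
#'   patient columns) and `episodes`, as produced by the generator or read
#'   back with [read_study_csv()].
#' @param study the study name (must have a dialect in `mapping`).
#' @param mapping a mapping configuration.
#' @return a list of class `cf_cdm` with tibbles `patients` (one row per
#'   record), `visits`, and `episodes`, each carrying `source_study` and
#'   `record_id` provenance. The names of structurally missing variables are
#'   attached as the `"structural"` attribute on each tibble.
#' @export
map_to_cdm <- function(extract, study, mapping = load_mapping_config()) {
  sc <- mapping$studies[[study]]
  if (is.null(sc)) {
    abort(paste0("no mapping table for study: ", study),
      class = "cohortforge_config_error"
    )
  }
  reg <- cdm_variable_registry()
  unavailable <- mapping$availability$unavailable[[study]] %||% character(0)

  decode <- function(x, var) {
    vm <- sc$values[[var]]
    if (is.null(vm)) return(x)
    codes <- names(vm)
    canonical <- unlist(vm, use.names = FALSE)
    x <- as.character(x)
    out <- canonical[match(x, codes)]
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      abort(paste0(
        "unmapped source code(s) for `", var, "` in study ", study, ": ",
        paste(unique(x[bad]), collapse = ", ")
      ), class = "cohortforge_unmapped_code")
    }
    out
  }

  date_vars <- c(
    "entry_date", "date_of_birth", "date_of_diagnosis",
    "date_of_symptom_onset", "visit_date", "start_date", "stop_date"
  )
  num_vars <- c(COV_VARS, "height_cm", "weight_kg", "dose")

  build <- function(tbl, table_name) {
    colmap <- sc$columns[[table_name]]
    vars <- reg[[table_name]]
    out <- tibble::tibble(.rows = nrow(tbl))
    if ("record_id" %in% names(tbl)) out$record_id <- tbl$record_id
    for (v in vars) {
      src <- colmap[[v]]
      if (is.null(src)) { # structurally unavailable for this study
        out[[v]] <- if (v %in% date_vars) as.Date(NA) else
          if (v %in% num_vars) NA_real_ else NA_character_
        next
      }
      if (!src %in% names(tbl)) {
        abort(paste0(
          "study ", study, " extract is missing mapped column `", src, "`"
        ), class = "cohortforge_schema_error")
      }
      x <- decode(tbl[[src]], v)
      if (v %in% date_vars) x <- as.Date(x)
      if (v %in% num_vars) x <- as.numeric(x)
      out[[v]] <- x
    }
    out$source_study <- rep(study, nrow(out))
    attr(out, "structural") <- intersect(unavailable, vars)
    out
  }

  main <- dplyr::as_tibble(extract$main)
  patients <- build(
    dplyr::distinct(
      main, dplyr::across(dplyr::any_of(c(
        "record_id", unlist(sc$columns$records, use.names = FALSE)
      )))
    ),
    "records"
  )
  if (anyDuplicated(patients$record_id) > 0) {
    abort(paste0(
      "study ", study, ": inconsistent patient-level fields within a record"
    ), class = "cohortforge_schema_error")
  }
  visits <- build(main, "visits")
  episodes <- build(dplyr::as_tibble(extract$episodes), "episodes")

  check_cov_ranges(visits, study)
  both <- !is.na(patients$date_of_symptom_onset) & !is.na(patients$date_of_diagnosis)
  if (any(both & patients$date_of_symptom_onset > patients$date_of_diagnosis)) {
    abort(paste0("study ", study, ": symptom onset after diagnosis"),
      class = "cohortforge_schema_error"
    )
  }
  bad_ep <- !is.na(episodes$stop_date) & episodes$stop_date < episodes$start_date
  if (any(bad_ep)) {
    abort(paste0("study ", study, ": episode stop date before start date"),
      class = "cohortforge_schema_error"
    )
  }

  structure(
    list(patients = patients, visits = visits, episodes = episodes),
    class = c("cf_cdm", "list")
  )
}

cov_ranges <- function() {
  list(
    ajc = c(0, 71), ljc = c(0, 71), chaq = c(0, 3), esr = c(0, Inf),
    crp = c(0, Inf), pga = c(0, 10), pge = c(0, 10), pain_vas = c(0, 10)
  )
}

check_cov_ranges <- function(visits, study) {
  for (v in names(cov_ranges())) {
    r <- cov_ranges()[[v]]
    x <- visits[[v]]
    bad <- !is.na(x) & (x < r[1] | x > r[2])
    if (any(bad)) {
      abort(sprintf(
        "study %s: `%s` outside [%g, %g] (e.g. %g)", study, v, r[1], r[2],
        x[which(bad)[1]]
      ), class = "cohortforge_range_error")
    }
  }
  invisible(visits)
}

#' Pool per-study CDM sets
#'
#' Concatenates the harmonised per-study tables, preserving `source_study`
#' provenance. All inputs must share an identical schema per table; a
#' mismatch is an error naming the offending columns. Row counts are
#' conserved: the pooled table has exactly the sum of the input rows.
#'
#' @param cdm_sets a list of `cf_cdm` objects.
#' @return a single `cf_cdm` with pooled `patients`, `visits`, `episodes`.
#' @export
pool_records <- function(cdm_sets) {
  stopifnot(length(cdm_sets) > 0)
  for (x in cdm_sets) stopifnot(inherits(x, "cf_cdm"))
  pool_one <- function(tbl_name) {
    tbls <- lapply(cdm_sets, `[[`, tbl_name)
    ref <- names(tbls[[1]])
    for (i in seq_along(tbls)) {
      diff <- c(setdiff(ref, names(tbls[[i]])), setdiff(names(tbls[[i]]), ref))
      if (length(diff) > 0) {
        abort(paste0(
          "schema mismatch pooling `", tbl_name, "`: ",
          paste(unique(diff), collapse = ", ")
        ), class = "cohortforge_schema_error")
      }
    }
    pooled <- dplyr::bind_rows(tbls)
    attr(pooled, "structural") <- lapply(tbls, attr, "structural")
    pooled
  }
  structure(
    list(
      patients = pool_one("patients"),
      visits = pool_one("visits"),
      episodes = pool_one("episodes")
    ),
    class = c("cf_cdm", "list")
  )
}

#' Attach cluster identifiers to a pooled CDM set
#'
#' Joins the linkage result onto the pooled tables by `record_id`, adding a
#' `cluster_id` column (the person identifier used by all downstream
#' cohort-building steps) and dropping the raw identifier column from the
#' patients table.
#'
#' @param cdm a `cf_cdm` (pooled or single-study).
#' @param linkage a `cf_linkage` over the same records.
#' @return the `cf_cdm` with `cluster_id` on every table and `nhs_number`
#'   removed.
#' @export
attach_clusters <- function(cdm, linkage) {
  stopifnot(inherits(cdm, "cf_cdm"), inherits(linkage, "cf_linkage"))
  lut <- linkage$records[, c("record_id", "cluster_id")]
  add <- function(tbl) {
    tbl$cluster_id <- lut$cluster_id[match(tbl$record_id, lut$record_id)]
    if (any(is.na(tbl$cluster_id))) {
      abort("records present in CDM but absent from linkage",
        class = "cohortforge_schema_error"
      )
    }
    tbl
  }
  cdm$patients <- add(cdm$patients)
  cdm$patients$nhs_number <- NULL
  cdm$visits <- add(cdm$visits)
  cdm$episodes <- add(cdm$episodes)
  cdm
}
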