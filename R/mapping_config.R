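#' Load and validate a study-dialect mapping configuration
#'
#' The mapping configuration defines, for each contributing study, the column
#' names of its extract dialect, the value maps that collapse its codings to
#' the common data model (CDM), and the variable-availability matrix (which
#' CDM variables each study structurally never collected). The package ships
#' a default configuration under `inst/extdata/mapping.yaml`; users may copy
#' and edit it, e.g. to add a study or extend a value map.
#'
#' @param path path to a YAML mapping file; default: the shipped configuration.
#' @return a validated mapping configuration (a named list with classes
#'   `cf_mapping_config`), with elements `availability`, `drug_classes`
#'   and `studies`.
#' @export
load_mapping_config <- function(path = default_mapping_path()) {
  if (!file.exists(path)) {
    abort(paste0("mapping config not found: ", path),
      class = "cohortforge_config_error"
    )
  }
  cfg <- yaml::read_yaml(path)
  validate_mapping_config(cfg)
}

default_mapping_path <- function() {
  system.file("extdata", "mapping.yaml", package = "cohortforge", mustWork = TRUE)
}

# CDM variables the availability matrix speaks about, grouped by table.
cdm_variable_registry <- function() {
  list(
    records = c(
      "local_patient_id", "nhs_number", "entry_date", "date_of_birth",
      "gender", "ethnicity", "ilar_subtype", "date_of_diagnosis",
      "date_of_symptom_onset", "ana", "rf", "hla_b27", "uveitis_ever"
    ),
    visits = c("visit_date", COV_VARS, "height_cm", "weight_kg"),
    episodes = c("drug", "start_date", "stop_date", "route", "dose", "stop_reason")
  )
}

validate_mapping_config <- function(cfg) {
  for (nm in c("availability", "drug_classes", "studies")) {
    if (is.null(cfg[[nm]])) {
      abort(paste0("mapping config is missing `", nm, "`"),
        class = "cohortforge_config_error"
      )
    }
  }
  reg <- cdm_variable_registry()
  all_vars <- unlist(reg, use.names = FALSE)
  unav <- cfg$availability$unavailable
  for (study in names(cfg$studies)) {
    sc <- cfg$studies[[study]]
    bad <- setdiff(unlist(lapply(sc$columns, names)), all_vars)
    if (length(bad) > 0) {
      abort(paste0(
        "study ", study, " maps unknown CDM variables: ",
        paste(bad, collapse = ", ")
      ), class = "cohortforge_config_error")
    }
    # structural absence must be consistent: an unavailable variable has no
    # column mapping, an available one (other than plumbing) does
    mapped <- unlist(lapply(sc$columns, names))
    clash <- intersect(unav[[study]], mapped)
    if (length(clash) > 0) {
      abort(paste0(
        "study ", study, " maps variables declared unavailable: ",
        paste(clash, collapse = ", ")
      ), class = "cohortforge_config_error")
    }
  }
  structure(cfg, class = c("cf_mapping_config", "list"))
}

#' Query the variable-availability matrix
#'
#' Returns whether a study collected a CDM variable at all. A variable that
#' is `"unavailable"` is *structurally* missing: it is absent from that
#' study's extract dialect and is missing for 100% of that study's mapped
#' records.
#'
#' @param study one of the configured study names.
#' @param variable a CDM variable name.
#' @param config a mapping configuration (default: the shipped one).
#' @return `"available"` or `"unavailable"`.
#' @examples
#' availability("CHARMS", "pain_vas")
#' availability("CAPS", "date_of_symptom_onset")
#' @export
availability <- function(study, variable, config = load_mapping_config()) {
  if (!study %in% names(config$studies)) {
    abort(paste0("unknown study: ", study), class = "cohortforge_key_error")
  }
  all_vars <- unlist(cdm_variable_registry(), use.names = FALSE)
  if (!variable %in% all_vars) {
    abort(paste0("unknown CDM variable: ", variable),
      class = "cohortforge_key_error"
    )
  }
  unav <- config$availability$unavailable[[study]]
  if (variable %in% unav) "unavailable" else "available"
}

#' The full availability matrix as a tibble
#'
#' @param config a mapping configuration.
#' @return a tibble with columns `variable` and one logical column per study
#'   (`TRUE` = collected).
#' @export
availability_matrix <- function(config = load_mapping_config()) {
  vars <- unlist(cdm_variable_registry(), use.names = FALSE)
  studies <- names(config$studies)
  out <- tibble::tibble(variable = vars)
  for (s in studies) {
    out[[s]] <- !vars %in% config$availability$unavailable[[s]]
  }
  out
}

# drug name -> class lookup ("MTX", "TNFi", "other-biologic")
drug_class_of <- function(drug, config) {
  map <- config$drug_classes
  lut <- setNames(
    rep(names(map), lengths(map)),
    unlist(map, use.names = FALSE)
  )
  unname(lut[as.character(drug)])
}
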