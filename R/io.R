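#' Read one study extract CSV
#'
#' Reads a dialect CSV (UTF-8, comma-delimited, header row, empty string =
#' missing), types the dialect's date columns as ISO-8601, and quarantines
#' rows with unparseable dates in an error sidecar rather than dropping them
#' silently. A missing mandatory column (the record ID or the dialect's
#' identifier column, when expected) is a schema error naming it.
#'
#' @param path CSV path.
#' @param study study name (selects the dialect).
#' @param table `"main"` (visit-level rows carrying patient columns) or
#'   `"episodes"`.
#' @param mapping mapping configuration.
#' @return list with `records` (clean rows, dates parsed) and `sidecar`
#'   (quarantined rows with a `parse_error` column).
#' @export
read_study_csv <- function(path, study, table = c("main", "episodes"),
                           mapping = load_mapping_config()) {
  table <- match.arg(table)
  sc <- mapping$studies[[study]]
  if (is.null(sc)) {
    abort(paste0("unregistered dialect: ", study),
      class = "cohortforge_config_error"
    )
  }
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cohortforge_config_error")
  }
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = c(""), progress = FALSE
  )
  mandatory <- "record_id"
  if (table == "main") mandatory <- c(mandatory, sc$identifier_column)
  absent <- setdiff(mandatory, names(raw))
  if (length(absent) > 0) {
    abort(paste0(
      "study ", study, " ", table, " extract is missing mandatory column(s): ",
      paste(absent, collapse = ", ")
    ), class = "cohortforge_schema_error")
  }

  date_vars <- c(
    "entry_date", "date_of_birth", "date_of_diagnosis",
    "date_of_symptom_onset", "visit_date", "start_date", "stop_date"
  )
  colmaps <- if (table == "main") {
    c(sc$columns$records, sc$columns$visits)
  } else {
    sc$columns$episodes
  }
  date_cols <- unlist(colmaps[intersect(names(colmaps), date_vars)],
    use.names = FALSE
  )
  bad <- rep(FALSE, nrow(raw))
  reason <- rep(NA_character_, nrow(raw))
  for (col in intersect(date_cols, names(raw))) {
    x <- raw[[col]]
    parsed <- as.Date(x, format = "%Y-%m-%d")
    broke <- !is.na(x) & is.na(parsed)
    reason[broke & !bad] <- paste0("unparseable date in `", col, "`")
    bad <- bad | broke
    raw[[col]] <- dplyr::if_else(broke, x, as.character(parsed))
  }
  sidecar <- raw[bad, , drop = FALSE]
  if (nrow(sidecar) > 0) sidecar$parse_error <- reason[bad]
  records <- raw[!bad, , drop = FALSE]
  for (col in intersect(date_cols, names(records))) {
    records[[col]] <- as.Date(records[[col]])
  }
  list(records = records, sidecar = sidecar)
}

#' Write the generated extracts, planted truth and config echo to disk
#'
#' One main CSV and one treatment-episode CSV per study (UTF-8, comma
#' delimiter, header row, ISO-8601 dates, empty string = missing), the
#' planted truth as JSON, and the generator configuration echoed as YAML.
#'
#' @param cohort a `cf_cohort` from [generate_cohort()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a character vector of the files written.
#' @export
write_extracts <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "cf_cohort"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in names(cohort$extracts)) {
    fm <- file.path(outdir, paste0(s, ".csv"))
    fe <- file.path(outdir, paste0(s, "_episodes.csv"))
    readr::write_csv(cohort$extracts[[s]]$main, fm, na = "", progress = FALSE)
    readr::write_csv(cohort$extracts[[s]]$episodes, fe, na = "", progress = FALSE)
    files <- c(files, fm, fe)
  }
  ft <- file.path(outdir, "planted_truth.json")
  truth <- lapply(cohort$truth, function(tbl) {
    tbl <- as.data.frame(tbl)
    for (col in names(tbl)) {
      if (inherits(tbl[[col]], "Date")) tbl[[col]] <- as.character(tbl[[col]])
    }
    tbl
  })
  jsonlite::write_json(truth, ft, dataframe = "columns", na = "null",
    auto_unbox = FALSE)
  fc <- file.path(outdir, "generator_config.yaml")
  cfg <- cohort$config
  yaml::write_yaml(unclass(cfg), fc)
  invisible(c(files, ft, fc))
}

#' Create or load a run configuration
#'
#' Bundles everything one pipeline run needs: the output directory, the salt
#' file, the mapping configuration, the generator configuration, study
#' precedence, window constants and the master seed. All referenced paths
#' are checked at validation time, before any stage runs.
#'
#' @param outdir output directory for all pipeline artefacts.
#' @param salt_file path to the salt file (must exist; see [write_salt()]).
#' @param generator a `cf_generator_config`.
#' @param mapping_path path to the mapping YAML.
#' @param precedence study precedence, highest first.
#' @param windows window constants, see [default_windows()].
#' @param seed master seed; overrides the generator config's seed so one
#'   integer reproduces the whole run.
#' @param log_level `"info"` or `"quiet"`.
#' @return a validated `cf_run_config`.
#' @export
run_config <- function(outdir, salt_file,
                       generator = paper_calibrated_config(),
                       mapping_path = default_mapping_path(),
                       precedence = default_precedence(),
                       windows = default_windows(),
                       seed = generator$seed,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (!file.exists(salt_file)) {
    abort(paste0("salt file does not exist: ", salt_file),
      class = "cohortforge_config_error"
    )
  }
  if (!file.exists(mapping_path)) {
    abort(paste0("mapping config does not exist: ", mapping_path),
      class = "cohortforge_config_error"
    )
  }
  for (w in list(windows$t1, windows$t2)) {
    if (length(w) != 2 || w[1] > w[2]) {
      abort("windows must be well-ordered (lower <= upper)",
        class = "cohortforge_config_error"
      )
    }
  }
  generator$seed <- as.integer(seed)
  structure(
    list(
      outdir = outdir, salt_file = salt_file, generator = generator,
      mapping_path = mapping_path, precedence = precedence,
      windows = windows, seed = as.integer(seed), log_level = log_level
    ),
    class = c("cf_run_config", "list")
  )
}

#' Write a salt file
#'
#' @param path destination path.
#' @param salt character scalar; by default 32 random bytes, hex-encoded.
#' @return the path, invisibly.
#' @export
write_salt <- function(path, salt = NULL) {
  if (is.null(salt)) {
    salt <- paste(as.character(openssl::rand_bytes(32)), collapse = "")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(salt, path)
  invisible(path)
}

cf_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(...))
}

#' Run the full harmonisation pipeline
#'
#' Chains generate, pseudonymise/link, harmonise, cohort building and
#' reporting, writing every artefact under `config$outdir` and a manifest
#' (file MD5 hashes, row counts, seed, config echo) that makes reruns
#' byte-comparable. Any stage failure writes a `FAILED` marker next to the
#' partial outputs and returns a non-zero status.
#'
#' @param config a `cf_run_config`.
#' @return (invisibly) list with `status` (0 = success), `manifest`, and on
#'   success the in-memory `linkage`, `summary`, `cohorts` and reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cf_run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, files = list())
  written <- function(path, rows) {
    manifest$files[[basename(path)]] <<- list(
      md5 = paste(as.character(openssl::md5(file(path))), collapse = ""),
      rows = rows
    )
  }
  result <- tryCatch({
    mapping <- load_mapping_config(config$mapping_path)
    salt <- read_salt(config$salt_file)

    # -- generate ----------------------------------------------------------
    cohort <- generate_cohort(config$generator, mapping = mapping)
    exdir <- file.path(outdir, "extracts")
    files <- write_extracts(cohort, exdir)
    for (f in files) {
      nr <- if (grepl("\\.csv$", f)) nrow(readr::read_csv(
        f, col_types = readr::cols(.default = readr::col_character()),
        progress = FALSE
      )) else NA_integer_
      written(f, nr)
    }
    cf_log(config, "generate: %d persons, %d records",
      nrow(cohort$truth$persons), nrow(cohort$truth$records))

    # -- read back + link --------------------------------------------------
    reads <- lapply(STUDIES, function(s) {
      main <- read_study_csv(file.path(exdir, paste0(s, ".csv")), s, "main",
        mapping)
      eps <- read_study_csv(file.path(exdir, paste0(s, "_episodes.csv")), s,
        "episodes", mapping)
      if (nrow(main$sidecar) > 0 || nrow(eps$sidecar) > 0) {
        side <- file.path(outdir, paste0(s, "_sidecar.csv"))
        readr::write_csv(dplyr::bind_rows(main$sidecar, eps$sidecar), side,
          na = "", progress = FALSE)
        written(side, nrow(main$sidecar) + nrow(eps$sidecar))
      }
      list(main = main$records, episodes = eps$records)
    })
    names(reads) <- STUDIES

    link_input <- dplyr::bind_rows(lapply(STUDIES, function(s) {
      sc <- mapping$studies[[s]]
      m <- reads[[s]]$main
      tibble::tibble(
        study = s,
        record_id = m$record_id,
        local_patient_id = m[[sc$columns$records$local_patient_id]],
        identifier = m[[sc$identifier_column]]
      ) |> dplyr::distinct(.data$record_id, .keep_all = TRUE)
    }))
    linkage <- assign_cluster_ids(link_input, salt)
    dup <- summarise_duplication(linkage)
    fsum <- file.path(outdir, "duplication_summary.json")
    jsonlite::write_json(
      list(
        n_records = dup$n_records, n_individuals = dup$n_individuals,
        n_duplicate_records = dup$n_duplicate_records,
        n_duplicate_individuals = dup$n_duplicate_individuals,
        pct_duplicate_records = dup$pct_duplicate_records,
        multiplicity_by_study_count = as.list(dup$multiplicity_by_study_count)
      ),
      fsum, auto_unbox = TRUE
    )
    written(fsum, NA_integer_)
    fcl <- file.path(outdir, "record_clusters.csv")
    readr::write_csv(
      dplyr::select(linkage$records, "study", "record_id", "local_patient_id",
        "cluster_id", "linkable"),
      fcl, na = "", progress = FALSE
    )
    written(fcl, nrow(linkage$records))
    cf_log(config,
      "link: %d records -> %d clusters (%d duplicate records, %.1f%%)",
      dup$n_records, dup$n_individuals, dup$n_duplicate_records,
      dup$pct_duplicate_records)

    # -- harmonise ---------------------------------------------------------
    cdm_sets <- lapply(STUDIES, function(s) map_to_cdm(reads[[s]], s, mapping))
    pooled <- pool_records(cdm_sets)
    pooled <- attach_clusters(pooled, linkage)
    for (tbl_name in c("patients", "visits", "episodes")) {
      f <- file.path(outdir, paste0("cdm_", tbl_name, ".csv"))
      readr::write_csv(pooled[[tbl_name]], f, na = "", progress = FALSE)
      written(f, nrow(pooled[[tbl_name]]))
    }
    cf_log(config, "harmonise: pooled %d records, %d visits, %d episode rows",
      nrow(pooled$patients), nrow(pooled$visits), nrow(pooled$episodes))

    # -- cohorts -----------------------------------------------------------
    cohorts <- lapply(c("MTX", "TNFi"), function(dc) {
      build_cohort(pooled, dc, mapping, config$precedence, config$windows)
    })
    names(cohorts) <- c("MTX", "TNFi")
    for (dc in names(cohorts)) {
      f <- file.path(outdir, paste0(tolower(dc), "_cohort.csv"))
      readr::write_csv(cohorts[[dc]]$rows, f, na = "", progress = FALSE)
      written(f, nrow(cohorts[[dc]]$rows))
      fl <- file.path(outdir, paste0(tolower(dc), "_exclusions.json"))
      jsonlite::write_json(
        c(cohorts[[dc]]$ledger,
          list(exclusion_reasons = table(
            cohorts[[dc]]$exclusions$exclusion_reasons[
              !cohorts[[dc]]$exclusions$eligible]
          ) |> as.list())),
        fl, auto_unbox = TRUE
      )
      written(fl, NA_integer_)
      cf_log(config, "cohort %s: %d rows, %d duplicates removed, %d excluded",
        dc, cohorts[[dc]]$ledger$retained_rows,
        cohorts[[dc]]$ledger$removed_duplicates,
        cohorts[[dc]]$ledger$excluded_persons)
    }

    # -- reports -----------------------------------------------------------
    reports <- lapply(cohorts, missingness_report, mapping = mapping)
    for (dc in names(reports)) {
      f <- file.path(outdir, paste0(tolower(dc), "_missingness.csv"))
      readr::write_csv(reports[[dc]], f, na = "", progress = FALSE)
      written(f, nrow(reports[[dc]]))
      ch <- characteristics_table(cohorts[[dc]])
      f2 <- file.path(outdir, paste0(tolower(dc), "_characteristics.csv"))
      readr::write_csv(ch, f2, na = "", progress = FALSE)
      written(f2, nrow(ch))
    }

    fman <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, fman, auto_unbox = TRUE)
    list(
      status = 0L, manifest = manifest, linkage = linkage, summary = dup,
      cdm = pooled, cohorts = cohorts, reports = reports
    )
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(outdir, "FAILED"))
    list(status = 1L, manifest = manifest, error = conditionMessage(e))
  })
  invisible(result)
}
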