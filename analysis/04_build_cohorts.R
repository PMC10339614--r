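#!/usr/bin/env Rscript
# Stage 4 — build the MTX and TNFi starter cohorts.
#
# For each drug class: identify each record's index course, resolve
# duplicate person-level records by the study precedence hierarchy
# (CHARMS > BSPAR-Et > BCRD > CAPS), apply the shared inclusion criteria
# (ILAR-classified JIA, treatment-naive, continued >= 3 months, at least one
# core outcome variable at baseline), and extract baseline and 6-month
# visits. The conservation ledger is checked exactly: every candidate record
# is either retained, removed as a duplicate, or excluded with a coded
# reason.

suppressPackageStartupMessages(library(cohortforge))
suppressPackageStartupMessages(library(dplyr))

outdir <- "results/pipeline"
exdir <- file.path(outdir, "extracts")
mapping <- load_mapping_config()
salt <- read_salt(file.path(outdir, "salt.txt"))

reads <- lapply(names(mapping$studies), function(s) {
  list(
    main = read_study_csv(file.path(exdir, paste0(s, ".csv")), s, "main",
      mapping)$records,
    episodes = read_study_csv(file.path(exdir, paste0(s, "_episodes.csv")),
      s, "episodes", mapping)$records
  )
})
names(reads) <- names(mapping$studies)
link_input <- bind_rows(lapply(names(reads), function(s) {
  sc <- mapping$studies[[s]]
  m <- reads[[s]]$main
  tibble::tibble(
    study = s, record_id = m$record_id,
    local_patient_id = m[[sc$columns$records$local_patient_id]],
    identifier = m[[sc$identifier_column]]
  ) |> distinct(record_id, .keep_all = TRUE)
}))
linkage <- assign_cluster_ids(link_input, salt)
cdms <- lapply(names(reads), function(s) map_to_cdm(reads[[s]], s, mapping))
pooled <- attach_clusters(pool_records(cdms), linkage)

for (dc in c("MTX", "TNFi")) {
  ch <- build_cohort(pooled, dc, mapping)
  print(ch)
  l <- ch$ledger
  stopifnot(
    l$candidate_records == l$retained_rows + l$excluded_persons + l$removed_duplicates,
    anyDuplicated(ch$rows$cluster_id) == 0
  )
  reasons <- ch$exclusions |>
    filter(!eligible) |>
    count(exclusion_reasons, sort = TRUE)
  cat("Exclusion reasons:\n")
  print(reasons, n = Inf)
  readr::write_csv(ch$rows, file.path(outdir, paste0(tolower(dc), "_cohort.csv")),
    na = "")
  jsonlite::write_json(
    c(l, list(exclusion_reasons = setNames(
      as.list(reasons$n), reasons$exclusion_reasons
    ))),
    file.path(outdir, paste0(tolower(dc), "_exclusions.json")),
    auto_unbox = TRUE
  )
}

mtx <- readr::read_csv(file.path(outdir, "mtx_cohort.csv"), show_col_types = FALSE)
tnfi <- readr::read_csv(file.path(outdir, "tnfi_cohort.csv"), show_col_types = FALSE)
both <- intersect(mtx$cluster_id, tnfi$cluster_id)
cat(sprintf(
  "%d children appear in both cohorts, having started both treatments at different, consecutive timepoints.\n",
  length(both)
))
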