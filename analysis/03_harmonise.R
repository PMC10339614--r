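#!/usr/bin/env Rscript
# Stage 3 — map the study dialects into the common data model and pool.
#
# Each dialect is renamed, decoded (granular codes collapsed to the most
# inclusive shared definition) and typed; variables a study never collected
# are materialised as structurally missing. The four CDM sets are pooled
# with provenance and the linkage clusters attached, and the pooled tables
# written as CSV. A small structural-missingness audit confirms that every
# (study, variable) marked unavailable is 100% missing after mapping.

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

cat(sprintf(
  "Pooled CDM: %d records, %d visits, %d episode rows from %d studies.\n",
  nrow(pooled$patients), nrow(pooled$visits), nrow(pooled$episodes),
  length(reads)
))

# structural-missingness audit
audit <- bind_rows(lapply(names(mapping$studies), function(s) {
  vars <- mapping$availability$unavailable[[s]]
  bind_rows(lapply(vars, function(v) {
    vals <- c(
      pooled$patients[[v]][pooled$patients$source_study == s],
      pooled$visits[[v]][pooled$visits$source_study == s],
      pooled$episodes[[v]][pooled$episodes$source_study == s]
    )
    tibble::tibble(study = s, variable = v, pct_missing = 100 * mean(is.na(vals)))
  }))
}))
print(audit, n = Inf)
stopifnot(all(audit$pct_missing == 100))
cat("Structural-missingness audit passed: unavailable variables are 100% missing.\n")

for (tbl in c("patients", "visits", "episodes")) {
  readr::write_csv(pooled[[tbl]], file.path(outdir, paste0("cdm_", tbl, ".csv")),
    na = "")
}
cat(sprintf("Wrote pooled CDM tables under %s\n", outdir))
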