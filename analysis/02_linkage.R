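#!/usr/bin/env Rscript
# Stage 2 — pseudonymised deterministic linkage.
#
# Reads the four study extracts back from disk, validates each record's
# NHS-style identifier, computes salted SHA-256 digests, groups records into
# person clusters, and summarises the duplication structure (how many
# children contributed records to more than one study, and how many records
# that duplication represents).

suppressPackageStartupMessages(library(cohortforge))
suppressPackageStartupMessages(library(dplyr))

outdir <- "results/pipeline"
exdir <- file.path(outdir, "extracts")
mapping <- load_mapping_config()
salt <- read_salt(file.path(outdir, "salt.txt"))

link_input <- bind_rows(lapply(names(mapping$studies), function(s) {
  sc <- mapping$studies[[s]]
  main <- read_study_csv(file.path(exdir, paste0(s, ".csv")), s, "main",
    mapping)$records
  tibble::tibble(
    study = s, record_id = main$record_id,
    local_patient_id = main[[sc$columns$records$local_patient_id]],
    identifier = main[[sc$identifier_column]]
  ) |> distinct(record_id, .keep_all = TRUE)
}))

linkage <- assign_cluster_ids(link_input, salt)
dup <- summarise_duplication(linkage)
print(dup)

readr::write_csv(
  select(linkage$records, study, record_id, local_patient_id, cluster_id,
    linkable),
  file.path(outdir, "record_clusters.csv")
)
jsonlite::write_json(
  list(
    n_records = dup$n_records, n_individuals = dup$n_individuals,
    n_duplicate_records = dup$n_duplicate_records,
    n_duplicate_individuals = dup$n_duplicate_individuals,
    pct_duplicate_records = dup$pct_duplicate_records,
    multiplicity_by_study_count = as.list(dup$multiplicity_by_study_count)
  ),
  file.path(outdir, "duplication_summary.json"),
  auto_unbox = TRUE
)
cat(sprintf(
  "Of %d records (%d individuals), %d records (%.1f%%, %d individuals) represent the same child in more than one place.\n",
  dup$n_records, dup$n_individuals, dup$n_duplicate_records,
  dup$pct_duplicate_records, dup$n_duplicate_individuals
))
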