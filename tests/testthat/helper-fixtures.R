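# Shared fixtures: everything is generated in code at test time.

# A small four-study cohort with known overlap structure.
small_config <- function(seed = 7, corruption = 0, missing_id = 0,
                         n = 60,
                         membership = c(
                           singleton = 40, multi_within = 5, two_study = 10,
                           three_study = 4, four_study = 1
                         ),
                         extras = 3) {
  generator_config(
    mode = "exact_count", n_individuals = n, membership = membership,
    extra_duplicate_records = extras,
    identifier_corruption_rate = corruption,
    identifier_missing_rate = missing_id,
    seed = seed
  )
}

# linkage input (one row per record) from planted truth
truth_link_input <- function(cohort) {
  cohort$truth$records[, c("study", "record_id", "local_patient_id", "identifier")]
}

# generate -> map -> pool -> link -> attach, all in memory
make_linked_cdm <- function(config, salt = "fixture-salt",
                            mapping = load_mapping_config()) {
  cohort <- generate_cohort(config, mapping = mapping)
  linkage <- assign_cluster_ids(truth_link_input(cohort), salt)
  cdms <- lapply(
    names(cohort$extracts),
    function(s) map_to_cdm(cohort$extracts[[s]], s, mapping)
  )
  pooled <- attach_clusters(pool_records(cdms), linkage)
  list(cohort = cohort, linkage = linkage, cdm = pooled)
}

# Independent modulus-11 oracle, deliberately written differently from the
# package implementation (digit loop, no vectorisation).
oracle_valid_nhs <- function(x) {
  x <- gsub("[ -]", "", x)
  if (!grepl("^[0-9]{10}$", x)) return(FALSE)
  d <- as.integer(strsplit(x, "")[[1]])
  s <- 0L
  for (i in 1:9) s <- s + d[i] * (11L - i)
  r <- s %% 11L
  chk <- 11L - r
  if (chk == 11L) chk <- 0L
  if (chk == 10L) return(FALSE)
  d[10] == chk
}

# expected duplicate removals per drug class from planted truth: every
# record carries the person's episode history, so a person with k records
# and at least one episode of the class contributes k - 1 removals
expected_removals <- function(cohort, drug_class,
                              mapping = load_mapping_config()) {
  eps <- cohort$truth$episodes
  eps$drug_class <- cohortforge:::drug_class_of(eps$drug, mapping)
  with_class <- unique(eps$person_id[eps$drug_class == drug_class])
  counts <- table(cohort$truth$records$person_id)
  sum(counts[as.character(with_class)] - 1L)
}

# Large fixture shared by the sampling-bound tests: 2000 singleton persons,
# 30% injected ESR missingness, no treatment switching / early stopping /
# prior exposure so nearly everyone reaches the cohort. Built once per run.
.fixture_cache <- new.env(parent = emptyenv())
big_fixture_cohort <- function() {
  if (!is.null(.fixture_cache$big)) return(.fixture_cache$big)
  ts <- default_treatment_spec()
  ts$p_tnfi <- 0
  ts$p_stop <- 0
  ts$p_prior_same_class <- 0
  cfg <- generator_config(
    mode = "exact_count", n_individuals = 2000,
    membership = c(singleton = 2000, multi_within = 0, two_study = 0,
                   three_study = 0, four_study = 0),
    extra_duplicate_records = 0,
    missingness_rates = list(esr = 0.30),
    treatment_spec = ts,
    seed = 103
  )
  lc <- make_linked_cdm(cfg)
  .fixture_cache$big <- build_cohort(lc$cdm, "MTX")
  .fixture_cache$big
}

# a bare cohort-dataset object for report-level tests
manual_cohort <- function(rows, drug_class = "MTX") {
  structure(
    list(
      drug_class = drug_class, rows = rows, removed = tibble::tibble(),
      removed_duplicates = 0L, exclusions = tibble::tibble(),
      ledger = list(
        candidate_records = nrow(rows), candidate_persons = nrow(rows),
        retained_rows = nrow(rows), removed_duplicates = 0L,
        excluded_persons = 0L
      )
    ),
    class = c("cf_cohort_dataset", "list")
  )
}
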