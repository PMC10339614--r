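# Window selection, duplicate resolution hierarchy, inclusion criteria,
# cohort building.

visits_at <- function(days, start = as.Date("2015-06-01")) {
  n <- length(days)
  tibble::tibble(
    record_id = "R1", visit_date = start + days,
    ajc = rep(1, n), ljc = rep(1, n), chaq = rep(1, n), esr = rep(10, n),
    crp = rep(5, n), pga = rep(2, n), pge = rep(2, n), pain_vas = rep(2, n)
  )
}

test_that("T2 selects the in-window visit closest to 6 months", {
  start <- as.Date("2015-06-01")
  # |200-183| = 17 beats |100-183| = 83
  tp <- select_visit(visits_at(c(100, 200)), start, "T2")
  expect_identical(tp$days_from_start, 200L)
  # a lone +400-day visit is outside the 91..365 window
  tp2 <- select_visit(visits_at(400), start, "T2")
  expect_null(tp2$selected_visit)
  expect_true(is.na(tp2$days_from_start))
  # equidistant +170/+196 (both 13 days from target): earlier visit wins
  tp3 <- select_visit(visits_at(c(170, 196)), start, "T2")
  expect_identical(tp3$days_from_start, 170L)
  # window boundaries are inclusive
  expect_identical(select_visit(visits_at(91), start, "T2")$days_from_start, 91L)
  expect_identical(select_visit(visits_at(365), start, "T2")$days_from_start, 365L)
})

test_that("T1 selects the latest visit in the 3 months before drug start", {
  start <- as.Date("2015-06-01")
  tp <- select_visit(visits_at(c(-80, -10, -2)), start, "T1")
  expect_identical(tp$days_from_start, -2L)
  # visits after start or more than 91 days before are out of window
  expect_null(select_visit(visits_at(c(-120, 5)), start, "T1")$selected_visit)
  expect_identical(select_visit(visits_at(0), start, "T1")$days_from_start, 0L)
  expect_identical(select_visit(visits_at(-91), start, "T1")$days_from_start, -91L)
  # empty visit list
  expect_null(select_visit(visits_at(numeric(0)), start, "T1")$selected_visit)
})

test_that("selected visits are always in-window and distance-minimal", {
  set.seed(61)
  win <- default_windows()
  for (i in 1:1000) {
    k <- sample(0:6, 1)
    days <- sort(sample(-200:500, k))
    start <- as.Date("2014-01-01") + sample(0:1000, 1)
    for (tp_name in c("T1", "T2")) {
      tp <- select_visit(visits_at(days, start), start, tp_name)
      w <- if (tp_name == "T1") win$t1 else win$t2
      inw <- days[days >= w[1] & days <= w[2]]
      if (length(inw) == 0) {
        expect_null(tp$selected_visit)
      } else {
        d <- tp$days_from_start
        expect_true(d >= w[1] && d <= w[2])
        if (tp_name == "T1") {
          expect_equal(d, max(inw))
        } else {
          dist <- abs(inw - win$t2_target)
          expect_equal(abs(d - win$t2_target), min(dist))
          # tie-break: no in-window visit with equal distance is earlier
          expect_equal(d, min(inw[dist == min(dist)]))
        }
      }
    }
  }
})

cand_row <- function(study, record_id = paste0(study, "-R1"), n_miss = 0,
                     start = as.Date("2015-01-01")) {
  tibble::tibble(
    record_id = record_id, source_study = study, n_missing_covs = n_miss,
    start_date = start
  )
}

test_that("duplicate resolution follows the study precedence hierarchy", {
  # CHARMS record kept over CAPS for the same child's course
  r <- resolve_duplicates(dplyr::bind_rows(cand_row("CHARMS"), cand_row("CAPS")))
  expect_identical(r$retained$source_study, "CHARMS")
  expect_identical(r$removed$removal_reason, "duplicate-lower-precedence")
  # CAPS vs BCRD under the default order: BCRD wins
  r2 <- resolve_duplicates(dplyr::bind_rows(cand_row("CAPS"), cand_row("BCRD")))
  expect_identical(r2$retained$source_study, "BCRD")
  # a single record is retained unchanged
  r3 <- resolve_duplicates(cand_row("CAPS"))
  expect_identical(nrow(r3$removed), 0L)
  # same-study tie: fewer missing COVs wins, then earlier start
  r4 <- resolve_duplicates(dplyr::bind_rows(
    cand_row("CAPS", "CAPS-R1", n_miss = 3),
    cand_row("CAPS", "CAPS-R2", n_miss = 1)
  ))
  expect_identical(r4$retained$record_id, "CAPS-R2")
  r5 <- resolve_duplicates(dplyr::bind_rows(
    cand_row("CAPS", "CAPS-R1", start = as.Date("2015-05-01")),
    cand_row("CAPS", "CAPS-R2", start = as.Date("2015-01-01"))
  ))
  expect_identical(r5$retained$record_id, "CAPS-R2")
  # a custom precedence order is honoured
  r6 <- resolve_duplicates(
    dplyr::bind_rows(cand_row("CHARMS"), cand_row("CAPS")),
    precedence = c("CAPS", "CHARMS", "BSPAR-Et", "BCRD")
  )
  expect_identical(r6$retained$source_study, "CAPS")
})

elig_fixture <- function(stop_offset = NA, ilar = "systemic",
                         prior_start = NULL, covs_missing = FALSE) {
  start <- as.Date("2015-06-01")
  idx <- tibble::tibble(
    cluster_id = "CL1", record_id = "R1", drug = "Methotrexate",
    start_date = start,
    stop_date = if (is.na(stop_offset)) as.Date(NA) else start + stop_offset
  )
  episodes <- idx[, c("cluster_id", "drug", "start_date")]
  if (!is.null(prior_start)) {
    episodes <- dplyr::bind_rows(episodes, tibble::tibble(
      cluster_id = "CL1", drug = "Methotrexate", start_date = prior_start
    ))
  }
  sv <- visits_at(-5, start)[1, ]
  if (covs_missing) sv[, COV_VARS] <- NA_real_
  t1 <- structure(
    list(timepoint = "T1", window = c(-91, 0), selected_visit = sv,
         days_from_start = -5L),
    class = c("cf_timepoint", "list")
  )
  patient <- tibble::tibble(cluster_id = "CL1", ilar_subtype = ilar)
  list(patient = patient, episodes = episodes, idx = idx, t1 = t1)
}

test_that("inclusion criteria accumulate all failures without short-circuit", {
  f <- elig_fixture(stop_offset = 60, ilar = NA,
    prior_start = as.Date("2013-01-01"), covs_missing = TRUE)
  r <- apply_inclusion_criteria(f$patient, f$episodes, f$idx, f$t1, "MTX")
  expect_false(r$eligible)
  reasons <- strsplit(r$exclusion_reasons, ",")[[1]]
  expect_setequal(reasons, c(
    "no-JIA-ILAR", "not-treatment-naive", "stopped-before-3-months",
    "no-COV-data"
  ))
})

test_that("each criterion triggers on its own", {
  f <- elig_fixture(stop_offset = 60)
  r <- apply_inclusion_criteria(f$patient, f$episodes, f$idx, f$t1, "MTX")
  expect_identical(r$exclusion_reasons, "stopped-before-3-months")
  # 91 days is the boundary: continued exactly 3 months passes
  f2 <- elig_fixture(stop_offset = 91)
  expect_true(apply_inclusion_criteria(f2$patient, f2$episodes, f2$idx, f2$t1,
    "MTX")$eligible)
  f3 <- elig_fixture(covs_missing = TRUE)
  r3 <- apply_inclusion_criteria(f3$patient, f3$episodes, f3$idx, f3$t1, "MTX")
  expect_identical(r3$exclusion_reasons, "no-COV-data")
  f4 <- elig_fixture(prior_start = as.Date("2013-01-01"))
  r4 <- apply_inclusion_criteria(f4$patient, f4$episodes, f4$idx, f4$t1, "MTX")
  expect_identical(r4$exclusion_reasons, "not-treatment-naive")
  # all-pass: ILAR present, first-ever ongoing course, a COV at baseline
  f5 <- elig_fixture()
  r5 <- apply_inclusion_criteria(f5$patient, f5$episodes, f5$idx, f5$t1, "MTX")
  expect_true(r5$eligible)
  expect_identical(r5$exclusion_reasons, "")
  # no index episode at all
  r6 <- apply_inclusion_criteria(f5$patient, f5$episodes[0, ], NULL, f5$t1, "MTX")
  expect_match(r6$exclusion_reasons, "no-index-episode")
})

test_that("cohort pipeline: uniqueness, conservation, planted removals", {
  lc <- make_linked_cdm(small_config(seed = 67))
  for (dc in c("MTX", "TNFi")) {
    ch <- build_cohort(lc$cdm, dc)
    # person-level uniqueness
    expect_identical(anyDuplicated(ch$rows$cluster_id), 0L)
    # conservation ledger: candidates = retained + removed + excluded
    l <- ch$ledger
    expect_identical(l$candidate_records, l$candidate_persons + l$removed_duplicates)
    expect_identical(l$candidate_persons, l$retained_rows + l$excluded_persons)
    # removed duplicates equal the planted cross-record duplication
    expect_identical(l$removed_duplicates, as.integer(expected_removals(lc$cohort, dc)))
    # precedence soundness: retained study outranks all removed ones per person
    prec <- match(ch$rows$source_study, default_precedence())
    rem <- ch$removed
    if (nrow(rem) > 0) {
      worst <- tapply(match(rem$source_study, default_precedence()),
        rem$cluster_id, min)
      shared <- intersect(names(worst), ch$rows$cluster_id)
      expect_true(all(
        prec[match(shared, ch$rows$cluster_id)] <= worst[shared]
      ))
    }
  }
})

test_that("a person starting MTX then TNFi appears in both cohorts", {
  lc <- make_linked_cdm(small_config(seed = 71, n = 80,
    membership = c(singleton = 60, multi_within = 5, two_study = 10,
                   three_study = 4, four_study = 1)))
  mtx <- build_cohort(lc$cdm, "MTX")
  tnfi <- build_cohort(lc$cdm, "TNFi")
  both <- intersect(mtx$rows$cluster_id, tnfi$rows$cluster_id)
  expect_gt(length(both), 0)
  # and their start dates are consecutive: TNFi after MTX
  m <- mtx$rows[match(both, mtx$rows$cluster_id), "start_date", drop = TRUE]
  t <- tnfi$rows[match(both, tnfi$rows$cluster_id), "start_date", drop = TRUE]
  expect_true(all(t > m))
})

test_that("widening the T2 window never shrinks a cohort", {
  lc <- make_linked_cdm(small_config(seed = 73))
  win_narrow <- default_windows()
  win_narrow$t2 <- c(122, 244) # the 4-8 month variant
  win_wide <- default_windows()
  n_narrow <- nrow(build_cohort(lc$cdm, "MTX", windows = win_narrow)$rows)
  n_wide <- nrow(build_cohort(lc$cdm, "MTX", windows = win_wide)$rows)
  expect_gte(n_wide, n_narrow)
})

test_that("an empty CDM yields an empty cohort with a zero ledger", {
  lc <- make_linked_cdm(small_config(seed = 79, n = 6,
    membership = c(singleton = 6, multi_within = 0, two_study = 0,
                   three_study = 0, four_study = 0),
    extras = 0))
  empty <- lc$cdm
  empty$episodes <- empty$episodes[0, ]
  ch <- build_cohort(empty, "MTX")
  expect_identical(nrow(ch$rows), 0L)
  expect_identical(ch$removed_duplicates, 0L)
})

test_that("bulk time-point selection agrees with the per-record operation", {
  lc <- make_linked_cdm(small_config(seed = 83))
  mtx <- build_cohort(lc$cdm, "MTX")
  rows <- mtx$rows
  for (i in seq_len(min(nrow(rows), 25))) {
    visits <- lc$cdm$visits[lc$cdm$visits$record_id == rows$record_id[i], ]
    for (tp in c("T1", "T2")) {
      ref <- select_visit(visits, rows$start_date[i], tp)
      col <- paste0(tolower(tp), "_days_from_start")
      if (is.null(ref$selected_visit)) {
        expect_true(is.na(rows[[col]][i]))
      } else {
        expect_identical(rows[[col]][i], ref$days_from_start)
      }
    }
  }
})
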