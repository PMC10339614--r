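# JADAS, ACR Pedi, missingness and characteristics reporting.

test_that("JADAS closed-form cases: floor, mid-range, double truncation", {
  expect_identical(jadas(0, 0, 0, 10, "JADAS-71")$value, 0)
  expect_identical(jadas(3.5, 2.0, 5, 40, "JADAS-71")$value, 12.5)
  # cap (30 -> 10) and ESR clamp ((200-20)/10 -> 10) both active
  j <- jadas(10, 10, 30, 200, "JADAS-10")
  expect_identical(j$value, 40)
  expect_identical(unname(j$components["ajc"]), 10)
  expect_identical(unname(j$components["esr"]), 10)
  # value is always the sum of the four components
  expect_identical(j$value, sum(j$components))
})

test_that("JADAS respects variant caps and bounds", {
  expect_identical(jadas(10, 10, 71, 200, "JADAS-27")$value, 10 + 10 + 27 + 10)
  expect_identical(jadas(10, 10, 71, 200, "JADAS-71")$value, 101)
  expect_identical(jadas(10, 10, 71, 200, "JADAS-10")$value, 40)
  expect_error(jadas(11, 0, 0, 0), class = "cohortforge_range_error")
  expect_error(jadas(0, 0, 80, 0), class = "cohortforge_range_error")
})

test_that("JADAS with missing components is incomputable and names them", {
  j <- jadas(NA, 5, 3, 20)
  expect_true(is.na(j$value))
  expect_identical(j$missing_components, "pga")
  j2 <- jadas(NA, 5, NA, NA)
  expect_setequal(j2$missing_components, c("pga", "ajc", "esr"))
})

test_that("JADAS matches brute-force recomputation on 1000 random inputs", {
  set.seed(91)
  for (i in 1:1000) {
    pga <- round(runif(1, 0, 10), 1)
    pge <- round(runif(1, 0, 10), 1)
    ajc <- sample(0:71, 1)
    esr <- sample(0:250, 1)
    variant <- sample(c("JADAS-10", "JADAS-27", "JADAS-71"), 1)
    cap <- switch(variant, "JADAS-10" = 10, "JADAS-27" = 27, "JADAS-71" = 71)
    # independent oracle: explicit branches instead of min/max algebra
    esr_term <- (esr - 20) / 10
    if (esr_term < 0) esr_term <- 0
    if (esr_term > 10) esr_term <- 10
    ajc_term <- if (ajc > cap) cap else ajc
    want <- pga + pge + ajc_term + esr_term
    expect_equal(jadas(pga, pge, ajc, esr, variant)$value, want)
  }
})

test_that("ACR Pedi handles the canonical response patterns", {
  base <- setNames(rep(10, 6), ACR_CORE)
  # no change: non-responder with zero improved
  r <- acr_pedi(base, base, 30)
  expect_false(r$responder)
  expect_identical(r$n_improved, 0L)
  # uniform 50% improvement: responder at 30 and 50, not at 70
  half <- base * 0.5
  expect_true(acr_pedi(base, half, 30)$responder)
  expect_true(acr_pedi(base, half, 50)$responder)
  expect_false(acr_pedi(base, half, 70)$responder)
  # 3 improved 40%, 2 worsened 40%, 1 unchanged: fails the worsening rule
  fu <- base
  fu[1:3] <- 6
  fu[4:5] <- 14
  r2 <- acr_pedi(base, fu, 30)
  expect_false(r2$responder)
  expect_identical(r2$n_improved, 3L)
  expect_identical(r2$n_worsened, 2L)
})

test_that("zero baselines cannot improve and worsen only if follow-up > 0", {
  base <- setNames(c(0, 10, 10, 10, 10, 10), ACR_CORE)
  fu_flat <- setNames(c(0, 5, 5, 5, 0, 10), ACR_CORE)
  r <- acr_pedi(base, fu_flat, 30)
  expect_true(r$responder) # 0 -> 0 is not worsening; 4 variables improved
  fu_up <- fu_flat
  fu_up[1] <- 2 # 0 -> 2 counts as worsened
  r2 <- acr_pedi(base, fu_up, 30)
  expect_identical(r2$n_worsened, 1L)
  expect_true(r2$responder) # still <= 1 worsened
})

test_that("ACR Pedi with missing core variables is incomputable", {
  base <- setNames(c(NA, 10, 10, 10, 10, 10), ACR_CORE)
  fu <- setNames(rep(5, 6), ACR_CORE)
  r <- acr_pedi(base, fu, 30)
  expect_true(is.na(r$responder))
  expect_identical(r$missing_components, "pga")
})

test_that("ACR Pedi agrees with truth-table evaluation over the change grid", {
  changes <- c(-50, -31, -30, 0, 30, 31, 50)
  grid <- as.matrix(expand.grid(rep(list(changes), 6)))
  base <- setNames(rep(100, 6), ACR_CORE)
  for (level in c(30, 50, 70)) {
    got <- logical(nrow(grid))
    want <- logical(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      fu <- setNames(100 + grid[i, ], ACR_CORE)
      got[i] <- acr_pedi(base, fu, level)$responder
      # independent truth table on the change percentages themselves
      want[i] <- sum(grid[i, ] <= -level) >= 3 && sum(grid[i, ] > 30) <= 1
    }
    expect_identical(got, want)
  }
})

test_that("a CHARMS-only cohort reports pain VAS 100% missing, structural", {
  cfg <- generator_config(
    mode = "exact_count", n_individuals = 40,
    membership = c(singleton = 40, multi_within = 0, two_study = 0,
                   three_study = 0, four_study = 0),
    extra_duplicate_records = 0, seed = 97
  )
  lc <- make_linked_cdm(cfg)
  keep <- lc$cdm$patients$source_study == "CHARMS"
  charms_only <- lc$cdm
  charms_only$patients <- charms_only$patients[keep, ]
  ok_rec <- charms_only$patients$record_id
  charms_only$visits <- charms_only$visits[charms_only$visits$record_id %in% ok_rec, ]
  charms_only$episodes <- charms_only$episodes[charms_only$episodes$record_id %in% ok_rec, ]
  ch <- build_cohort(charms_only, "MTX")
  expect_true(all(ch$rows$source_study == "CHARMS"))
  rep <- missingness_report(ch)
  pv <- rep[rep$variable == "pain_vas" & rep$timepoint == "T1", ]
  expect_identical(pv$pct_missing, 100)
  expect_identical(pv$pct_structural, 100)
})

test_that("a zero-missingness fixture reports 0% everywhere at baseline", {
  cfg <- generator_config(
    mode = "exact_count", n_individuals = 30,
    membership = c(singleton = 30, multi_within = 0, two_study = 0,
                   three_study = 0, four_study = 0),
    extra_duplicate_records = 0,
    missingness_rates = list(), # no random missingness at all
    seed = 101
  )
  lc <- make_linked_cdm(cfg)
  # keep studies without structural COV gaps (CHARMS lacks pain VAS)
  keep <- lc$cdm$patients$source_study != "CHARMS"
  sub <- lc$cdm
  sub$patients <- sub$patients[keep, ]
  sub$visits <- sub$visits[sub$visits$record_id %in% sub$patients$record_id, ]
  sub$episodes <- sub$episodes[sub$episodes$record_id %in% sub$patients$record_id, ]
  ch <- build_cohort(sub, "MTX")
  rep <- missingness_report(ch)
  t1 <- rep[rep$timepoint == "T1", ]
  expect_true(all(t1$pct_missing == 0))
})

test_that("injected missingness is recovered from the report", {
  ch <- big_fixture_cohort()
  expect_gt(nrow(ch$rows), 1200)
  rep <- missingness_report(ch)
  esr_t1 <- rep$pct_missing[rep$variable == "esr" & rep$timepoint == "T1"]
  expect_lt(abs(esr_t1 - 30), 2)
})

test_that("characteristics table counts a hand-built 10-person cohort", {
  rows <- tibble::tibble(
    cluster_id = sprintf("CL%02d", 1:10),
    gender = c(rep("female", 7), rep("male", 3)),
    ethnicity = c(rep("Caucasian", 8), "Non-Caucasian", NA),
    ilar_subtype = c(rep("systemic", 5), rep("psoriatic", 5)),
    uveitis_ever = rep(c("yes", "no"), 5),
    date_of_symptom_onset = as.Date("2010-01-01") + (0:9),
    date_of_diagnosis = as.Date(NA),
    date_of_birth = as.Date("2004-01-01"),
    source_study = "CAPS",
    t1_ajc = c(1:9, NA), t1_ljc = rep(2, 10)
  )
  ct <- characteristics_table(manual_cohort(rows))
  fem <- ct[ct$characteristic == "gender" & ct$level == "female", ]
  expect_identical(fem$n, 7L)
  expect_identical(fem$pct, 70)
  # categorical blocks sum to the cohort N
  for (block in c("gender", "ethnicity", "ilar_subtype", "uveitis")) {
    expect_identical(sum(ct$n[ct$characteristic == block]), 10L)
  }
  ajc <- ct[ct$characteristic == "ajc_baseline", ]
  expect_identical(ajc$mean, 5)
  expect_identical(ajc$n, 9L)
})

test_that("generator-default demographics surface in the characteristics", {
  ct <- characteristics_table(big_fixture_cohort())
  fem <- ct$pct[ct$characteristic == "gender" & ct$level == "female"]
  # generator plants 67.6% female; binomial noise at this n is ~1 point
  expect_lt(abs(fem - 67.6), 3)
  # planted ages are Normal(6.6, 4.3) truncated at zero by redraw, whose
  # expectation is mu + sigma * phi(-mu/sigma) / (1 - Phi(-mu/sigma))
  a <- -6.6 / 4.3
  trunc_mean <- 6.6 + 4.3 * dnorm(a) / (1 - pnorm(a))
  onset <- ct[ct$characteristic == "age_at_onset_years", ]
  expect_lt(abs(onset$mean - trunc_mean), 0.4)
})

test_that("empty cohorts report gracefully", {
  empty <- manual_cohort(tibble::tibble())
  rep <- missingness_report(empty)
  expect_true(all(is.na(rep$pct_missing)))
  expect_true(isTRUE(attr(rep, "empty_cohort")))
  ct <- characteristics_table(empty)
  expect_true(all(ct$n == 0L))
})

test_that("missingness percentages are invariant to row order", {
  ch <- big_fixture_cohort()
  shuffled <- ch
  set.seed(1)
  shuffled$rows <- shuffled$rows[sample.int(nrow(shuffled$rows)), ]
  expect_identical(
    missingness_report(ch)$pct_missing,
    missingness_report(shuffled)$pct_missing
  )
})
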