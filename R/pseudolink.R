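#' Salted one-way digest of a patient identifier
#'
#' Computes an uppercase-hex SHA-256 digest over the canonicalised
#' identifier bytes followed by the salt bytes. Equal (identifier, salt)
#' pairs always give equal digests, so the digest can link records across
#' studies without exposing the identifier; a project-specific salt makes
#' the digests unique to the project. Canonicalisation strips spaces and
#' hyphens only (NHS numbers are conventionally printed in 3-3-4 groups).
#'
#' This is an emulation of the salted-digest pseudonymisation procedure used
#' by identifier-pseudonymisation tools; bit-compatibility with any external
#' tool is not claimed, and the package ships its own test vectors.
#'
#' @param identifier a valid NHS-style number (see [validate_nhs_number()]).
#' @param salt a non-empty character scalar or raw vector.
#' @return a 64-character uppercase hexadecimal string.
#' @examples
#' compute_digest("450 557 7104", "project-salt")
#' @export
compute_digest <- function(identifier, salt) {
  salt_raw <- salt_as_raw(salt)
  canon <- canonicalise_identifier(identifier)
  if (length(canon) != 1L || !validate_nhs_number(canon)) {
    abort("invalid identifier", class = "cohortforge_invalid_identifier")
  }
  digest_raw(charToRaw(canon), salt_raw)
}

salt_as_raw <- function(salt) {
  if (is.raw(salt)) {
    if (length(salt) == 0) {
      abort("salt must be non-empty", class = "cohortforge_config_error")
    }
    return(salt)
  }
  if (!is.character(salt) || length(salt) != 1L || !nzchar(salt)) {
    abort("salt must be non-empty", class = "cohortforge_config_error")
  }
  charToRaw(salt)
}

digest_raw <- function(id_raw, salt_raw) {
  h <- openssl::sha256(c(id_raw, salt_raw))
  toupper(paste(as.character(h), collapse = ""))
}

#' Read a salt file
#'
#' Reads the whole file as bytes, with trailing newline characters stripped
#' so that editor-added final newlines do not change every digest.
#'
#' @param path path to the salt file.
#' @return a raw vector.
#' @export
read_salt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("salt file not found: ", path),
      class = "cohortforge_config_error"
    )
  }
  raw <- readBin(path, "raw", n = file.size(path))
  while (length(raw) > 0 && raw[length(raw)] %in% as.raw(c(0x0a, 0x0d))) {
    raw <- raw[-length(raw)]
  }
  if (length(raw) == 0) {
    abort("salt must be non-empty", class = "cohortforge_config_error")
  }
  raw
}

#' Assign cluster identifiers by digest linkage
#'
#' Records whose identifiers produce equal salted digests are the same
#' person and share a cluster. Records with a missing or invalid identifier
#' are never linked: each forms its own singleton cluster flagged
#' "unlinkable" and is also returned in the rejected list. Cluster IDs are
#' sequential opaque tokens assigned in input order (first appearance), not
#' derived from the digest; the digest-to-cluster map is returned as a
#' separate element so that shareable outputs need not carry digests.
#'
#' @param records a data frame with at least columns `study`, `record_id`
#'   and an identifier column.
#' @param salt salt (character or raw, or a file path via [read_salt()]).
#' @param id_col name of the identifier column.
#' @return an object of class `cf_linkage`: list with
#'   * `records`: the input plus `cluster_id` and `linkable`;
#'   * `clusters`: one row per cluster (`cluster_id`, `n_records`,
#'     `n_studies`, `unlinkable`);
#'   * `rejected`: records with missing/invalid identifiers and the reason;
#'   * `digest_map`: cluster_id to digest, for linkable clusters only.
#' @export
assign_cluster_ids <- function(records, salt, id_col = "identifier") {
  stopifnot(is.data.frame(records))
  for (col in c("study", "record_id")) {
    if (!col %in% names(records)) {
      abort(paste0("records must carry a `", col, "` column"),
        class = "cohortforge_schema_error"
      )
    }
  }
  if (!id_col %in% names(records)) {
    abort(paste0("identifier column not found: ", id_col),
      class = "cohortforge_schema_error"
    )
  }
  salt_raw <- salt_as_raw(salt)

  ids <- canonicalise_identifier(records[[id_col]])
  linkable <- !is.na(records[[id_col]]) & validate_nhs_number(ids)
  digests <- rep(NA_character_, nrow(records))
  if (any(linkable)) {
    uniq <- unique(ids[linkable])
    dg <- vapply(
      uniq, function(x) digest_raw(charToRaw(x), salt_raw), character(1),
      USE.NAMES = FALSE
    )
    digests[linkable] <- dg[match(ids[linkable], uniq)]
  }

  # sequential cluster tokens in input order; unlinkable records are
  # singleton clusters in the same sequence
  key <- ifelse(linkable, digests, paste0("__unlinkable__", seq_len(nrow(records))))
  first <- !duplicated(key)
  uniq_keys <- key[first]
  uniq_tokens <- sprintf("CL%06d", seq_along(uniq_keys))
  cluster_id <- uniq_tokens[match(key, uniq_keys)]

  out <- dplyr::as_tibble(records)
  out$cluster_id <- cluster_id
  out$linkable <- linkable

  clusters <- out |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_studies = dplyr::n_distinct(.data$study),
      unlinkable = !any(.data$linkable),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster_id)

  rejected <- out[!linkable, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(
      is.na(records[[id_col]][!linkable]), "missing identifier",
      "invalid identifier"
    )
  } else {
    rejected$reason <- character(0)
  }

  digest_map <- tibble::tibble(
    cluster_id = cluster_id[first & linkable],
    digest = digests[first & linkable]
  )

  structure(
    list(
      records = out, clusters = clusters,
      rejected = rejected, digest_map = digest_map
    ),
    class = c("cf_linkage", "list")
  )
}

#' Summarise the duplication structure of a linked record set
#'
#' Counts records and individuals (clusters), the records and individuals
#' involved in duplication (clusters with two or more records), and the
#' multiplicity histogram by number of distinct studies: the 1-study entry
#' counts individuals with multiple records within a single study only.
#'
#' @param linkage a `cf_linkage` from [assign_cluster_ids()].
#' @return an object of class `cf_duplication_summary`.
#' @export
summarise_duplication <- function(linkage) {
  stopifnot(inherits(linkage, "cf_linkage"))
  cl <- linkage$clusters
  n_records <- sum(cl$n_records)
  n_individuals <- nrow(cl)
  dup <- cl[cl$n_records >= 2L, , drop = FALSE]
  n_duplicate_records <- sum(dup$n_records)
  n_duplicate_individuals <- nrow(dup)
  pct <- if (n_records == 0) 0 else round(100 * n_duplicate_records / n_records, 1)
  mult <- setNames(integer(4), as.character(1:4))
  if (nrow(dup) > 0) {
    tab <- table(factor(pmin(dup$n_studies, 4L), levels = 1:4))
    mult[] <- as.integer(tab)
  }
  structure(
    list(
      n_records = n_records,
      n_individuals = n_individuals,
      n_duplicate_records = n_duplicate_records,
      n_duplicate_individuals = n_duplicate_individuals,
      pct_duplicate_records = pct,
      multiplicity_by_study_count = mult
    ),
    class = c("cf_duplication_summary", "list")
  )
}

#' @export
print.cf_duplication_summary <- function(x, ...) {
  cat(sprintf(
    "Duplication summary: %d records from %d individuals\n", x$n_records,
    x$n_individuals
  ))
  cat(sprintf(
    "  %d records (%.1f%%) in multi-record clusters, %d individuals\n",
    x$n_duplicate_records, x$pct_duplicate_records, x$n_duplicate_individuals
  ))
  m <- x$multiplicity_by_study_count
  cat(sprintf(
    "  by study count: within 1 study %d | 2 studies %d | 3 studies %d | 4 studies %d\n",
    m[["1"]], m[["2"]], m[["3"]], m[["4"]]
  ))
  invisible(x)
}

#' Reconcile digest clusters against an externally asserted duplicate list
#'
#' Study teams often hold known-duplicate lists built from internal NHS
#' number or genetic comparisons. This cross-check partitions asserted pairs
#' into those the digest linkage confirms (same cluster) and those it missed
#' (different clusters — identifier-error suspects), and reports
#' digest-discovered links absent from the asserted list.
#'
#' @param linkage a `cf_linkage`.
#' @param asserted_pairs data frame with columns `study1`, `id1`, `study2`,
#'   `id2` referencing records by study and local patient ID.
#' @return a list of class `cf_reconciliation` with tibbles `confirmed`,
#'   `missed`, `discovered` and `unresolvable`.
#' @export
reconcile_known_duplicates <- function(linkage, asserted_pairs) {
  stopifnot(inherits(linkage, "cf_linkage"))
  ap <- dplyr::as_tibble(asserted_pairs)
  need <- c("study1", "id1", "study2", "id2")
  if (!all(need %in% names(ap))) {
    abort(paste0(
      "asserted_pairs needs columns: ", paste(need, collapse = ", ")
    ), class = "cohortforge_schema_error")
  }
  recs <- linkage$records
  if (!"local_patient_id" %in% names(recs)) {
    abort("linkage records must carry `local_patient_id`",
      class = "cohortforge_schema_error"
    )
  }
  ref <- paste(recs$study, recs$local_patient_id, sep = "|")
  clusters_of <- function(study, id) {
    unique(recs$cluster_id[ref == paste(study, id, sep = "|")])
  }
  status <- character(nrow(ap))
  for (i in seq_len(nrow(ap))) {
    c1 <- clusters_of(ap$study1[i], ap$id1[i])
    c2 <- clusters_of(ap$study2[i], ap$id2[i])
    status[i] <- if (length(c1) == 0 || length(c2) == 0) {
      "unresolvable"
    } else if (length(intersect(c1, c2)) > 0) {
      "confirmed"
    } else {
      "missed"
    }
  }
  ap$status <- status

  # digest-discovered pairs: distinct (study, local id) member pairs sharing
  # a cluster, not present in the asserted list (either orientation)
  members <- recs |>
    dplyr::distinct(.data$cluster_id, .data$study, .data$local_patient_id) |>
    dplyr::add_count(.data$cluster_id, name = "n_members") |>
    dplyr::filter(.data$n_members >= 2L)
  asserted_keys <- c(
    paste(ap$study1, ap$id1, ap$study2, ap$id2, sep = "|"),
    paste(ap$study2, ap$id2, ap$study1, ap$id1, sep = "|")
  )
  discovered <- members |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::reframe({
      pr <- utils::combn(paste(.data$study, .data$local_patient_id, sep = "|"), 2)
      tibble::tibble(member1 = pr[1, ], member2 = pr[2, ])
    }) |>
    dplyr::mutate(key = paste(.data$member1, .data$member2, sep = "|")) |>
    dplyr::filter(!.data$key %in% asserted_keys) |>
    dplyr::select(-"key")

  structure(
    list(
      confirmed = ap[ap$status == "confirmed", , drop = FALSE],
      missed = ap[ap$status == "missed", , drop = FALSE],
      unresolvable = ap[ap$status == "unresolvable", , drop = FALSE],
      discovered = discovered
    ),
    class = c("cf_reconciliation", "list")
  )
}

#' Replace an identifier column with pseudonymous cluster IDs
#'
#' @param tbl a data frame carrying an identifier column.
#' @param linkage a `cf_linkage` whose digest map defines the cluster IDs.
#' @param salt the same salt used to build `linkage`.
#' @param id_col identifier column name.
#' @return `tbl` with the identifier column removed and `cluster_id` added;
#'   rows whose identifier is missing/invalid get `NA` cluster IDs.
#' @export
pseudonymise_table <- function(tbl, linkage, salt, id_col = "identifier") {
  stopifnot(inherits(linkage, "cf_linkage"))
  if (!id_col %in% names(tbl)) {
    abort(paste0("identifier column not found: ", id_col),
      class = "cohortforge_schema_error"
    )
  }
  salt_raw <- salt_as_raw(salt)
  ids <- canonicalise_identifier(tbl[[id_col]])
  ok <- !is.na(tbl[[id_col]]) & validate_nhs_number(ids)
  dg <- rep(NA_character_, nrow(tbl))
  if (any(ok)) {
    uniq <- unique(ids[ok])
    h <- vapply(uniq, function(x) digest_raw(charToRaw(x), salt_raw),
      character(1), USE.NAMES = FALSE)
    dg[ok] <- h[match(ids[ok], uniq)]
  }
  tbl$cluster_id <- linkage$digest_map$cluster_id[
    match(dg, linkage$digest_map$digest)
  ]
  tbl[[id_col]] <- NULL
  tbl
}
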