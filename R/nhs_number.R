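#' NHS-number check digits and validation
#'
#' UK NHS (and Scottish CHI) numbers are 10-digit identifiers whose final
#' digit is a modulus-11 check digit over the first nine: each of digits 1-9
#' is weighted 10 down to 2, the weighted sum is reduced modulo 11, and the
#' check digit is 11 minus the remainder, with 11 mapped to 0. A remainder of
#' 1 gives a "check digit" of 10, which is not a digit: no valid number has
#' that prefix. This scheme detects every single-digit substitution (11 is
#' prime, so no weight times a non-zero digit change is divisible by 11).
#'
#' `nhs_check_digit()` returns the check digit implied by a 9-digit prefix,
#' or `NA` when the prefix admits no valid check digit.
#' `validate_nhs_number()` accepts any character input; spaces and hyphens
#' are stripped (NHS numbers are conventionally printed in 3-3-4 groups)
#' before the length and check-digit rules are applied.
#'
#' @param prefix9 a string of exactly 9 digits.
#' @param x character vector of candidate identifiers.
#' @return `nhs_check_digit()`: integer in 0..9 or `NA`.
#'   `validate_nhs_number()`: logical vector, `FALSE` for anything malformed.
#' @examples
#' nhs_check_digit("450557710")
#' validate_nhs_number(c("450 557 7104", "4505577105", "123"))
#' @export
nhs_check_digit <- function(prefix9) {
  stopifnot(is.character(prefix9), length(prefix9) == 1L)
  if (!grepl("^[0-9]{9}$", prefix9)) {
    abort("`prefix9` must be exactly 9 digits.", class = "cohortforge_value_error")
  }
  d <- as.integer(strsplit(prefix9, "", fixed = TRUE)[[1]])
  r <- sum(d * 10:2) %% 11L
  chk <- 11L - r
  if (chk == 11L) chk <- 0L
  if (chk == 10L) return(NA_integer_)
  chk
}

#' @rdname nhs_check_digit
#' @export
validate_nhs_number <- function(x) {
  if (length(x) == 0L) return(logical(0))
  x <- as.character(x)
  canon <- canonicalise_identifier(x)
  ok <- !is.na(canon) & grepl("^[0-9]{10}$", canon)
  out <- logical(length(x))
  if (!any(ok)) return(out)
  mat <- vapply(
    strsplit(canon[ok], "", fixed = TRUE),
    function(d) as.integer(d),
    integer(10)
  )
  # mat is 10 x n; weighted sum over rows 1..9
  s <- as.integer(crossprod(mat[1:9, , drop = FALSE], 10:2))
  chk <- 11L - (s %% 11L)
  chk[chk == 11L] <- 0L
  out[ok] <- chk != 10L & chk == mat[10L, ]
  out
}

# Strip spaces and hyphens only; no other transformation before hashing or
# validation.
canonicalise_identifier <- function(x) {
  gsub("[ -]", "", as.character(x))
}

#' Generate synthetic NHS-style test numbers
#'
#' Draws distinct 10-digit numbers with valid modulus-11 check digits from
#' the reserved `999`-prefixed test range, which the NHS never allocates to
#' real people. Prefixes whose check digit would be 10 are rejected and
#' redrawn.
#'
#' @param n how many distinct numbers to draw.
#' @return character vector of `n` distinct valid identifiers.
#' @export
generate_nhs_numbers <- function(n) {
  stopifnot(is.numeric(n), n >= 0)
  n <- as.integer(n)
  if (n > 800000L) {
    abort("test range cannot supply that many distinct identifiers",
      class = "cohortforge_config_error"
    )
  }
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    body <- sprintf("%06d", sample.int(1000000L, need * 2L, replace = TRUE) - 1L)
    prefix <- paste0("999", body)
    chk <- vapply(prefix, nhs_check_digit, integer(1), USE.NAMES = FALSE)
    cand <- paste0(prefix, chk)[!is.na(chk)]
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Corrupt one digit of an identifier
#'
#' Emulates a transcription error in a study database: one position of a
#' 10-digit identifier is replaced by a uniformly chosen *different* digit,
#' so the output always differs from the input. Because the modulus-11
#' scheme detects all single-digit substitutions, corrupting a valid number
#' always yields an invalid one.
#'
#' @param identifier a 10-digit string.
#' @param position optional position 1..10 to force; default random.
#' @return a 10-digit string differing from `identifier` in exactly one digit.
#' @export
corrupt_identifier <- function(identifier, position = NULL) {
  stopifnot(is.character(identifier), length(identifier) == 1L)
  if (!grepl("^[0-9]{10}$", identifier)) {
    abort("`identifier` must be a 10-digit string.",
      class = "cohortforge_value_error"
    )
  }
  d <- strsplit(identifier, "", fixed = TRUE)[[1]]
  pos <- if (is.null(position)) sample.int(10L, 1L) else as.integer(position)
  stopifnot(pos >= 1L, pos <= 10L)
  alternatives <- setdiff(as.character(0:9), d[pos])
  d[pos] <- sample(alternatives, 1L)
  paste(d, collapse = "")
}
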