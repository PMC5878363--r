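#' Normalize an identity component for key construction
#'
#' Identity fields are stored verbatim in the registries; all cleaning is
#' done here, non-destructively, at key-construction time. Normalization is
#' deterministic and idempotent.
#'
#' @param raw character vector of raw field values (`NA` allowed).
#' @param kind one of `"name"`, `"ssn"`, `"date"`, `"sex"`.
#'   * `name`: uppercased, diacritics folded to ASCII, every non-alphabetic
#'     character (spaces, hyphens, apostrophes) stripped.
#'   * `ssn`: digits only; anything that is not exactly 9 digits after
#'     stripping becomes the empty string (an unusable component).
#'   * `date`: a `Date` (or ISO-8601 string) rendered as `YYYYMMDD`.
#'   * `sex`: first letter, uppercased, one of `M`/`F`; anything else
#'     (including `"unknown"`) becomes empty and the component is treated
#'     as missing.
#' @return character vector; empty string marks a missing/unusable component.
#' @export
#' @examples
#' normalize_component("O'Brien-Smith ", "name") # "OBRIENSMITH"
#' normalize_component("123-45-6789", "ssn")     # "123456789"
normalize_component <- function(raw, kind = c("name", "ssn", "date", "sex")) {
  kind <- match.arg(kind)
  if (inherits(raw, "Date")) {
    raw <- ifelse(is.na(raw), NA_character_, format(raw, "%Y-%m-%d"))
  }
  x <- as.character(raw)
  x[is.na(x)] <- ""
  switch(kind,
    name = {
      x <- toupper(x)
      # fold diacritics to plain ASCII before stripping
      folded <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
      keep <- is.na(folded)
      folded[keep] <- x[keep]
      gsub("[^A-Z]", "", toupper(folded))
    },
    ssn = {
      d <- gsub("[^0-9]", "", x)
      d[nchar(d) != 9L] <- ""
      d
    },
    date = {
      d <- gsub("[^0-9]", "", x)
      d[nchar(d) != 8L] <- ""
      d
    },
    sex = {
      s <- toupper(substr(trimws(x), 1L, 1L))
      s[!s %in% c("M", "F")] <- ""
      s
    }
  )
}

#' American Soundex phonetic encoding
#'
#' Standard four-character American Soundex (first letter + three digits,
#' zero-padded): vowels separate codes, `H`/`W` are transparent between
#' consonants of equal code, adjacent equal codes collapse.
#'
#' @param x character vector of names (already or not yet normalized;
#'   non-alphabetic characters are ignored).
#' @return character vector of codes such as `"R163"`; empty input encodes
#'   to the empty string.
#' @export
#' @examples
#' soundex(c("Robert", "Rupert", "Tymczak")) # "R163" "R163" "T522"
soundex <- function(x) {
  code_of <- c(
    B = 1, F = 1, P = 1, V = 1,
    C = 2, G = 2, J = 2, K = 2, Q = 2, S = 2, X = 2, Z = 2,
    D = 3, T = 3,
    L = 4,
    M = 5, N = 5,
    R = 6
  )
  vapply(x, function(nm) {
    nm <- gsub("[^A-Z]", "", toupper(ifelse(is.na(nm), "", nm)))
    if (nchar(nm) == 0L) return("")
    letters_ <- strsplit(nm, "")[[1]]
    first <- letters_[1L]
    out <- character(0)
    prev_code <- if (first %in% names(code_of)) code_of[[first]] else 0L
    for (ch in letters_[-1L]) {
      if (ch %in% c("H", "W")) next            # transparent: keep prev_code
      if (ch %in% c("A", "E", "I", "O", "U", "Y")) {
        prev_code <- 0L                        # vowel separates codes
        next
      }
      code <- code_of[[ch]]
      if (!identical(code, prev_code)) out <- c(out, code)
      prev_code <- code
      if (length(out) >= 3L) break
    }
    paste0(first, paste0(c(out, 0, 0, 0)[1:3], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Component-wise normalized identity pieces used by every key.
.norm_identity <- function(identity) {
  tibble::tibble(
    first = normalize_component(identity$first_name, "name"),
    last  = normalize_component(identity$last_name, "name"),
    dob   = normalize_component(identity$dob, "date"),
    sex   = normalize_component(identity$sex_at_birth, "sex"),
    ssn   = normalize_component(identity$ssn, "ssn")
  )
}

# Paste components into a key string; any empty component voids the key.
.compose_key <- function(...) {
  parts <- list(...)
  any_empty <- Reduce(`|`, lapply(parts, function(p) p == ""))
  out <- do.call(paste, c(parts, sep = "|"))
  out[any_empty] <- ""
  out
}

#' Build the deterministic match-key set for a registry's identities
#'
#' Eleven composite identity keys (the HIV variant) built from first name,
#' last name, date of birth, sex at birth and SSN; the STD variant drops
#' the SSN-exact key (K1), leaving ten. Each key is an exact-match string;
#' a key whose required components are missing gets an empty `key_string`
#' and can never match. The catalogue:
#'
#' * K1 — SSN (exact 9 digits)
#' * K2 — last + first + DOB + sex
#' * K3 — soundex(last) + soundex(first) + DOB
#' * K4 — last + first + sex + DOB with month/day order-canonicalised
#'   (year + sorted(month, day)), so a one-sided day/month transposition
#'   still agrees
#' * K5 — last + first initial + DOB + sex
#' * K6 — alphabetically sorted name pair + DOB + sex (catches a one-sided
#'   first/last swap)
#' * K7 — last + birth year + sex + SSN last 4
#' * K8 — soundex(last) + first + birth year + sex
#' * K9 — last + first + DOB (no sex)
#' * K10 — first 3 of last + first 3 of first + DOB + sex
#' * K11 — SSN last 4 + DOB + sex
#'
#' @param identities data frame with columns `native_id`, `first_name`,
#'   `last_name`, `dob`, `sex_at_birth`, `ssn` (a persons table from a
#'   registry extract, with its native ID renamed to `native_id`).
#' @param variant `"hiv11"` (keys 1–11) or `"std10"` (keys 2–11).
#' @return long tibble `(native_id, key_id, key_string)`; one row per
#'   identity per key, empty `key_string` for unusable keys.
#' @export
build_keys <- function(identities, variant = c("hiv11", "std10")) {
  variant <- match.arg(variant)
  n <- .norm_identity(identities)
  yr <- substr(n$dob, 1L, 4L)
  mo <- substr(n$dob, 5L, 6L)
  dy <- substr(n$dob, 7L, 8L)
  dob_canon <- paste0(yr, pmin(mo, dy), pmax(mo, dy))
  dob_canon[n$dob == ""] <- ""
  name_lo <- pmin(n$first, n$last)
  name_hi <- pmax(n$first, n$last)
  ssn4 <- substr(n$ssn, 6L, 9L)
  sdx_last <- soundex(n$last)
  sdx_first <- soundex(n$first)

  keys <- list(
    `1`  = n$ssn,
    `2`  = .compose_key(n$last, n$first, n$dob, n$sex),
    `3`  = .compose_key(sdx_last, sdx_first, n$dob),
    `4`  = .compose_key(n$last, n$first, n$sex, dob_canon),
    `5`  = .compose_key(n$last, substr(n$first, 1L, 1L), n$dob, n$sex),
    `6`  = .compose_key(name_lo, name_hi, n$dob, n$sex),
    `7`  = .compose_key(n$last, yr, n$sex, ssn4),
    `8`  = .compose_key(sdx_last, n$first, yr, n$sex),
    `9`  = .compose_key(n$last, n$first, n$dob),
    `10` = .compose_key(substr(n$last, 1L, 3L), substr(n$first, 1L, 3L),
                        n$dob, n$sex),
    `11` = .compose_key(ssn4, n$dob, n$sex)
  )
  key_ids <- if (variant == "hiv11") 1:11 else 2:11
  purrr::map_dfr(key_ids, function(k) {
    tibble::tibble(
      native_id = identities$native_id,
      key_id = k,
      key_string = keys[[as.character(k)]]
    )
  })
}
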