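#' Registry extract containers
#'
#' The three registries are held as lists of plain tibbles joined by their
#' native IDs, mirroring the delimited-text extract layout (one file per
#' entity):
#'
#' * `cohort_extract`: `persons`, `labs`, `art`, `std`, `visits`, keyed by
#'   `study_id`.
#' * `surveillance_extract`: `persons`, `labs`, keyed by `ehars_id`.
#' * `std_extract`: `persons`, `events`, keyed by `std_id`.
#'
#' Identity fields (names, DOB, sex at birth, SSN) are stored verbatim;
#' all normalization happens at key-construction time.
#'
#' @name registry-extracts
NULL

.sex_levels <- c("male", "female", "unknown")
.race_levels <- c("nh_black", "nh_white", "other_unknown")
.state_levels <- c("DC", "MD", "VA", "other")
.risk_levels <- c("msm_idu", "idu", "msm", "heterosexual", "perinatal",
                  "other_unknown")
.disease_levels <- c("syphilis", "gonorrhea", "chlamydia")

# Column schemas: type in {chr, date, num, lgl}; nullable marks columns whose
# empty/failed values do not reject the row. `enum` constrains values.
.col <- function(type, nullable = FALSE, enum = NULL) {
  list(type = type, nullable = nullable, enum = enum)
}

.schema_identity <- function() list(
  first_name = .col("chr"),
  last_name = .col("chr"),
  dob = .col("date"),
  sex_at_birth = .col("chr", enum = .sex_levels),
  ssn = .col("chr", nullable = TRUE)
)

.schema_labs <- function(id) {
  s <- list(
    lab_id = .col("chr"),
    test_type = .col("chr", enum = c("CD4", "VL")),
    value = .col("num"),
    below_detection = .col("lgl"),
    collection_date = .col("date"),
    source_facility = .col("chr")
  )
  c(setNames(list(.col("chr")), id), s)
}

.cohort_schemas <- function() list(
  persons = c(
    list(study_id = .col("chr"), enrollment_site = .col("chr"),
         enrollment_date = .col("date")),
    .schema_identity(),
    list(
      race_ethnicity = .col("chr", enum = .race_levels),
      state_of_residence = .col("chr", enum = .state_levels),
      transmission_risk = .col("chr", enum = .risk_levels),
      hiv_dx_date = .col("date", nullable = TRUE),
      aids_ever = .col("lgl"),
      oi_at_aids = .col("lgl", nullable = TRUE),
      housing = .col("chr"),
      employment = .col("chr"),
      insurance = .col("chr"),
      comorbidities = .col("chr", nullable = TRUE),
      vital_status = .col("chr", enum = c("alive", "deceased")),
      withdrawal_date = .col("date", nullable = TRUE),
      transfer_date = .col("date", nullable = TRUE)
    )
  ),
  labs = .schema_labs("study_id"),
  art = list(study_id = .col("chr"), start_date = .col("date"),
             end_date = .col("date", nullable = TRUE)),
  std = list(study_id = .col("chr"),
             disease = .col("chr", enum = .disease_levels),
             disease_date = .col("date")),
  visits = list(study_id = .col("chr"), visit_date = .col("date"))
)

.surveillance_schemas <- function() list(
  persons = c(
    list(ehars_id = .col("chr")),
    .schema_identity(),
    list(
      hiv_dx_date = .col("date", nullable = TRUE),
      aids_dx_date = .col("date", nullable = TRUE),
      oi_at_aids = .col("lgl", nullable = TRUE),
      transmission_risk = .col("chr", enum = .risk_levels),
      state_of_residence = .col("chr", enum = .state_levels),
      vital_status = .col("chr", enum = c("alive", "deceased"))
    )
  ),
  labs = .schema_labs("ehars_id")
)

.std_schemas <- function() list(
  persons = c(list(std_id = .col("chr")), .schema_identity()),
  events = list(std_id = .col("chr"),
                disease = .col("chr", enum = .disease_levels),
                disease_date = .col("date"))
)

# Read one CSV against a schema; returns list(data, errors). Row-level
# failures (bad date/number/logical/enum in a non-nullable column) drop the
# row and collect a line-numbered error; a missing mandatory column stops.
.read_table <- function(path, schema, table_name) {
  if (!file.exists(path)) stop("missing registry file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE,
    na = character())
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[names(schema)]
  n <- nrow(raw)
  errors <- tibble::tibble(file = character(0), line = integer(0),
                           column = character(0), message = character(0))
  bad_row <- rep(FALSE, n)
  out <- list()
  for (cn in names(schema)) {
    spec <- schema[[cn]]
    x <- raw[[cn]]
    empty <- is.na(x) | x == ""
    conv <- switch(spec$type,
      chr = ifelse(empty, NA_character_, x),
      date = as.Date(ifelse(empty, NA_character_, x), format = "%Y-%m-%d"),
      num = suppressWarnings(as.numeric(ifelse(empty, NA_character_, x))),
      lgl = ifelse(empty, NA, x == "TRUE" | x == "true")
    )
    failed <- !empty & is.na(conv)
    if (spec$type == "lgl") {
      failed <- !empty & !(x %in% c("TRUE", "true", "FALSE", "false"))
      conv[failed] <- NA
    }
    if (!is.null(spec$enum)) failed <- failed | (!empty & !(x %in% spec$enum))
    bad <- failed | (if (spec$nullable) FALSE else empty)
    if (any(bad)) {
      # line numbers are 1-based data rows + 1 for the header
      errors <- dplyr::bind_rows(errors, tibble::tibble(
        file = basename(path), line = which(bad) + 1L, column = cn,
        message = ifelse(empty[bad], "missing required value",
                         paste0("invalid ", spec$type, " value '",
                                x[bad], "'"))
      ))
      bad_row <- bad_row | bad
    }
    out[[cn]] <- conv
  }
  list(data = tibble::as_tibble(out)[!bad_row, ], errors = errors)
}

.read_extract <- function(dir, schemas, id_col, class_name, sort_tables) {
  parts <- purrr::map(names(schemas), function(tn) {
    .read_table(file.path(dir, paste0(tn, ".csv")), schemas[[tn]], tn)
  })
  names(parts) <- names(schemas)
  errors <- purrr::map_dfr(parts, "errors")
  tables <- purrr::map(parts, "data")
  dup <- tables[[1L]][[id_col]][duplicated(tables[[1L]][[id_col]])]
  if (length(dup) > 0L) {
    stop("duplicate ", id_col, " in ", class_name, " persons table: ",
         paste(unique(dup), collapse = ", "))
  }
  tables <- purrr::imap(tables, function(tb, tn) {
    dplyr::arrange(tb, dplyr::across(dplyr::all_of(sort_tables[[tn]])))
  })
  structure(c(tables, list(errors = errors)), class = class_name)
}

#' Read registry extracts from a directory of CSV files
#'
#' Each extract is a directory holding one UTF-8 comma-separated file per
#' entity with a mandatory header and ISO-8601 (`YYYY-MM-DD`) dates:
#' `persons.csv`, `labs.csv`, `art.csv`, `std.csv`, `visits.csv` for the
#' cohort; `persons.csv`, `labs.csv` for HIV surveillance; `persons.csv`,
#' `events.csv` for STD surveillance. Rows whose required fields fail to
#' parse are rejected individually and collected in a line-numbered error
#' table (`$errors`, also via [registry_errors()]); a missing mandatory
#' column or a duplicated native ID stops with a schema error. Records are
#' returned sorted by native ID.
#'
#' @param dir path to the extract directory.
#' @return a `cohort_extract`, `surveillance_extract` or `std_extract`.
#' @export
read_cohort_extract <- function(dir) {
  .read_extract(dir, .cohort_schemas(), "study_id", "cohort_extract",
    list(persons = "study_id", labs = c("study_id", "collection_date",
                                        "lab_id"),
         art = c("study_id", "start_date"),
         std = c("study_id", "disease", "disease_date"),
         visits = c("study_id", "visit_date")))
}

#' @rdname read_cohort_extract
#' @export
read_surveillance_extract <- function(dir) {
  .read_extract(dir, .surveillance_schemas(), "ehars_id",
    "surveillance_extract",
    list(persons = "ehars_id",
         labs = c("ehars_id", "collection_date", "lab_id")))
}

#' @rdname read_cohort_extract
#' @export
read_std_extract <- function(dir) {
  .read_extract(dir, .std_schemas(), "std_id", "std_extract",
    list(persons = "std_id",
         events = c("std_id", "disease", "disease_date")))
}

.empty_errors <- function() {
  tibble::tibble(file = character(0), line = integer(0),
                 column = character(0), message = character(0))
}

.sort_orders <- list(
  cohort_extract = list(
    persons = "study_id", labs = c("study_id", "collection_date", "lab_id"),
    art = c("study_id", "start_date"),
    std = c("study_id", "disease", "disease_date"),
    visits = c("study_id", "visit_date")),
  surveillance_extract = list(
    persons = "ehars_id", labs = c("ehars_id", "collection_date", "lab_id")),
  std_extract = list(
    persons = "std_id", events = c("std_id", "disease", "disease_date"))
)

.new_extract <- function(tables, class_name) {
  orders <- .sort_orders[[class_name]]
  tables <- purrr::imap(tables, function(tb, tn) {
    dplyr::arrange(tibble::as_tibble(tb),
                   dplyr::across(dplyr::all_of(orders[[tn]])))
  })
  structure(c(tables, list(errors = .empty_errors())), class = class_name)
}

#' Construct registry extracts from in-memory tables
#'
#' Used by the synthetic generator and by tests; tables are coerced to
#' tibbles and put in the canonical (reader) row order, so a constructed
#' extract compares equal to its written-and-reread self.
#'
#' @param persons,labs,art,std,visits,events component tables (see
#'   [read_cohort_extract()] for the schemas).
#' @return the classed extract object.
#' @export
cohort_extract <- function(persons, labs, art, std, visits) {
  .new_extract(list(persons = persons, labs = labs, art = art, std = std,
                    visits = visits), "cohort_extract")
}

#' @rdname cohort_extract
#' @export
surveillance_extract <- function(persons, labs) {
  .new_extract(list(persons = persons, labs = labs), "surveillance_extract")
}

#' @rdname cohort_extract
#' @export
std_extract <- function(persons, events) {
  .new_extract(list(persons = persons, events = events), "std_extract")
}

#' Collected row-level errors from a registry read
#' @param x an extract object from [read_cohort_extract()] and friends.
#' @return tibble with `file`, `line`, `column`, `message`.
#' @export
registry_errors <- function(x) x$errors

.write_table <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(lubridate::is.Date),
                                        ~ format(.x, "%Y-%m-%d")))
  readr::write_csv(df, path, na = "", progress = FALSE)
}

.write_extract <- function(x, dir, tables) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tn in tables) .write_table(x[[tn]], file.path(dir, paste0(tn, ".csv")))
  invisible(dir)
}

#' Write registry extracts to a directory of CSV files
#'
#' Inverse of the readers: ISO-8601 dates, empty string for `NA`,
#' deterministic row order. `read_*_extract(write_*_extract(x))` is the
#' identity on valid extracts.
#'
#' @param x the extract object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_extract <- function(x, dir) {
  .write_extract(x, dir, c("persons", "labs", "art", "std", "visits"))
}

#' @rdname write_cohort_extract
#' @export
write_surveillance_extract <- function(x, dir) {
  .write_extract(x, dir, c("persons", "labs"))
}

#' @rdname write_cohort_extract
#' @export
write_std_extract <- function(x, dir) {
  .write_extract(x, dir, c("persons", "events"))
}

#' Write a comparison report as deterministic CSV tables
#'
#' Writes each table of a report (a named list of data frames, as produced
#' by [compare_pre_post()] / [build_cascade()]) to `<name>.csv` under
#' `out_dir`. Output is byte-identical for identical input: stable row
#' order as given, numeric columns rendered with exactly two decimals
#' (columns ending in `_pct` included), counts as integers, `NA` empty.
#'
#' @param report named list of data frames.
#' @param out_dir output directory.
#' @return invisible character vector of written paths.
#' @export
write_report_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- purrr::imap_chr(report, function(df, nm) {
    df <- dplyr::mutate(
      df,
      dplyr::across(dplyr::where(is.double),
                    ~ ifelse(is.na(.x), NA_character_, sprintf("%.2f", .x))),
      dplyr::across(dplyr::where(lubridate::is.Date),
                    ~ format(.x, "%Y-%m-%d"))
    )
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, p, na = "", progress = FALSE)
    p
  })
  invisible(paths)
}
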