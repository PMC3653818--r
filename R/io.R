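# Readers, writers and validators for the registry file schemas:
# individual records, aggregated counts, age groups, standard population,
# population distribution (person-years) and general-population life tables.
# All files are plain delimited text with a mandatory header row; comma and
# semicolon delimiters are auto-detected (comma wins a tie). Age-group
# indices in files are 1-based.

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) {
    stop("file '", path, "' is empty (no header row)", call. = FALSE)
  }
  n_comma <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  n_semi <- lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
  if (n_semi > n_comma) ";" else ","
}

read_delim_auto <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  if (is.null(delimiter)) delimiter <- detect_delimiter(path)
  utils::read.table(path, header = TRUE, sep = delimiter,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, strip.white = TRUE)
}

# case/punctuation-insensitive column lookup; returns index or stops
find_column <- function(df, name, path) {
  norm <- function(x) gsub("[._ ]", "", tolower(x))
  hit <- which(norm(names(df)) == norm(name))
  if (length(hit) != 1L) {
    stop("column '", name, "' missing (or duplicated) in '", path,
         "'; found: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  hit
}

#' Read an individual-records file
#'
#' Reads a delimited file of diagnosed patients, one row per patient, with
#' sex, disease group, age and date at diagnosis, vital status, date at end
#' of follow-up and follow-up time in years. Every row is validated; rows
#' that violate an invariant are either raised as an error naming the row
#' (the default) or returned as a reject report, so no row is ever silently
#' dropped.
#'
#' @param path Path to the file.
#' @param schema Named character vector mapping canonical field names
#'   (`patient_id`, `sex`, `disease_group`, `age`, `diagnosis_month`,
#'   `diagnosis_year`, `end_month`, `end_year`, `status`, `follow_up`) to the
#'   column headers used in the file. Defaults to the conventional headers
#'   `Patient_ID, Sex, d_group, d_age, i_month, i_year, f_month, f_year,
#'   Status, Follow_up`.
#' @param status_codes Length-2 named vector giving the file's codes for
#'   `dead` and `alive`; defaults to `c(dead = 1, alive = 0)`.
#' @param delimiter Field delimiter; `NULL` auto-detects comma vs semicolon.
#' @param on_invalid `"error"` (default) stops at the first batch of invalid
#'   rows, naming each row and reason; `"reject"` drops them and attaches a
#'   reject report (`attr(x, "rejects")`, a data frame with `row`, `reason`).
#' @return A data frame of class `individual_records` with canonical column
#'   names, `status` recoded to 1 = dead, 0 = alive/censored.
#' @details When the stored follow-up time disagrees with the elapsed time
#'   between the diagnosis and end dates by more than 1/12 year, the stored
#'   follow-up time is taken as authoritative and a warning is issued.
#' @export
read_individual_records <- function(path, schema = NULL,
                                    status_codes = c(dead = 1, alive = 0),
                                    delimiter = NULL,
                                    on_invalid = c("error", "reject")) {
  on_invalid <- match.arg(on_invalid)
  default_schema <- c(patient_id = "Patient_ID", sex = "Sex",
                      disease_group = "d_group", age = "d_age",
                      diagnosis_month = "i_month", diagnosis_year = "i_year",
                      end_month = "f_month", end_year = "f_year",
                      status = "Status", follow_up = "Follow_up")
  if (!is.null(schema)) default_schema[names(schema)] <- schema
  schema <- default_schema

  raw <- read_delim_auto(path, delimiter)
  idx <- vapply(schema, find_column, integer(1), df = raw, path = path)
  out <- raw[idx]
  names(out) <- names(schema)

  numeric_fields <- c("sex", "age", "diagnosis_month", "diagnosis_year",
                      "end_month", "end_year", "status", "follow_up")
  reasons <- rep.int("", nrow(out))
  add_reason <- function(bad, msg) {
    reasons[bad] <<- ifelse(reasons[bad] == "", msg,
                            paste(reasons[bad], msg, sep = "; "))
  }
  for (f in numeric_fields) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- is.na(v) & !is.na(out[[f]])
    if (any(bad)) {
      add_reason(bad, paste0("non-numeric ", f, " ('", out[[f]][bad], "')"))
    }
    out[[f]] <- v
  }
  add_na <- is.na(out$sex) | is.na(out$age) | is.na(out$status) |
    is.na(out$follow_up)
  if (any(add_na)) add_reason(add_na & reasons == "", "missing mandatory field")

  ok <- reasons == ""
  add_reason(ok & !(out$sex %in% c(1, 2)),
             "sex not in {1, 2}")
  add_reason(ok & !(out$status %in% status_codes), "status not a known code")
  add_reason(ok & out$follow_up < 0, "negative follow-up time")
  add_reason(ok & out$age < 0, "negative age at diagnosis")
  end_before <- ok &
    (out$end_year + out$end_month / 12 <
       out$diagnosis_year + out$diagnosis_month / 12)
  add_reason(end_before, "end of follow-up precedes diagnosis")

  bad <- which(reasons != "")
  if (length(bad) > 0L) {
    report <- data.frame(row = bad, reason = reasons[bad],
                         stringsAsFactors = FALSE)
    if (on_invalid == "error") {
      stop("invalid rows in '", path, "':\n",
           paste0("  row ", report$row, ": ", report$reason,
                  collapse = "\n"), call. = FALSE)
    }
    out <- out[-bad, , drop = FALSE]
  } else {
    report <- data.frame(row = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  }

  # stored follow-up is authoritative over the redundant date pair
  elapsed <- (out$end_year - out$diagnosis_year) +
    (out$end_month - out$diagnosis_month) / 12
  off <- which(!is.na(elapsed) & abs(elapsed - out$follow_up) > 1 / 12 + 1e-9)
  if (length(off) > 0L) {
    warning(length(off), " record(s) have follow-up time inconsistent with ",
            "the diagnosis/end dates by more than 1/12 year; the stored ",
            "follow-up time is used", call. = FALSE)
  }
  out$status <- as.integer(out$status == status_codes[["dead"]])
  rownames(out) <- NULL
  attr(out, "rejects") <- report
  class(out) <- c("individual_records", "data.frame")
  out
}

#' Read an aggregated-counts file
#'
#' Reads a delimited table of case counts and person-years at risk by sex,
#' 1-based age-group index, calendar year and disease group (columns
#' `Sex, Age.group, Year, Group, Cases, Population`).
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @return A data frame of class `aggregated_counts` with columns `sex`,
#'   `age_group`, `year`, `disease`, `cases`, `person_years`.
#' @export
read_aggregated <- function(path, delimiter = NULL) {
  raw <- read_delim_auto(path, delimiter)
  cols <- c(sex = "Sex", age_group = "Age.group", year = "Year",
            disease = "Group", cases = "Cases", person_years = "Population")
  idx <- vapply(cols, find_column, integer(1), df = raw, path = path)
  out <- raw[idx]
  names(out) <- names(cols)
  for (f in c("sex", "age_group", "year", "cases", "person_years")) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    if (anyNA(v) && !all(is.na(out[[f]]) == is.na(v))) {
      stop("non-numeric value in column '", cols[[f]], "' of '", path, "'",
           call. = FALSE)
    }
    out[[f]] <- v
  }
  out$disease <- as.character(out$disease)
  as_aggregated_counts(out, path = path)
}

#' Construct and validate an aggregated-counts table
#'
#' @param x Data frame with columns `sex`, `age_group`, `year`, `disease`,
#'   `cases`, `person_years`.
#' @param path Optional file name used in error messages.
#' @return `x` with class `aggregated_counts`, sorted by key.
#' @export
as_aggregated_counts <- function(x, path = NULL) {
  where <- if (is.null(path)) "" else paste0(" in '", path, "'")
  need <- c("sex", "age_group", "year", "disease", "cases", "person_years")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("missing columns", where, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[need]
  if (any(x$cases < 0, na.rm = TRUE) || anyNA(x$cases)) {
    stop("cases must be non-negative", where, call. = FALSE)
  }
  if (any(x$cases != round(x$cases))) {
    stop("cases must be whole numbers", where, call. = FALSE)
  }
  if (any(x$person_years <= 0, na.rm = TRUE) || anyNA(x$person_years)) {
    stop("person-years must be positive", where, call. = FALSE)
  }
  key <- paste(x$sex, x$age_group, x$year, x$disease, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sex, age-group, year, disease) key", where, ": ",
         gsub("\\|", ", ", dup), call. = FALSE)
  }
  x <- x[order(x$disease, x$sex, x$year, x$age_group), , drop = FALSE]
  rownames(x) <- NULL
  x$cases <- as.integer(round(x$cases))
  class(x) <- c("aggregated_counts", "data.frame")
  x
}

#' Write an aggregated-counts table
#'
#' Writes with the canonical header `Sex, Age.group, Year, Group, Cases,
#' Population`; a write-then-read round trip reproduces the table exactly.
#'
#' @param x An `aggregated_counts` table.
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @export
write_aggregated <- function(x, path, delimiter = ",") {
  out <- data.frame(Sex = x$sex, Age.group = x$age_group, Year = x$year,
                    Group = x$disease, Cases = x$cases,
                    Population = format(x$person_years, digits = 15,
                                        scientific = FALSE, trim = TRUE),
                    check.names = FALSE)
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a standard-population weight file
#'
#' Columns `Age.group` (1-based index) and `Weight`; one positive weight per
#' age group.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @return Numeric vector of weights ordered by age-group index.
#' @export
read_standard_population <- function(path, delimiter = NULL) {
  raw <- read_delim_auto(path, delimiter)
  g <- as.numeric(raw[[find_column(raw, "Age.group", path)]])
  w <- as.numeric(raw[[find_column(raw, "Weight", path)]])
  if (anyNA(g) || anyNA(w)) stop("non-numeric entry in '", path, "'",
                                 call. = FALSE)
  if (any(w <= 0)) stop("standard-population weights must be positive",
                        call. = FALSE)
  if (!identical(sort(g), as.numeric(seq_along(g)))) {
    stop("age-group indices in '", path, "' must be 1..k without gaps",
         call. = FALSE)
  }
  w[order(g)]
}

#' Read an age-group definition file
#'
#' Columns `Age.group`, `Lower`, `Upper`; `Upper` of the final group may be
#' blank, `Inf` or `NA` for an open-ended group. Bounds follow the half-open
#' convention `[Lower, Upper)`.
#'
#' @inheritParams read_standard_population
#' @return An [age_scheme()].
#' @export
read_age_scheme <- function(path, delimiter = NULL) {
  raw <- read_delim_auto(path, delimiter)
  g <- as.numeric(raw[[find_column(raw, "Age.group", path)]])
  lo <- as.numeric(raw[[find_column(raw, "Lower", path)]])
  up <- suppressWarnings(as.numeric(raw[[find_column(raw, "Upper", path)]]))
  o <- order(g)
  age_scheme(lo[o], up[o])
}

#' Read a population-distribution (person-years) file
#'
#' Columns `Sex`, `Age.group` (1-based), `Year`, `Population`.
#'
#' @inheritParams read_standard_population
#' @return Data frame with columns `sex`, `age_group`, `year`,
#'   `person_years`.
#' @export
read_population <- function(path, delimiter = NULL) {
  raw <- read_delim_auto(path, delimiter)
  cols <- c(sex = "Sex", age_group = "Age.group", year = "Year",
            person_years = "Population")
  idx <- vapply(cols, find_column, integer(1), df = raw, path = path)
  out <- raw[idx]
  names(out) <- names(cols)
  for (f in names(out)) out[[f]] <- as.numeric(out[[f]])
  if (anyNA(out)) stop("non-numeric entry in '", path, "'", call. = FALSE)
  if (any(out$person_years <= 0)) {
    stop("person-years must be positive in '", path, "'", call. = FALSE)
  }
  key <- paste(out$sex, out$age_group, out$year)
  if (anyDuplicated(key)) {
    stop("duplicate (sex, age-group, year) key in '", path, "'",
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a general-population life table
#'
#' Columns `Sex`, `Age` (single year of age), `Year` (calendar year),
#' `Prob` (annual survival probability, in (0, 1]). Within each sex the age
#' and year coverage must be a complete grid.
#'
#' @inheritParams read_standard_population
#' @return An object of class `life_table`: a data frame with columns
#'   `sex`, `age`, `year`, `prob`.
#' @export
read_life_table <- function(path, delimiter = NULL) {
  raw <- read_delim_auto(path, delimiter)
  cols <- c(sex = "Sex", age = "Age", year = "Year", prob = "Prob")
  idx <- vapply(cols, find_column, integer(1), df = raw, path = path)
  out <- raw[idx]
  names(out) <- names(cols)
  for (f in names(out)) out[[f]] <- as.numeric(out[[f]])
  if (anyNA(out)) stop("non-numeric entry in '", path, "'", call. = FALSE)
  as_life_table(out)
}

#' @rdname read_life_table
#' @param x Data frame with columns `sex`, `age`, `year`, `prob`.
#' @export
as_life_table <- function(x) {
  need <- c("sex", "age", "year", "prob")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("life table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[need]
  if (any(x$prob <= 0 | x$prob > 1)) {
    stop("life-table survival probabilities must lie in (0, 1]",
         call. = FALSE)
  }
  for (s in unique(x$sex)) {
    sub <- x[x$sex == s, ]
    ages <- sort(unique(sub$age))
    years <- sort(unique(sub$year))
    if (any(diff(ages) != 1) || any(diff(years) != 1) ||
        nrow(sub) != length(ages) * length(years) ||
        anyDuplicated(paste(sub$age, sub$year))) {
      stop("life table for sex ", s,
           " must cover a complete contiguous age x year grid",
           call. = FALSE)
    }
  }
  x <- x[order(x$sex, x$age, x$year), ]
  rownames(x) <- NULL
  class(x) <- c("life_table", "data.frame")
  x
}

#' Write a life table
#'
#' @param x A `life_table`.
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @export
write_life_table <- function(x, path, delimiter = ",") {
  out <- data.frame(Sex = x$sex, Age = x$age, Year = x$year,
                    Prob = format(x$prob, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Aggregate individual records into counts by sex, age group and year
#'
#' Tallies diagnoses into the cells of a person-years distribution. Every
#' cell of the distribution is emitted for every disease present in the
#' records (zero-case cells included); person-years are copied from the
#' distribution. A record whose (sex, age group, diagnosis year) cell is
#' absent from the distribution is a coverage error.
#'
#' @param records An `individual_records` data frame.
#' @param pop Person-years distribution as returned by [read_population()].
#' @param scheme An [age_scheme()].
#' @return An `aggregated_counts` table.
#' @export
aggregate_individuals <- function(records, pop, scheme = age_scheme()) {
  if (nrow(pop) == 0L) stop("empty population distribution", call. = FALSE)
  diseases <- unique(records$disease_group)
  if (length(diseases) == 0L) diseases <- NA_character_
  pop_key <- paste(pop$sex, pop$age_group, pop$year)

  if (nrow(records) > 0L) {
    grp <- age_to_group(records$age, scheme)
    rec_key <- paste(records$sex, grp, records$diagnosis_year)
    missing <- !(rec_key %in% pop_key)
    if (any(missing)) {
      stop("population distribution lacks cell(s) for record(s): ",
           paste(unique(rec_key[missing]), collapse = "; "),
           " (sex, age-group, year)", call. = FALSE)
    }
  }

  cells <- pop[rep(seq_len(nrow(pop)), times = length(diseases)), ]
  cells$disease <- rep(as.character(diseases), each = nrow(pop))
  cells$cases <- 0L
  if (nrow(records) > 0L) {
    full_key <- paste(rec_key, records$disease_group)
    tab <- table(full_key)
    cell_key <- paste(pop_key[rep(seq_len(nrow(pop)), length(diseases))],
                      cells$disease)
    hit <- match(names(tab), cell_key)
    cells$cases[hit] <- as.integer(tab)
  }
  as_aggregated_counts(cells)
}
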