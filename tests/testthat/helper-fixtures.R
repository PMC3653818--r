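# In-code fixtures shared across test files.

write_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# individual-records file with the conventional header
individual_file <- function(rows, sep = ",") {
  header <- paste(c("Patient_ID", "Sex", "d_group", "d_age", "i_month",
                    "i_year", "f_month", "f_year", "Status", "Follow_up"),
                  collapse = sep)
  write_tmp(c(header, vapply(rows, paste, "", collapse = sep)))
}

aggregated_file <- function(df, sep = ",") {
  f <- tempfile(fileext = ".csv")
  out <- data.frame(Sex = df$sex, Age.group = df$age_group,
                    Year = df$year, Group = df$disease, Cases = df$cases,
                    Population = df$person_years, check.names = FALSE)
  write.table(out, f, sep = sep, row.names = FALSE, quote = FALSE)
  f
}

# flat life table: one survival probability everywhere
flat_life_table <- function(prob = 1, sexes = 1:2, ages = 0:109,
                            years = 1990:2030) {
  lt <- expand.grid(sex = sexes, age = ages, year = years,
                    KEEP.OUT.ATTRS = FALSE)
  lt$prob <- prob
  as_life_table(lt)
}

# random aggregated two-period tables for decomposition properties
random_two_periods <- function(k = 6) {
  list(c1 = rpois(k, 20), y1 = runif(k, 500, 5000),
       c2 = rpois(k, 25), y2 = runif(k, 500, 5000))
}
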