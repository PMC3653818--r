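# Synthetic-registry generator with known ground truth. Case counts per
# sex x age-group x year cell are Poisson with mean rate x person-years,
# where age-specific rates change by a constant multiplicative factor per
# year (so the true EAPC is known). Patient survival follows an additive
# hazard: the constant background hazard implied by the synthetic life
# table plus a constant disease excess hazard, so the true relative
# survival has the closed form exp(-excess * t). Censoring is
# administrative at 31 December of the last study year.

#' Specification of a synthetic registry
#'
#' @param age_scheme_obj An [age_scheme()].
#' @param years Calendar years of diagnosis.
#' @param sexes Sex codes generated.
#' @param disease Disease-group label.
#' @param base_rates Age-specific incidence rates per 100,000 person-years
#'   in the first year; the default is an adult-cancer-like profile rising
#'   steeply with age.
#' @param annual_rate_change Multiplicative change of every age-specific
#'   rate per calendar year; the true EAPC is
#'   `(annual_rate_change - 1) * 100`.
#' @param base_population Person-years per sex x age-group cell in the
#'   first year.
#' @param annual_pop_growth Multiplicative person-years growth per year.
#' @param excess_hazard Constant annual excess death hazard of patients;
#'   the true relative survival at t years is `exp(-excess_hazard * t)`.
#' @param background_survival Annual general-population survival
#'   probability (constant over sex, age and year in the synthetic life
#'   table).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return Object of class `registry_spec`.
#' @export
registry_spec <- function(age_scheme_obj = age_scheme(),
                          years = 1995:2004,
                          sexes = c(1, 2),
                          disease = "Synthetic",
                          base_rates = c(1, 1, 1, 2, 3, 5, 8, 12, 20, 35,
                                         60, 90, 130, 170, 200, 230, 250,
                                         260),
                          annual_rate_change = 1.02,
                          base_population = 30000,
                          annual_pop_growth = 1.01,
                          excess_hazard = 0.15,
                          background_survival = 0.97,
                          seed = 1L) {
  if (length(base_rates) != n_groups(age_scheme_obj)) {
    stop("'base_rates' needs one rate per age group", call. = FALSE)
  }
  if (any(base_rates < 0) || annual_rate_change <= 0) {
    stop("rates must be non-negative and the annual change positive",
         call. = FALSE)
  }
  if (background_survival <= 0 || background_survival > 1) {
    stop("'background_survival' must lie in (0, 1]", call. = FALSE)
  }
  if (excess_hazard < 0) stop("'excess_hazard' must be non-negative",
                              call. = FALSE)
  out <- list(age_scheme = age_scheme_obj, years = as.integer(years),
              sexes = sexes, disease = disease, base_rates = base_rates,
              annual_rate_change = annual_rate_change,
              base_population = base_population,
              annual_pop_growth = annual_pop_growth,
              excess_hazard = excess_hazard,
              background_survival = background_survival,
              seed = as.integer(seed))
  class(out) <- "registry_spec"
  out
}

# deterministic expected rates per 100,000 for a given year
spec_rates <- function(spec, year) {
  spec$base_rates * spec$annual_rate_change^(year - spec$years[1])
}

spec_person_years <- function(spec, year) {
  spec$base_population * spec$annual_pop_growth^(year - spec$years[1])
}

#' Simulate a registry with known ground truth
#'
#' Draws case counts and individual patient histories from a
#' [registry_spec()] and optionally writes the six delimited files a
#' registry analysis consumes (individual records, aggregated counts,
#' population distribution, standard population, age groups, life table)
#' plus a ground-truth manifest. Aggregating the generated individual
#' records reproduces the generated aggregated table exactly.
#'
#' @param spec A [registry_spec()].
#' @param dir Output directory; `NULL` (default) skips writing and returns
#'   the in-memory objects only.
#' @return List with components `individual` (`individual_records`),
#'   `aggregated` (`aggregated_counts`), `population`, `life_table`,
#'   `standard_population`, `age_scheme`, `truth` (list of ground-truth
#'   quantities) and, when `dir` is given, `paths`.
#' @export
simulate_registry <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "registry_spec"))
  set.seed(spec$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1, 2)

  scheme <- spec$age_scheme
  k <- n_groups(scheme)
  years <- spec$years
  last_year <- max(years)

  # person-years distribution (identical for each sex)
  pop <- expand.grid(sex = spec$sexes, age_group = seq_len(k),
                     year = years, KEEP.OUT.ATTRS = FALSE)
  pop <- pop[order(pop$sex, pop$year, pop$age_group), ]
  pop$person_years <- spec_person_years(spec, pop$year)
  rownames(pop) <- NULL

  # Poisson case counts per cell
  set.seed(stream_seeds[1])
  mu <- spec$base_rates[pop$age_group] *
    spec$annual_rate_change^(pop$year - years[1]) / 1e5 * pop$person_years
  pop$cases <- stats::rpois(nrow(pop), mu)
  agg <- as_aggregated_counts(data.frame(
    sex = pop$sex, age_group = pop$age_group, year = pop$year,
    disease = spec$disease, cases = pop$cases,
    person_years = pop$person_years))

  # individual records for every case; additive-hazard survival
  set.seed(stream_seeds[2])
  cells <- pop[pop$cases > 0, , drop = FALSE]
  n <- sum(cells$cases)
  idx <- rep(seq_len(nrow(cells)), cells$cases)
  lower <- scheme$lower[cells$age_group[idx]]
  upper <- ifelse(is.infinite(scheme$upper[cells$age_group[idx]]),
                  scheme$lower[cells$age_group[idx]] + 15,
                  scheme$upper[cells$age_group[idx]])
  age <- lower + floor(stats::runif(n) * (upper - lower))
  month <- sample.int(12, n, replace = TRUE)
  diag_year <- cells$year[idx]
  hazard <- -log(spec$background_survival) + spec$excess_hazard
  death_time <- if (hazard > 0) stats::rexp(n, hazard) else rep(Inf, n)
  censor_time <- (last_year + 1) - (diag_year + (month - 0.5) / 12)
  status <- as.integer(death_time <= censor_time)
  follow_up <- round(pmin(death_time, censor_time), 2)
  follow_up[follow_up == 0] <- 0.01  # diagnosis and death in the same month
  end_frac <- diag_year + (month - 0.5) / 12 + follow_up
  end_year <- floor(end_frac)
  end_month <- pmin(12, pmax(1, round((end_frac - end_year) * 12 + 0.5)))

  individual <- data.frame(
    patient_id = seq_len(n), sex = cells$sex[idx],
    disease_group = spec$disease, age = age,
    diagnosis_month = month, diagnosis_year = diag_year,
    end_month = end_month, end_year = end_year,
    status = status, follow_up = follow_up)
  class(individual) <- c("individual_records", "data.frame")

  # constant synthetic life table covering all attained ages and years
  max_fu <- ceiling(max(c(0, follow_up, (last_year + 1) - min(years))))
  lt <- expand.grid(sex = spec$sexes, age = 0:119,
                    year = min(years):(last_year + max_fu + 1),
                    KEEP.OUT.ATTRS = FALSE)
  lt$prob <- spec$background_survival
  lt <- as_life_table(lt)

  truth <- registry_truth(spec)

  out <- list(individual = individual, aggregated = agg,
              population = pop[c("sex", "age_group", "year",
                                 "person_years")],
              life_table = lt,
              standard_population = if (k == 18) {
                world_standard_population()
              } else rep(1, k),
              age_scheme = scheme, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(individual = file.path(dir, "individual_records.csv"),
               aggregated = file.path(dir, "aggregated.csv"),
               population = file.path(dir, "population.csv"),
               standard_population = file.path(dir,
                                               "standard_population.csv"),
               age_groups = file.path(dir, "age_groups.csv"),
               life_table = file.path(dir, "life_table.csv"),
               manifest = file.path(dir, "ground_truth.txt"))
    ind_out <- data.frame(Patient_ID = individual$patient_id,
                          Sex = individual$sex,
                          d_group = individual$disease_group,
                          d_age = individual$age,
                          i_month = individual$diagnosis_month,
                          i_year = individual$diagnosis_year,
                          f_month = individual$end_month,
                          f_year = individual$end_year,
                          Status = individual$status,
                          Follow_up = individual$follow_up)
    utils::write.table(ind_out, paths["individual"], sep = ",",
                       row.names = FALSE, quote = FALSE)
    write_aggregated(agg, paths["aggregated"])
    pop_out <- data.frame(Sex = out$population$sex,
                          Age.group = out$population$age_group,
                          Year = out$population$year,
                          Population = format(out$population$person_years,
                                              digits = 15,
                                              scientific = FALSE,
                                              trim = TRUE))
    utils::write.table(pop_out, paths["population"], sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(Age.group = seq_len(k),
                 Weight = out$standard_population),
      paths["standard_population"], sep = ",", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(Age.group = scheme$age_group, Lower = scheme$lower,
                 Upper = ifelse(is.infinite(scheme$upper), NA,
                                scheme$upper)),
      paths["age_groups"], sep = ",", row.names = FALSE, quote = FALSE)
    write_life_table(lt, paths["life_table"])
    writeLines(paste(names(truth), vapply(truth, format, "", digits = 10),
                     sep = " = "), paths["manifest"])
    out$paths <- paths
  }
  out
}

# ground-truth quantities implied by a registry spec (no sampling)
registry_truth <- function(spec) {
  years <- spec$years
  std <- world_standard_population()
  if (length(std) != n_groups(spec$age_scheme)) {
    std <- rep(1, n_groups(spec$age_scheme))
  }
  half <- split(years, rep(1:2, each = ceiling(length(years) / 2),
                           length.out = length(years)))
  block <- function(yrs) {
    cases <- Reduce(`+`, lapply(yrs, function(y) {
      spec_rates(spec, y) / 1e5 * spec_person_years(spec, y)
    }))
    py_total <- sum(vapply(yrs, function(y) spec_person_years(spec, y),
                           numeric(1)))
    list(cases = cases, py = rep(py_total, n_groups(spec$age_scheme)))
  }
  b1 <- block(half[[1]]); b2 <- block(half[[2]])
  dec <- decompose_net_change(b1$cases, b1$py, b2$cases, b2$py)
  list(
    eapc_pct = (spec$annual_rate_change - 1) * 100,
    relative_survival_5yr = exp(-5 * spec$excess_hazard),
    simr_block2_vs_block1 = sum(b2$cases) /
      expected_events(b1$cases, b1$py, b2$py),
    net_change_pct = dec$net[dec$scale == "percent"],
    risk_pct = dec$risk[dec$scale == "percent"],
    size_pct = dec$size[dec$scale == "percent"],
    structure_pct = dec$structure[dec$scale == "percent"])
}
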