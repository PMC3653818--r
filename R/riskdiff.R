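# Decomposition of the net change in disease burden between two periods or
# areas (Bashir-Esteve partition): the change in total cases splits exactly
# into a population-size component, a population-structure component, and a
# residual risk component. With reference counts C1_i and person-years Y1_i
# (rates r_i = C1_i / Y1_i, totals N1, N2):
#
#   net       = sum(C2) - sum(C1)
#   size      = sum(C1) * (N2/N1 - 1)          (uniform population growth)
#   structure = sum(r_i Y2_i) - sum(C1) * N2/N1 (age-pyramid shift at old rates)
#   risk      = sum(C2) - sum(r_i Y2_i)        (residual: changed rates)
#
# so net = risk + size + structure by construction. On the percent scale
# each term is divided by sum(C1); on the crude-rate scale the partition is
# applied to CR2 - CR1, where the size term vanishes. The ordering
# convention (size first, structure second, risk as residual) is fixed:
# component values depend on it.

#' Decompose the net change in cases between two periods or areas
#'
#' Partitions the difference in total cases (and in the crude rate) between
#' a reference and a target population into risk, population-size and
#' population-structure components, on three scales: absolute cases,
#' percent of the reference total, and crude rate per 100,000 person-years.
#' Rates within each period are treated as constant (inputs pooled over the
#' period). No significance assessment is attached to the components.
#'
#' @param ref_cases,ref_person_years Reference (first period/area) case
#'   counts and person-years per age group.
#' @param target_cases,target_person_years Target (second period/area)
#'   counts and person-years on the same age-group scheme.
#' @return Object of class `riskdiff_decomposition`: a data frame with one
#'   row per scale (`absolute_cases`, `percent`, `crude_rate_per_100k`) and
#'   columns `net`, `risk`, `size`, `structure`, `population`
#'   (= size + structure). `risk + size + structure = net` holds exactly on
#'   every scale.
#' @examples
#' decompose_net_change(c(10, 10), c(1000, 1000), c(10, 30), c(1000, 2000))
#' @export
decompose_net_change <- function(ref_cases, ref_person_years,
                                 target_cases, target_person_years) {
  k <- length(ref_cases)
  if (length(ref_person_years) != k || length(target_cases) != k ||
      length(target_person_years) != k) {
    stop("both periods must share one age-group scheme", call. = FALSE)
  }
  if (any(ref_person_years <= 0) || any(target_person_years <= 0)) {
    stop("person-years must be positive in every age group of both periods",
         call. = FALSE)
  }
  C1 <- sum(ref_cases); C2 <- sum(target_cases)
  N1 <- sum(ref_person_years); N2 <- sum(target_person_years)
  r <- ref_cases / ref_person_years
  at_old_rates <- sum(r * target_person_years)

  net_abs <- C2 - C1
  size_abs <- C1 * (N2 / N1 - 1)
  structure_abs <- at_old_rates - C1 * N2 / N1
  risk_abs <- C2 - at_old_rates

  if (C1 == 0) {
    pct <- rep(NA_real_, 4)
    warning("reference period has zero cases; percent scale undefined",
            call. = FALSE)
  } else {
    pct <- 100 * c(net_abs, risk_abs, size_abs, structure_abs) / C1
  }

  scale_cr <- 1e5 / N2
  out <- data.frame(
    scale = c("absolute_cases", "percent", "crude_rate_per_100k"),
    net = c(net_abs, pct[1], 1e5 * (C2 / N2 - C1 / N1)),
    risk = c(risk_abs, pct[2], risk_abs * scale_cr),
    size = c(size_abs, pct[3], 0),
    structure = c(structure_abs, pct[4],
                  1e5 * (at_old_rates / N2 - C1 / N1)),
    stringsAsFactors = FALSE)
  out$population <- out$size + out$structure
  class(out) <- c("riskdiff_decomposition", "data.frame")
  out
}

#' @export
print.riskdiff_decomposition <- function(x, digits = 3, ...) {
  cat("Net-change decomposition (net = risk + size + structure):\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
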