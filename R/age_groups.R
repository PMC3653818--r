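#' Age-group schemes
#'
#' An age-group scheme partitions age (in completed years) into ordered,
#' contiguous half-open intervals `[lower, upper)`. The first interval must
#' start at 0 and only the last interval may be open-ended (`upper = Inf`).
#' The default scheme is the conventional eighteen 5-year groups
#' 0-4, 5-9, ..., 80-84, 85+.
#'
#' @param lower Integer vector of lower bounds, starting at 0, strictly
#'   increasing.
#' @param upper Integer vector of upper bounds (exclusive); the last may be
#'   `Inf` (or `NA`, treated as open-ended). Defaults to contiguous bounds
#'   derived from `lower`.
#' @return An object of class `age_scheme`: a data frame with columns
#'   `age_group` (1-based index), `lower`, `upper`, `label`.
#' @examples
#' age_scheme()                  # 18 five-year groups 0-4 ... 85+
#' age_scheme(c(0, 15, 65))      # 0-14, 15-64, 65+
#' @export
age_scheme <- function(lower = seq(0, 85, by = 5),
                       upper = c(lower[-1], Inf)) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  upper[is.na(upper)] <- Inf
  if (length(lower) != length(upper)) {
    stop("'lower' and 'upper' must have the same length", call. = FALSE)
  }
  if (lower[1] != 0) {
    stop("age-group scheme must start at age 0", call. = FALSE)
  }
  if (any(diff(lower) <= 0) || any(upper <= lower)) {
    stop("age groups must be strictly increasing and non-empty", call. = FALSE)
  }
  k <- length(lower)
  if (any(is.infinite(upper[-k]))) {
    stop("only the last age group may be open-ended", call. = FALSE)
  }
  if (k > 1 && any(upper[-k] != lower[-1])) {
    stop("age groups must be contiguous (upper[i] == lower[i+1])",
         call. = FALSE)
  }
  label <- ifelse(is.infinite(upper),
                  paste0(lower, "+"),
                  paste0(lower, "-", upper - 1))
  out <- data.frame(age_group = seq_len(k), lower = lower, upper = upper,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("age_scheme", "data.frame")
  out
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("Age-group scheme with", nrow(x), "groups:",
      paste(x$label, collapse = ", "), "\n")
  invisible(x)
}

n_groups <- function(scheme) nrow(scheme)

#' Map ages to age-group indices
#'
#' Ages at or above the lower bound of the final group map into that group,
#' including when the scheme's last interval is closed (ages beyond the last
#' closed interval fall into the final group).
#'
#' @param age Numeric vector of ages in completed years.
#' @param scheme An [age_scheme()].
#' @return Integer vector of 1-based age-group indices.
#' @export
age_to_group <- function(age, scheme = age_scheme()) {
  if (any(age < 0, na.rm = TRUE)) {
    stop("negative age", call. = FALSE)
  }
  idx <- findInterval(age, scheme$lower)
  idx[idx > nrow(scheme)] <- nrow(scheme)
  as.integer(idx)
}

# widths in years; infinite for an open-ended final group
group_widths <- function(scheme) scheme$upper - scheme$lower
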