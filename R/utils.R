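#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows across all_of pull rename n
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Cost categories: the four input-category columns every ledger, matrix and
# allocation result is broken down by.
COST_CATEGORIES <- c("drugs_supplies", "staffing", "other_recurrent", "fixed")

FACILITY_LEVELS <- c("community", "2", "3", "4", "5", "6", "nursing_home",
                     "admin_district", "admin_province", "ministry")
TRUSTEES <- c("public", "fbo_ngo", "private")

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds away from zero), used for all
#' report-level figures. Base `round()` rounds half to even, which does not
#' match how published cost tables are rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(2.5)   # 3, where round(2.5) gives 2
#' round_half_away(-2.5)  # -3
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so values that are exactly .5 in decimal but stored
  # fractionally below it in binary still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g (got %g)", name, min, x))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g (got %g)", name, min, x))
  }
  invisible(x)
}

assert_has_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
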