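#' Annual cost of a dosing regimen
#'
#' Treatment cost over a 12-month course: price per vial x vials per
#' administration x administrations per year.
#'
#' @param price_per_vial Price of one vial (currency units).
#' @param vials_per_administration Vials given at each administration.
#' @param administrations_per_year Administrations over the year (12 for a
#'   monthly schedule).
#' @param permissive Allow zero counts (cost 0) instead of erroring.
#' @return Annual cost (currency units / year).
#' @export
#' @examples
#' annual_cost(1319.39, 2, 12)  # 31665.36
annual_cost <- function(price_per_vial, vials_per_administration,
                        administrations_per_year, permissive = FALSE) {
  counts <- c(vials_per_administration, administrations_per_year)
  if (any(counts != round(counts))) {
    abort_mcda("vials and administrations per year must be whole numbers")
  }
  lo <- if (permissive) 0 else 1
  if (any(price_per_vial <= 0) || any(counts < lo)) {
    abort_mcda("regimen values must be positive (set `permissive` to allow zero counts)")
  }
  price_per_vial * vials_per_administration * administrations_per_year
}

#' Daily average cost
#'
#' Annual cost spread over 365 days.
#'
#' @param annual Annual cost (>= 0).
#' @return Cost per day.
#' @export
#' @examples
#' round_half_up(daily_cost(31665.36))  # 86.75
daily_cost <- function(annual) {
  if (any(annual < 0)) abort_mcda("annual cost must be nonnegative")
  annual / 365
}

#' Affordability of an annual treatment cost
#'
#' Annual treatment cost as a percentage of annual household disposable
#' income, with household income taken as per-capita disposable income
#' times household size.
#'
#' @param annual Annual treatment cost (>= 0).
#' @param per_capita_income Per-capita disposable income (currency / year).
#' @param household_size Persons per household (default the calibrated
#'   2.62; see [calibrate_household_size()]).
#' @return Percentage of household disposable income.
#' @export
#' @examples
#' round_half_up(affordability(31665.36, 41314))  # 29.25
affordability <- function(annual, per_capita_income, household_size = 2.62) {
  if (any(annual < 0)) abort_mcda("annual cost must be nonnegative")
  if (any(per_capita_income <= 0)) abort_mcda("income must be positive")
  if (any(household_size <= 0)) abort_mcda("household size must be positive")
  100 * annual / (per_capita_income * household_size)
}

#' Calibrate the household-size parameter
#'
#' The affordability percentages in a published table imply a household
#' size that is rarely printed alongside them. This fits it by brute
#' force: grid search over `grid`, minimizing the maximum absolute
#' deviation between computed and target percentages over every
#' (cost, income) pair.
#'
#' @param annual_costs Numeric vector of annual treatment costs.
#' @param incomes Numeric vector of per-capita incomes.
#' @param target_percent Matrix of published percentages, rows = incomes,
#'   columns = costs.
#' @param grid Candidate household sizes (default 1.00 to 4.00 by 0.01).
#' @return List with `household_size` (best fit) and `max_abs_dev`.
#' @export
calibrate_household_size <- function(annual_costs, incomes, target_percent,
                                     grid = seq(1, 4, by = 0.01)) {
  target <- as.matrix(target_percent)
  if (!all(dim(target) == c(length(incomes), length(annual_costs)))) {
    abort_mcda("`target_percent` must be incomes x costs")
  }
  dev <- vapply(grid, function(h) {
    max(abs(100 * outer(1 / (incomes * h), annual_costs) - target))
  }, numeric(1))
  best <- which.min(dev)
  list(household_size = grid[best], max_abs_dev = dev[best])
}

#' Formulary coverage rates
#'
#' Percentage of surveyed institutions stocking the drug, per institution
#' type and overall (the overall rate uses summed counts, i.e. the
#' count-weighted mean of the per-type rates).
#'
#' @param survey Data frame with columns `type`, `stocked`, `total`.
#' @return Data frame `type`, `stocked`, `total`, `coverage_percent`,
#'   with a final `"overall"` row.
#' @export
#' @examples
#' coverage_rate(data.frame(type = "all", stocked = 34, total = 60))
coverage_rate <- function(survey) {
  need <- c("type", "stocked", "total")
  if (!is.data.frame(survey) || !all(need %in% names(survey))) {
    abort_mcda("`survey` needs columns type, stocked, total")
  }
  if (any(survey$total <= 0)) abort_mcda("institution totals must be positive")
  if (any(survey$stocked < 0 | survey$stocked > survey$total)) {
    abort_mcda("stocked counts must lie in [0, total]")
  }
  out <- survey[, need]
  out$coverage_percent <- 100 * out$stocked / out$total
  overall <- data.frame(type = "overall",
                        stocked = sum(survey$stocked),
                        total = sum(survey$total))
  overall$coverage_percent <- 100 * overall$stocked / overall$total
  rbind(out, overall)
}
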