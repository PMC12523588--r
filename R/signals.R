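#' Drug-event 2x2 contingency table
#'
#' The standard disproportionality table for one drug-event pair in a
#' spontaneous-report database: `a` = reports with the target drug and the
#' target event, `b` = target drug with other events, `c` = other drugs
#' with the target event, `d` = other drugs with other events. The case
#' count N of the signal rules is `a`.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @param event Optional event name carried through to results.
#' @return An object of class `contingency_2x2`.
#' @export
#' @examples
#' contingency_2x2(30, 70, 100, 900)
contingency_2x2 <- function(a, b, c, d, event = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort_mcda("cells a, b, c, d must be nonnegative integers")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d), event = event),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("Drug-event 2x2 table%s\n",
              if (is.null(x$event)) "" else paste0(" [", x$event, "]")))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

# internal: apply Haldane-Anscombe +0.5 to all cells
correct_cells <- function(tab) {
  tab$a <- tab$a + 0.5; tab$b <- tab$b + 0.5
  tab$c <- tab$c + 0.5; tab$d <- tab$d + 0.5
  tab
}

#' Proportional reporting ratio
#'
#' PRR = (a / (a + b)) / (c / (c + d)): the event's share of the target
#' drug's reports relative to its share of all other drugs' reports.
#'
#' @param table A `contingency_2x2`.
#' @param correction Apply the +0.5 continuity correction to all four
#'   cells; without it, zero denominators (a + b = 0, c + d = 0 or c = 0)
#'   are an error.
#' @return The PRR (dimensionless).
#' @export
prr <- function(table, correction = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  t0 <- if (correction) correct_cells(table) else table
  if (t0$a <= 0 || t0$a + t0$b <= 0 || t0$c + t0$d <= 0 || t0$c <= 0) {
    abort_mcda("PRR undefined: zero cell or zero denominator (enable `correction` to use +0.5 cells)")
  }
  (t0$a / (t0$a + t0$b)) / (t0$c / (t0$c + t0$d))
}

#' Reporting odds ratio with confidence interval
#'
#' ROR = (a d) / (b c), with a Wald (Woolf) confidence interval on the log
#' scale: exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table A `contingency_2x2` with all cells positive (or enable
#'   `correction` for +0.5 on all cells).
#' @param level Confidence level (default 0.95).
#' @param correction Haldane-Anscombe +0.5 correction for zero cells.
#' @return Named numeric vector `ror`, `ci_low`, `ci_high`.
#' @export
ror_with_ci <- function(table, level = 0.95, correction = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  check_fraction(level, "level")
  t0 <- if (correction) correct_cells(table) else table
  if (min(t0$a, t0$b, t0$c, t0$d) <= 0) {
    abort_mcda("ROR undefined: zero cell (enable `correction` to use +0.5 cells)")
  }
  ror <- (t0$a * t0$d) / (t0$b * t0$c)
  se <- sqrt(1 / t0$a + 1 / t0$b + 1 / t0$c + 1 / t0$d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(ror = ror, ci_low = exp(log(ror) - z * se), ci_high = exp(log(ror) + z * se))
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' Pearson's chi-squared on the drug-event table, with the Yates
#' continuity correction applied by default (the convention of the
#' PRR-based signal criterion).
#'
#' @param table A `contingency_2x2`.
#' @param yates Apply the Yates continuity correction (default `TRUE`).
#' @return The chi-squared statistic.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- matrix(c(table$a, table$c, table$b, table$d), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_mcda("chi-squared undefined: zero margin")
  }
  unname(suppressWarnings(stats::chisq.test(m, correct = yates))$statistic)
}

#' Dual signal rule on precomputed statistics
#'
#' Applies the two screening rules to already-computed statistics, e.g. a
#' published signal table: the PRR rule (PRR > `prr_threshold`, strict,
#' and chi-squared >= `chi2_threshold`) and the ROR rule (case count
#' >= `n_threshold` and lower confidence limit > 1, strict). A signal
#' requires both.
#'
#' @param prr_value PRR estimate.
#' @param chi2_value Chi-squared statistic.
#' @param n_case Number of drug-event co-occurrence reports.
#' @param ror_ci_low Lower limit of the ROR confidence interval.
#' @param prr_threshold,chi2_threshold,n_threshold Rule cutoffs.
#' @return List with `prr_positive`, `ror_positive`, `signal` (logical).
#' @export
#' @examples
#' signal_rule(11.60, 2069.63, 223, 11.46)$signal  # TRUE
signal_rule <- function(prr_value, chi2_value, n_case, ror_ci_low,
                        prr_threshold = 2, chi2_threshold = 4,
                        n_threshold = 3) {
  prr_pos <- prr_value > prr_threshold & chi2_value >= chi2_threshold
  ror_pos <- n_case >= n_threshold & ror_ci_low > 1
  list(prr_positive = prr_pos, ror_positive = ror_pos,
       signal = prr_pos & ror_pos)
}

#' Dual-criterion disproportionality signal
#'
#' Evaluates both published screening rules on one drug-event table and
#' flags a signal only when both are positive:
#' PRR rule: PRR > 2 and chi-squared >= 4 (strict / non-strict as
#' written); ROR rule: case count N = a >= 3 and the lower 95% confidence
#' limit of the ROR > 1.
#'
#' @param table A `contingency_2x2`.
#' @param prr_threshold PRR cutoff (exclusive; default 2).
#' @param chi2_threshold Chi-squared cutoff (inclusive; default 4).
#' @param n_threshold Minimum case count (inclusive; default 3).
#' @param ci_level Confidence level for the ROR interval (default 0.95).
#' @param yates Yates correction for the chi-squared statistic.
#' @param correction +0.5 continuity correction for zero cells in the
#'   estimators.
#' @return An object of class `signal_result`: list with `event`, `n_case`,
#'   `prr`, `chi2`, `ror`, `ror_ci_low`, `ror_ci_high`, `prr_positive`,
#'   `ror_positive`, `signal`.
#' @export
#' @examples
#' flag_signal(contingency_2x2(30, 70, 100, 900))
flag_signal <- function(table, prr_threshold = 2, chi2_threshold = 4,
                        n_threshold = 3, ci_level = 0.95, yates = TRUE,
                        correction = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  p <- prr(table, correction = correction)
  x2 <- chi2_2x2(table, yates = yates)
  r <- ror_with_ci(table, level = ci_level, correction = correction)
  rule <- signal_rule(p, x2, table$a, r[["ci_low"]],
                      prr_threshold = prr_threshold,
                      chi2_threshold = chi2_threshold,
                      n_threshold = n_threshold)
  structure(list(event = table$event, n_case = table$a, prr = p, chi2 = x2,
                 ror = r[["ror"]], ror_ci_low = r[["ci_low"]],
                 ror_ci_high = r[["ci_high"]],
                 prr_positive = rule$prr_positive,
                 ror_positive = rule$ror_positive,
                 signal = rule$signal),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf(
    "%sN = %d | PRR = %.2f, chi2 = %.2f (%s) | ROR = %.2f [%.2f, %.2f] (%s) -> signal: %s\n",
    if (is.null(x$event)) "" else paste0(x$event, ": "),
    x$n_case, x$prr, x$chi2, if (x$prr_positive) "+" else "-",
    x$ror, x$ror_ci_low, x$ror_ci_high, if (x$ror_positive) "+" else "-",
    if (x$signal) "YES" else "no"))
  invisible(x)
}

# internal: light name normalization (case folding, whitespace trimming)
normalize_term <- function(x) tolower(trimws(x))

#' Screen all events of a target drug for signals
#'
#' Tabulates one 2x2 table per event from case-level report rows
#' (`report_id`, `drug`, `event`; one row per drug-event mention within a
#' report) and evaluates the dual signal criterion for every event ever
#' co-reported with the target drug. Counts are at report level: a report
#' mentioning the drug and the event once or many times contributes one
#' unit to `a`.
#'
#' @param reports Data frame with columns `report_id`, `drug`, `event`
#'   (deduplicated reports assumed).
#' @param target_drug Drug name (matched after case folding and trimming).
#' @param ... Passed to [flag_signal()] (thresholds, corrections).
#' @return Data frame, one row per event, columns `event`, `a`, `b`, `c`,
#'   `d`, `prr`, `chi2`, `ror`, `ror_ci_low`, `ror_ci_high`,
#'   `prr_positive`, `ror_positive`, `signal`, sorted by case count then
#'   PRR (both decreasing), ties broken by event name.
#' @export
screen_events <- function(reports, target_drug, ...) {
  need <- c("report_id", "drug", "event")
  if (!is.data.frame(reports) || !all(need %in% names(reports))) {
    abort_mcda("`reports` needs columns report_id, drug, event")
  }
  if (nrow(reports) == 0L) abort_mcda("empty report table")
  reports$drug <- normalize_term(reports$drug)
  reports$event <- normalize_term(reports$event)
  target_drug <- normalize_term(target_drug)
  n_total <- length(unique(reports$report_id))
  target_ids <- unique(reports$report_id[reports$drug == target_drug])
  n_target <- length(target_ids)
  is_target <- reports$report_id %in% target_ids
  # per event: reports containing the event, split by target-drug exposure
  ev_target <- unique(reports[is_target, c("report_id", "event")])
  ev_other <- unique(reports[!is_target, c("report_id", "event")])
  events <- sort(unique(ev_target$event))
  if (length(events) == 0L) {
    return(data.frame(event = character(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), d = numeric(0), prr = numeric(0),
                      chi2 = numeric(0), ror = numeric(0),
                      ror_ci_low = numeric(0), ror_ci_high = numeric(0),
                      prr_positive = logical(0), ror_positive = logical(0),
                      signal = logical(0)))
  }
  a_tab <- table(factor(ev_target$event, levels = events))
  c_tab <- table(factor(ev_other$event, levels = events))
  rows <- lapply(events, function(e) {
    a <- as.numeric(a_tab[[e]]); cc <- as.numeric(c_tab[[e]])
    tab <- contingency_2x2(a, n_target - a, cc, (n_total - n_target) - cc,
                           event = e)
    res <- tryCatch(flag_signal(tab, ...), error = function(err) NULL)
    if (is.null(res)) {
      return(data.frame(event = e, a = a, b = n_target - a, c = cc,
                        d = (n_total - n_target) - cc,
                        prr = NA_real_, chi2 = NA_real_, ror = NA_real_,
                        ror_ci_low = NA_real_, ror_ci_high = NA_real_,
                        prr_positive = FALSE, ror_positive = FALSE,
                        signal = FALSE))
    }
    data.frame(event = e, a = a, b = n_target - a, c = cc,
               d = (n_total - n_target) - cc,
               prr = res$prr, chi2 = res$chi2, ror = res$ror,
               ror_ci_low = res$ror_ci_low, ror_ci_high = res$ror_ci_high,
               prr_positive = res$prr_positive, ror_positive = res$ror_positive,
               signal = res$signal)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$a, ifelse(is.na(out$prr), Inf, -out$prr), out$event), ]
  rownames(out) <- NULL
  out
}
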