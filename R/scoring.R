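#' Expert score panel
#'
#' Validates a long-format panel of evidence-based expert scores: one row
#' per (expert, strategy, criterion) with an integer score on the 1-10
#' scale. Missing cells may simply be absent; they are excluded from
#' summaries with a reported count.
#'
#' @param scores Data frame with columns `expert_id`, `strategy`,
#'   `criterion`, `score`.
#' @return An object of class `score_panel` (the validated data frame).
#' @export
score_panel <- function(scores) {
  need <- c("expert_id", "strategy", "criterion", "score")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    abort_mcda("`scores` needs columns expert_id, strategy, criterion, score")
  }
  if (nrow(scores) == 0L) abort_mcda("empty score panel")
  s <- scores$score
  bad <- which(is.na(s) | s != as.integer(s) | s < 1 | s > 10)
  if (length(bad)) {
    abort_mcda(sprintf("score out of range at row %d: %s (must be an integer in 1..10)",
                       bad[1], format(s[bad[1]])))
  }
  dup <- duplicated(scores[, c("expert_id", "strategy", "criterion")])
  if (any(dup)) {
    abort_mcda(sprintf("duplicate score for expert '%s', strategy '%s', criterion '%s'",
                       scores$expert_id[dup][1], scores$strategy[dup][1],
                       scores$criterion[dup][1]))
  }
  structure(as.data.frame(scores), class = c("score_panel", "data.frame"))
}

#' Score band of a mean expert score
#'
#' Bands the 1-10 evidence scale as poor (1-3), moderate (4-7) or
#' excellent (8-10). Non-integer means are banded by rounding half-up to
#' the nearest integer.
#'
#' @param mean_score Numeric vector of (mean) scores in \[1, 10\].
#' @return Character vector: `"poor"`, `"moderate"` or `"excellent"`.
#' @export
score_band <- function(mean_score) {
  if (any(mean_score < 1 - 1e-9 | mean_score > 10 + 1e-9, na.rm = TRUE)) {
    abort_mcda("mean scores must lie in [1, 10]")
  }
  r <- round_half_up(mean_score, 0)
  ifelse(r <= 3, "poor", ifelse(r <= 7, "moderate", "excellent"))
}

#' Summarize an expert score panel
#'
#' Mean and sample standard deviation (n - 1 denominator) of the expert
#' scores for every (strategy, criterion) cell, with the number of experts
#' contributing and of missing entries, and the qualitative band of the
#' mean.
#'
#' @param panel A `score_panel` (or data frame accepted by [score_panel()]).
#' @return Data frame with columns `strategy`, `criterion`, `n_experts`,
#'   `n_missing`, `esc_mean`, `esc_sd`, `band`.
#' @export
summarize_panel <- function(panel) {
  if (!inherits(panel, "score_panel")) panel <- score_panel(panel)
  experts <- unique(panel$expert_id)
  cells <- unique(panel[, c("strategy", "criterion")])
  rownames(cells) <- NULL
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- panel[panel$strategy == cells$strategy[i] &
                 panel$criterion == cells$criterion[i], ]
    data.frame(strategy = cells$strategy[i], criterion = cells$criterion[i],
               n_experts = nrow(sub),
               n_missing = length(experts) - nrow(sub),
               esc_mean = mean(sub$score),
               esc_sd = if (nrow(sub) > 1L) stats::sd(sub$score) else 0,
               stringsAsFactors = FALSE)
  }))
  out$band <- score_band(out$esc_mean)
  out
}

#' Comprehensive score of one criterion
#'
#' The comprehensive score CS of a criterion is its global weight Wc times
#' the mean expert score ESc. Arithmetic is exact; round only at display.
#'
#' @param wc Global criterion weight(s) in \[0, 1\].
#' @param esc Mean expert score(s) in \[1, 10\] (0 allowed only with wc 0).
#' @return Numeric vector of comprehensive scores (points).
#' @export
#' @examples
#' comprehensive_score(0.1982, 7.71)              # 1.528...
#' round_half_up(comprehensive_score(0.1982, 7.71))  # 1.53 as displayed
comprehensive_score <- function(wc, esc) {
  if (any(wc < 0 | wc > 1, na.rm = TRUE)) {
    abort_mcda("criterion weights must lie in [0, 1]")
  }
  if (any(esc < 0 | esc > 10, na.rm = TRUE)) {
    abort_mcda("mean expert scores must lie in [0, 10]")
  }
  wc * esc
}

#' Overall strategy value report
#'
#' Combines criterion weights with mean expert scores into per-criterion
#' comprehensive scores, domain subtotals, the overall value of each
#' strategy (the weighted sum over all criteria) and the resulting
#' ranking. Ties on the overall score are reported as ties (same rank).
#'
#' @param hierarchy A `criteria_hierarchy`, or a named numeric vector of
#'   global criterion weights (in which case domains default to one
#'   domain `"all"` unless `domains` gives a criterion -> domain map).
#' @param summaries Data frame as returned by [summarize_panel()] (columns
#'   `strategy`, `criterion`, `esc_mean`; `esc_sd` optional), covering
#'   every hierarchy criterion for every strategy.
#' @param domains Optional named character vector mapping criterion names
#'   to domain names when `hierarchy` is a bare weight vector.
#' @return An object of class `value_report`: list with `criteria` (per
#'   strategy x criterion data frame with `wc`, `esc_mean`, `esc_sd`, `cs`),
#'   `domains` (per strategy x domain CS subtotals), `overall` (data frame
#'   `strategy`, `overall_cs`, `rank`, sorted by rank).
#' @export
value_report <- function(hierarchy, summaries, domains = NULL) {
  if (inherits(hierarchy, "criteria_hierarchy")) {
    wc <- global_weights(hierarchy)
    dom_map <- stats::setNames(hierarchy$domain, hierarchy$criterion)
  } else if (is.numeric(hierarchy) && !is.null(names(hierarchy))) {
    wc <- hierarchy
    dom_map <- if (is.null(domains)) {
      stats::setNames(rep("all", length(wc)), names(wc))
    } else domains[names(wc)]
  } else {
    abort_mcda("`hierarchy` must be a criteria_hierarchy or named weights")
  }
  need <- c("strategy", "criterion", "esc_mean")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries))) {
    abort_mcda("`summaries` needs columns strategy, criterion, esc_mean")
  }
  strategies <- unique(summaries$strategy)
  missing <- do.call(rbind, lapply(strategies, function(s) {
    have <- summaries$criterion[summaries$strategy == s]
    miss <- setdiff(names(wc), have)
    if (length(miss)) data.frame(strategy = s, criterion = miss) else NULL
  }))
  if (!is.null(missing) && nrow(missing)) {
    abort_mcda(sprintf("missing score summaries for: %s",
                       paste(sprintf("%s/%s", missing$strategy, missing$criterion),
                             collapse = ", ")))
  }
  crit <- summaries[summaries$criterion %in% names(wc),
                    intersect(c(need, "esc_sd"), names(summaries))]
  crit$wc <- wc[crit$criterion]
  crit$domain <- dom_map[crit$criterion]
  crit$cs <- comprehensive_score(crit$wc, crit$esc_mean)
  # keep hierarchy display order within each strategy
  crit <- crit[order(match(crit$strategy, strategies),
                     match(crit$criterion, names(wc))), ]
  rownames(crit) <- NULL
  dom <- stats::aggregate(cs ~ strategy + domain, data = crit, FUN = sum)
  dom <- dom[order(match(dom$strategy, strategies),
                   match(dom$domain, unique(dom_map))), ]
  names(dom)[names(dom) == "cs"] <- "domain_cs"
  rownames(dom) <- NULL
  overall <- stats::aggregate(cs ~ strategy, data = crit, FUN = sum)
  names(overall)[names(overall) == "cs"] <- "overall_cs"
  overall$rank <- rank(-overall$overall_cs, ties.method = "min")
  overall <- overall[order(overall$rank, overall$strategy), ]
  rownames(overall) <- NULL
  structure(list(criteria = crit, domains = dom, overall = overall),
            class = "value_report")
}

#' @export
print.value_report <- function(x, digits = 2, ...) {
  cat("MCDA value report\n\nOverall strategy scores:\n")
  o <- x$overall
  o$overall_cs <- sprintf("%.*f", digits, round_half_up(o$overall_cs, digits))
  print(o, row.names = FALSE)
  cat("\nDomain comprehensive-score subtotals:\n")
  d <- x$domains
  d$domain_cs <- sprintf("%.*f", digits, round_half_up(d$domain_cs, digits))
  print(d, row.names = FALSE)
  invisible(x)
}
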