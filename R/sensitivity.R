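#' Domain-level effective scores of a strategy
#'
#' The effective score of a domain is the local-weight-weighted mean of
#' its criteria's mean expert scores: sum over the domain's criteria of
#' (local weight within domain) x ESc. On unrounded inputs this equals the
#' domain's comprehensive-score subtotal divided by the domain weight, so
#' a fixture built from printed (rounded) tables can use that division
#' instead (see `from_totals`).
#'
#' @param report A `value_report` whose criteria table carries per-criterion
#'   `wc` and `domain`, or `NULL` when `from_totals` is given.
#' @param from_totals Optional data frame `strategy`, `domain`, `domain_cs`
#'   of printed domain subtotals; used with `domain_weights`.
#' @param domain_weights Named numeric vector of baseline domain weights
#'   (fractions), required with `from_totals`.
#' @return Data frame `strategy`, `domain`, `domain_score` (points on the
#'   1-10 scale).
#' @export
domain_effective_scores <- function(report = NULL, from_totals = NULL,
                                    domain_weights = NULL) {
  if (!is.null(from_totals)) {
    if (is.null(domain_weights) || is.null(names(domain_weights))) {
      abort_mcda("`domain_weights` (named) required with `from_totals`")
    }
    if (any(domain_weights <= 0)) abort_mcda("zero-weight domain")
    out <- from_totals
    out$domain_score <- out$domain_cs / domain_weights[out$domain]
    return(out[, c("strategy", "domain", "domain_score")])
  }
  stopifnot(inherits(report, "value_report"))
  crit <- report$criteria
  dw <- stats::aggregate(wc ~ strategy + domain, data = crit, FUN = sum)
  names(dw)[names(dw) == "wc"] <- "domain_weight"
  if (any(dw$domain_weight <= 0)) abort_mcda("zero-weight domain")
  dom <- merge(report$domains, dw, by = c("strategy", "domain"), sort = FALSE)
  dom$domain_score <- dom$domain_cs / dom$domain_weight
  dom[, c("strategy", "domain", "domain_score")]
}

#' Weight-allocation scenario set
#'
#' Validates a table of alternative domain-weight scenarios (percent,
#' one row per scenario). Each row must cover every domain and sum to 100.
#' By default a scenario must preserve the baseline hierarchical order of
#' the domains (weakly decreasing weights along `baseline_order`); the
#' check can be overridden for published scenario sets that bump a single
#' domain out of order.
#'
#' @param weights Numeric matrix or data frame, rows = scenarios, columns
#'   named after the domains, entries in percent.
#' @param baseline_order Optional character vector of domain names in
#'   baseline weight order (heaviest first). When supplied, scenarios
#'   violating the order are refused unless `allow_reorder = TRUE`.
#' @param allow_reorder Admit scenarios that break the baseline order.
#' @return An object of class `weight_scenarios` (numeric matrix, percent).
#' @export
weight_scenarios <- function(weights, baseline_order = NULL,
                             allow_reorder = FALSE) {
  w <- as.matrix(weights)
  if (nrow(w) == 0L) abort_mcda("at least one scenario is required")
  if (is.null(colnames(w))) abort_mcda("scenario columns must be named after domains")
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort_mcda("scenario weights must be positive and finite")
  }
  sums <- rowSums(w)
  bad <- which(abs(sums - 100) > 1e-6)
  if (length(bad)) {
    abort_mcda(sprintf("scenario %d weights sum to %.6f, not 100", bad[1], sums[bad[1]]))
  }
  if (is.null(rownames(w))) rownames(w) <- paste0("scenario_", seq_len(nrow(w)))
  if (!is.null(baseline_order) && !allow_reorder) {
    if (!setequal(baseline_order, colnames(w))) {
      abort_mcda("`baseline_order` must name exactly the scenario domains")
    }
    ord <- w[, baseline_order, drop = FALSE]
    viol <- which(apply(ord, 1, function(r) any(diff(r) > 1e-9)))
    if (length(viol)) {
      abort_mcda(sprintf(
        "scenario %d violates the baseline hierarchical order of domains (set allow_reorder = TRUE to admit it)",
        viol[1]))
    }
  }
  structure(w, class = c("weight_scenarios", "matrix", "array"))
}

#' Overall scores under a weight scenario
#'
#' Recomputes each strategy's overall comprehensive score under one
#' scenario's domain weights: sum over domains of (scenario weight / 100)
#' x domain effective score.
#'
#' @param scenario Named numeric vector of domain weights in percent
#'   (one scenario row), covering every domain in `domain_scores`.
#' @param domain_scores Data frame `strategy`, `domain`, `domain_score`
#'   as from [domain_effective_scores()].
#' @return Named numeric vector of overall CS per strategy.
#' @export
apply_scenario <- function(scenario, domain_scores) {
  doms <- unique(domain_scores$domain)
  if (!all(doms %in% names(scenario))) {
    abort_mcda(sprintf("scenario is missing domains: %s",
                       paste(setdiff(doms, names(scenario)), collapse = ", ")))
  }
  strategies <- unique(domain_scores$strategy)
  vapply(stats::setNames(strategies, strategies), function(s) {
    sub <- domain_scores[domain_scores$strategy == s, ]
    sum(scenario[sub$domain] / 100 * sub$domain_score)
  }, numeric(1))
}

#' Rank stability across weight scenarios
#'
#' Applies every scenario, ranks the strategies under each, and declares
#' the analysis stable when every scenario reproduces the baseline
#' ranking. The margin (overall-CS difference between the top two
#' strategies) is reported per scenario so near-ties remain visible.
#'
#' @param baseline_weights Named numeric vector of baseline domain weights
#'   (percent or fractions; only relative size matters for the ranking,
#'   but percent is expected for the scenario table).
#' @param scenarios A `weight_scenarios` object (or matrix accepted by
#'   [weight_scenarios()]).
#' @param domain_scores Data frame from [domain_effective_scores()].
#' @return An object of class `stability_result`: list with `baseline`
#'   (named CS vector), `baseline_ranking` (strategies, best first),
#'   `scenario_cs` (matrix scenarios x strategies), `rankings` (list of
#'   character vectors), `margins` (numeric per scenario), `stable`.
#' @export
check_rank_stability <- function(baseline_weights, scenarios, domain_scores) {
  if (!inherits(scenarios, "weight_scenarios")) {
    scenarios <- weight_scenarios(scenarios)
  }
  bw <- baseline_weights / sum(baseline_weights) * 100
  base_cs <- apply_scenario(bw, domain_scores)
  base_rank <- names(sort(base_cs, decreasing = TRUE))
  per <- lapply(seq_len(nrow(scenarios)), function(i) {
    cs <- apply_scenario(scenarios[i, ], domain_scores)
    list(cs = cs, ranking = names(sort(cs, decreasing = TRUE)),
         margin = if (length(cs) > 1) diff(sort(cs, decreasing = TRUE)[2:1]) else NA_real_)
  })
  cs_mat <- do.call(rbind, lapply(per, `[[`, "cs"))
  rownames(cs_mat) <- rownames(scenarios)
  rankings <- lapply(per, `[[`, "ranking")
  names(rankings) <- rownames(scenarios)
  structure(list(
    baseline = base_cs,
    baseline_ranking = base_rank,
    scenario_cs = cs_mat,
    rankings = rankings,
    margins = stats::setNames(vapply(per, `[[`, numeric(1), "margin"),
                              rownames(scenarios)),
    stable = all(vapply(rankings, identical, logical(1), base_rank))
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Rank stability across %d scenarios: %s\n",
              nrow(x$scenario_cs), if (x$stable) "STABLE" else "NOT stable"))
  cat("Baseline ranking:", paste(x$baseline_ranking, collapse = " > "), "\n\n")
  tab <- cbind(round_half_up(x$scenario_cs, 2),
               margin = round_half_up(x$margins, 4))
  print(tab)
  invisible(x)
}
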