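#' Compose a two-level criteria hierarchy
#'
#' Builds a hierarchy of value domains and their criteria from a vector of
#' domain weights and one local weight vector per domain. Each criterion's
#' global weight is the product of its domain's weight and its local weight
#' within the domain, so global weights sum to 1.
#'
#' Weight vectors are expected to sum to 1 within 1e-6; vectors that do not
#' are renormalized with a warning (printed weight tables often sum to
#' slightly more or less than 100% after rounding).
#'
#' @param domain_weights Named numeric vector of domain weights (fractions).
#' @param criterion_weights Named list, one element per domain (same names,
#'   same order), each a named numeric vector of local criterion weights.
#' @return An object of class `criteria_hierarchy`: a data frame with
#'   columns `domain`, `criterion`, `domain_weight`, `local_weight`,
#'   `global_weight`, plus attribute `domains` (named domain weights).
#' @export
#' @examples
#' h <- compose_hierarchy(
#'   c(safety = 0.6, economics = 0.4),
#'   list(safety = c(pre_market = 0.5, post_market = 0.5),
#'        economics = c(cost = 1)))
#' sum(h$global_weight)  # 1
compose_hierarchy <- function(domain_weights, criterion_weights) {
  if (is.null(names(domain_weights)) || any(names(domain_weights) == "")) {
    abort_mcda("`domain_weights` must be named")
  }
  if (anyDuplicated(names(domain_weights))) {
    abort_mcda("duplicate domain names")
  }
  if (!setequal(names(criterion_weights), names(domain_weights))) {
    abort_mcda("`criterion_weights` must have one element per domain, same names")
  }
  criterion_weights <- criterion_weights[names(domain_weights)]
  dw <- renormalize(domain_weights, "domain weights")
  rows <- lapply(names(dw), function(d) {
    lw <- renormalize(criterion_weights[[d]], sprintf("criteria of domain '%s'", d))
    if (is.null(names(lw)) || any(names(lw) == "")) {
      abort_mcda(sprintf("criterion weights of domain '%s' must be named", d))
    }
    data.frame(domain = d, criterion = names(lw),
               domain_weight = dw[[d]], local_weight = as.numeric(lw),
               global_weight = dw[[d]] * as.numeric(lw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$criterion)) {
    abort_mcda(sprintf("duplicate criterion names: %s",
                       paste(unique(out$criterion[duplicated(out$criterion)]),
                             collapse = ", ")))
  }
  rownames(out) <- NULL
  structure(out, class = c("criteria_hierarchy", "data.frame"), domains = dw)
}

# internal: force a weight vector onto the simplex, warning beyond 1e-6
renormalize <- function(w, what) {
  if (!is.numeric(w) || length(w) == 0L || any(!is.finite(w)) || any(w < 0)) {
    abort_mcda(sprintf("%s must be nonnegative finite numbers", what))
  }
  s <- sum(w)
  if (s <= 0) abort_mcda(sprintf("%s sum to zero", what))
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("%s sum to %.6f; renormalizing to 1", what, s),
            call. = FALSE)
  }
  w / s
}

#' @export
print.criteria_hierarchy <- function(x, ...) {
  cat(sprintf("Criteria hierarchy: %d domains, %d criteria\n",
              length(attr(x, "domains")), nrow(x)))
  df <- as.data.frame(x)
  df$domain_weight <- round(df$domain_weight, 4)
  df$local_weight <- round(df$local_weight, 4)
  df$global_weight <- round(df$global_weight, 4)
  print(df)
  invisible(x)
}

#' Global criterion weights of a hierarchy
#'
#' @param hierarchy A `criteria_hierarchy`.
#' @return Named numeric vector of global weights (sums to 1).
#' @export
global_weights <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "criteria_hierarchy"))
  stats::setNames(hierarchy$global_weight, hierarchy$criterion)
}

#' Full AHP weighting pipeline for a two-level hierarchy
#'
#' Given one (or several, per expert) judgment matrices for the domain
#' level and for each domain's criteria, aggregates experts, extracts
#' priority weights, checks consistency and composes the hierarchy.
#'
#' @param domain_judgments A `pcm` or list of per-expert `pcm`s comparing
#'   the domains.
#' @param criterion_judgments Named list (by domain): each element a `pcm`
#'   or list of per-expert `pcm`s comparing that domain's criteria.
#' @param expert_weights Optional authority coefficients for the experts,
#'   used in the geometric-mean aggregation.
#' @param cr_threshold Consistency-ratio acceptability threshold.
#' @return A list with `hierarchy` (a `criteria_hierarchy`) and
#'   `consistency` (list of `ahp_consistency`, one per node, named
#'   `"domains"` and after each domain).
#' @export
ahp_hierarchy_weights <- function(domain_judgments, criterion_judgments,
                                  expert_weights = NULL, cr_threshold = 0.1) {
  one_node <- function(j) {
    if (is.numeric(j) && !is.matrix(j)) {
      # degenerate node (e.g. a one-criterion domain): weights given directly
      return(list(weights = j / sum(j), consistency = NULL))
    }
    m <- if (inherits(j, "pcm")) j else aggregate_judgments(j, expert_weights)
    list(weights = ahp_weights(m)$weights,
         consistency = ahp_consistency(m, threshold = cr_threshold))
  }
  dom <- one_node(domain_judgments)
  if (is.null(names(dom$weights))) {
    names(dom$weights) <- names(criterion_judgments)
  }
  crit <- lapply(criterion_judgments, one_node)
  hierarchy <- compose_hierarchy(dom$weights,
                                 lapply(crit, function(x) x$weights))
  consistency <- c(list(domains = dom$consistency),
                   lapply(crit, function(x) x$consistency))
  list(hierarchy = hierarchy, consistency = consistency)
}
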