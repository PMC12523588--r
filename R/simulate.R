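# Seeded simulators for every input the pipeline consumes. Each generator
# derives its own RNG stream from the master seed by a fixed offset, so
# adding a generator never shifts the draws of an existing one.

.seed_offsets <- c(judgments = 101L, scores = 202L, reports = 303L)

with_stream <- function(seed, which, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + .seed_offsets[[which]]) %% .Machine$integer.max)
  expr
}

#' Simulate expert judgment matrices around true weights
#'
#' Draws per-expert pairwise comparison matrices for one hierarchy node:
#' each upper-triangle entry is (w_i / w_j) * exp(eps) with
#' eps ~ Normal(0, sigma^2), optionally snapped to the nearest Saaty scale
#' value; the lower triangle is filled with exact reciprocals. With
#' sigma = 0 and no snapping the matrices are perfectly consistent and the
#' AHP pipeline recovers `true_weights` exactly.
#'
#' @param true_weights Positive named numeric vector of ground-truth
#'   weights for the node's elements.
#' @param n_experts Number of experts (>= 1).
#' @param sigma Log-scale multiplicative noise standard deviation (>= 0).
#' @param snap Snap entries to the admissible Saaty values.
#' @param seed Master seed; the judgment stream is derived from it.
#' @return List of `n_experts` `pcm` objects.
#' @export
simulate_judgments <- function(true_weights, n_experts, sigma = 0,
                               snap = FALSE, seed = 1L) {
  stopifnot(is.numeric(true_weights), length(true_weights) >= 2,
            all(true_weights > 0), n_experts >= 1, sigma >= 0)
  n <- length(true_weights)
  base <- outer(true_weights, true_weights, "/")
  with_stream(seed, "judgments", {
    lapply(seq_len(n_experts), function(k) {
      m <- base
      up <- which(upper.tri(m))
      m[up] <- m[up] * exp(stats::rnorm(length(up), 0, sigma))
      if (snap) m[up] <- snap_to_saaty(m[up])
      m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
      diag(m) <- 1
      if (!is.null(names(true_weights))) {
        dimnames(m) <- list(names(true_weights), names(true_weights))
      }
      pcm(m, permissive = TRUE)
    })
  })
}

#' Simulate an expert score panel around true criterion means
#'
#' Draws integer expert scores from a discretized truncated normal: a
#' Normal(mean, dispersion) draw rounded to the nearest integer and
#' clipped to \[1, 10\]. With dispersion 0 every expert emits the rounded
#' mean; as the panel grows the empirical means converge to the truth.
#'
#' @param means Data frame with columns `strategy`, `criterion`, `mean`
#'   (true mean score on the 1-10 scale) and optionally `sd` (dispersion,
#'   default 0).
#' @param n_experts Number of experts.
#' @param seed Master seed; the score stream is derived from it.
#' @return A `score_panel` with experts `"E1"`, `"E2"`, ...
#' @export
simulate_scores <- function(means, n_experts, seed = 1L) {
  need <- c("strategy", "criterion", "mean")
  if (!is.data.frame(means) || !all(need %in% names(means))) {
    abort_mcda("`means` needs columns strategy, criterion, mean")
  }
  if (is.null(means$sd)) means$sd <- 0
  stopifnot(n_experts >= 1, all(means$sd >= 0),
            all(means$mean >= 1 & means$mean <= 10))
  with_stream(seed, "scores", {
    rows <- lapply(seq_len(nrow(means)), function(i) {
      draws <- stats::rnorm(n_experts, means$mean[i], means$sd[i])
      score <- pmin(10, pmax(1, round_half_up(draws, 0)))
      data.frame(expert_id = paste0("E", seq_len(n_experts)),
                 strategy = means$strategy[i],
                 criterion = means$criterion[i],
                 score = as.integer(score),
                 stringsAsFactors = FALSE)
    })
    score_panel(do.call(rbind, rows))
  })
}

#' Simulate a case-level spontaneous-report table
#'
#' Emulates a spontaneous adverse-event reporting database: each report is
#' assigned a drug (the target drug with probability `target_share`,
#' otherwise a background drug) and one event drawn from the background
#' event distribution. For the target drug, the probabilities of events
#' listed in `signal_lambda` are multiplied by their reporting-rate ratio
#' lambda and the distribution renormalized, implanting disproportionality
#' signals of chosen strength.
#'
#' @param n_reports Number of reports.
#' @param event_probs Named numeric vector of background event
#'   probabilities (must sum to 1 within 1e-9).
#' @param target_share Fraction of reports mentioning the target drug.
#' @param signal_lambda Named numeric vector of reporting-rate ratios
#'   (names must appear in `event_probs`); lambda = 1 means no signal.
#' @param target_drug,background_drug Drug labels used in the output.
#' @param seed Master seed; the report stream is derived from it.
#' @return Data frame `report_id`, `drug`, `event` readable by
#'   [screen_events()].
#' @export
simulate_reports <- function(n_reports, event_probs, target_share,
                             signal_lambda = numeric(0),
                             target_drug = "target_drug",
                             background_drug = "other_drug", seed = 1L) {
  stopifnot(n_reports >= 1, all(event_probs > 0))
  if (abs(sum(event_probs) - 1) > 1e-9) {
    abort_mcda("`event_probs` must sum to 1")
  }
  if (is.null(names(event_probs))) abort_mcda("`event_probs` must be named")
  check_fraction(target_share, "target_share")
  if (length(signal_lambda)) {
    if (any(signal_lambda <= 0) ||
        !all(names(signal_lambda) %in% names(event_probs))) {
      abort_mcda("`signal_lambda` must be positive and name known events")
    }
  }
  p_target <- event_probs
  p_target[names(signal_lambda)] <- p_target[names(signal_lambda)] * signal_lambda
  p_target <- p_target / sum(p_target)
  with_stream(seed, "reports", {
    is_target <- stats::runif(n_reports) < target_share
    events <- character(n_reports)
    if (any(is_target)) {
      events[is_target] <- sample(names(event_probs), sum(is_target),
                                  replace = TRUE, prob = p_target)
    }
    if (any(!is_target)) {
      events[!is_target] <- sample(names(event_probs), sum(!is_target),
                                   replace = TRUE, prob = event_probs)
    }
    data.frame(report_id = sprintf("R%07d", seq_len(n_reports)),
               drug = ifelse(is_target, target_drug, background_drug),
               event = events, stringsAsFactors = FALSE)
  })
}
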