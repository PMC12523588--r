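# File ingestion, validation and report rendering. All tabular I/O is
# UTF-8 comma-separated text with a header row; judgment files may carry
# fractional entries as "1/3"-style strings.

parse_ratio <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  frac <- grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", x)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/")
    out[frac] <- vapply(parts, function(p) {
      as.numeric(p[1]) / as.numeric(p[2])
    }, numeric(1))
  }
  out
}

#' Read a judgment matrix file
#'
#' Reads one expert's pairwise comparison matrix for one hierarchy node
#' from a comma-separated file whose first row and first column carry the
#' element names. Entries may be decimal numbers or fractions written as
#' `"1/3"`. Only the upper triangle need be filled; empty lower-triangle
#' cells are completed with reciprocals.
#'
#' @param path File path.
#' @param node Optional node name (defaults to the file name).
#' @param permissive Passed to [pcm()].
#' @return A `pcm` object.
#' @export
read_judgment_matrix <- function(path, node = NULL, permissive = FALSE) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m <- apply(as.matrix(raw), c(1, 2), parse_ratio)
  if (!identical(rownames(m), colnames(m))) {
    abort_mcda(sprintf("'%s': row and column names must match", path))
  }
  pcm(m, node = if (is.null(node)) basename(path) else node,
      permissive = permissive)
}

#' Write a judgment matrix file
#'
#' @param matrix A `pcm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_judgment_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pcm"))
  m <- unclass(matrix)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("item_", seq_len(nrow(m)))
  }
  utils::write.csv(as.data.frame(m), path, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an expert roster
#'
#' Comma-separated file with columns `expert_id`, `ca`, `cs`.
#'
#' @param path File path.
#' @return Data frame with authority coefficients added (see
#'   [panel_authority()]).
#' @export
read_expert_roster <- function(path) {
  panel_authority(utils::read.csv(path, stringsAsFactors = FALSE,
                                  fileEncoding = "UTF-8"))
}

#' Read a long-format score panel
#'
#' Comma-separated file with columns `expert_id`, `strategy`, `criterion`,
#' `score`.
#'
#' @param path File path.
#' @return A `score_panel`.
#' @export
read_score_panel <- function(path) {
  score_panel(utils::read.csv(path, stringsAsFactors = FALSE,
                              fileEncoding = "UTF-8"))
}

#' Read weight scenarios
#'
#' Comma-separated file, one row per scenario: a `scenario_id` column plus
#' one column per domain with weights in percent.
#'
#' @param path File path.
#' @param ... Passed to [weight_scenarios()].
#' @return A `weight_scenarios` matrix.
#' @export
read_scenarios <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  ids <- if ("scenario_id" %in% names(df)) df$scenario_id else seq_len(nrow(df))
  m <- as.matrix(df[, setdiff(names(df), "scenario_id"), drop = FALSE])
  rownames(m) <- as.character(ids)
  weight_scenarios(m, ...)
}

#' Read a case-level report table
#'
#' Comma-separated file with columns `report_id`, `drug`, `event`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_reports <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("report_id", "drug", "event")
  if (!all(need %in% names(df))) {
    abort_mcda(sprintf("'%s' needs columns %s", path,
                       paste(need, collapse = ", ")))
  }
  df
}

#' Write a value report
#'
#' Writes the per-criterion table (mean +/- SD and CS per strategy,
#' mirroring the published layout) as CSV and, optionally, the complete
#' report at full precision as JSON.
#'
#' @param report A `value_report`.
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_value_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "value_report"))
  utils::write.csv(report$criteria, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (!is.null(json_path)) {
    # I(17) = 17 significant digits, enough to round-trip doubles exactly
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = I(17), dataframe = "rows")
  }
  invisible(path)
}

#' Read a value report written by [write_value_report()]
#'
#' @param json_path JSON path written with `json_path` above.
#' @return A `value_report`.
#' @export
read_value_report <- function(json_path) {
  x <- jsonlite::fromJSON(json_path, simplifyDataFrame = TRUE)
  structure(list(criteria = as.data.frame(x$criteria),
                 domains = as.data.frame(x$domains),
                 overall = as.data.frame(x$overall)),
            class = "value_report")
}

#' Validate pipeline input files
#'
#' Checks every supplied file against its schema and collects all
#' violations instead of failing at the first. Recognized roles:
#' `judgments` (character vector of judgment-matrix files), `roster`,
#' `panel`, `scenarios`, `reports`.
#'
#' @param paths Named list of file paths by role.
#' @return Data frame `role`, `path`, `message` (zero rows when all inputs
#'   are valid), with attribute `valid`.
#' @export
validate_inputs <- function(paths) {
  checks <- list(
    judgments = read_judgment_matrix, roster = read_expert_roster,
    panel = read_score_panel, scenarios = read_scenarios,
    reports = read_reports)
  problems <- list()
  note <- function(role, path, msg) {
    problems[[length(problems) + 1L]] <<- data.frame(
      role = role, path = path, message = msg, stringsAsFactors = FALSE)
  }
  for (role in names(paths)) {
    if (!role %in% names(checks)) {
      note(role, NA_character_, sprintf("unknown input role '%s'", role))
      next
    }
    for (p in paths[[role]]) {
      if (!file.exists(p)) {
        note(role, p, "file does not exist")
        next
      }
      tryCatch(checks[[role]](p),
               error = function(e) note(role, p, conditionMessage(e)),
               warning = function(w) note(role, p, conditionMessage(w)))
    }
  }
  out <- if (length(problems)) do.call(rbind, problems) else
    data.frame(role = character(0), path = character(0),
               message = character(0), stringsAsFactors = FALSE)
  attr(out, "valid") <- nrow(out) == 0L
  out
}

#' Run the full comprehensive-value pipeline
#'
#' Ties the stages together: AHP weighting from expert judgments (or given
#' weights), panel summarization and overall scoring, weight-scenario
#' sensitivity analysis, adverse-event signal screening and the
#' economics/accessibility calculators. All outputs plus a run manifest
#' (package version, seed, output listing) are written to `out_dir`; on
#' any stage failure partial outputs are removed.
#'
#' @param config Named list with components:
#'   \describe{
#'     \item{hierarchy}{either a `criteria_hierarchy`, or a list with
#'       `domain_judgments` and `criterion_judgments` as in
#'       [ahp_hierarchy_weights()], or a named numeric vector of global
#'       criterion weights plus `domains` map.}
#'     \item{panel}{a `score_panel` or path to one.}
#'     \item{scenarios}{optional `weight_scenarios` or path.}
#'     \item{reports}{optional case-level report table or path, with
#'       `target_drug`.}
#'     \item{economics}{optional list with `price_per_vial`,
#'       `vials_per_administration`, `administrations_per_year`,
#'       `per_capita_income`, `household_size`, and optional `coverage`
#'       survey data frame.}
#'     \item{signal_thresholds}{optional list overriding `prr_threshold`,
#'       `chi2_threshold`, `n_threshold`, `ci_level`.}
#'     \item{seed}{integer seed recorded in the manifest.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `report`, `stability`, `signals`,
#'   `economics` (whichever stages ran).
#' @export
run_pipeline <- function(config, out_dir) {
  if (!is.list(config)) abort_mcda("`config` must be a list")
  if (is.null(config$panel)) abort_mcda("config$panel is required")
  if (is.character(config$panel) && !file.exists(config$panel)) {
    abort_mcda(sprintf("panel file '%s' does not exist", config$panel))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    written <<- c(written, p)
    p
  }

  # -- weighting stage
  h <- config$hierarchy
  if (inherits(h, "criteria_hierarchy")) {
    weights <- global_weights(h)
    dom_map <- stats::setNames(h$domain, h$criterion)
  } else if (is.list(h) && !is.null(h$domain_judgments)) {
    fit <- ahp_hierarchy_weights(h$domain_judgments, h$criterion_judgments,
                                 expert_weights = h$expert_weights)
    weights <- global_weights(fit$hierarchy)
    dom_map <- stats::setNames(fit$hierarchy$domain, fit$hierarchy$criterion)
  } else if (is.numeric(h) && !is.null(names(h))) {
    weights <- h
    dom_map <- config$domains
    if (is.null(dom_map)) {
      dom_map <- stats::setNames(rep("all", length(h)), names(h))
    }
  } else {
    abort_mcda("config$hierarchy must be a hierarchy, judgments, or named weights")
  }

  # -- scoring stage
  panel <- config$panel
  if (is.character(panel)) panel <- read_score_panel(panel)
  summaries <- summarize_panel(panel)
  report <- value_report(weights, summaries, domains = dom_map)
  write_value_report(report, file.path(out_dir, "value_report.csv"),
                     json_path = file.path(out_dir, "value_report.json"))
  written <- c(written, file.path(out_dir, c("value_report.csv",
                                             "value_report.json")))

  # -- sensitivity stage
  stability <- NULL
  if (!is.null(config$scenarios)) {
    scen <- config$scenarios
    if (is.character(scen)) scen <- read_scenarios(scen, allow_reorder = TRUE)
    dscores <- domain_effective_scores(report)
    dw <- tapply(weights, dom_map[names(weights)], sum)
    stability <- check_rank_stability(dw[colnames(scen)], scen, dscores)
    emit(data.frame(scenario = rownames(stability$scenario_cs),
                    stability$scenario_cs,
                    margin = stability$margins, check.names = FALSE),
         "sensitivity.csv")
  }

  # -- signal stage
  signals <- NULL
  if (!is.null(config$reports)) {
    rep_tab <- config$reports
    if (is.character(rep_tab)) rep_tab <- read_reports(rep_tab)
    if (is.null(config$target_drug)) {
      abort_mcda("config$target_drug is required with config$reports")
    }
    th <- config$signal_thresholds
    signals <- do.call(screen_events,
                       c(list(reports = rep_tab,
                              target_drug = config$target_drug), th))
    emit(signals, "signals.csv")
  }

  # -- economics stage
  econ_out <- NULL
  ec <- config$economics
  if (!is.null(ec)) {
    ann <- annual_cost(ec$price_per_vial, ec$vials_per_administration,
                       ec$administrations_per_year)
    rows <- data.frame(
      scenario = names(ann) %||% seq_along(ann),
      annual_cost = ann, daily_cost = daily_cost(ann))
    if (!is.null(ec$per_capita_income)) {
      hs <- ec$household_size %||% 2.62
      aff <- outer(ec$per_capita_income, ann,
                   function(inc, a) affordability(a, inc, hs))
      for (i in seq_along(ec$per_capita_income)) {
        rows[[paste0("affordability_", names(ec$per_capita_income)[i])]] <-
          aff[i, ]
      }
    }
    econ_out <- list(costs = rows)
    emit(rows, "economics.csv")
    if (!is.null(ec$coverage)) {
      econ_out$coverage <- coverage_rate(ec$coverage)
      emit(econ_out$coverage, "coverage.csv")
    }
  }

  manifest <- list(
    package = "mcdaval",
    version = as.character(utils::packageVersion("mcdaval")),
    seed = config$seed %||% NA,
    timestamp = NULL,  # deliberately omitted: outputs must be byte-identical
    outputs = basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  written <- c(written, file.path(out_dir, "manifest.json"))
  ok <- TRUE
  invisible(list(report = report, stability = stability, signals = signals,
                 economics = econ_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration file
#'
#' Reads a pipeline configuration from YAML (`.yml`/`.yaml`) or JSON
#' (`.json`); the structure mirrors the `config` argument of
#' [run_pipeline()], with file paths in place of in-memory objects.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_mcda(sprintf("config file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort_mcda("config must be a .yaml/.yml or .json file")
  }
}
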