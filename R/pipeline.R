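# End-to-end orchestration: config -> parsed reports -> deduplicated
# cohort -> signal, onset and risk-factor tables -> CSV/JSON bundle.

pipeline_schema_version <- "1.0"

#' Read a pipeline configuration
#'
#' @param path YAML file; see [validate_config()] for the recognised
#'   fields.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_dir <- dirname(normalizePath(path))
  cfg
}

resolve_path <- function(path, config) {
  if (is.null(path)) return(NULL)
  if (!is.null(config$config_dir) && !file.exists(path)) {
    alt <- file.path(config$config_dir, path)
    if (file.exists(alt)) return(alt)
  }
  path
}

#' Validate a pipeline configuration
#'
#' Checks the configuration without side effects and returns findings as
#' data: exactly one of `input_dirs` (real ASCII quarters) or
#' `synthetic` (generator parameters) must be set; referenced paths must
#' exist; thresholds and probabilities must be sane.
#'
#' @param config Configuration list (from [read_pipeline_config()] or
#'   built in code).
#' @return Tibble of findings: `level` (`"error"`/`"warning"`), `field`,
#'   `message`.  Empty when the configuration is clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  note <- function(level, field, message) {
    findings[[length(findings) + 1]] <<- tibble::tibble(
      level = level, field = field, message = message
    )
  }
  has_real <- !is.null(config$input_dirs)
  has_syn <- !is.null(config$synthetic)
  if (has_real && has_syn) {
    note("error", "input", "Both real input_dirs and a synthetic block are set; choose one.")
  }
  if (!has_real && !has_syn) {
    note("error", "input", "Neither input_dirs nor a synthetic block is set.")
  }
  if (has_real) {
    for (d in config$input_dirs) {
      dd <- resolve_path(d, config)
      if (!dir.exists(dd)) note("error", "input_dirs", paste0("Directory not found: ", d))
    }
    for (f in c("lexicon", "smq")) {
      if (is.null(config[[f]])) {
        note("error", f, paste0("Real-input mode needs a '", f, "' path."))
      } else if (is.character(config[[f]]) &&
                 !file.exists(resolve_path(config[[f]], config) %||% "")) {
        note("error", f, paste0("File not found: ", config[[f]]))
      }
    }
  }
  if (has_syn) {
    ok <- tryCatch({
      do.call(synthetic_config, config$synthetic)
      TRUE
    }, error = function(e) {
      note("error", "synthetic", conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  if (!is.null(config$thresholds)) {
    tryCatch(do.call(signal_thresholds, config$thresholds),
             error = function(e) note("error", "thresholds", conditionMessage(e)))
    for (nm in c("min_cases", "prr_min", "chi2_min", "ebgm_min")) {
      v <- config$thresholds[[nm]]
      if (!is.null(v) && (!is.numeric(v) || v < 0)) {
        note("error", "thresholds", paste0(nm, " must be non-negative."))
      }
    }
  }
  if (is.null(config$seed) && has_syn) {
    note("warning", "seed", "No seed set; synthetic runs will not be reproducible.")
  }
  if (length(findings) == 0) {
    tibble::tibble(level = character(), field = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes parse (or simulate) -> deduplicate -> cohort -> SMQ signal
#' table -> PT-level scans -> top-event rankings -> descriptive summary
#' -> annual counts -> Weibull onset table -> risk-factor tables, and
#' writes each product as CSV plus a `run_metadata.json` carrying the
#' configuration echo, seed, schema version and the record counts at
#' every stage.  All randomness flows from the single config seed via a
#' named substream per module.
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (default `config$out_dir`).
#' @return Invisibly, the named list of result tibbles.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("Invalid pipeline configuration:\n  ",
         paste(findings$message[findings$level == "error"], collapse = "\n  "),
         call. = FALSE)
  }
  if (is.null(out_dir)) stop("No output directory configured.", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$synthetic)) {
    syn_cfg <- do.call(synthetic_config, config$synthetic)
    reports <- run_stage("simulate", simulate_reports(
      syn_cfg, seed = substream_seed(config$seed %||% syn_cfg$seed %||% 1,
                                     "simulate")
    ))
    lexicon <- synthetic_lexicon(syn_cfg)
    smq <- synthetic_smq(syn_cfg)
  } else {
    reports <- run_stage("parse", {
      parts <- lapply(config$input_dirs, function(d) {
        read_faers_quarter(resolve_path(d, config))
      })
      out <- dplyr::bind_rows(parts)
      class(out) <- c("faers_reports", class(out))
      out
    })
    lexicon <- run_stage("lexicon", {
      if (is.character(config$lexicon)) {
        read_drug_lexicon(resolve_path(config$lexicon, config))
      } else {
        validate_lexicon(config$lexicon)
      }
    })
    smq <- run_stage("smq", {
      if (is.character(config$smq)) {
        read_smq(resolve_path(config$smq, config))
      } else {
        smq_definition(config$smq$name %||% "smq", config$smq$pts)
      }
    })
  }
  n_parsed <- nrow(reports)
  deduped <- run_stage("deduplicate", dedupe_reports(reports))
  n_dedup <- nrow(deduped)
  roles <- config$roles %||% "PS"
  cohort <- run_stage("cohort", build_cohort(deduped, lexicon, smq,
                                             roles = roles))
  drugs <- cohort_drugs(cohort)
  thresholds <- do.call(signal_thresholds, config$thresholds %||% list())
  yates <- isTRUE(config$yates)

  grid <- run_stage("mgps", drug_event_grid(cohort))
  prior <- run_stage("mgps", fit_mgps_prior(tibble::tibble(a = grid$a,
                                                           e = grid$e)))
  results <- list()
  results$signal_table <- run_stage("signals", smq_signal_table(
    cohort, drugs = drugs, prior = prior, thresholds = thresholds,
    yates = yates
  ))
  results$pt_scan <- run_stage("pt_scan", dplyr::bind_rows(lapply(
    drugs, function(k) pt_level_scan(cohort, k, prior = prior,
                                     thresholds = thresholds, yates = yates)
  )))
  results$top_events <- run_stage("top_events", dplyr::bind_rows(lapply(
    drugs, function(k) {
      out <- top_events(cohort, k, k = config$top_k %||% 30)
      if (nrow(out) > 0) out$drug <- k
      out
    }
  )))
  results$reporting_proportion <- run_stage("signals", dplyr::bind_rows(
    lapply(drugs, function(k) reporting_proportion(cohort, k))
  ))
  results$descriptive_summary <- run_stage("descriptive",
                                           descriptive_summary(cohort))
  results$annual_counts <- run_stage("descriptive", annual_counts(cohort))
  results$weibull <- run_stage("onset", weibull_onset_table(cohort))
  results$onset_bins <- run_stage("onset", onset_bin_table(cohort))
  results$risk_factors <- run_stage("risk_factors", dplyr::bind_rows(lapply(
    drugs, function(k) {
      tryCatch(risk_factor_table(cohort, k), error = function(e) {
        warning("Risk-factor model skipped for '", k, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    }
  )))

  for (nm in names(results)) {
    readr::write_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     na = "")
  }
  metadata <- list(
    schema_version = pipeline_schema_version,
    seed = config$seed,
    roles = roles,
    yates_correction = yates,
    thresholds = unclass(thresholds),
    counts = list(parsed = n_parsed, deduplicated = n_dedup,
                  cohort_rows = nrow(cohort)),
    onset_anomalies = attr(cohort, "onset_anomalies"),
    drugs = drugs,
    config = config[setdiff(names(config), "config_dir")]
  )
  jsonlite::write_json(metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(c(results, list(metadata = metadata, cohort = cohort)))
}

#' Simulate a batch and write it as a FAERS-style quarter
#'
#' @param config Configuration list (with a `synthetic` block) or a
#'   `synthetic_config`.
#' @param dir Output directory for the six ASCII files.
#' @param seed Seed override.
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(config, dir, seed = NULL) {
  syn_cfg <- if (inherits(config, "synthetic_config")) config
  else do.call(synthetic_config, config$synthetic %||% config)
  seed <- seed %||% syn_cfg$seed %||% config$seed
  reports <- simulate_reports(syn_cfg, seed = seed)
  write_faers_quarter(reports, dir)
}
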