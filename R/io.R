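## File I/O and the analysis driver.
##
## Plain-text tabular interchange: drug libraries as CSV with unit-suffixed
## columns (molar IC50s, percent I_K1 block), traces and metrics as CSV,
## classification reports and run manifests as JSON. Every writer's output
## is re-parseable by the matching reader.

.DRUG_COLS <- c("name", "ic50_na_M", "ic50_cal_M", "ic50_kr_M", "ic50_ks_M",
                "ik1_block_pct", "concentration_M", "known_group")

#' Read a drug library from CSV
#'
#' The schema has columns `name, ic50_na_M, ic50_cal_M, ic50_kr_M,
#' ic50_ks_M, ik1_block_pct, concentration_M, known_group` (extra columns,
#' e.g. `provenance`, are ignored). An empty IC50 cell means "no block".
#' All validation failures are reported together, itemized by row and
#' field.
#'
#' @param path CSV file path.
#' @return Named list of [drug_profile()] objects.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DRUG_COLS, names(df))
  if (length(missing)) {
    stop("drug table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  drugs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    d <- tryCatch(
      drug_profile(
        name = row$name,
        ic50_na = .na_if_empty(row$ic50_na_M),
        ic50_cal = .na_if_empty(row$ic50_cal_M),
        ic50_kr = .na_if_empty(row$ic50_kr_M),
        ic50_ks = .na_if_empty(row$ic50_ks_M),
        ik1_block_pct = ifelse(is.na(row$ik1_block_pct), 0,
                               row$ik1_block_pct),
        concentration = row$concentration_M,
        known_group = ifelse(is.na(row$known_group) ||
                               !nzchar(row$known_group),
                             NA_character_, row$known_group)
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(d)) {
      problems <- c(problems, sprintf("row %d (%s): %s", i, row$name, d))
    } else {
      drugs[[row$name]] <- d
    }
  }
  if (length(problems)) {
    stop("invalid drug table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  drugs
}

.na_if_empty <- function(x) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1 || is.na(x)) NA else x
}

#' Write a drug library to CSV
#'
#' @param drugs list of [drug_profile()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(drugs, path) {
  if (inherits(drugs, "torsim_drug")) drugs <- list(drugs)
  df <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(name = d$name, ic50_na_M = d$ic50[["na"]],
               ic50_cal_M = d$ic50[["cal"]], ic50_kr_M = d$ic50[["kr"]],
               ic50_ks_M = d$ic50[["ks"]], ik1_block_pct = d$ik1_block_pct,
               concentration_M = d$concentration,
               known_group = d$known_group)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a voltage trace as CSV
#'
#' Tabular form with unit-suffixed columns (`time_ms`, `V_mV`); stimulus
#' bookkeeping travels in commented header lines so the file round-trips.
#'
#' @param trace a `torsim_trace`.
#' @param path CSV path.
#' @return `path` (write) or a `torsim_trace` (read).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "torsim_trace"))
  hdr <- c(
    sprintf("# model_kind: %s", trace$model_kind),
    sprintf("# frequency_hz: %g", trace$frequency_hz),
    sprintf("# stim_duration_ms: %g", trace$stim_duration_ms),
    sprintf("# stimulus_amplitude: %g", trace$stimulus_amplitude),
    sprintf("# stimulus_times_ms: %s",
            paste(trace$stimulus_times, collapse = ";"))
  )
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    data.frame(time_ms = trace$time_ms, V_mV = trace$V_mV), path,
    sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  st <- get("stimulus_times_ms")
  structure(
    list(time_ms = df$time_ms, V_mV = df$V_mV, states = NULL,
         stimulus_times = if (nzchar(st))
           as.numeric(strsplit(st, ";")[[1]]) else numeric(0),
         stim_duration_ms = as.numeric(get("stim_duration_ms")),
         stimulus_amplitude = as.numeric(get("stimulus_amplitude")),
         frequency_hz = as.numeric(get("frequency_hz")),
         model_kind = get("model_kind"), final_state = NULL),
    class = "torsim_trace"
  )
}

#' Run a complete analysis task and write its artifacts
#'
#' Drives the pipeline end to end for one of the study tasks and writes
#' plain-text artifacts plus a JSON manifest (inputs, applied conductance
#' scale factors, solver settings, package version) into `out_dir`:
#' \describe{
#'   \item{`simulate`}{steady pacing (control vs optional drug): trace CSVs
#'     and per-beat metrics.}
#'   \item{`grid-scan`}{the spermine x g_CaL variability grid: tidy CSV,
#'     one row per cell.}
#'   \item{`spm-step`}{the 3 to 5 uM spermine step: trace CSV and event
#'     report.}
#'   \item{`classify`}{decision tree (+ simulation where the tree defers)
#'     over a drug library: JSON report.}
#'   \item{`population-scan`}{the 3^n extreme-value scan: tidy CSV, one
#'     row per combination.}
#' }
#'
#' @param task one of `"simulate"`, `"grid-scan"`, `"spm-step"`,
#'   `"classify"`, `"population-scan"`.
#' @param model a [make_model()] object.
#' @param out_dir output directory (created if needed).
#' @param drug a [drug_profile()] / [directive_block()] / `NULL`; for
#'   `classify`, a list of profiles (default: [default_drug_library()]).
#' @param params,protocol optional overrides.
#' @param schedule [spm_step_schedule()] for `spm-step`.
#' @param parameter_specs specs for `population-scan` (default: spermine
#'   and g_CaL around their nominal means).
#' @param tree_only for `classify`: skip the simulation stage.
#' @param seed integer recorded in the manifest and used for any sampling.
#' @return Invisible list of written file paths (incl. `manifest`).
#' @export
run_analysis <- function(task = c("simulate", "grid-scan", "spm-step",
                                  "classify", "population-scan"),
                         model = make_model("endocardial"),
                         out_dir = ".", drug = NULL, params = NULL,
                         protocol = NULL, schedule = spm_step_schedule(),
                         parameter_specs = NULL, tree_only = FALSE,
                         seed = 1) {
  task <- match.arg(task)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- model$nominal_params
  if (is.null(protocol)) protocol <- default_protocol(model)
  paths <- list()
  factors <- if (!is.null(drug) && (inherits(drug, "torsim_drug") ||
                                    inherits(drug, "torsim_block"))) {
    as.list(block_factors(drug))
  } else {
    NULL
  }
  if (task == "simulate") {
    tr_c <- run_paced_to_steady(model, params, NULL, protocol)
    paths$trace_control <- file.path(out_dir, "trace_control.csv")
    write_trace(tr_c, paths$trace_control)
    paths$metrics_control <- file.path(out_dir, "metrics_control.csv")
    utils::write.csv(beat_metrics(tr_c), paths$metrics_control,
                     row.names = FALSE)
    if (!is.null(drug)) {
      tr_d <- run_paced_to_steady(model, params, drug, protocol)
      paths$trace_drug <- file.path(out_dir, "trace_drug.csv")
      write_trace(tr_d, paths$trace_drug)
      paths$metrics_drug <- file.path(out_dir, "metrics_drug.csv")
      utils::write.csv(beat_metrics(tr_d), paths$metrics_drug,
                       row.names = FALSE)
    }
  } else if (task == "grid-scan") {
    g <- run_variability_grid(model, drug, params = params,
                              protocol = protocol)
    paths$grid <- file.path(out_dir, "grid.csv")
    utils::write.csv(g$cells, paths$grid, row.names = FALSE)
  } else if (task == "spm-step") {
    s <- run_spm_step(model, params, drug, schedule, protocol)
    paths$trace <- file.path(out_dir, "spm_step_trace.csv")
    write_trace(s$trace, paths$trace)
    paths$events <- file.path(out_dir, "spm_step_events.json")
    jsonlite::write_json(
      list(arrhythmia = s$arrhythmia, latency_s = s$latency_s,
           switch_time_ms = s$switch_time_ms,
           event_times_ms = s$event_times_ms),
      paths$events, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (task == "classify") {
    lib <- if (is.null(drug)) default_drug_library() else drug
    if (inherits(lib, "torsim_drug")) lib <- list(lib)
    rep <- lapply(lib, function(d) {
      cl <- classify_drug(model, d, params, protocol,
                          simulate = if (tree_only) FALSE else NA)
      list(drug = cl$drug, tree_outcome = cl$tree_outcome, trail = cl$trail,
           simulated_group = cl$simulated_group,
           known_group = d$known_group,
           metrics = if (!is.null(cl$effect)) unclass(cl$effect) else NULL)
    })
    paths$report <- file.path(out_dir, "classification.json")
    jsonlite::write_json(unname(rep), paths$report, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else { # population-scan
    if (is.null(parameter_specs)) {
      parameter_specs <- list(
        spm_population_spec(),
        population_spec("g_CaL", mean = 2.0, sd = 0.25)
      )
    }
    ps <- run_population_scan(model, drug, parameter_specs, params,
                              protocol)
    paths$combinations <- file.path(out_dir, "population_scan.csv")
    utils::write.csv(ps$combinations, paths$combinations, row.names = FALSE)
    paths$risk <- file.path(out_dir, "population_risk.json")
    jsonlite::write_json(
      list(n_parameters = length(ps$parameter_specs),
           n_combinations = nrow(ps$combinations),
           n_prime = ps$n_prime, risk = ps$risk, clipped = ps$clipped),
      paths$risk, auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- list(
    task = task, model_kind = model$kind,
    drug = if (inherits(drug, "torsim_drug")) drug$name
           else if (inherits(drug, "torsim_block"))
             sprintf("block %s %g%%", drug$channel, drug$pct)
           else if (is.list(drug)) vapply(drug, function(d) d$name, "")
           else NULL,
    conductance_factors = factors,
    frequency_hz = protocol$frequency_hz,
    pre_pacing_beats = protocol$pre_pacing_beats,
    solver = list(method = "lsoda", rtol = .RTOL, atol = .ATOL),
    seed = seed,
    package_version = as.character(utils::packageVersion("torsim")),
    timestamp = format(Sys.time(), tz = "UTC"),
    artifacts = lapply(paths, basename)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
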