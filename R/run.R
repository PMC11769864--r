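# Run orchestration: simulate / analyze / report entry points with manifests
# and deterministic seeds, plus YAML (or JSON) configuration round-tripping.
# A thin command-line wrapper over these functions ships in inst/cli.

.region_to_list <- function(spec) {
  out <- list(name = spec$name, type = spec$type,
              outward_hint = as.numeric(spec$outward_hint))
  if (spec$type == "box") {
    out$center <- as.numeric(spec$center)
    out$half_extents <- as.numeric(spec$half_extents)
    out$rotation <- as.numeric(spec$rotation)  # column-major 3x3
  } else {
    out$seed_point <- as.numeric(spec$seed_point)
    out$radius <- spec$radius
  }
  out
}

.region_from_list <- function(x) {
  if (x$type == "box") {
    region_spec(x$name, "box", center = x$center,
                half_extents = x$half_extents,
                rotation = matrix(x$rotation, 3L, 3L),
                outward_hint = x$outward_hint)
  } else {
    region_spec(x$name, "sphere", seed_point = x$seed_point,
                radius = x$radius, outward_hint = x$outward_hint)
  }
}

#' Write a scan-analysis configuration file
#'
#' Serializes the reference length, model frame, the six region selectors and
#' the per-file scan table (path, scan id, strategy label) as YAML. All
#' geometry is in millimetres.
#'
#' @param path output path (`.yaml`/`.yml`, or `.json`).
#' @param regions named list of the six [region_spec()]s.
#' @param bar a [reference_bar()] or length in mm.
#' @param frame a [reference_frame()].
#' @param scans data frame with columns `path`, `scan_id`, `strategy`.
#' @return The path, invisibly.
#' @export
write_scan_config <- function(path, regions, bar = reference_bar(),
                              frame = reference_frame(), scans = NULL) {
  if (is.numeric(bar)) bar <- reference_bar(bar)
  cfg <- list(
    units = "mm",
    reference_length_mm = bar$length_mm,
    frame = list(origin = as.numeric(frame$origin),
                 axes = as.numeric(frame$axes)),
    regions = lapply(unname(regions), .region_to_list),
    scans = if (is.null(scans)) list() else {
      lapply(seq_len(nrow(scans)), function(i) as.list(scans[i, , drop = FALSE]))
    }
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15L)
  }
  invisible(path)
}

#' Read a scan-analysis configuration file
#'
#' @param path a YAML or JSON file written by [write_scan_config()] (or
#'   hand-authored with the same schema).
#' @return List with `bar`, `frame`, `regions` (named), `scans` (data frame).
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  regions <- lapply(cfg$regions, function(x) {
    x$center <- unlist(x$center); x$half_extents <- unlist(x$half_extents)
    x$rotation <- unlist(x$rotation); x$outward_hint <- unlist(x$outward_hint)
    x$seed_point <- unlist(x$seed_point)
    .region_from_list(x)
  })
  names(regions) <- vapply(regions, `[[`, character(1L), "name")
  scans <- if (length(cfg$scans) > 0L) {
    do.call(rbind, lapply(cfg$scans, function(s) {
      data.frame(path = s$path, scan_id = s$scan_id, strategy = s$strategy,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(path = character(), scan_id = character(), strategy = character())
  }
  list(bar = reference_bar(cfg$reference_length_mm),
       frame = reference_frame(unlist(cfg$frame$origin),
                               matrix(unlist(cfg$frame$axes), 3L, 3L)),
       regions = regions, scans = scans)
}

.write_manifest <- function(dir, extra = list()) {
  manifest <- c(list(package = "archbar",
                     version = as.character(utils::packageVersion("archbar")),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

.prepare_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0L) {
    stop("output directory ", out_dir,
         " is not empty; pass overwrite = TRUE to reuse it", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

#' Simulate a scan study and write the per-scan records
#'
#' @param out_dir output directory; receives `records.csv` and
#'   `manifest.json`.
#' @param seed mandatory integer seed (no wall-clock default: simulation runs
#'   must be reproducible).
#' @param n_per_group scans per strategy.
#' @param profiles strategy profiles (default: the nine-strategy grid).
#' @param fast closed-form fast path (`TRUE`) or full mesh path.
#' @param spec a [synthetic_model_spec()].
#' @param overwrite allow writing into a non-empty directory.
#' @return The records data frame, invisibly.
#' @export
run_simulate <- function(out_dir, seed, n_per_group = 25,
                         profiles = default_strategy_profiles(),
                         fast = TRUE, spec = synthetic_model_spec(),
                         overwrite = FALSE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("seed is mandatory in simulate mode", call. = FALSE)
  }
  .prepare_out_dir(out_dir, overwrite)
  records <- simulate_strategy_study(profiles, n_per_group, seed = seed,
                                     fast = fast, spec = spec)
  utils::write.csv(records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, list(mode = "simulate", seed = as.integer(seed),
                                n_per_group = n_per_group,
                                n_records = nrow(records),
                                fast = fast,
                                strategies = vapply(profiles, `[[`,
                                                    character(1L), "strategy_id")))
  invisible(records)
}

#' Analyze STL scans listed in a configuration
#'
#' Runs the per-scan bar analysis for every file in the configuration's scan
#' table. Per-file failures are logged to stderr and collected; the run
#' continues and the result records how many files failed.
#'
#' @param config path to a configuration file (see [write_scan_config()]) or
#'   an equivalent list.
#' @param out_dir output directory; receives `measurements.csv` and
#'   `manifest.json`.
#' @param overwrite allow writing into a non-empty directory.
#' @return List with `records` (data frame), `n_ok`, `n_failed`, `errors`
#'   (named character), invisibly.
#' @export
run_analyze <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_scan_config(config)
  if (nrow(config$scans) == 0L) {
    stop("usage error: the configuration lists no input scans", call. = FALSE)
  }
  .prepare_out_dir(out_dir, overwrite)
  rows <- list(); errors <- character()
  for (i in seq_len(nrow(config$scans))) {
    entry <- config$scans[i, ]
    res <- tryCatch({
      mesh <- read_stl(entry$path)
      cfg <- scan_config(config$regions, config$bar, config$frame,
                         scan_id = entry$scan_id, strategy = entry$strategy)
      as.data.frame(analyze_scan(mesh, cfg))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("analyze failed for ", entry$path, ": ", res)
      errors[entry$scan_id] <- res
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else {
    stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(.measurement_columns))),
                    .measurement_columns)
  }
  utils::write.csv(records, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, list(mode = "analyze",
                                n_ok = nrow(records),
                                n_failed = length(errors),
                                reference_length_mm = config$bar$length_mm))
  invisible(list(records = records, n_ok = nrow(records),
                 n_failed = length(errors), errors = errors))
}

#' Build and write the accuracy report from a records CSV
#'
#' @param records a data frame of per-scan measurements or the path to a
#'   records CSV (as written by [run_simulate()] / [run_analyze()]).
#' @param out_dir output directory; receives `report.json`,
#'   `table_linear.csv`, `table_angular.csv` and `manifest.json`.
#' @param family_alpha,m passed to [build_report()].
#' @param overwrite allow writing into a non-empty directory.
#' @return The [build_report()] result, invisibly.
#' @export
run_report <- function(records, out_dir, family_alpha = 0.05, m = 3,
                       overwrite = FALSE) {
  if (is.character(records)) {
    if (!file.exists(records)) stop("records file not found: ", records, call. = FALSE)
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("strategy", .report_parameters), names(records))
  if (length(missing_cols) > 0L) {
    stop("records schema mismatch, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .prepare_out_dir(out_dir, overwrite)
  report <- build_report(records, family_alpha = family_alpha, m = m)
  tables <- report_tables(report)
  utils::write.csv(tables$linear, file.path(out_dir, "table_linear.csv"),
                   row.names = FALSE)
  utils::write.csv(tables$angular, file.path(out_dir, "table_angular.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .write_manifest(out_dir, list(mode = "report",
                                n_records = nrow(records),
                                family_alpha = family_alpha, m = m,
                                threshold = report$threshold))
  invisible(report)
}
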