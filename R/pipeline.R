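#' Run one pipeline stage from a configuration list
#'
#' R-level entry point behind the command-line interface. Dispatches on
#' `config$command`:
#'
#' * `"phantom"` — generate a synthetic scan and labels, write both as NIfTI.
#' * `"prep"` — read a scan, run [preprocess_case()], write the standardized
#'   volume plus a JSON sidecar with the threshold quantities and provenance.
#' * `"augment"` — read a scan (and optional labels), run [augment_case()],
#'   write the augmented pair.
#' * `"eval"` — read predicted and ground-truth labels, run
#'   [evaluate_case()], write a per-case JSON report and a CSV table.
#' * `"report"` — aggregate a directory of per-case JSON reports into
#'   summary CSVs (per class with trailing Average row, and per tooth
#'   position).
#'
#' Inputs are never mutated; all outputs are new files under `out_dir`.
#' Every run writes a provenance record (inputs, configuration hash, package
#' version, seed). All randomness derives from `config$seed`. Reports
#' contain no timestamps, so reruns with the same seed are byte-identical.
#'
#' @param config Named list with `command`, `out_dir`, `seed` and
#'   stage-specific fields (see Details); a YAML file can be loaded with
#'   [load_run_config()].
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$command))
    cbct_abort("config must name a `command`.", "bad_config")
  command <- match.arg(config$command,
                       c("phantom", "prep", "augment", "eval", "report"))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)

  artifacts <- switch(command,
    phantom = {
      pc_args <- config[intersect(names(config), names(formals(phantom_config)))]
      pc_args$seed <- seed
      ph <- generate_phantom(do.call(phantom_config, pc_args))
      paths <- list(image = file.path(out_dir, "phantom.nii.gz"),
                    labels = file.path(out_dir, "phantom_labels.nii.gz"))
      write_volume(ph$volume, paths$image)
      write_volume(ph$labels, paths$labels)
      paths
    },
    prep = {
      vol <- read_volume(required(config, "input"))
      pc_args <- config[intersect(names(config),
                                  names(formals(preprocess_config)))]
      pp <- preprocess_case(vol, do.call(preprocess_config, pc_args))
      paths <- list(image = file.path(out_dir, "prep.nii.gz"),
                    sidecar = file.path(out_dir, "prep.json"))
      write_volume(pp$volume, paths$image)
      sidecar <- pp$provenance
      if (!is.null(pp$threshold))
        sidecar$threshold <- as.list(tidy(pp$threshold))
      write_json_report(sidecar, paths$sidecar)
      paths
    },
    augment = {
      vol <- read_volume(required(config, "input"))
      lab <- if (!is.null(config$labels_input))
        read_volume(config$labels_input, labels = TRUE)
      ac_args <- config[intersect(names(config),
                                  names(formals(augment_config)))]
      ac_args$seed <- seed
      aug <- augment_case(vol, lab, do.call(augment_config, ac_args))
      paths <- list(image = file.path(out_dir, "augmented.nii.gz"))
      write_volume(aug$volume, paths$image)
      if (!is.null(aug$labels)) {
        paths$labels <- file.path(out_dir, "augmented_labels.nii.gz")
        write_volume(aug$labels, paths$labels)
      }
      paths
    },
    eval = {
      pred <- read_volume(required(config, "pred"), labels = TRUE)
      gt <- read_volume(required(config, "gt"), labels = TRUE)
      rep <- evaluate_case(pred, gt)
      paths <- list(json = file.path(out_dir, "report.json"),
                    csv = file.path(out_dir, "report.csv"))
      write_json_report(as.data.frame(rep), paths$json)
      utils::write.csv(rep, paths$csv, row.names = FALSE)
      paths
    },
    report = {
      files <- sort(list.files(required(config, "reports_dir"),
                               pattern = "\\.json$", full.names = TRUE))
      if (length(files) == 0)
        cbct_abort("no JSON case reports found.", "missing_input")
      reports <- purrr::map(files, function(f) {
        df <- jsonlite::fromJSON(f)
        structure(tibble::as_tibble(df),
                  class = c("metric_report", class(tibble::tibble())))
      })
      agg <- aggregate_reports(reports)
      paths <- list(by_class = file.path(out_dir, "summary_by_class.csv"),
                    by_position = file.path(out_dir,
                                            "summary_by_position.csv"))
      utils::write.csv(agg$by_class, paths$by_class, row.names = FALSE)
      utils::write.csv(agg$by_position, paths$by_position, row.names = FALSE)
      paths
    })

  prov <- list(command = command,
               inputs = config[intersect(names(config),
                                         c("input", "labels_input", "pred",
                                           "gt", "reports_dir"))],
               config_hash = rlang::hash(config),
               package_version = as.character(utils::packageVersion("cbctools")),
               seed = seed,
               artifacts = artifacts)
  prov_path <- file.path(out_dir, paste0(command, "_provenance.json"))
  write_json_report(prov, prov_path)
  artifacts$provenance <- prov_path
  invisible(artifacts)
}

required <- function(config, field) {
  if (is.null(config[[field]]))
    cbct_abort(sprintf("config field `%s` is required for command `%s`.",
                       field, config$command), "bad_config")
  config[[field]]
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Command-line flags are merged over the file values by the CLI wrapper;
#' here the file is read and minimally validated.
#'
#' @param path YAML file.
#' @return Named list usable with [run_pipeline()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    cbct_abort(paste0("config file not found: ", path), "missing_input")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg))
    cbct_abort("config file must contain a YAML mapping.", "bad_config")
  cfg
}
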