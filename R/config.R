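# Run-configuration loading and fail-fast validation. Bulk runs are long;
# every config error must surface before any image is read.

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration declaring masks, markers, queries and
#' options, fills defaults, and validates everything up front: thresholds
#' in 0-255, unique layer names, and every query parsing against the
#' declared layers. Validation errors are collected and reported together.
#'
#' Expected structure:
#' \preformatted{
#' masks:   [{name, token, threshold}, ...]
#' markers: [{name, token, threshold}, ...]
#' queries: ["SNAKA under vimentin, NOTepi/tumor", ...]
#' options: {on_missing: skip|fail, save_images: false}
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The validated configuration list with `layers` (named list of
#'   [layer_spec]) attached.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stopf("config must be .yaml/.yml or .json, got .%s", ext)
  }
  validate_config(cfg)
}

#' Validate an in-memory run configuration
#'
#' @param cfg List with `masks`, `markers`, `queries`, optional `options`.
#' @return The configuration with defaults filled and `layers` attached.
#' @export
validate_config <- function(cfg) {
  errors <- character()
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  as_entries <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  cfg$masks <- as_entries(cfg$masks)
  cfg$markers <- as_entries(cfg$markers)
  if (length(cfg$masks) == 0L) note("config: at least one mask is required")
  if (length(cfg$markers) == 0L) note("config: at least one marker is required")

  layers <- list()
  for (kind in c("mask", "marker")) {
    for (e in cfg[[paste0(kind, "s")]]) {
      if (is.null(e$name) || is.null(e$token) || is.null(e$threshold)) {
        note("%s entry missing name/token/threshold: %s", kind,
             paste(names(e), collapse = ","))
        next
      }
      thr <- suppressWarnings(as.numeric(e$threshold))
      if (is.na(thr) || thr < 0 || thr > 255 || thr != round(thr)) {
        note("%s '%s': threshold must be an integer in 0-255 (got %s)",
             kind, e$name, e$threshold)
        next
      }
      if (e$name %in% names(layers)) {
        note("duplicate layer name '%s'", e$name)
        next
      }
      layers[[e$name]] <- layer_spec(e$name, e$token, thr, kind)
    }
  }

  queries <- as.character(cfg$queries %||% character())
  if (length(queries) == 0L) note("config: at least one query is required")
  if (length(errors) == 0L) {
    for (q in queries) {
      tryCatch(parse_query(q, layers),
               error = function(e) note("%s", conditionMessage(e)))
    }
  }

  opts <- cfg$options %||% list()
  opts$on_missing <- opts$on_missing %||% "skip"
  if (!opts$on_missing %in% c("skip", "fail")) {
    note("options.on_missing must be 'skip' or 'fail' (got '%s')",
         opts$on_missing)
  }
  opts$save_images <- isTRUE(opts$save_images)

  if (length(errors) > 0L) {
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  }
  cfg$options <- opts
  cfg$queries <- queries
  cfg$layers <- layers
  cfg
}

#' Write a run manifest
#'
#' Records everything that affects the numbers of a run -- tool version,
#' the full resolved configuration, input files with MD5 hashes, seeds, and
#' per-stage parameters -- as JSON, so a run can be audited and reproduced.
#' The manifest carries a timestamp; all table/image outputs of a
#' deterministic stage are byte-identical across reruns, the manifest's
#' timestamp field alone differs.
#'
#' @param path Output JSON path.
#' @param stage Stage name (e.g. `"smia"`).
#' @param config Resolved configuration/parameter list.
#' @param input_files Character vector of input paths (hashed).
#' @param seed Seed(s) used, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, config, input_files = character(),
                           seed = NULL) {
  input_files <- input_files[file.exists(input_files)]
  manifest <- list(
    tool = "stromaquant",
    version = as.character(utils::packageVersion("stromaquant")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = if (length(input_files)) {
      data.frame(path = input_files,
                 md5 = unname(tools::md5sum(input_files)),
                 stringsAsFactors = FALSE)
    } else list()
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
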