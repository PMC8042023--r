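# Table schemas and validated CSV IO. Units are micrometres and minutes in
# every table; pixel units appear only inside the imaging internals.

wm_schemas <- list(
  truth = list(cell_id = "character", motor_id = "character",
               frame = "numeric", time_min = "numeric", x_um = "numeric",
               y_um = "numeric", P_y_um = "numeric", N_y_true = "numeric",
               color = "character", type = "character",
               L_active_um = "numeric", cell_length_um = "numeric",
               septal_offset_um = "numeric", phase = "character"),
  observed = list(cell_id = "character", motor_id = "character",
                  frame = "numeric", time_min = "numeric", x_um = "numeric",
                  y_um = "numeric", P_y_um = "numeric", color = "character"),
  lineage = list(mother_id = "character", daughter_id = "character",
                 motor_id = "character", N_y_mother = "numeric",
                 N_y_daughter = "numeric", side = "numeric"),
  traces = list(cell_id = "character", trace_id = "numeric",
                frame = "numeric", time_min = "numeric", x_um = "numeric",
                y_um = "numeric", P_y_um = "numeric"),
  geometry = list(cell_id = "character", frame = "numeric",
                  time_min = "numeric", cell_length_um = "numeric",
                  phase = "character"),
  spots = list(frame = "numeric", x_px = "numeric", y_px = "numeric",
               amplitude = "numeric", sigma_px = "numeric",
               background = "numeric"),
  pairs = list(cell_id = "character", trace_i = "numeric",
               trace_j = "numeric", time_min = "numeric", dt = "numeric",
               D_x = "numeric", D_y = "numeric", V_Dx = "numeric",
               V_Dy = "numeric"),
  hubble = list(cell_id = "character", time_min = "numeric", H = "numeric",
                stderr = "numeric", n_pairs = "numeric"),
  normalized = list(trace_id = "numeric", cell_id = "character",
                    frame = "numeric", time_min = "numeric",
                    Y_um = "numeric", L_um = "numeric", N_y = "numeric",
                    phase = "character")
)

check_schema <- function(df, schema, where = "table") {
  sch <- wm_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema, call. = FALSE)
  missing <- setdiff(names(sch), names(df))
  if (length(missing)) {
    stop(sprintf("%s does not match the '%s' schema; missing columns: %s",
                 where, schema, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  extra <- setdiff(names(df), names(sch))
  if (length(extra)) {
    message(sprintf("note: %s has extra columns (preserved): %s",
                    where, paste(extra, collapse = ", ")))
  }
  for (col in names(sch)) {
    if (sch[[col]] == "numeric" && !is.numeric(df[[col]])) {
      stop(sprintf("%s column '%s' must be numeric", where, col),
           call. = FALSE)
    }
    if (sch[[col]] == "character" && !is.character(df[[col]])) {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df
}

#' Write a validated CSV table
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @param schema Schema name (one of `names(wallmark:::wm_schemas)`); `NULL`
#'   skips validation.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = NULL) {
  if (!is.null(schema)) df <- check_schema(df, schema, where = path)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a validated CSV table
#'
#' @param path CSV path (UTF-8, header row, `.` decimal separator regardless
#'   of locale).
#' @param schema Schema name; `NULL` skips validation.
#' @return Data frame.
#' @export
read_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, dec = ".")
  if (!is.null(schema)) df <- check_schema(df, schema, where = path)
  df
}

#' Read a simulation/pipeline configuration file
#'
#' YAML (or JSON, which YAML subsumes) with the [sim_config()] keys at top
#' level, plus an optional `pipeline:` block (`generations`,
#' `new_motors_per_daughter`, `stages`). Unknown top-level keys are an error
#' naming every offending key.
#'
#' @param path Config file path.
#' @return List with `sim` (a `wm_sim_config`) and `pipeline` (a list).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipe_defaults <- list(generations = 1, new_motors_per_daughter = 0,
                        stages = c("simulate", "analyze", "bernoulli"))
  pipe <- utils::modifyList(pipe_defaults, raw$pipeline %||% list())
  raw$pipeline <- NULL
  preset <- raw$preset; raw$preset <- NULL
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim <- if (!is.null(preset)) {
    do.call(sim_preset, c(list(medium = preset), raw))
  } else {
    do.call(sim_config, raw)
  }
  list(sim = sim, pipeline = pipe)
}

#' Write a run manifest
#'
#' Records the resolved configuration, the root seed and named substream
#' seeds, the package version, and an md5 checksum of every output file.
#' Identical manifests (checksums included) imply byte-identical CSV outputs.
#'
#' @param dir Output directory whose files are checksummed.
#' @param config The resolved `wm_sim_config`.
#' @param pipeline The pipeline options used.
#' @return The manifest list, invisibly; written to `manifest.json`.
#' @export
write_manifest <- function(dir, config, pipeline = list()) {
  files <- setdiff(list.files(dir), "manifest.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  streams <- c("placement:c1", "noise", "miss", "coin:c1", "shot:c1:1",
               "bootstrap", "bernoulli-init")
  manifest <- list(
    package = "wallmark",
    version = as.character(utils::packageVersion("wallmark")),
    root_seed = config$rng_seed,
    substream_seeds = stats::setNames(
      lapply(streams, function(s) substream_seed(config$rng_seed, s)),
      streams),
    config = unclass(config),
    pipeline = pipeline,
    checksums = sums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
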