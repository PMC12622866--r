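# Run configuration (YAML) and tidy-table CSV I/O. All tables are long form,
# UTF-8, header row, '.' decimal, integer days.

.config_defaults <- list(
  communities = c("1A", "2A", "2A-1P"),
  landscape = "star",
  n_patches = NULL,          # 5 for star, 50 for scale_free
  attach = 2L,
  configs = c("1C", "1P", "4C", "4P"),
  replicates = 100L,
  days = 26L,
  master_seed = 1L,
  outdir = "metarecover-out",
  verbosity = "info"
)

#' Load a run configuration
#'
#' Reads a YAML file with any subset of the keys `communities`, `landscape`
#' (`star` or `scale_free`), `n_patches`, `attach`, `configs`, `replicates`,
#' `days`, `master_seed`, `outdir`, `verbosity`. Missing keys take the
#' documented defaults (`days = 26`, `replicates = 100`, the four study
#' configurations); unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.config_defaults, raw)
  if (!cfg$landscape %in% c("star", "scale_free"))
    stop("config key 'landscape' must be 'star' or 'scale_free'")
  for (k in c("replicates", "days", "master_seed", "attach"))
    if (!is.numeric(cfg[[k]]))
      stop("config key '", k, "' must be numeric")
  bad <- setdiff(cfg$configs, c("1C", "1P", "4C", "4P"))
  if (length(bad))
    stop("config key 'configs' has invalid entries: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(cfg$communities, community_labels())
  if (length(bad))
    stop("config key 'communities' has unknown labels: ",
         paste(bad, collapse = ", "))
  if (is.null(cfg$n_patches))
    cfg$n_patches <- if (cfg$landscape == "star") 5L else 50L
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config A `run_config` (or plain list of valid keys).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x))
    cat(" ", k, "=", paste(x[[k]], collapse = ", "), "\n")
  invisible(x)
}

.check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " table missing column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Credit-table CSV I/O
#'
#' One row per (replicate, scale); write-then-read is the identity.
#'
#' @param credits Credit table (see [run_factorial()]).
#' @param path File path.
#' @export
write_credit_table <- function(credits, path) {
  utils::write.csv(credits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_credit_table
#' @export
read_credit_table <- function(path) {
  .check_columns(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 c("community", "config", "number", "location", "replicate",
                   "scale", "credit", "credit_ln1p"), "credit")
}

#' Trajectory CSV I/O
#'
#' Long form: one row per (day, patch, species).
#'
#' @param sim A `metacommunity_sim` (or a long trajectory data frame).
#' @param path File path.
#' @export
write_trajectory <- function(sim, path) {
  df <- if (inherits(sim, "metacommunity_sim")) as.data.frame(sim) else sim
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  .check_columns(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 c("day", "patch", "species", "abundance"), "trajectory")
}

#' Observation-series CSV I/O (day, patch, species, count)
#' @param series Data frame with at least `day` and `count` (optional
#'   `patch`, `species` filled with defaults on write).
#' @param path File path.
#' @export
write_observation_series <- function(series, path) {
  if (is.null(series$patch)) series$patch <- 0L
  if (is.null(series$species)) series$species <- "Bb"
  utils::write.csv(series[c("day", "patch", "species", "count")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_observation_series
#' @export
read_observation_series <- function(path) {
  .check_columns(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 c("day", "patch", "species", "count"), "observation")
}

#' Write the effect tables of a fitted effects model
#'
#' Writes `anova.csv` (term, df, F, p) and `effects.csv` (per-level
#' predictions with CIs) into `dir`.
#'
#' @param fit An `effects_fit`.
#' @param dir Output directory (created if needed).
#' @export
write_effect_tables <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fit$anova, file.path(dir, "anova.csv"), row.names = FALSE)
  utils::write.csv(fit$predictions, file.path(dir, "effects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a run manifest
#'
#' Records the resolved configuration, its file hash, the master seed and the
#' package/R versions alongside the outputs, so identical manifests imply
#' identical outputs.
#'
#' @param config A `run_config`.
#' @param dir Output directory.
#' @return Path of the manifest file.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- c(
    paste0("config_md5: ", unname(tools::md5sum(cfg_path))),
    paste0("master_seed: ", config$master_seed),
    paste0("package_version: ",
           as.character(utils::packageVersion("metarecover"))),
    paste0("r_version: ", R.version.string)
  )
  path <- file.path(dir, "manifest.txt")
  writeLines(manifest, path)
  path
}
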