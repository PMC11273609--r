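# Shared readers and writers: curve bundles, event tables, trajectories.

#' Write a curve bundle to a directory
#'
#' Each curve becomes a two-column tab-separated trace
#' (`separation_nm`, `force_pN`); the generation truth goes to
#' `truth.tsv` and the condition, seed and acquisition parameters to a
#' YAML sidecar `metadata.yaml`.
#'
#' @param bundle a `curve_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_curve_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "curve_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(bundle$curves)) {
    cv <- bundle$curves[[i]]
    write.table(
      data.frame(separation_nm = cv$separation_nm,
                 force_pN = cv$force_pN),
      file.path(dir, sprintf("curve_%05d.tsv", i)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(condition = as.list(bundle$preset),
         acquisition = unclass(bundle$params),
         n_curves = length(bundle$curves),
         n_complexes = bundle$n_complexes, seed = bundle$seed),
    file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a curve bundle from a directory
#'
#' @param dir a directory written by [write_curve_bundle()].
#' @return a `curve_bundle`.
#' @export
read_curve_bundle <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) stop("missing metadata file: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  preset <- as.data.frame(meta$condition, stringsAsFactors = FALSE)
  class(preset) <- c("condition_presets", "data.frame")
  params <- do.call(acquisition_params, meta$acquisition)
  files <- sort(list.files(dir, pattern = "^curve_\\d+\\.tsv$",
                           full.names = TRUE))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  curves <- lapply(seq_along(files), function(i) {
    tr <- read.delim(files[i])
    structure(list(separation_nm = tr$separation_nm,
                   force_pN = tr$force_pN, segment = "retract",
                   truth = truth[i, -1, drop = FALSE]),
              class = "force_curve")
  })
  structure(
    list(curves = curves, truth = truth, preset = preset,
         params = params, n_complexes = meta$n_complexes,
         seed = meta$seed),
    class = "curve_bundle"
  )
}

#' Write an event table as TSV
#'
#' @param events event data frame from [analyze_bundle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path a TSV written by [write_events_tsv()].
#' @return event data frame.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("missing events file: ", path)
  read.delim(path)
}

#' Write a BD trajectory as TSV with a YAML sidecar
#'
#' @param traj a `bd_trajectory`.
#' @param path output TSV path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bd_trajectory"))
  write.table(traj$frames, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  yaml::write_yaml(list(params = unclass(traj$params),
                        seed = traj$seed),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a BD trajectory written by [write_trajectory()]
#'
#' @param path TSV path.
#' @return a `bd_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("missing trajectory file: ", path)
  frames <- read.delim(path)
  meta_path <- paste0(path, ".yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  params <- if (!is.null(meta)) do.call(bd_params, meta$params[
    c("timestep_fs", "temperature_K", "record_every_ns", "duration_ns",
      "n_replicas", "seed")]) else NULL
  structure(list(frames = frames, params = params,
                 seed = if (!is.null(meta)) meta$seed else NA),
            class = "bd_trajectory")
}
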