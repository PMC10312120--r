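#' Write / read the epoch container
#'
#' Serializes an `epoch_set` to the package's epoch container (an RDS
#' file carrying the data array with `fs`, time axis, channel names,
#' window label, and optional reaction times, plus a format tag). The
#' round trip is lossless (bitwise-equal arrays), and reading validates
#' the schema, naming any missing field.
#'
#' @param epochs an `epoch_set`.
#' @param path output file path.
#' @return `write_epochs`: the path, invisibly. `read_epochs`: the
#'   validated `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  validate_epoch_set(epochs)
  obj <- unclass(epochs)
  obj$format <- "betadyn-epochs-v1"
  saveRDS(obj, path, version = 2L)
  invisible(path)
}

#' @rdname write_epochs
#' @param path container file path.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "betadyn-epochs-v1"))
    stop("epoch_set schema error: not a betadyn epoch container")
  for (f in c("data", "fs", "time", "channels", "window"))
    if (is.null(obj[[f]]))
      stop(sprintf("epoch_set schema error: missing field '%s'", f))
  x <- structure(obj[c("data", "fs", "time", "channels", "window", "rts")],
                 class = "epoch_set")
  validate_epoch_set(x)
  x
}

#' Write a synthetic dataset to disk
#'
#' Writes the pretarget and precue epoch containers plus the ground truth
#' as JSON (burst records, reaction-time features and coefficients,
#' per-trial coupling strengths, seed) into a directory.
#'
#' @param dataset a dataset list from [make_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_epochs(dataset$pretarget, file.path(dir, "pretarget.rds"))
  write_epochs(dataset$precue, file.path(dir, "precue.rds"))
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir dataset directory.
#' @return list with `pretarget`, `precue`, `ground_truth`.
#' @export
read_dataset <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.json")
  list(pretarget = read_epochs(file.path(dir, "pretarget.rds")),
       precue = read_epochs(file.path(dir, "precue.rds")),
       ground_truth = if (file.exists(gt_path))
         jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL)
}
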