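# Delimited-text table formats. Every file starts with '#' comment header
# lines stating units (positions mm, times s, angles deg) and the seed, and
# all tables round-trip losslessly through data.table's fwrite/fread.

table_specs <- list(
  trajectories = c("participant", "trial", "t", "hand", "x", "missing"),
  metadata = c("trial", "participant", "session", "instruction", "mirror",
               "posture_raw", "excluded"),
  cycles = c("participant", "trial", "cycle_index", "start", "end", "t_mid",
             "speed_level", "rel_phase", "valid"),
  outcomes = c("participant", "trial", "speed_level", "instruction",
               "mirror", "posture_raw", "posture_pooled", "speed_pooled",
               "rel_phase", "correct", "tolerance"))

write_bp_table <- function(data, path, kind, seed = NULL) {
  hdr <- c(sprintf("# bimphase %s table", kind),
           "# units: positions mm, times s, angles deg",
           sprintf("# seed: %s", seed %||% "NA"))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(data, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

read_bp_table <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  required <- table_specs[[kind]]
  head_lines <- readLines(path, n = 50)
  skip <- sum(cumprod(startsWith(head_lines, "#")))
  dt <- data.table::fread(path, skip = skip, header = TRUE)
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop(sprintf("%s file '%s' lacks required column(s): %s",
                 kind, path, paste(miss, collapse = ", ")))
  as.data.frame(dt)
}

#' Write / read a long-format trajectory table
#'
#' Columns: `participant`, `trial`, `t` (s, uniformly sampled), `hand`
#' (`left`/`right`), `x` (lateral position, mm), optional extra dimensions
#' (e.g. `y`), `missing` (0/1). Reading validates the header and uniform
#' sampling within each trial and hand.
#'
#' @param trajectories trajectory data frame.
#' @param path file path.
#' @param seed seed recorded in the file header.
#' @return `read_trajectories` returns the validated data frame;
#'   `write_trajectories` the path, invisibly.
#' @export
write_trajectories <- function(trajectories, path, seed = NULL) {
  miss <- setdiff(table_specs$trajectories, names(trajectories))
  if (length(miss)) stop("trajectories lack column(s): ",
                         paste(miss, collapse = ", "))
  write_bp_table(trajectories, path, "trajectories", seed)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  out <- read_bp_table(path, "trajectories")
  groups <- split(out$t, list(out$hand, out$trial), drop = TRUE)
  ok <- vapply(groups, function(tt) {
    dts <- diff(tt)
    length(dts) < 2 ||
      max(abs(dts - stats::median(dts))) <= stats::median(dts) * 1.001
  }, logical(1))
  if (!all(ok))
    stop("non-uniform sampling in trial/hand group: ",
         names(groups)[which(!ok)[1]])
  out
}

#' Write / read trial metadata, cycle and outcome tables
#'
#' Thin wrappers around the package's delimited-text format with per-kind
#' required-column validation.
#'
#' @param data the table to write.
#' @param path file path.
#' @param seed seed recorded in the file header.
#' @return Readers return validated data frames; writers the path,
#'   invisibly.
#' @export
write_metadata <- function(data, path, seed = NULL) {
  write_bp_table(data, path, "metadata", seed)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) read_bp_table(path, "metadata")

#' @rdname write_metadata
#' @export
write_cycles <- function(data, path, seed = NULL) {
  write_bp_table(data, path, "cycles", seed)
}

#' @rdname write_metadata
#' @export
read_cycles <- function(path) read_bp_table(path, "cycles")

#' @rdname write_metadata
#' @export
write_outcomes <- function(data, path, seed = NULL) {
  write_bp_table(data, path, "outcomes", seed)
}

#' @rdname write_metadata
#' @export
read_outcomes <- function(path) read_bp_table(path, "outcomes")

#' Write a run manifest
#'
#' Records the package version, R version, seed, configuration and the MD5
#' digest of every input file, so that any stage can be re-run and verified
#' bit-identically. Deliberately contains no timestamps.
#'
#' @param path output JSON path.
#' @param seed integer seed of the run.
#' @param config list of run parameters.
#' @param inputs character vector of input file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(), inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "bimphase",
                   version = as.character(utils::packageVersion("bimphase")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed, config = config, input_md5 = digests)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
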