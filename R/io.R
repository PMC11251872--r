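#' Write / read region-level time series as TSV
#'
#' One file per subject, header row = region names, one row per volume.
#'
#' @param series T x N matrix with column names.
#' @param path file path.
#' @export
write_roi_tsv <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' @rdname write_roi_tsv
#' @return `read_roi_tsv`: the T x N numeric matrix.
#' @export
read_roi_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write / read a six-column motion table (whitespace-delimited)
#'
#' @param motion T x 6 matrix.
#' @param path file path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Write / read a group design table as CSV
#'
#' @param design data frame with `subject_id`, `group`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Plain-text volume serialization
#'
#' Minimal text format for 3-D/4-D arrays (no binary NIfTI dependency is
#' available offline): first line `dims: d1 d2 ...`, then the values in
#' column-major order, whitespace-separated.
#'
#' @param arr numeric array.
#' @param path file path.
#' @export
write_volume_text <- function(arr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("dims:", paste(dim(arr), collapse = " ")), con)
  writeLines(paste(format(as.vector(arr), digits = 8, trim = TRUE,
                          scientific = TRUE),
                   collapse = " "), con)
}

#' @rdname write_volume_text
#' @export
read_volume_text <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(sub("^dims: *", "", lines[1]), " ")[[1]])
  vals <- as.numeric(strsplit(paste(lines[-1], collapse = " "), " +")[[1]])
  array(vals, dim = dims)
}

#' Write a complete simulated study to a directory
#'
#' Emits, per subject: the ROI series (`<id>_bold.tsv`), the motion table
#' (`<id>_motion.txt`), and ground truth (`<id>_truth.json`: state ids,
#' per-volume state labels, motion-spike frames). Plus `design.csv` and the
#' generator parameters (`config.json`).
#'
#' @param sim a `roi_sim` from [simulate_roi_timeseries()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$subjects) {
    write_roi_tsv(s$series, file.path(dir, paste0(s$id, "_bold.tsv")))
    write_motion(s$motion, file.path(dir, paste0(s$id, "_motion.txt")))
    jsonlite::write_json(
      list(state_ids = s$state_ids, states = s$states,
           spike_frames = s$spike_frames,
           wm = s$wm, csf = s$csf),
      file.path(dir, paste0(s$id, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
  }
  write_design(sim$design, file.path(dir, "design.csv"))
  cfg <- sim$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "state_args")],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated study directory back
#'
#' @param dir directory written by [write_simulation()].
#' @return List with `subjects` (id, group, series, motion, truth),
#'   `design`.
#' @export
read_simulation <- function(dir) {
  design <- read_design(file.path(dir, "design.csv"))
  subjects <- lapply(seq_len(nrow(design)), function(i) {
    id <- design$subject_id[i]
    truth <- jsonlite::read_json(file.path(dir, paste0(id, "_truth.json")),
                                 simplifyVector = TRUE)
    list(id = id, group = design$group[i],
         series = read_roi_tsv(file.path(dir, paste0(id, "_bold.tsv"))),
         motion = read_motion(file.path(dir, paste0(id, "_motion.txt"))),
         states = as.integer(unlist(truth$states)),
         spike_frames = as.integer(unlist(truth$spike_frames)),
         wm = truth$wm, csf = truth$csf)
  })
  list(subjects = subjects, design = design)
}
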