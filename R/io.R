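# Delimited-text interchange: segments (one per row), state matrices with a
# header row of neuron indices, labels, and stability contours. Plain text
# keeps every artifact diffable and tool-agnostic.

#' Write ECG segments as delimited text
#'
#' One segment per row, tab-delimited, no header. For an [ecg_dataset()] a
#' sidecar `<path>.meta.yaml` records labels and generation metadata so the
#' dataset can be regenerated bit-exactly.
#'
#' @param dataset an [ecg_dataset()] or a plain segment matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments <- function(dataset, path) {
  segs <- if (inherits(dataset, "ecg_dataset")) dataset$segments else dataset
  utils::write.table(segs, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (inherits(dataset, "ecg_dataset")) {
    meta <- dataset$meta
    meta$class0 <- unclass(meta$class0)
    meta$class1 <- unclass(meta$class1)
    meta$labels <- dataset$labels
    meta$rate <- dataset$rate
    meta$d <- dataset$d
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Read segments written by [write_segments()]
#'
#' @param path file path.
#' @return a numeric matrix, one segment per row; if a sidecar metadata file
#'   exists, labels are attached as attribute `labels`.
#' @export
read_segments <- function(path) {
  segs <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(segs) <- NULL
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    attr(segs, "labels") <- as.integer(meta$labels)
  }
  segs
}

#' Write a reservoir state matrix as delimited text
#'
#' Tab-delimited with a header row of neuron indices (`r1 ... rN`).
#'
#' @param states matrix from [run_reservoir()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_states <- function(states, path) {
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("r", seq_len(ncol(states)))
  }
  utils::write.table(states, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a state matrix written by [write_states()]
#'
#' @param path file path.
#' @return numeric matrix with neuron-index column names.
#' @export
read_states <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
}

#' Export a stability contour as delimited text
#'
#' Columns: omega1, omega2, max_root, stable.
#'
#' @param contour data.frame from [stability_contour()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contour <- function(contour, path) {
  utils::write.table(contour, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
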