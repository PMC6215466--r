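# Plain-text interchange: time series, per-vertex scalar maps, motion
# traces, and parcel labels with a JSON sidecar.  Everything is TSV so
# outputs stay diffable and readable by any downstream tool.

#' Write / read a vertex-by-frame time series as TSV
#'
#' Rows are vertices, columns frames, no row names.
#'
#' @param timeseries vertex x frame matrix.
#' @param path output file.
#' @return the path (write) or the matrix (read).
#' @export
write_timeseries_tsv <- function(timeseries, path) {
  write.table(timeseries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  as.matrix(read.delim(path, header = FALSE))
}

#' Write / read a per-vertex scalar map as single-column TSV
#'
#' NA values (medial wall / invalid) are written as the string `NA`.
#'
#' @param values per-vertex numeric vector (a `boundary_map` also works).
#' @param path output file.
#' @return the path (write) or the numeric vector (read).
#' @export
write_map_tsv <- function(values, path) {
  write.table(data.frame(value = boundary_values(values)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  read.delim(path)$value
}

#' Write / read a motion trace as TSV
#'
#' Columns tx, ty, tz (mm) and rx, ry, rz (radians), one row per frame.
#'
#' @param motion frames x 6 matrix.
#' @param path output file.
#' @return the path (write) or the matrix (read).
#' @export
write_motion_tsv <- function(motion, path) {
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(read.delim(path))
}

#' Write / read parcel labels with a JSON sidecar
#'
#' The TSV holds one integer label per vertex (0 = unassigned); the JSON
#' sidecar records threshold, parcel ids, seed vertices and (optionally)
#' the parcel-to-system and system-type maps.
#'
#' @param parcellation a `parcellation` or integer label vector.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @param sidecar extra named entries merged into the sidecar.
#' @return the path (write) or, for read, a list `labels` + sidecar fields.
#' @export
write_labels_tsv <- function(parcellation, path, sidecar = list()) {
  labels <- parcel_labels(parcellation)
  write.table(data.frame(label = labels), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(n_parcels = length(unique(labels[labels > 0])))
  if (inherits(parcellation, "parcellation")) {
    meta$threshold_q <- parcellation$threshold_q
    meta$seed_vertices <- parcellation$seed_vertices
  }
  meta <- utils::modifyList(meta, sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  labels <- as.integer(read.delim(path)$label)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  c(list(labels = labels), meta)
}
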