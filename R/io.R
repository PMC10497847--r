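# Plain-format readers and writers: 16-bit TIFF images with a YAML
# sidecar for the pixel size, trajectory CSVs, and protein-table TSVs
# with a sample-to-group CSV.

#' Write a fluorescence image as 16-bit TIFF with a metadata sidecar
#'
#' @param image a [fluorescence_image()].
#' @param path output TIFF path; pixel size is recorded in
#'   `<path>.meta.yaml`.
#' @param max_count full-scale count mapped to 65535.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, max_count = NULL) {
  stopifnot(inherits(image, "fluorescence_image"))
  mx <- max_count %||% max(image$intensity, 1)
  m <- pmin(pmax(image$intensity / mx, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_um = image$pixel_size,
                        max_count = mx), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a fluorescence image written by [write_image_tiff()]
#'
#' @param path TIFF path (expects the `<path>.meta.yaml` sidecar; a
#'   `pixel_size` argument overrides it).
#' @param pixel_size optional pixel size in um.
#' @return a [fluorescence_image()].
#' @export
read_image_tiff <- function(path, pixel_size = NULL) {
  m <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  px <- pixel_size %||% meta$pixel_size_um
  if (is.null(px)) stop_invalid("read_image_tiff(): pixel size unknown")
  fluorescence_image(m * (meta$max_count %||% 1), px)
}

#' Write a trajectory CSV
#'
#' Columns: `time_s`, `nose_x_cm`, `nose_y_cm`, `body_x_cm`, `body_y_cm`,
#' `climbing`.
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV path as written by [write_trajectory_csv()].
#' @param sample_rate_hz nominal sampling rate; inferred from the time
#'   column when omitted.
#' @param arena_cm arena side, cm.
#' @return a [trajectory()].
#' @export
read_trajectory_csv <- function(path, sample_rate_hz = NULL, arena_cm = 33) {
  df <- utils::read.csv(path)
  rate <- sample_rate_hz %||% (1 / stats::median(diff(df$time_s)))
  trajectory(df$time_s, cbind(df$nose_x_cm, df$nose_y_cm),
             cbind(df$body_x_cm, df$body_y_cm), df$climbing, rate, arena_cm)
}

#' Write a protein table as TSV plus a group-map CSV
#'
#' The TSV columns are `protein_id`, `mw_kda`, `unique_peptides`, then one
#' raw-intensity column per sample (missing as empty cells); the group map
#' CSV has columns `sample`, `group`.
#'
#' @param table a [protein_table()].
#' @param path output TSV path; the group map goes to
#'   `<path>.groups.csv`.
#' @return `path`, invisibly.
#' @export
write_protein_table_tsv <- function(table, path) {
  stopifnot(inherits(table, "protein_table"))
  df <- cbind(table$proteins, as.data.frame(table$intensities))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  utils::write.csv(data.frame(sample = names(table$groups),
                              group = unname(table$groups)),
                   paste0(path, ".groups.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a protein table TSV written by [write_protein_table_tsv()]
#'
#' @param path TSV path (expects `<path>.groups.csv` unless `groups` is
#'   given).
#' @param groups optional named character vector sample -> group.
#' @return a [protein_table()].
#' @export
read_protein_table_tsv <- function(path, groups = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "")
  if (is.null(groups)) {
    gm <- utils::read.csv(paste0(path, ".groups.csv"))
    groups <- stats::setNames(gm$group, gm$sample)
  }
  meta_cols <- c("protein_id", "mw_kda", "unique_peptides")
  protein_table(df[meta_cols],
                as.matrix(df[setdiff(names(df), meta_cols)]), groups)
}
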