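#' Read and write ROI coordinate tables
#'
#' ROI inputs are plain CSV with columns `frame`, `role` (one of `pole1`,
#' `pole2`, `centromere`, `background`), `x`, `y` (0-based pixel
#' coordinates). `roi_table_to_poles()` reshapes the long table into the
#' per-frame wide pole table consumed by [separation_series()].
#'
#' @param path CSV file path.
#' @return `read_roi_csv()` returns the validated long data frame.
#' @export
read_roi_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "role", "x", "y")
  if (!all(need %in% names(d)))
    stop("ROI CSV needs columns ", paste(need, collapse = ", "))
  ok_roles <- c("pole1", "pole2", "centromere", "background")
  if (!all(d$role %in% ok_roles))
    stop("unknown ROI role(s): ",
         paste(setdiff(unique(d$role), ok_roles), collapse = ", "))
  d
}

#' @param rois A long ROI table from [read_roi_csv()].
#' @rdname read_roi_csv
#' @export
roi_table_to_poles <- function(rois) {
  p1 <- rois[rois$role == "pole1", c("frame", "x", "y")]
  p2 <- rois[rois$role == "pole2", c("frame", "x", "y")]
  names(p1)[2:3] <- c("pole1_x", "pole1_y")
  names(p2)[2:3] <- c("pole2_x", "pole2_y")
  out <- merge(p1, p2, by = "frame")
  if (!nrow(out)) stop("no frames with both pole1 and pole2 ROIs")
  out[order(out$frame), , drop = FALSE]
}

#' Tidy measurement output
#'
#' All assay outputs are written as tidy CSV, one row per measurement, with
#' identifying columns plus `assay`, `value`, `units`.
#'
#' @param df Data frame of measurements.
#' @param path Output CSV path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run provenance manifest
#'
#' Writes a YAML manifest capturing the assay name, package version, seed,
#' configuration, and checksums of the input files, so dataset-relative
#' quantities (e.g. a control-derived solidity threshold) stay traceable to
#' the run that produced them.
#'
#' @param out_dir Output directory (created if needed).
#' @param assay Assay name.
#' @param config Named list of assay parameters.
#' @param inputs Character vector of input file paths to checksum.
#' @param seed Seed used for any randomness in the run.
#' @return Path of the manifest file, invisibly.
#' @export
run_manifest <- function(out_dir, assay, config = list(),
                         inputs = character(), seed = NA_integer_) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  checksums <- if (length(inputs))
    vapply(inputs, function(f) unname(tools::md5sum(f)), character(1))
  else character()
  manifest <- list(
    assay = assay,
    package = "mitoquant",
    version = as.character(utils::packageVersion("mitoquant")),
    seed = seed,
    config = config,
    inputs = as.list(checksums))
  path <- file.path(out_dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
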