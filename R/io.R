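#' Write a reflectance image as 16-bit TIFF with sidecar metadata
#'
#' Intensities (expected in [0, 1]) are stored as single-channel 16-bit
#' TIFF; pixel size and labels go to a YAML sidecar \code{<path>.yml} so the
#' geometry survives the round trip.
#'
#' @param img A \code{\link{reflectance_image}}.
#' @param path Output file path (.tif).
#' @return \code{path}, invisibly.
#' @export
write_reflectance_tiff <- function(img, path) {
  stopifnot(inherits(img, "reflectance_image"))
  v <- pmin(pmax(img$intensities, 0), 1)
  tiff::writeTIFF(v, path, bits.per.sample = 16)
  yaml::write_yaml(list(pixel_size_um = img$pixel_size,
                        group_min = img$group_min, image_id = img$image_id),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a reflectance image written by \code{\link{write_reflectance_tiff}}
#'
#' @param path TIFF file path; \code{<path>.yml} must hold the pixel size.
#' @param pixel_size Override for the pixel size (um/px) when no sidecar
#'   file exists.
#' @return A \code{\link{reflectance_image}}.
#' @export
read_reflectance_tiff <- function(path, pixel_size = NULL) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  meta <- list()
  side <- paste0(path, ".yml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  ps <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  if (is.null(ps)) stop("invalid-parameter: pixel size not found; pass pixel_size")
  reflectance_image(v, pixel_size = ps,
                    group_min = meta$group_min %||% NA_real_,
                    image_id = meta$image_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a voxel mask as a multi-page TIFF stack
#'
#' @param vol A \code{\link{voxel_volume}}; values are clipped to [0, 1].
#' @param path Output file path (.tif); metadata goes to \code{<path>.yml}.
#' @return \code{path}, invisibly.
#' @export
write_mask_stack <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$values)
  pages <- lapply(seq_len(d[3]), function(k)
    pmin(pmax(vol$values[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(voxel_size_um = vol$voxel_size,
                        cell_id = vol$cell_id, group_min = vol$group_min,
                        time_h = vol$time_h),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a voxel stack written by \code{\link{write_mask_stack}}
#'
#' @param path TIFF stack path.
#' @param voxel_size Override voxel size (um) when no sidecar exists.
#' @return A \code{\link{voxel_volume}}.
#' @export
read_mask_stack <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    arr[, , k] <- pg
  }
  meta <- list()
  side <- paste0(path, ".yml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  vs <- if (!is.null(voxel_size)) voxel_size else meta$voxel_size_um
  if (is.null(vs)) stop("invalid-parameter: voxel size not found; pass voxel_size")
  voxel_volume(round(arr), voxel_size = unlist(vs),
               cell_id = meta$cell_id %||% NA_character_,
               group_min = meta$group_min %||% NA_real_,
               time_h = meta$time_h %||% NA_real_)
}

#' Read an ICP-AES uptake table
#'
#' Expects tab-separated columns \code{group_min}, \code{time_h},
#' \code{replicate}, \code{c_m_mgL}.
#'
#' @param path TSV file path.
#' @return An \code{\link{uptake_series}} data frame (column \code{value}
#'   holds c_m in mg/L).
#' @export
read_uptake_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("group_min", "time_h", "replicate", "c_m_mgL")
  if (!all(need %in% names(df)))
    stop("invalid-parameter: expected columns ", paste(need, collapse = ", "))
  uptake_series(time_h = df$time_h, value = df$c_m_mgL,
                group_min = df$group_min, replicate = df$replicate)
}

#' Write an uptake table as TSV
#'
#' @param series An \code{\link{uptake_series}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_uptake_tsv <- function(series, path) {
  df <- data.frame(group_min = series$group_min, time_h = series$time_h,
                   replicate = series$replicate, c_m_mgL = series$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 6-significant-digit TSV writer used for all report tables (stable diffs).
write_report_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled ICP-AES group summary table
#'
#' Mean and SD of the measured gold concentration (C_m, mg/L) and its
#' per-cell particle-count conversion (C_eq, x10^4) for a 4-exposure x
#' 3-timepoint uptake study (times on the clock of particle administration:
#' fixation 0, 3 and 24 h after irradiation = 3, 6 and 27 h of exposure to
#' particles). Ships with the package as reference input for worked
#' examples and the built-in verification suite.
#'
#' @return Data frame with columns group_min, time_h, c_m_mean, c_m_sd,
#'   c_eq_mean, c_eq_sd.
#' @export
icpaes_reference <- function() {
  utils::read.delim(system.file("extdata", "icpaes_group_summary.tsv",
                                package = "sonognp"),
                    sep = "\t", stringsAsFactors = FALSE)
}

#' Bundled cluster-size group means
#'
#' Mean and SD of pooled intracellular cluster equivalent diameters (um)
#' per ultrasound exposure group, as summarised from ten reflectance images
#' per group in the study the package's defaults emulate.
#'
#' @return Data frame with columns group_min, mean_um, sd_um.
#' @export
cluster_reference <- function() {
  utils::read.delim(system.file("extdata", "cluster_group_means.tsv",
                                package = "sonognp"),
                    sep = "\t", stringsAsFactors = FALSE)
}
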