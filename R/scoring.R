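#' Cross-correlation coefficient between two density grids
#'
#' Pearson correlation of voxel values between a reference (experimental)
#' grid and a model-derived grid, evaluated over a mask taken from the
#' reference grid only: voxels where the reference exceeds
#' \code{mask_threshold} (default: the reference mean).
#'
#' @param grid_a reference grid (numeric array); defines the mask.
#' @param grid_b model grid, same shape.
#' @param mask_threshold mask cutoff on \code{grid_a} (default
#'   \code{mean(grid_a)}).
#' @return The cross-correlation coefficient in [-1, 1].
#' @export
ccc <- function(grid_a, grid_b, mask_threshold = NULL) {
  if (!identical(dim(grid_a), dim(grid_b))) {
    stop_mcsarch("grids must have identical shape", "invalid_input_error")
  }
  thr <- mask_threshold %||% mean(grid_a)
  mask <- grid_a > thr
  if (!any(mask)) {
    stop_mcsarch("empty mask: no reference voxel above threshold",
                 "undefined_score_error")
  }
  a <- grid_a[mask]; b <- grid_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_mcsarch("zero variance inside mask", "undefined_score_error")
  }
  stats::cor(a, b)
}

#' Combined model-quality score
#'
#' The mean of two equally weighted metrics: the cross-correlation
#' coefficient between model and experimental density (goodness of fit)
#' and an externally computed voroMQA score (stereochemical/interface
#' quality). Higher is better.
#'
#' @param ccc_value cross-correlation coefficient.
#' @param voromqa_value externally supplied voroMQA score.
#' @return \code{(ccc_value + voromqa_value) / 2}.
#' @examples
#' gscore(0.8, 0.6) # 0.7
#' @export
gscore <- function(ccc_value, voromqa_value) {
  if (!all(is.finite(c(ccc_value, voromqa_value)))) {
    stop_mcsarch("scores must be finite", "invalid_input_error")
  }
  (ccc_value + voromqa_value) / 2
}

#' Read and write density grids as MRC (mode 2)
#'
#' Minimal MRC-2014 support for single-volume float32 (mode 2) maps: the
#' 1024-byte header is written with grid dimensions, unit cell equal to
#' \code{voxel_size} times the grid, and min/max/mean statistics; extended
#' headers are skipped on read. This covers the map files exchanged by
#' fitting and scoring tools.
#'
#' @param path file path.
#' @param grid numeric 3-D array (write).
#' @param voxel_size voxel edge in Angstroms (write).
#' @return \code{read_mrc}: a 3-D array with attribute \code{voxel_size};
#'   \code{write_mrc}: the path, invisibly.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (mode != 2) {
    stop_mcsarch(sprintf("unsupported MRC mode %d (only mode 2)", mode),
                 "format_error")
  }
  invisible(readBin(con, "integer", 3, size = 4, endian = "little")) # nstart
  invisible(readBin(con, "integer", 3, size = 4, endian = "little")) # mx..mz
  cell <- readBin(con, "numeric", 6, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  vals <- readBin(con, "numeric", prod(n), size = 4, endian = "little")
  arr <- array(vals, dim = n)
  attr(arr, "voxel_size") <- cell[1] / n[1]
  arr
}

#' @rdname read_mrc
#' @export
write_mrc <- function(grid, path, voxel_size = 1) {
  d <- dim(grid)
  if (length(d) != 3) {
    stop_mcsarch("grid must be a 3-D array", "invalid_input_error")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nstart
  wi(d)                      # mx my mz
  wf(c(d * voxel_size, 90, 90, 90))  # cell lengths + angles
  wi(c(1, 2, 3))             # axis order
  wf(c(min(grid), max(grid), mean(grid)))
  wi(c(1, 0))                # ispg, nsymbt
  writeBin(raw(100), con)    # extra (25 words)
  wf(c(0, 0, 0))             # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(grid))
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  wf(as.numeric(grid))
  invisible(path)
}
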