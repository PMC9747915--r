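#' 3D scalar image with physical voxel spacing and an ROI mask
#'
#' The elementary imaging container of the package: a 3D intensity array, a
#' per-axis physical spacing in millimetres, and a binary region-of-interest
#' mask of identical shape. The coordinate convention is fixed: voxel indices
#' are 0-based internally, and the physical position of a voxel is
#' `index * spacing` (origin at the centre of the first voxel).
#'
#' @param intensities numeric 3D array of voxel intensities.
#' @param spacing numeric length-3 vector, voxel spacing (x, y, z) in mm,
#'   all strictly positive.
#' @param mask logical/0-1 3D array, same shape as `intensities`, with at
#'   least one foreground voxel.
#' @return an object of class `voxel_image` (a list with elements
#'   `intensities`, `spacing`, `mask`).
#' @examples
#' img <- voxel_image(array(rnorm(64), c(4, 4, 4)), c(1, 1, 2),
#'                    array(TRUE, c(4, 4, 4)))
#' img$spacing
#' @export
voxel_image <- function(intensities, spacing, mask) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("'intensities' must be a 3D array")
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(intensities)))
    stop("'mask' and 'intensities' must have identical shape")
  if (!any(mask)) stop("mask must contain at least one foreground voxel")
  structure(list(intensities = intensities,
                 spacing = as.numeric(spacing),
                 mask = mask),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_image: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, %d ROI voxels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$mask)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal single-file NIfTI-1 I/O (.nii / .nii.gz). No NIfTI reader ships
# with the installed R stack, so the subset needed here (3D scalar volumes,
# pixdim spacing, common datatypes, optional gzip) is implemented directly.
# Orientation metadata beyond a diagonal sform is neither read nor written.
# ---------------------------------------------------------------------------

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' Stores intensities as float32 in a single-file NIfTI-1 (`.nii`, or
#' gzip-compressed when the path ends in `.nii.gz`), with voxel spacing in
#' `pixdim` and a diagonal sform. Masks are written with the same routine
#' (0/1 values).
#'
#' @param data 3D numeric array.
#' @param spacing length-3 voxel spacing in mm.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, spacing, path) {
  stopifnot(is.array(data), length(dim(data)) == 3L, length(spacing) == 3L)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  dm <- dim(data)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)   # data_type..dim_info
  wi(c(3L, dm, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(16L, 2)                                    # datatype = float32
  wi(32L, 2)                                    # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))                 # pixdim[8], qfac = 1
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                                 # quatern b,c,d + qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0))                    # srow_x
  wf(c(0, spacing[2], 0, 0))                    # srow_y
  wf(c(0, 0, spacing[3], 0))                    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                         # extension flag
  wf(as.numeric(data))
  invisible(path)
}

#' Read a single-file NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array, scale slope/intercept applied) and
#'   `spacing` (length-3, mm).
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd_i <- function(off, size, n = 1, endian) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = TRUE)
  }
  rd_f <- function(off, n = 1, endian) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4, endian = endian)
  }
  endian <- "little"
  if (rd_i(0, 4, 1, endian) != 348L) {
    endian <- "big"
    if (rd_i(0, 4, 1, endian) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "'")
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported")
  dimv <- rd_i(40, 2, 8, endian)
  ndim <- dimv[1]
  if (ndim < 3L) stop("expected a 3D volume")
  dm <- dimv[2:4]
  if (ndim > 3L && any(dimv[5:(1 + ndim)] > 1L))
    stop("only 3D volumes are supported")
  datatype <- rd_i(70, 2, 1, endian)
  pixdim <- rd_f(76, 8, endian)
  vox_offset <- rd_f(108, 1, endian)
  scl_slope <- rd_f(112, 1, endian)
  scl_inter <- rd_f(116, 1, endian)
  n <- prod(dm)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "16" = readBin(con, "double", n = n, size = 4, endian = endian),
    "64" = readBin(con, "double", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dm), spacing = abs(pixdim[2:4]))
}

#' Read an image/mask NIfTI pair as a `voxel_image`
#'
#' @param image_path NIfTI file with intensities.
#' @param mask_path NIfTI file with a 0/1 ROI mask on the same grid.
#' @return a [voxel_image()].
#' @export
read_voxel_image <- function(image_path, mask_path) {
  img <- read_nifti(image_path)
  msk <- read_nifti(mask_path)
  if (!identical(dim(img$data), dim(msk$data)))
    stop("image and mask grids differ")
  voxel_image(img$data, img$spacing, msk$data > 0.5)
}

#' Write a `voxel_image` as an image/mask NIfTI pair
#'
#' @param image a [voxel_image()].
#' @param image_path,mask_path output NIfTI paths.
#' @return invisibly, a character vector of the two paths.
#' @export
write_voxel_image <- function(image, image_path, mask_path) {
  stopifnot(inherits(image, "voxel_image"))
  write_nifti(image$intensities, image$spacing, image_path)
  write_nifti(array(as.numeric(image$mask), dim(image$mask)), image$spacing,
              mask_path)
  invisible(c(image_path, mask_path))
}
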