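#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes uncompressed single-file NIfTI-1 (.nii) volumes with
#' 3-D or 4-D float32/float64/uint8/int16/int32 data, which is all this
#' package needs for beta series, masks and statistic maps. Values are
#' stored little-endian; scl_slope/scl_inter are honoured on read. No R
#' NIfTI package is assumed to be installed.
#'
#' @param path file path ending in .nii
#' @return `read_nifti`: list with `data` (array), `voxdim_mm` (length-3),
#'   `origin_mm` (length-3, from the sform translation)
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    seek(con, 0L)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  seek(con, 40L)
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dim0[1L]
  if (ndim < 3L || ndim > 4L) stop("only 3-D/4-D volumes supported (got ", ndim, "-D)")
  dims <- dim0[2L:(1L + ndim)]
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!startsWith(magic, "n+1")) stop("unsupported NIfTI magic: ", magic)
  seek(con, 280L)
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 3L, 4L, byrow = TRUE)
  n <- prod(dims)
  seek(con, vox_offset)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims),
       voxdim_mm = pixdim[2L:4L],
       origin_mm = srow[, 4L])
}

#' @rdname read_nifti
#' @param vol 3-D or 4-D numeric array
#' @param voxdim_mm voxel size in mm per axis
#' @param origin_mm world coordinate of voxel (1,1,1)
#' @param datatype "float32" (default) or "float64"
#' @export
write_nifti <- function(vol, path, voxdim_mm = c(3, 3, 3),
                        origin_mm = c(0, 0, 0),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(vol)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("vol must be a 3-D or 4-D array")
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  size <- bitpix / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i4(348L)                       # sizeof_hdr
  w_raw(36L)                       # data_type..dim_info
  dim8 <- c(length(dims), dims, rep(1L, 7L - length(dims)))
  w_i2(dim8)                       # dim[8]
  w_f4(c(0, 0, 0))                 # intent_p1..p3
  w_i2(0L)                         # intent_code
  w_i2(dt_code)                    # datatype
  w_i2(bitpix)                     # bitpix
  w_i2(0L)                         # slice_start
  w_f4(c(1, voxdim_mm, rep(1, 4L))) # pixdim[8] (qfac = 1)
  w_f4(352)                        # vox_offset
  w_f4(1)                          # scl_slope
  w_f4(0)                          # scl_inter
  w_i2(0L); writeBin(raw(2L), con) # slice_end, slice_code, xyzt_units
  w_f4(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                  # glmax, glmin
  w_raw(80L + 24L)                 # descrip, aux_file
  w_i2(0L)                         # qform_code
  w_i2(1L)                         # sform_code
  w_f4(rep(0, 6L))                 # quaternions + offsets (qform unused)
  srow <- rbind(c(voxdim_mm[1], 0, 0, origin_mm[1]),
                c(0, voxdim_mm[2], 0, origin_mm[2]),
                c(0, 0, voxdim_mm[3], origin_mm[3]))
  w_f4(as.numeric(t(srow)))        # srow_x, srow_y, srow_z
  w_raw(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                        # extension flag
  writeBin(as.numeric(vol), con, size = size, endian = "little")
  invisible(path)
}

#' Beta-series I/O: 4-D NIfTI plus a stimulus-label TSV sidecar
#'
#' @param bs a `beta_series` object (see [beta_series()])
#' @param prefix file prefix; writes `<prefix>.nii` and `<prefix>_labels.tsv`
#' @export
write_beta_series <- function(bs, prefix) {
  grid <- bs$grid
  vol <- array(0, c(grid$dim, nrow(bs$data)))
  lin <- which(bs$mask)
  for (s in seq_len(nrow(bs$data))) {
    v3 <- array(0, grid$dim)
    v3[lin] <- bs$data[s, ]
    vol[, , , s] <- v3
  }
  write_nifti(vol, paste0(prefix, ".nii"), voxdim_mm = grid$voxdim_mm,
              origin_mm = grid$origin_mm)
  write.table(data.frame(stimulus = bs$labels), paste0(prefix, "_labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_beta_series
#' @param mask logical 3-D array (the analysis mask)
#' @param subject_id subject identifier
#' @export
read_beta_series <- function(prefix, mask, subject_id = basename(prefix)) {
  nif <- read_nifti(paste0(prefix, ".nii"))
  lab <- read.delim(paste0(prefix, "_labels.tsv"), stringsAsFactors = FALSE)
  if (length(dim(nif$data)) != 4L) stop("beta series must be a 4-D volume")
  if (nrow(lab) != dim(nif$data)[4L])
    stop("sidecar has ", nrow(lab), " labels but volume has ",
         dim(nif$data)[4L], " stimuli")
  grid <- volume_grid(dim(nif$data)[1:3], nif$voxdim_mm, nif$origin_mm)
  if (!identical(dim(mask), grid$dim)) stop("mask grid does not match beta grid")
  lin <- which(mask)
  dat <- t(apply(nif$data, 4L, function(v) v[lin]))
  if (length(lin) == 1L) dat <- matrix(dat, ncol = 1L)
  beta_series(subject_id, grid, lab$stimulus, dat, mask)
}
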