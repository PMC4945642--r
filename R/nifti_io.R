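#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for uncompressed single-file NIfTI-1
#' (`.nii`), float32, little-endian, 3D or 4D. This covers the package's
#' export needs (beta/T/contrast/boost/group maps and synthetic cohorts);
#' it is not a general-purpose NIfTI implementation (no compressed files,
#' no orientation matrices beyond a diagonal scaling, no extensions).
#'
#' @param vol 3D or 4D numeric array.
#' @param path output path (`.nii`).
#' @param voxel_size voxel edge in mm (scalar or length 3).
#' @param tr repetition time in seconds (written to `pixdim[4]` for 4D).
#' @param descrip up to 79 characters stored in the header description
#'   (used to carry the model tag).
#' @return `write_nifti` returns `path` invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size = 1, tr = 1, descrip = "") {
  nd <- length(dim(vol))
  stopifnot(nd %in% c(3, 4))
  dims <- dim(vol)
  voxel_size <- rep_len(voxel_size, 3)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                       # unused (data_type..dim_info)
  wi(c(nd, dims, rep(1, 7 - nd)), 2)           # dim[8]
  writeBin(raw(14), con)                       # intent_p1..intent_code
  wi(16, 2)                                    # datatype = NIFTI_TYPE_FLOAT32
  wi(32, 2)                                    # bitpix
  wi(0, 2)                                     # slice_start
  wf(c(1, voxel_size, tr, 0, 0, 0))            # pixdim[8]
  wf(352)                                      # vox_offset
  wf(c(1, 0))                                  # scl_slope, scl_inter
  writeBin(raw(12), con)                       # slice_end..cal_min
  wf(c(0, 0))                                  # slice_duration, toffset
  wi(c(0, 0), 4)                               # glmax, glmin
  dch <- charToRaw(substr(descrip, 1, 79))
  writeBin(c(dch, raw(80 - length(dch))), con) # descrip[80]
  writeBin(raw(24), con)                       # aux_file[24]
  wi(c(0, 0), 2)                               # qform_code, sform_code
  wf(rep(0, 18))                               # quaternions + srow
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  writeBin(as.numeric(vol), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti` returns the array with attributes `voxel_size`,
#'   `tr` and `descrip`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n, size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348) stop("not a NIfTI-1 file (bad sizeof_hdr)")
  if (rawToChar(hdr[345:347]) != "n+1")
    stop("only single-file NIfTI-1 (.nii) is supported")
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  dtype <- ri(70, 2)
  if (dtype != 16) stop("only float32 NIfTI volumes are supported")
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  dch <- hdr[149:228]
  nz <- which(dch == as.raw(0))
  descrip <- rawToChar(dch[seq_len(if (length(nz)) nz[1] - 1 else 80)])
  seek(con, vox_offset)
  n <- prod(dims)
  v <- readBin(con, "numeric", n, size = 4, endian = "little")
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  arr <- array(v, dim = dims)
  attr(arr, "voxel_size") <- pixdim[2:4]
  attr(arr, "tr") <- pixdim[5]
  attr(arr, "descrip") <- descrip
  arr
}
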