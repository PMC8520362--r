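#' Read a scattered point cloud from CSV
#'
#' The interchange format is a UTF-8 CSV with header columns `x_mm`,
#' `y_mm`, `z_mm`, `value`.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_cloud_csv <- function(path) {
  if (!file.exists(path)) stop("point-cloud file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("x_mm", "y_mm", "z_mm", "value")
  if (!all(need %in% names(dt)))
    stop("point-cloud CSV must have columns ", paste(need, collapse = ", "),
         ": ", path)
  point_cloud(as.matrix(dt[, c("x_mm", "y_mm", "z_mm")]), dt$value)
}

#' Write a point cloud to CSV
#'
#' @param cloud a [point_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  dt <- data.table::data.table(x_mm = cloud$positions[, 1],
                               y_mm = cloud$positions[, 2],
                               z_mm = cloud$positions[, 3],
                               value = cloud$values)
  data.table::fwrite(dt, path)
  invisible(path)
}

mask_path <- function(path) {
  sub("(\\.nii\\.gz|\\.nii|\\.mha)$", "_mask\\1", path)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.mha$", path)) "mha"
  else stop("unsupported volume format (use .nii, .nii.gz or .mha): ", path)
}

write_nifti_vol <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
}

write_mha_vol <- function(arr, spacing, origin, path, type) {
  dims <- dim(arr)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.17g %.17g %.17g",
                   origin[1], origin[2], origin[3]),
           "CenterOfRotation = 0 0 0",
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
           sprintf("ElementType = %s",
                   if (type == "float") "MET_FLOAT" else "MET_UCHAR"),
           "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (type == "float") {
    writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  } else {
    writeBin(as.raw(arr), con)
  }
  invisible(path)
}

read_mha_vol <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("corrupt MetaImage header (no data): ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("corrupt MetaImage header line: ", line)
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(kv[2])
    if (key == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementSpacing", "Offset", "ElementType")
  if (!all(need %in% names(hdr)))
    stop("corrupt MetaImage header, missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ": ", path)
  if (hdr$ElementDataFile != "LOCAL")
    stop("only LOCAL MetaImage payloads are supported: ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  n <- prod(dims)
  data <- switch(hdr$ElementType,
                 MET_FLOAT = readBin(con, numeric(), n, size = 4L,
                                     endian = "little"),
                 MET_UCHAR = as.numeric(readBin(con, raw(), n)),
                 stop("unsupported MetaImage element type: ",
                      hdr$ElementType))
  if (length(data) != n) stop("truncated MetaImage payload: ", path)
  list(data = array(data, dims), spacing = spacing, origin = origin)
}

#' Write a volume to NIfTI-1 or MetaImage
#'
#' The format follows the file extension (`.nii`, `.nii.gz` or `.mha`);
#' spacing and origin go into the header; intensities are stored as
#' 32-bit floats with missing voxels as NaN, and the missing mask is
#' written alongside as an 8-bit volume with suffix `_mask`.
#'
#' @param volume a [voxel_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_grid"))
  fmt <- volume_format(path)
  data <- volume$data
  data[is.na(data)] <- NaN
  mask <- array(as.integer(volume$mask), volume$dim)
  if (fmt == "nifti") {
    write_nifti_vol(data, volume$spacing, volume$origin, path, "float")
    write_nifti_vol(mask, volume$spacing, volume$origin, mask_path(path),
                    "uint8")
  } else {
    write_mha_vol(data, volume$spacing, volume$origin, path, "float")
    write_mha_vol(mask, volume$spacing, volume$origin, mask_path(path),
                  "uchar")
  }
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' Restores geometry (shape, spacing, origin) exactly and intensities to
#' 32-bit float precision; if the `_mask` sidecar is present, voxels
#' masked out (or stored as NaN) come back as `NA`.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.mha` volume.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    spacing <- RNifti::pixdim(img)[1:3]
    origin <- RNifti::xform(img)[1:3, 4]
  } else {
    v <- read_mha_vol(path)
    data <- v$data
    spacing <- v$spacing
    origin <- v$origin
  }
  mp <- mask_path(path)
  if (file.exists(mp)) {
    m <- if (fmt == "nifti") as.array(RNifti::readNifti(mp))
         else read_mha_vol(mp)$data
    data[m == 0] <- NA_real_
  }
  data[is.nan(data)] <- NA_real_
  voxel_grid(dim(data), spacing, origin, data = data)
}

#' Round-trip a volume through disk
#'
#' Convenience wrapper: [write_volume()] then [read_volume()].
#'
#' @param volume a [voxel_grid()].
#' @param path file path (format by extension).
#' @return The re-read [voxel_grid()].
#' @export
roundtrip_volume <- function(volume, path) {
  write_volume(volume, path)
  read_volume(path)
}
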