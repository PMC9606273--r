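#' Read a 3D density image
#'
#' Reads MetaImage (`.mha`, local uncompressed data) or NIfTI
#' (`.nii`/`.nii.gz`) files into a [density_image()]. Density values are
#' returned as stored (mg HA/cm^3 for calibrated HR-pQCT data). Only
#' isotropic voxels are accepted.
#'
#' @param path File path.
#' @param format `"mha"` or `"nifti"`; inferred from the extension when `NULL`.
#' @return A [density_image()].
#' @export
read_image <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% infer_format(path)
  switch(format,
         mha = read_mha(path),
         nifti = read_nifti(path),
         stop("unsupported format: ", format, call. = FALSE))
}

#' Write a 3D density image
#'
#' Writes MetaImage or NIfTI. Density images are stored as 32-bit float
#' (lossless for single-precision data); masks should be written with
#' `dtype = "uint8"`.
#'
#' @param image A [density_image()].
#' @param path Output path (`.mha`, `.nii` or `.nii.gz`).
#' @param format `"mha"` or `"nifti"`; inferred from the extension when `NULL`.
#' @param dtype `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL, dtype = "float32") {
  stopifnot(is_density_image(image))
  dtype <- match.arg(dtype, c("float32", "uint8"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  format <- format %||% infer_format(path)
  switch(format,
         mha = write_mha(image, path, dtype),
         nifti = write_nifti_img(image, path, dtype),
         stop("unsupported format: ", format, call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return("mha")
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  stop("cannot infer image format from path: ", path, call. = FALSE)
}

check_isotropic <- function(spacing) {
  if (diff(range(spacing)) > 1e-6 * max(spacing))
    stop(sprintf("anisotropic voxels are not supported: spacing = (%s) mm",
                 paste(signif(spacing, 6), collapse = ", ")), call. = FALSE)
  spacing[1]
}

# ---- MetaImage (local, uncompressed) --------------------------------------

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line,
                               call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only LOCAL MetaImage data is supported", call. = FALSE)
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("expected a 3D MetaImage", call. = FALSE)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  vox <- check_isotropic(spacing)
  origin <- as.numeric(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_FLOAT"
  spec <- switch(type,
                 MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
                 MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
                 MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
                 MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
                 MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE),
                 stop("unsupported MetaImage ElementType: ", type,
                      call. = FALSE))
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True") ||
    identical(hdr$ElementByteOrderMSB, "True")
  n <- prod(dims)
  raw <- readBin(con, what = spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = if (msb) "big" else "little")
  if (length(raw) != n) stop("truncated MetaImage data block", call. = FALSE)
  density_image(array(as.numeric(raw), dims), voxel_size = vox,
                origin = origin)
}

write_mha <- function(image, path, dtype) {
  d <- dim(image$values)
  type <- if (dtype == "uint8") "MET_UCHAR" else "MET_FLOAT"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.17g %.17g %.17g", image$origin[1], image$origin[2],
            image$origin[3]),
    "CenterOfRotation = 0 0 0",
    sprintf("ElementSpacing = %.17g %.17g %.17g", image$voxel_size,
            image$voxel_size, image$voxel_size),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", type),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vals <- as.numeric(image$values)
  if (dtype == "uint8") {
    if (any(vals < 0 | vals > 255))
      stop("values outside 0..255 cannot be written as uint8", call. = FALSE)
    writeBin(as.raw(as.integer(round(vals))), con)
  } else {
    writeBin(vals, con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- NIfTI via RNifti ------------------------------------------------------

read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- check_isotropic(RNifti::pixdim(img))
  arr <- array(as.numeric(img), dim(img))
  # qform offset gives the physical position of voxel (0,0,0)
  q <- RNifti::niftiHeader(img)
  origin <- c(q$qoffset_x, q$qoffset_y, q$qoffset_z)
  density_image(arr, voxel_size = vox, origin = origin)
}

write_nifti_img <- function(image, path, dtype) {
  arr <- image$values
  datatype <- if (dtype == "uint8") "uint8" else "float"
  if (dtype == "uint8" && any(arr < 0 | arr > 255))
    stop("values outside 0..255 cannot be written as uint8", call. = FALSE)
  hdr <- RNifti::niftiHeader(RNifti::asNifti(arr))
  hdr$pixdim[2:4] <- image$voxel_size
  hdr$qoffset_x <- image$origin[1]
  hdr$qoffset_y <- image$origin[2]
  hdr$qoffset_z <- image$origin[3]
  hdr$qform_code <- 1L
  img <- RNifti::asNifti(arr, reference = hdr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write the three compartment masks as 8-bit images
#'
#' @param masks A [bone_masks()].
#' @param dir Output directory (created if missing).
#' @param like A [density_image()] supplying voxel size and origin.
#' @param format `"mha"` (default) or `"nifti"`.
#' @return Named vector of the three file paths, invisibly.
#' @export
write_masks <- function(masks, dir, like, format = "mha") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "mha") ".mha" else ".nii.gz"
  paths <- c(whole = file.path(dir, paste0("mask_whole", ext)),
             cortical = file.path(dir, paste0("mask_cortical", ext)),
             trabecular = file.path(dir, paste0("mask_trabecular", ext)))
  for (nm in names(paths)) {
    img <- density_image(array(as.numeric(masks[[nm]]), dim(masks[[nm]])),
                         voxel_size = like$voxel_size, origin = like$origin)
    write_image(img, paths[[nm]], dtype = "uint8")
  }
  invisible(paths)
}

#' Read compartment masks written by [write_masks()]
#' @param dir Directory containing the three mask files.
#' @param format `"mha"` (default) or `"nifti"`.
#' @return A [bone_masks()].
#' @export
read_masks <- function(dir, format = "mha") {
  ext <- if (format == "mha") ".mha" else ".nii.gz"
  rd <- function(nm) read_image(file.path(dir, paste0("mask_", nm, ext)))$values > 0.5
  bone_masks(rd("whole"), rd("cortical"), rd("trabecular"))
}
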