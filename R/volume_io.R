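#' Read a 3D volume with spacing metadata
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`,
#' `.mhd`) and directories of numbered PNG/TIFF slices with a JSON
#' sidecar `spacing.json` containing `{"spacing_mm": [sx, sy, sz]}`.
#' Files whose voxel values are all in \{0, 1\} are returned as a
#' [VoxelGrid-class] (binary mask), anything else as a
#' [GrayscaleVolume-class]; `as` overrides the detection.
#'
#' Spacing must be present and positive; there is never a silent 1-mm
#' default.
#'
#' @param path file (or slice directory) to read
#' @param as "auto" (default), "mask" or "grayscale"
#' @param spacing optional numeric(3) spacing override in mm (required for
#'   slice stacks without a sidecar)
#' @return a [VoxelGrid-class] or [GrayscaleVolume-class]
#' @export
readVolume <- function(path, as = c("auto", "mask", "grayscale"),
                       spacing = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) return(.read_stack(path, as, spacing))
  ext <- tolower(sub("^.*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  if (grepl("\\.nii(\\.gz)?$", ext)) {
    img <- RNifti::readNifti(path)
    sp <- abs(RNifti::pixdim(img)[1:3])
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  } else if (ext %in% c(".mha", ".mhd")) {
    mi <- .read_metaimage(path)
    arr <- mi$data
    sp <- mi$spacing
  } else {
    stop("unreadable format: ", ext,
         " (supported: .nii, .nii.gz, .mha, .mhd, slice directory)")
  }
  if (!is.null(spacing)) sp <- as.numeric(spacing)
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("spacing unknown: file carries no usable spacing metadata ",
         "and no 'spacing' override was given")
  .wrap_volume(arr, sp, as)
}

.wrap_volume <- function(arr, sp, as) {
  arr <- array(as.vector(as.numeric(arr)), dim(arr))  # strip classes/attrs
  vals_binary <- all(arr %in% c(0, 1))
  if (as == "mask" || (as == "auto" && vals_binary)) {
    if (!vals_binary) stop("values outside {0,1}; cannot read as mask")
    VoxelGrid(arr, sp)
  } else {
    GrayscaleVolume(arr * 1.0, sp)
  }
}

.read_stack <- function(path, as, spacing) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/TIFF slices found in ", path)
  if (is.null(spacing)) {
    sidecar <- file.path(path, "spacing.json")
    if (!file.exists(sidecar))
      stop("spacing unknown: slice stack has no spacing.json sidecar")
    spacing <- as.numeric(jsonlite::read_json(sidecar,
                                              simplifyVector = TRUE)$spacing_mm)
  }
  read1 <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE))
        stop("package 'png' required for PNG stacks")
      m <- png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' required for TIFF stacks")
      m <- tiff::readTIFF(f)
    }
    if (length(dim(m)) == 3L) m <- m[, , 1]   # drop extra channels
    t(m)                                      # [row=y, col=x] -> [x, y]
  }
  slices <- lapply(files, read1)
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(dim(slices[[1]]), length(slices)))
  .wrap_volume(arr, as.numeric(spacing), as)
}

#' Write a 3D volume (spacing preserved)
#'
#' NIfTI (`.nii`, `.nii.gz`) via RNifti, MetaImage (`.mha` single file,
#' `.mhd` + `.raw` pair) through the built-in uncompressed writer. Masks
#' are stored as 8-bit integers, grayscale volumes as doubles.
#'
#' @param x a [VoxelGrid-class] or [GrayscaleVolume-class]
#' @param path output path; the extension selects the format
#' @return `path`, invisibly
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "VoxelGrid") || is(x, "GrayscaleVolume"))
  arr <- voxelData(x)
  if (is.logical(arr)) {
    arr <- arr + 0L
  }
  sp <- voxelSpacing(x)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path,
                       datatype = if (is(x, "VoxelGrid")) "uint8" else "double")
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    .write_metaimage(arr, sp, voxelOrigin(x), path,
                     uchar = is(x, "VoxelGrid"))
  } else {
    stop("unsupported output format for ", path)
  }
  invisible(path)
}

# -- MetaImage (uncompressed) ------------------------------------------------

.mi_types <- list(MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                  MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
                  MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                  MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                  MET_INT = list(what = "integer", size = 4, signed = TRUE),
                  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line)) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  type <- .mi_types[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported MetaImage ElementType: ",
                          hdr$ElementType)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("raw data file not found: ", rawpath)
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    raw <- readBin(rcon, type$what, n = n, size = type$size,
                   signed = type$signed, endian = "little")
  }
  if (length(raw) != n) stop("truncated MetaImage data in ", path)
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else NULL
  list(data = array(raw, dim = dims), spacing = spacing)
}

.write_metaimage <- function(arr, spacing, origin, path, uchar) {
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local_data) "LOCAL" else
    paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(arr), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, digits = 17),
                                           collapse = " ")),
           paste("Offset =", paste(format(origin, digits = 17),
                                   collapse = " ")),
           paste("ElementType =", if (uchar) "MET_UCHAR" else "MET_DOUBLE"),
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  write_data <- function(c2) {
    if (uchar) writeBin(as.integer(arr), c2, size = 1, endian = "little")
    else writeBin(as.double(arr), c2, size = 8, endian = "little")
  }
  if (local_data) {
    write_data(con)
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    write_data(rcon)
  }
  invisible(path)
}

# -- resampling --------------------------------------------------------------

#' Resample a volume to a new voxel spacing
#'
#' The physical extent is preserved to within one voxel per axis (output
#' dimensions are the rounded extent / target ratio). Binary masks use
#' linear interpolation of the 0/1 field followed by thresholding at 0.5
#' (inclusive) by default, which mirrors the smooth boundaries produced by
#' contouring on rescaled slices; `"nearest"` is available as an
#' alternative. Grayscale volumes are linearly interpolated.
#'
#' @param x a [VoxelGrid-class] or [GrayscaleVolume-class]
#' @param target_spacing numeric(3) (or scalar, recycled) in mm
#' @param interpolation "linear" (with 0.5 threshold for masks) or "nearest"
#' @return object of the same class on the new grid
#' @export
resampleGrid <- function(x, target_spacing,
                         interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be positive")
  d <- dim(x)
  extent <- d * voxelSpacing(x)
  out_dim <- as.integer(round(extent / target_spacing))
  if (any(out_dim < 2L))
    stop("target spacing too coarse: would yield fewer than 2 voxels ",
         "along an axis (physical extent ",
         paste(format(extent, digits = 4), collapse = " x "), " mm)")
  arr <- voxelData(x)
  storage.mode(arr) <- "double"
  res <- cpp_resample(arr, dim(arr), voxelSpacing(x), out_dim,
                      target_spacing, interpolation == "nearest")
  if (is(x, "VoxelGrid")) {
    VoxelGrid(res >= 0.5, target_spacing, voxelOrigin(x))
  } else {
    GrayscaleVolume(res, target_spacing, voxelOrigin(x))
  }
}

#' Upscale the X and Z axes (contouring preset)
#'
#' Reproduces the acquisition-side preprocessing in which image stacks are
#' scaled up `factor` times in X and Z before manual contouring: a
#' (0.45, 0.45, 0.40) mm grid becomes (0.09, 0.45, 0.08) mm for
#' `factor = 5`.
#'
#' @param x volume to upscale
#' @param factor integer upscale factor for X and Z (default 5)
#' @param interpolation passed to [resampleGrid()]
#' @export
upscaleXZ <- function(x, factor = 5, interpolation = "linear") {
  sp <- voxelSpacing(x)
  resampleGrid(x, sp / c(factor, 1, factor), interpolation)
}

#' Resample to an isotropic grid
#'
#' Morphometry (in particular sphere-based thickness) requires isotropic
#' voxels; the default target is the smallest input spacing so that no
#' axis loses resolution.
#'
#' @param x volume
#' @param target isotropic spacing in mm (default `min(voxelSpacing(x))`)
#' @param interpolation passed to [resampleGrid()]
#' @export
isotropicResample <- function(x, target = NULL, interpolation = "linear") {
  sp <- voxelSpacing(x)
  if (is.null(target)) target <- min(sp)
  if (max(abs(sp - target)) < 1e-12 * target) return(x)
  resampleGrid(x, rep(target, 3), interpolation)
}
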