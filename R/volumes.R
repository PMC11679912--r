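#' HU volume container
#'
#' A 3D Hounsfield-unit grid with voxel spacing (mm) and world origin.
#' The third array axis is the axial (craniocaudal) one: slice `i` of the
#' volume is the `i`-th axial plane.
#'
#' @param data numeric 3D array of HU values.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param origin numeric length-3 world origin in mm.
#' @return An object of class `hu_volume` (a 3D array with `spacing` and
#'   `origin` attributes).
#' @export
hu_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("expected 3D volume", call. = FALSE)
  }
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite", call. = FALSE)
  }
  structure(data * 1.0, spacing = as.numeric(spacing),
            origin = as.numeric(origin), class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = " x "),
              min(x), max(x)))
  invisible(x)
}

vol_spacing <- function(vol) attr(vol, "spacing")
vol_origin <- function(vol) attr(vol, "origin")

#' Number of axial slices of a volume
#' @param vol an `hu_volume` or 3D array.
#' @return Integer axial extent.
#' @export
n_axial_slices <- function(vol) dim(vol)[3]

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  stop("cannot guess volume format from extension: ", path, call. = FALSE)
}

#' Read an HU volume from NIfTI or MetaImage
#'
#' NIfTI (.nii/.nii.gz) is read through RNifti; MetaImage (.mha/.mhd) through
#' a built-in reader for the uncompressed LOCAL/raw variants. The volume must
#' be 3D; the last array axis is taken as axial.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"nifti"` or `"metaimage"`.
#' @return An [hu_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) {
      stop("expected 3D volume, got ", length(dim(arr)), "D: ", path, call. = FALSE)
    }
    spacing <- RNifti::pixdim(img)
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
    if (length(spacing) < 3L || any(!is.finite(spacing[1:3])) || any(spacing[1:3] <= 0)) {
      stop("missing or invalid voxel spacing metadata: ", path, call. = FALSE)
    }
    hu_volume(arr, spacing = spacing[1:3], origin = origin)
  } else {
    read_metaimage(path)
  }
}

#' Write an HU volume to NIfTI or MetaImage
#'
#' @param vol an [hu_volume()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param datatype on-disk scalar type, `"float"` (32-bit, default) or
#'   `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float", "double")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(vol, "hu_volume"))
  format <- guess_format(path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "nifti") {
    img <- RNifti::asNifti(unclass(vol) + 0)
    RNifti::pixdim(img) <- vol_spacing(vol)
    xf <- diag(c(vol_spacing(vol), 1))
    xf[1:3, 4] <- vol_origin(vol)
    img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
    RNifti::writeNifti(img, path, datatype = datatype)
  } else {
    write_metaimage(vol, path, datatype = datatype)
  }
  invisible(path)
}

# Minimal MetaImage reader: uncompressed MET_* element types, LOCAL (.mha)
# or sidecar .raw (.mhd) payloads. Multi-byte data are little-endian unless
# the header says otherwise.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  data_file <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("unexpected end of MetaImage header: ", path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- kv[2]; val <- trimws(kv[3])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_file <- val; break }
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "0")
  if (ndims != 3L) stop("expected 3D volume, got NDims=", ndims, ": ", path, call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  if (is.null(hdr[["ElementSpacing"]])) {
    stop("missing voxel spacing metadata (ElementSpacing): ", path, call. = FALSE)
  }
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  origin <- if (!is.null(hdr[["Offset"]])) {
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]])
  } else c(0, 0, 0)
  if (!is.null(hdr[["CompressedData"]]) && toupper(hdr[["CompressedData"]]) == "TRUE") {
    stop("compressed MetaImage data is not supported: ", path, call. = FALSE)
  }
  etype <- hdr[["ElementType"]] %||% "MET_FLOAT"
  spec <- switch(etype,
    MET_FLOAT  = list(what = "numeric", size = 4L),
    MET_DOUBLE = list(what = "numeric", size = 8L),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
    MET_INT    = list(what = "integer", size = 4L),
    stop("unsupported MetaImage ElementType: ", etype, call. = FALSE)
  )
  endian <- if (!is.null(hdr[["BinaryDataByteOrderMSB"]]) &&
                toupper(hdr[["BinaryDataByteOrderMSB"]]) == "TRUE") "big" else "little"
  n <- prod(dims)
  if (identical(data_file, "LOCAL")) {
    raw_vals <- readBin(con, spec$what, n = n, size = spec$size, endian = endian,
                        signed = spec$signed %||% TRUE)
  } else {
    raw_path <- file.path(dirname(path), data_file)
    if (!file.exists(raw_path)) stop("MetaImage data file not found: ", raw_path, call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    raw_vals <- readBin(rcon, spec$what, n = n, size = spec$size, endian = endian,
                        signed = spec$signed %||% TRUE)
  }
  if (length(raw_vals) != n) stop("truncated MetaImage payload: ", path, call. = FALSE)
  hu_volume(array(as.numeric(raw_vals), dim = dims), spacing = spacing, origin = origin)
}

write_metaimage <- function(vol, path, datatype = "float") {
  dims <- dim(vol)
  etype <- if (datatype == "float") "MET_FLOAT" else "MET_DOUBLE"
  size <- if (datatype == "float") 4L else 8L
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(format(vol_spacing(vol), scientific = FALSE), collapse = " ")),
    paste("Offset =", paste(format(vol_origin(vol), scientific = FALSE), collapse = " ")),
    paste("ElementType =", etype)
  )
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(vol), con, size = size, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(vol), rcon, size = size, endian = "little")
  }
  invisible(path)
}

#' Pair an aligned ground-truth CT with its synthetic CT
#'
#' Both volumes must share the same grid: identical shape, and spacing and
#' origin equal within `tol` mm (pairs are assumed pre-registered).
#'
#' @param gt,sct [hu_volume()] objects (ground-truth CT and synthetic CT).
#' @param patient_id opaque identifier string.
#' @param modality `"CBCT"` or `"MR"` — the modality the sCT was derived from.
#' @param tol geometry tolerance in mm (default 1e-3).
#' @return A `volume_pair` object.
#' @export
volume_pair <- function(gt, sct, patient_id = "anon", modality = c("CBCT", "MR"),
                        tol = 1e-3) {
  modality <- match.arg(modality)
  stopifnot(inherits(gt, "hu_volume"), inherits(sct, "hu_volume"))
  if (!identical(dim(gt), dim(sct))) {
    stop(sprintf("shape mismatch: GT %s vs sCT %s",
                 paste(dim(gt), collapse = "x"), paste(dim(sct), collapse = "x")),
         call. = FALSE)
  }
  if (max(abs(vol_spacing(gt) - vol_spacing(sct))) > tol) {
    stop("spacing mismatch beyond tolerance between GT and sCT", call. = FALSE)
  }
  if (max(abs(vol_origin(gt) - vol_origin(sct))) > tol) {
    stop("origin mismatch beyond tolerance between GT and sCT", call. = FALSE)
  }
  structure(list(patient_id = as.character(patient_id), modality = modality,
                 gt = gt, sct = sct),
            class = "volume_pair")
}

#' Build a volume pair from files on disk
#'
#' @param gt_path,sct_path paths to the ground-truth CT and synthetic CT.
#' @inheritParams volume_pair
#' @return A `volume_pair`.
#' @export
make_pair <- function(gt_path, sct_path, modality = c("CBCT", "MR"),
                      patient_id = NULL, tol = 1e-3) {
  modality <- match.arg(modality)
  if (is.null(patient_id)) {
    patient_id <- sub("\\.(nii(\\.gz)?|mha|mhd)$", "", basename(gt_path),
                      ignore.case = TRUE)
  }
  volume_pair(read_volume(gt_path), read_volume(sct_path),
              patient_id = patient_id, modality = modality, tol = tol)
}

#' @export
print.volume_pair <- function(x, ...) {
  cat(sprintf("<volume_pair> patient %s (%s), %s voxels\n", x$patient_id,
              x$modality, paste(dim(x$gt), collapse = " x ")))
  invisible(x)
}

#' Extract the ordered axial slices of a volume
#'
#' @param vol an `hu_volume` or 3D array.
#' @return A list of 2D matrices; element `i` is the `i`-th axial plane.
#'   An empty axial extent yields an empty list.
#' @export
extract_axial_slices <- function(vol) {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3L) stop("expected 3D volume", call. = FALSE)
  if (d[3] == 0L) return(list())
  lapply(seq_len(d[3]), function(i) unclass(vol)[, , i, drop = TRUE])
}

#' Stack axial slices back into a volume
#'
#' Inverse of [extract_axial_slices()].
#'
#' @param slices list of equally shaped 2D matrices.
#' @param spacing,origin geometry of the rebuilt volume.
#' @return An [hu_volume()].
#' @export
stack_axial_slices <- function(slices, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(slices) > 0L)
  d2 <- dim(slices[[1]])
  arr <- array(0, c(d2, length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  hu_volume(arr, spacing = spacing, origin = origin)
}

#' Assemble and optionally write a predicted-MAE overlay volume
#'
#' Builds the slice-constant "predicted MAE" volume: plane `i` of the output
#' is filled with `predictions[i]`, and the geometry is copied from the
#' source sCT so the overlay can be fused in any standard viewer.
#'
#' @param predictions numeric vector, one predicted MAE (HU) per axial slice.
#' @param source_sct the sCT `hu_volume` the predictions refer to.
#' @param path optional output path; when given the volume is written there
#'   as 32-bit NIfTI (conventional suffix `_pmae.nii.gz`).
#' @return The pMAE `hu_volume`, invisibly when `path` is given.
#' @export
write_pmae_volume <- function(predictions, source_sct, path = NULL) {
  stopifnot(inherits(source_sct, "hu_volume"))
  nz <- n_axial_slices(source_sct)
  if (length(predictions) != nz) {
    stop(sprintf("expected %d per-slice predictions, got %d", nz,
                 length(predictions)), call. = FALSE)
  }
  if (any(!is.finite(predictions)) || any(predictions < 0)) {
    stop("predicted MAE values must be finite and nonnegative", call. = FALSE)
  }
  d <- dim(source_sct)
  arr <- array(rep(as.numeric(predictions), each = d[1] * d[2]), dim = d)
  vol <- hu_volume(arr, spacing = vol_spacing(source_sct),
                   origin = vol_origin(source_sct))
  if (!is.null(path)) {
    write_volume(vol, path, datatype = "float")
    return(invisible(vol))
  }
  vol
}

#' Conventional pMAE overlay path for an sCT file
#' @param sct_path the sCT file path.
#' @return The matching `_pmae.nii.gz` path.
#' @export
pmae_path <- function(sct_path) {
  base <- sub("\\.(nii(\\.gz)?|mha|mhd)$", "", sct_path, ignore.case = TRUE)
  paste0(base, "_pmae.nii.gz")
}
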