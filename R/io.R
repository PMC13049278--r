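# Readers and writers binding the pipeline to disk: temperature series and
# volumetric maps as NIfTI, complex image dynamics as a real/imaginary-stacked
# NIfTI with a JSON sidecar documenting the layout, tables as headered CSV.

# Plain numeric array from a NIfTI image (drops image-header attributes).
nifti_array <- function(img) {
  arr <- as.array(img)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a temperature series as 4D NIfTI
#'
#' Spatial dims first, time last; voxel spacing (mm) and the frame interval
#' (s) are stored in the NIfTI pixdim. 2D series are written with a singleton
#' third dimension so time always occupies the fourth NIfTI dimension.
#'
#' @param series [temperature_series()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
write_temperature_nifti <- function(series, path) {
  if (!inherits(series, "temperature_series"))
    stop("series must be a temperature_series")
  d <- dim(series$frames)
  nd <- length(d) - 1L
  arr <- series$frames
  sp <- series$spacing_mm
  if (nd == 2L) {
    arr <- array(arr, dim = c(d[1:2], 1L, d[3]))
    sp <- c(sp, 1)
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(sp, series$frame_interval_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a temperature series from 4D NIfTI
#'
#' Inverse of [write_temperature_nifti()]; a singleton third dimension is
#' dropped back to a 2D series.
#'
#' @param path NIfTI file written by [write_temperature_nifti()]
#' @return [temperature_series()]
#' @export
read_temperature_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- nifti_array(img)
  pd <- RNifti::pixdim(img)
  d <- dim(arr)
  if (length(d) != 4L) stop("expected a 4D temperature NIfTI")
  sp <- pd[1:3]
  if (d[3] == 1L) {
    arr <- array(arr, dim = d[c(1, 2, 4)])
    sp <- sp[1:2]
  }
  temperature_series(arr, spacing_mm = sp, frame_interval_s = pd[4])
}

#' Write a deposited-power map as NIfTI with a JSON sidecar
#'
#' The values go to `<path>`; the crop box and provenance go to
#' `<path>.json`.
#'
#' @param q [qmap()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
write_qmap_nifti <- function(q, path) {
  if (!inherits(q, "qmap")) stop("q must be a qmap")
  img <- RNifti::asNifti(q$values)
  img <- RNifti::`pixdim<-`(img, q$spacing_mm)
  RNifti::writeNifti(img, path)
  meta <- list(units = "W/m^3", spacing_mm = q$spacing_mm,
               crop_roi = q$crop_roi, provenance = q$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a deposited-power map written by [write_qmap_nifti()]
#' @param path NIfTI path (the `<path>.json` sidecar is read if present)
#' @return [qmap()]
#' @export
read_qmap_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- nifti_array(img)
  sp <- RNifti::pixdim(img)[seq_along(dim(arr))]
  side <- paste0(path, ".json")
  crop <- NULL; prov <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$crop_roi))
      crop <- list(lo = as.integer(meta$crop_roi$lo),
                   hi = as.integer(meta$crop_roi$hi))
    if (!is.null(meta$provenance)) prov <- as.list(meta$provenance)
    if (!is.null(meta$spacing_mm)) sp <- meta$spacing_mm
  }
  qmap(arr, sp, crop_roi = crop, provenance = prov)
}

#' Write complex image dynamics as a real/imaginary-stacked NIfTI
#'
#' Container layout (documented in the `<path>.json` sidecar): a 5D NIfTI of
#' shape `(x, y, z, n_frames, 2)` — singleton z for 2D data — whose last axis
#' holds the real part (index 1) and imaginary part (index 2). The sidecar
#' records the layout tag, spatial dims, voxel spacing, and frame interval.
#'
#' @param frames list of [complex_image_frame()]
#' @param path output path (`.nii` or `.nii.gz`)
#' @param spacing_mm voxel spacing (mm)
#' @param frame_interval_s frame interval (s)
#' @return the path, invisibly
#' @export
write_complex_series <- function(frames, path, spacing_mm, frame_interval_s) {
  if (!length(frames) || !inherits(frames[[1L]], "complex_image_frame"))
    stop("frames must be a nonempty list of complex_image_frame objects")
  d <- dim(frames[[1L]]$data)
  nd <- length(d)
  nt <- length(frames)
  d3 <- if (nd == 2L) c(d, 1L) else d
  arr <- array(0, dim = c(d3, nt, 2L))
  nvox <- prod(d3)
  for (n in seq_len(nt)) {
    v <- frames[[n]]$data
    arr[(n - 1L) * nvox + seq_len(nvox)] <- Re(v)
    arr[(nt + n - 1L) * nvox + seq_len(nvox)] <- Im(v)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  meta <- list(layout = "real_imag_last_axis",
               spatial_dims = d, spacing_mm = spacing_mm,
               n_frames = nt, frame_interval_s = frame_interval_s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read complex image dynamics written by [write_complex_series()]
#' @param path NIfTI path with its `<path>.json` sidecar
#' @return list with `frames` (list of [complex_image_frame()]),
#'   `spacing_mm`, `frame_interval_s`
#' @export
read_complex_series <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing complex-series sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$layout, "real_imag_last_axis"))
    stop("unsupported complex container layout: ", meta$layout)
  arr <- nifti_array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) != 5L || d[5] != 2L)
    stop("expected a 5D real/imaginary-stacked NIfTI")
  nt <- d[4]
  sdims <- as.integer(meta$spatial_dims)
  nvox <- prod(d[1:3])
  frames <- vector("list", nt)
  for (n in seq_len(nt)) {
    re <- arr[(n - 1L) * nvox + seq_len(nvox)]
    im <- arr[(prod(d[1:4]) + (n - 1L) * nvox) + seq_len(nvox)]
    frames[[n]] <- complex_image_frame(array(complex(real = re, imaginary = im),
                                             dim = sdims),
                                       frame_index = n - 1L)
  }
  list(frames = frames, spacing_mm = meta$spacing_mm,
       frame_interval_s = meta$frame_interval_s)
}

#' Write a logical mask as NIfTI (0/1)
#' @param mask logical array
#' @param path output path
#' @param spacing_mm voxel spacing (mm)
#' @return the path, invisibly
#' @export
write_mask_nifti <- function(mask, path, spacing_mm) {
  arr <- array(as.numeric(mask), dim = dim(mask))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a data frame as headered CSV
#' @param df data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
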