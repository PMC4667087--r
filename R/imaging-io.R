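#' @name imaging-io
#' @title Image volume input/output and the co-registration contract
#'
#' @description All downstream analysis assumes the input channels are
#' co-registered and skull-stripped: every voxel's multispectral feature
#' vector must originate from the same anatomical location. These helpers
#' read NIfTI channels, verify the shared-grid contract, and refuse (rather
#' than silently resample) mismatched geometry.
NULL

new_channel_image <- function(data, voxel_size_mm, affine, channel_name) {
  structure(list(data = data,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine,
                 channel_name = channel_name),
            class = "channel_image")
}

#' Read a single MRI channel from a NIfTI file
#'
#' @param path Path to a 3-D NIfTI file (`.nii` or `.nii.gz`).
#' @param channel_name Channel label, conventionally one of `"FLAIR"`,
#'   `"T2"`, `"MT"`.
#' @return A `channel_image`: the 3-D data array plus voxel size (mm),
#'   4x4 grid-to-world affine and the channel name. NaN values (outside a
#'   mask) are permitted and preserved.
#' @export
read_channel <- function(path, channel_name = "FLAIR") {
  if (!file.exists(path)) stopf("cannot read channel '%s': file not found: %s",
                                channel_name, path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stopf("unreadable NIfTI file: %s (%s)",
                                            path, conditionMessage(e)))
  if (length(dim(img)) != 3L)
    stopf("expected a 3-D image, got %d-D: %s", length(dim(img)), path)
  new_channel_image(data = array(as.numeric(img), dim(img)),
                    voxel_size_mm = RNifti::pixdim(img)[1:3],
                    affine = structure(RNifti::xform(img), class = NULL),
                    channel_name = channel_name)
}

#' Write a channel image (or bare array) as NIfTI
#'
#' @param x A `channel_image`, or a numeric/logical 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size, required when `x` is a bare array.
#' @param datatype NIfTI storage type; `"float"` (32-bit) by default.
#' @return `path`, invisibly.
#' @export
write_channel <- function(x, path, voxel_size_mm = NULL, datatype = "float") {
  if (inherits(x, "channel_image")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$data
  }
  if (is.null(voxel_size_mm)) stopf("voxel_size_mm required for bare arrays")
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  img <- RNifti::`pixdim<-`(img, voxel_size_mm)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Assemble co-registered channels into a multispectral volume
#'
#' Verifies the registration contract: all channels (and the brain mask)
#' must share grid shape, voxel size and affine to within 1e-4 mm. Channel
#' order is preserved and becomes the feature-column order downstream.
#'
#' @param channels List of `channel_image` objects (>= 2).
#' @param brain_mask 3-D logical array; analysis is restricted to it.
#' @return A `multispectral_volume`: `channels`, `brain_mask`,
#'   `voxel_size_mm`, `n_channels`.
#' @export
assemble_multispectral <- function(channels, brain_mask) {
  if (length(channels) < 2L) stopf("need at least 2 channels, got %d",
                                   length(channels))
  ref <- channels[[1]]
  for (ch in channels[-1]) {
    if (!identical(dim(ch$data), dim(ref$data)))
      stopf("channel '%s' grid %s does not match '%s' grid %s (missing registration?)",
            ch$channel_name, paste(dim(ch$data), collapse = "x"),
            ref$channel_name, paste(dim(ref$data), collapse = "x"))
    if (max(abs(ch$voxel_size_mm - ref$voxel_size_mm)) > 1e-4)
      stopf("channel '%s' voxel size differs from '%s'", ch$channel_name,
            ref$channel_name)
    if (!is.null(ch$affine) && !is.null(ref$affine) &&
        max(abs(ch$affine - ref$affine)) > 1e-4)
      stopf("channel '%s' affine differs from '%s' (missing registration?)",
            ch$channel_name, ref$channel_name)
  }
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (!identical(dim(brain_mask), dim(ref$data)))
    stopf("brain mask grid does not match the channel grid")
  if (!any(brain_mask)) stopf("brain mask is empty")
  for (ch in channels)
    if (any(!is.finite(ch$data[brain_mask])))
      stopf("channel '%s' has non-finite values inside the brain mask",
            ch$channel_name)
  structure(list(channels = channels, brain_mask = brain_mask,
                 voxel_size_mm = ref$voxel_size_mm,
                 n_channels = length(channels)),
            class = "multispectral_volume")
}

#' @export
print.multispectral_volume <- function(x, ...) {
  cat(sprintf("Multispectral volume: %d channels (%s), grid %s, %.0f in-mask voxels\n",
              x$n_channels,
              paste(vapply(x$channels, `[[`, "", "channel_name"), collapse = ", "),
              paste(dim(x$brain_mask), collapse = "x"), sum(x$brain_mask)))
  invisible(x)
}

#' Compute a brain mask from a single channel
#'
#' Stand-in for skull stripping on phantom data: thresholds the image at a
#' quantile of its nonzero intensities, keeps the largest 26-connected
#' component and fills holes slice-wise.
#'
#' @param image A `channel_image` (a T2-like channel works well: brain
#'   tissue and CSF are both bright against the zero background).
#' @param quantile Quantile of nonzero intensities used as threshold,
#'   in (0, 1); default 0.5.
#' @return 3-D logical array.
#' @export
compute_brain_mask <- function(image, quantile = 0.5) {
  stopifnot(inherits(image, "channel_image"))
  if (quantile <= 0 || quantile >= 1) stopf("quantile must be in (0, 1)")
  dat <- image$data
  nz <- dat[is.finite(dat) & dat != 0]
  if (length(nz) == 0L) stopf("all-zero image: cannot compute a brain mask")
  thr <- stats::quantile(nz, quantile, names = FALSE)
  fg <- array(is.finite(dat) & dat >= thr, dim(dat))
  if (!any(fg)) return(fg)
  lab <- label_components(fg, 26)
  mask <- lab == 1L
  for (z in seq_len(dim(mask)[3])) mask[, , z] <- fill_holes_2d(mask[, , z])
  mask
}

# Fill background holes of a 2-D slice: background pixels not connected
# (4-connectivity) to the slice border become foreground.
fill_holes_2d <- function(sl) {
  dm <- dim(sl)
  bg <- !sl
  reach <- matrix(FALSE, dm[1], dm[2])
  frontier <- bg & (row(sl) %in% c(1L, dm[1]) | col(sl) %in% c(1L, dm[2]))
  while (any(frontier & !reach)) {
    reach <- reach | frontier
    grown <- matrix(FALSE, dm[1], dm[2])
    grown[-1, ] <- grown[-1, ] | reach[-dm[1], ]
    grown[-dm[1], ] <- grown[-dm[1], ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -dm[2]]
    grown[, -dm[2]] <- grown[, -dm[2]] | reach[, -1]
    frontier <- grown & bg & !reach
  }
  sl | (bg & !reach)
}
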