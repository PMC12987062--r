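# Reading, writing and basic conversions for multi-class label volumes.
# NIfTI axis order (x, y, z) is remapped at the I/O boundary so that the
# through-plane axis is always axis 1 internally (slice, row, column).

#' Read a label volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file into a [LabelVolume-class]. Values within
#' `1e-3` of an integer are rounded (NIfTI files written as float often carry
#' tiny representation error); anything farther from an integer is an error.
#'
#' @param path Path to a 3D NIfTI file.
#' @param classNames Ordered class map; defaults to [whsClassNames()]. Labels
#'   outside `[0, length(classNames) - 1]` are an error.
#' @return A [LabelVolume-class] with spacing taken from the file header.
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path, classNames = whsClassNames()) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  if (length(dim(a)) != 3L) stop("not a 3D volume: ", path)
  r <- round(a)
  if (max(abs(a - r)) > 1e-3)
    stop("non-integer label values in ", path)
  pd <- RNifti::pixdim(img)
  # NIfTI (x, y, z) -> internal (z, y, x)
  vox <- aperm(r, c(3, 2, 1))
  LabelVolume(vox, spacing = rev(pd[1:3]), classNames = classNames)
}

#' Write a label volume to NIfTI
#'
#' @param vol A [LabelVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @return Invisibly, `path`.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  a <- aperm(vol@voxels, c(3, 2, 1))  # internal (z, y, x) -> NIfTI (x, y, z)
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rev(vol@spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' One-hot encode a label volume
#'
#' Channel `c + 1` of the result is 1 exactly where the voxel class is `c`,
#' so channel sums are exactly 1 everywhere.
#'
#' @param vol A [LabelVolume-class].
#' @param nClasses Number of channels (background included); voxel values
#'   must be `< nClasses`.
#' @return A [ProbabilityVolume-class] with values in \{0, 1\}.
#' @export
toOneHot <- function(vol, nClasses = length(classNames(vol))) {
  v <- vol@voxels
  if (max(v) >= nClasses)
    stop("label ", max(v), " exceeds nClasses - 1 = ", nClasses - 1)
  arr <- array(0, c(nClasses, dim(v)))
  # channel-fastest layout: voxel j occupies entries (j-1)*C + 1 .. j*C
  arr[(seq_along(v) - 1L) * nClasses + as.integer(v) + 1L] <- 1
  ProbabilityVolume(arr, spacing = vol@spacing)
}

#' Discrete labels from class probabilities
#'
#' Per-voxel argmax over channels; ties are broken by the lowest class
#' index, so exactly uniform probabilities yield background.
#'
#' @param probs A [ProbabilityVolume-class].
#' @param classNames Class map for the result.
#' @return A [LabelVolume-class].
#' @export
argmaxLabels <- function(probs, classNames = whsClassNames()) {
  v <- probs@values
  C <- dim(v)[1]
  m <- matrix(v, nrow = C)
  lab <- max.col(t(m), ties.method = "first") - 1L
  LabelVolume(array(lab, dim(v)[-1]), spacing = probs@spacing,
              classNames = classNames[seq_len(min(C, length(classNames)))])
}

#' Crop or pad a label volume to a target shape
#'
#' Produces a volume of exactly `target` shape, cropping and/or padding with
#' background (class 0) as needed. With `center = "centroid"` the output is
#' centred on the foreground centre of mass rounded to the nearest voxel.
#'
#' @param vol A [LabelVolume-class].
#' @param target Integer `(D, H, W)` target shape, all >= 1.
#' @param center Either `"centroid"` or a 0-based voxel coordinate
#'   `(d, h, w)` to centre the output on.
#' @return A [LabelVolume-class] of shape `target`.
#' @export
cropOrPad <- function(vol, target, center = "centroid") {
  v <- vol@voxels
  dIn <- dim(v)
  target <- as.integer(target)
  stopifnot(length(target) == 3L, all(target >= 1L))
  if (identical(center, "centroid")) {
    fg <- which(v != 0L, arr.ind = TRUE)
    if (nrow(fg) == 0L)
      stop("cannot centre on centroid: volume has no foreground")
    center <- round(colMeans(fg)) - 1  # 0-based
  }
  center <- as.numeric(center)
  out <- array(0L, target)
  # voxel `center` maps to the output centre floor((target - 1) / 2)
  offset <- round(center) - floor((target - 1) / 2)  # input index of out[0,0,0]
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    i0 <- max(0, offset[ax])
    i1 <- min(dIn[ax] - 1, offset[ax] + target[ax] - 1)
    if (i0 > i1) next
    src[[ax]] <- (i0:i1) + 1L
    dst[[ax]] <- (i0:i1) - offset[ax] + 1L
  }
  if (!any(vapply(src, is.null, TRUE)))
    out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  LabelVolume(out, spacing = vol@spacing, classNames = vol@classNames)
}
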