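#' @import methods
#' @importFrom stats rnorm runif rpois quantile cor.test sd
#' @importFrom utils write.csv read.csv
#' @useDynLib whrecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Default whole-heart class map
#'
#' Ordered class names for the eight-label whole-heart convention used
#' throughout the package: background plus seven cardiac structures
#' (left/right ventricular cavities, left/right atria, left-ventricular
#' myocardium, ascending aorta, pulmonary artery).
#'
#' @return Character vector of length 8, named by integer class id 0..7.
#' @export
#' @examples
#' whsClassNames()
whsClassNames <- function() {
  c("0" = "background", "1" = "LV", "2" = "RV", "3" = "LA", "4" = "RA",
    "5" = "Myo", "6" = "AO", "7" = "PA")
}

#' LabelVolume: a multi-class segmentation volume
#'
#' An integer-valued 3D voxel grid of anatomical class ids together with its
#' physical voxel spacing and an ordered class map. The through-plane
#' (slice) axis is always axis 1 of the array, so a volume is indexed
#' `(slice, row, column)` = (z, y, x); spacing is `(sz, sy, sx)` in mm.
#' Voxel coordinates are 0-based with physical positions at voxel centres,
#' centre of voxel `i` at `i * spacing` along each axis.
#'
#' @slot voxels 3D integer array (D x H x W) of class ids in `[0, C]`.
#' @slot spacing Numeric length 3, `(sz, sy, sx)` in mm, all positive.
#' @slot classNames Ordered character vector mapping id -> structure name.
#' @export
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric",
                 classNames = "character"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (any(dim(v) < 1L)) return("all dimensions must be >= 1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values (sz, sy, sx)")
    if (any(v != round(v))) return("voxel values must be integers")
    C <- length(object@classNames) - 1L
    if (any(v < 0) || any(v > C))
      return(sprintf("voxel values must lie in [0, %d]", C))
    TRUE
  }
)

#' Construct a LabelVolume
#'
#' @param voxels 3D integer array (D x H x W), slice axis first.
#' @param spacing Numeric `(sz, sy, sx)` voxel spacing in mm.
#' @param classNames Ordered class map; defaults to [whsClassNames()].
#' @return A [LabelVolume-class] object.
#' @export
#' @examples
#' v <- LabelVolume(array(0L, c(4, 8, 8)), spacing = c(2, 1, 1))
#' dim(voxels(v))
LabelVolume <- function(voxels, spacing = c(1, 1, 1),
                        classNames = whsClassNames()) {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      classNames = classNames)
}

#' ProbabilityVolume: a per-class soft label field
#'
#' A 4D array of class probabilities, channel-first: `(C+1, D, H, W)` with
#' channel sums equal to 1 at every voxel. One-hot encodings are the special
#' case with values in \{0, 1\}.
#'
#' @slot values 4D numeric array `(C+1, D, H, W)`, entries in `[0, 1]`.
#' @slot spacing Numeric `(sz, sy, sx)` in mm.
#' @export
setClass("ProbabilityVolume",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 4L) return("values must be a 4D array (C, D, H, W)")
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      return("probabilities must lie in [0, 1]")
    s <- colSums(matrix(v, nrow = dim(v)[1]))
    if (max(abs(s - 1)) > 1e-6)
      return("channel sums must equal 1 at every voxel (tolerance 1e-6)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values")
    TRUE
  }
)

#' Construct a ProbabilityVolume
#'
#' @param values 4D numeric array, channel-first `(C, D, H, W)`.
#' @param spacing Numeric `(sz, sy, sx)` in mm.
#' @return A [ProbabilityVolume-class] object.
#' @export
ProbabilityVolume <- function(values, spacing = c(1, 1, 1)) {
  new("ProbabilityVolume", values = values, spacing = as.numeric(spacing))
}

#' DegradationConfig: parameters of the stochastic degradation operator
#'
#' Describes the acquisition-degradation model applied to clean label
#' volumes: per-slice rigid misalignment (translation/rotation sampled
#' uniformly within ranges, applied with probability `misalignProb`),
#' through-plane downsampling (`zFactor`, keeping slice indices congruent to
#' `zPhase`), and label-noise injection (boundary perturbation and speckle
#' blobs emulating segmentation defects).
#'
#' @slot translationRange Max `|dx|`, `|dy|` per slice, voxels (real).
#' @slot rotationRange Max in-plane rotation per slice, degrees.
#' @slot misalignProb Probability that a slice is displaced.
#' @slot zFactor Integer through-plane downsampling factor, >= 1.
#' @slot zPhase Residue class of slices kept, in `[0, zFactor)`.
#' @slot noise Named list: `boundaryProb` (per-slice probability of a
#'   boundary perturbation), `boundaryRadius` (voxels), `speckleRate`
#'   (Poisson blob rate per slice), `blobRadius` (voxels).
#' @slot severity Tag, one of `"easy"`, `"medium"`, `"hard"`, `"custom"`.
#' @export
setClass("DegradationConfig",
  representation(translationRange = "numeric", rotationRange = "numeric",
                 misalignProb = "numeric", zFactor = "integer",
                 zPhase = "integer", noise = "list", severity = "character"),
  validity = function(object) {
    if (object@translationRange < 0 || object@rotationRange < 0)
      return("ranges must be >= 0")
    if (object@misalignProb < 0 || object@misalignProb > 1)
      return("misalignProb must be in [0, 1]")
    if (object@zFactor < 1L) return("zFactor must be >= 1")
    if (object@zPhase < 0L || object@zPhase >= object@zFactor)
      return("zPhase must be in [0, zFactor)")
    n <- object@noise
    need <- c("boundaryProb", "boundaryRadius", "speckleRate", "blobRadius")
    if (!all(need %in% names(n))) return("incomplete noise specification")
    if (n$boundaryProb < 0 || n$boundaryProb > 1)
      return("boundaryProb must be in [0, 1]")
    if (n$speckleRate < 0) return("speckleRate must be >= 0")
    TRUE
  }
)

#' Construct a DegradationConfig
#'
#' @param translationRange Max per-slice translation magnitude, voxels.
#' @param rotationRange Max per-slice rotation, degrees.
#' @param misalignProb Per-slice displacement probability.
#' @param zFactor Through-plane downsampling factor (integer >= 1).
#' @param zPhase Residue class of kept slices, `0 <= zPhase < zFactor`.
#' @param noise List with `boundaryProb`, `boundaryRadius`, `speckleRate`,
#'   `blobRadius`; defaults to no noise.
#' @param severity Severity tag (informational).
#' @return A [DegradationConfig-class] object.
#' @seealso [severityPreset()] for the graded presets.
#' @export
#' @examples
#' degradationConfig(translationRange = 3, misalignProb = 0.6)
degradationConfig <- function(translationRange = 0, rotationRange = 0,
                              misalignProb = 0, zFactor = 1L, zPhase = 0L,
                              noise = list(boundaryProb = 0,
                                           boundaryRadius = 1,
                                           speckleRate = 0, blobRadius = 1),
                              severity = "custom") {
  new("DegradationConfig", translationRange = translationRange,
      rotationRange = rotationRange, misalignProb = misalignProb,
      zFactor = as.integer(zFactor), zPhase = as.integer(zPhase),
      noise = noise, severity = severity)
}

#' DegradationRecord: the realized transforms of one degradation draw
#'
#' A reproducibility ledger for the stochastic degradation operator: the
#' exact per-slice rigid transforms applied, the slice indices kept by
#' through-plane downsampling, and the log of injected noise events. A
#' record is sufficient to re-apply the identical misalignment to another
#' volume of the same shape (see [applyMisalignRecord()]).
#'
#' @slot transforms data.frame, one row per input slice: `slice` (0-based),
#'   `displaced`, `dx`, `dy`, `theta` (degrees).
#' @slot keptSlices Integer vector of kept slice indices (0-based).
#' @slot noiseEvents data.frame log of noise events.
#' @slot seed Integer seed used for the draw (NA if drawn from the ambient
#'   RNG stream).
#' @export
setClass("DegradationRecord",
  representation(transforms = "data.frame", keptSlices = "integer",
                 noiseEvents = "data.frame", seed = "integer"))

#' MetricsReport: per-structure evaluation of one case
#'
#' Holds per-class and mean Dice, 95th-percentile Hausdorff distance (mm),
#' average symmetric surface distance (mm), surface-to-volume curvature
#' intensity before and after correction, and the relative curvature
#' variation rate.
#'
#' @slot table data.frame, one row per class plus a `"mean"` row, columns
#'   `class`, `dice`, `hd95`, `assd`, `kappaPre`, `kappaPost`, `rKappa`.
#' @slot caseId Character case identifier.
#' @slot severity Character severity tag.
#' @export
setClass("MetricsReport",
  representation(table = "data.frame", caseId = "character",
                 severity = "character"))

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelVolume %d x %d x %d (D x H x W), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  tab <- tabulate(object@voxels + 1L, nbins = length(object@classNames))
  names(tab) <- object@classNames
  cat("voxel counts:\n")
  print(tab)
})

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityVolume %d classes, %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
})

setMethod("show", "DegradationConfig", function(object) {
  cat(sprintf(
    "DegradationConfig [%s]: |t| <= %.2f vox, |rot| <= %.2f deg, p = %.2f\n",
    object@severity, object@translationRange, object@rotationRange,
    object@misalignProb))
  cat(sprintf("  z downsampling: factor %d, phase %d\n",
              object@zFactor, object@zPhase))
  n <- object@noise
  cat(sprintf(
    "  noise: boundary p=%.2f r=%g, speckle rate=%g blob r=%g\n",
    n$boundaryProb, n$boundaryRadius, n$speckleRate, n$blobRadius))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport case '%s' (severity %s)\n",
              object@caseId, object@severity))
  print(object@table, digits = 4)
})

#' @rdname LabelVolume-class
#' @param object,x A `LabelVolume`.
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname LabelVolume-class
#' @export
setMethod("voxels", "LabelVolume", function(object) object@voxels)

#' Voxel spacing accessor
#' @param object A volume object.
#' @return Numeric `(sz, sy, sx)` in mm.
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname spacing
#' @export
setMethod("spacing", "LabelVolume", function(object) object@spacing)
#' @rdname spacing
#' @export
setMethod("spacing", "ProbabilityVolume", function(object) object@spacing)

#' Class map accessor
#' @param object A `LabelVolume`.
#' @return Named character vector mapping class id to structure name.
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @rdname classNames
#' @export
setMethod("classNames", "LabelVolume", function(object) object@classNames)

#' Probability values accessor
#' @param object A `ProbabilityVolume`.
#' @return 4D numeric array `(C, D, H, W)`.
#' @export
setGeneric("probValues", function(object) standardGeneric("probValues"))
#' @rdname probValues
#' @export
setMethod("probValues", "ProbabilityVolume", function(object) object@values)

#' Metrics table accessor
#' @param object A `MetricsReport`.
#' @return The per-class metrics data.frame.
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))
#' @rdname metricsTable
#' @export
setMethod("metricsTable", "MetricsReport", function(object) object@table)

#' @export
#' @rdname MetricsReport-class
#' @param x A `MetricsReport`.
#' @param row.names,optional,... Passed through (unused).
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  tab <- x@table
  tab$caseId <- x@caseId
  tab$severity <- x@severity
  tab
}
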