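#' @name auriMorph-generics
#' @title Generics for volume accessors and morphometry
#' @param x an object
#' @param ... further arguments passed to methods
NULL

#' @rdname auriMorph-generics
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname auriMorph-generics
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname auriMorph-generics
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))

#' @rdname auriMorph-generics
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname auriMorph-generics
#' @export
setGeneric("cartilageVolume", function(x) standardGeneric("cartilageVolume"))

#' @rdname auriMorph-generics
#' @export
setGeneric("cartilageSurface",
           function(x, ...) standardGeneric("cartilageSurface"))

#' @rdname auriMorph-generics
#' @export
setGeneric("thicknessMap", function(x, ...) standardGeneric("thicknessMap"))

#' @rdname auriMorph-generics
#' @export
setGeneric("meanThickness", function(x) standardGeneric("meanThickness"))

#' @rdname auriMorph-generics
#' @export
setGeneric("morphometryAll",
           function(x, ...) standardGeneric("morphometryAll"))

#' @rdname auriMorph-generics
#' @export
setGeneric("simulateRater",
           function(x, model, ...) standardGeneric("simulateRater"))

.vol_accessors <- function(cls) {
  setMethod("voxelData", cls, function(x) x@data)
  setMethod("voxelSpacing", cls, function(x) x@spacing)
  setMethod("voxelOrigin", cls, function(x) x@origin)
  setMethod("voxelVolume", cls, function(x) prod(x@spacing))
  setMethod("dim", cls, function(x) dim(x@data))
}
.vol_accessors("VoxelGrid")
.vol_accessors("GrayscaleVolume")

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  foreground: %d voxels (%.4g mm^3)\n",
              sum(object@data), sum(object@data) * prod(object@spacing)))
})

setMethod("show", "GrayscaleVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "GrayscaleVolume %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2],
    object@spacing[3]))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf(
    "MorphometryResult '%s': Cg.V %.4g mm^3, Cg.S %.4g mm^2, Cg.Th %.4g mm\n",
    object@specimen_id, object@cg_v, object@cg_s, object@cg_th))
  cat(sprintf("  computed at spacing %.4g x %.4g x %.4g mm\n",
              object@spacing_used[1], object@spacing_used[2],
              object@spacing_used[3]))
})

#' @export
#' @method as.data.frame MorphometryResult
as.data.frame.MorphometryResult <- function(x, ...) {
  data.frame(specimen_id = x@specimen_id, cg_v_mm3 = x@cg_v,
             cg_s_mm2 = x@cg_s, cg_th_mm = x@cg_th,
             sx = x@spacing_used[1], sy = x@spacing_used[2],
             sz = x@spacing_used[3], stringsAsFactors = FALSE)
}

setMethod("show", "PrecisionReport", function(object) {
  cat(sprintf("PrecisionReport [%s]\n", object@metric_name))
  cat(sprintf("  mean %.6g, PE_SD %.6g, PE_%%CV %.4g%%, dof %d (%s), ICC %s\n",
              object@mean, object@pe_sd, object@pe_pct_cv, object@dof,
              if (object@dof_ok) ">= 27" else "< 27",
              ifelse(is.na(object@icc), "NA", sprintf("%.4f", object@icc))))
})

setMethod("show", "PairwiseMaskComparison", function(object) {
  cat(sprintf(
    "PairwiseMaskComparison: r = %s, common %.3f, A-only %.3f, B-only %.3f\n",
    ifelse(is.na(object@pearson_r), "NA", sprintf("%.4f", object@pearson_r)),
    object@common_fraction, object@a_only_fraction, object@b_only_fraction))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom (%s), truth: Cg.V %.4g mm^3, Cg.S %.4g mm^2, Cg.Th %.4g mm [%s]\n",
              object@spec@shape, object@truth$cg_v, object@truth$cg_s,
              object@truth$cg_th, object@truth$method))
  show(object@grid)
})
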