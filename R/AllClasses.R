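#' @import methods
#' @importFrom stats rnorm qnorm sd cor aggregate coef lm
#' @importFrom utils read.csv write.csv
NULL

.check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !is.numeric(spacing) ||
      any(!is.finite(spacing)) || any(spacing <= 0))
    return("spacing must be three strictly positive finite numbers (mm)")
  NULL
}

#' Voxel grid: a 3D binary segmentation mask with physical spacing
#'
#' The universal currency of the morphometry pipeline: a 3D logical array
#' stored `[x, y, z]` (x fastest, the native R / NIfTI layout) together with
#' per-axis voxel spacing in mm and a physical origin. All physical
#' quantities (volume, surface, thickness) are computed from the spacing,
#' never from index counts alone, so anisotropic grids (e.g. the clinical
#' 0.45 x 0.45 x 0.40 mm MRI grid) are handled correctly.
#'
#' @slot data logical 3D array, `TRUE` = foreground (cartilage)
#' @slot spacing numeric(3), voxel spacing (sx, sy, sz) in mm, all > 0
#' @slot origin numeric(3), physical offset in mm (default zero)
#' @export
setClass("VoxelGrid",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!is.logical(object@data))
      msg <- c(msg, "data must be logical (binary mask)")
    if (anyNA(object@data))
      msg <- c(msg, "data must not contain NA")
    sp <- .check_spacing(object@spacing)
    if (!is.null(sp)) msg <- c(msg, sp)
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be three finite numbers (mm)")
    if (length(msg)) msg else TRUE
  })

#' Grayscale volume: a 3D scalar field with physical spacing
#'
#' Used for the micro-CT emulation, where voxel values are linear
#' attenuation coefficients in 1/cm, and for signed-distance or thickness
#' fields. Layout and spacing conventions as in [VoxelGrid-class].
#'
#' @slot data numeric 3D array of finite scalars
#' @slot spacing numeric(3), mm
#' @slot origin numeric(3), mm
#' @export
setClass("GrayscaleVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (!is.numeric(object@data))
      msg <- c(msg, "data must be numeric")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "data must contain finite values only")
    sp <- .check_spacing(object@spacing)
    if (!is.null(sp)) msg <- c(msg, sp)
    if (length(msg)) msg else TRUE
  })

#' @describeIn VoxelGrid-class constructor; numeric 0/1 input is coerced
#' @param data 3D array (logical or 0/1 numeric)
#' @param spacing numeric(3) voxel spacing in mm
#' @param origin numeric(3) physical origin in mm
#' @export
VoxelGrid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask data must contain only {0, 1} / {FALSE, TRUE}")
    storage <- dim(data)
    data <- as.logical(data)
    dim(data) <- storage
  }
  new("VoxelGrid", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn GrayscaleVolume-class constructor
#' @param data 3D numeric array
#' @param spacing numeric(3) voxel spacing in mm
#' @param origin numeric(3) physical origin in mm
#' @export
GrayscaleVolume <- function(data, spacing, origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("GrayscaleVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Morphometric summary of one cartilage mask
#'
#' Bundles cartilage volume Cg.V (mm^3), surface area Cg.S (mm^2) and mean
#' thickness Cg.Th (mm) with the isotropic spacing actually used.
#'
#' @slot specimen_id character label
#' @slot cg_v,cg_s,cg_th numeric metrics (mm^3, mm^2, mm)
#' @slot spacing_used numeric(3), mm
#' @export
setClass("MorphometryResult",
  representation(specimen_id = "character", cg_v = "numeric",
                 cg_s = "numeric", cg_th = "numeric",
                 spacing_used = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@cg_v < 0 || object@cg_s < 0 || object@cg_th < 0)
      msg <- c(msg, "metrics must be non-negative")
    if (object@cg_v == 0 && (object@cg_s != 0 || object@cg_th != 0))
      msg <- c(msg, "empty mask must have zero surface and thickness")
    if (length(msg)) msg else TRUE
  })

#' Per-voxel local thickness map
#'
#' Thickness (mm) defined on foreground voxels as the diameter of the
#' largest sphere that contains the voxel centre and fits entirely inside
#' the foreground; background voxels carry 0 with an explicit foreground
#' mask (avoids NaN portability issues on disk).
#'
#' @slot values numeric 3D array, mm (0 on background)
#' @slot mask logical 3D array, foreground support
#' @slot spacing numeric(3), mm (isotropic)
#' @export
setClass("ThicknessMap",
  representation(values = "array", mask = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@mask)))
      msg <- c(msg, "values and mask must share dimensions")
    if (any(object@values[object@mask] <= 0))
      msg <- c(msg, "every foreground thickness must be > 0")
    sp <- .check_spacing(object@spacing)
    if (!is.null(sp)) msg <- c(msg, sp)
    if (length(msg)) msg else TRUE
  })

#' Subjects x repeats table of one morphometric metric
#'
#' @slot values numeric matrix, n_subjects x m_repeats, no missing cells
#' @slot metric_name character label (e.g. "cg_v")
#' @slot subject_ids,repeat_ids character labels
#' @export
setClass("RepeatedMeasuresTable",
  representation(values = "matrix", metric_name = "character",
                 subject_ids = "character", repeat_ids = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (nrow(v) < 2L) msg <- c(msg, "need at least 2 subjects")
    if (ncol(v) < 2L) msg <- c(msg, "need at least 2 repeats (m_repeats < 2)")
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "no missing or non-finite cells allowed")
    if (length(object@subject_ids) != nrow(v))
      msg <- c(msg, "subject_ids must match rows")
    if (length(object@repeat_ids) != ncol(v))
      msg <- c(msg, "repeat_ids must match columns")
    if (length(msg)) msg else TRUE
  })

#' @describeIn RepeatedMeasuresTable-class constructor from a matrix
#' @param values numeric matrix (subjects in rows, repeats in columns)
#' @param metric_name metric label
#' @param subject_ids,repeat_ids optional labels (default from dimnames)
#' @export
repeatedMeasures <- function(values, metric_name = "metric",
                             subject_ids = NULL, repeat_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(subject_ids))
    subject_ids <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  if (is.null(repeat_ids))
    repeat_ids <- colnames(values) %||% paste0("R", seq_len(ncol(values)))
  dimnames(values) <- list(subject_ids, repeat_ids)
  new("RepeatedMeasuresTable", values = values, metric_name = metric_name,
      subject_ids = as.character(subject_ids),
      repeat_ids = as.character(repeat_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Precision report for one metric (Glüer precision errors + ICC)
#'
#' @slot metric_name character
#' @slot mean grand mean in metric units
#' @slot pe_sd root-mean-square per-subject SD (metric units)
#' @slot pe_pct_cv precision error as percent coefficient of variation
#' @slot dof degrees of freedom n (m - 1)
#' @slot dof_ok TRUE when dof >= 27 (the recommended minimum)
#' @slot icc two-way absolute-agreement single-measure ICC (NA until set)
#' @export
setClass("PrecisionReport",
  representation(metric_name = "character", mean = "numeric",
                 pe_sd = "numeric", pe_pct_cv = "numeric", dof = "integer",
                 dof_ok = "logical", icc = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pe_sd < 0 || object@pe_pct_cv < 0)
      msg <- c(msg, "precision errors must be >= 0")
    if (!is.na(object@icc) && object@icc > 1)
      msg <- c(msg, "icc must be <= 1")
    if (length(msg)) msg else TRUE
  })

#' Pairwise comparison of two masks of the same scan
#'
#' Fractions are taken over the union of the two foregrounds; `pearson_r`
#' is the voxel-wise Pearson correlation of the two indicator fields over
#' the 2-voxel-padded bounding box of the union.
#'
#' @slot pearson_r numeric in [-1, 1] (NA when undefined)
#' @slot common_fraction,a_only_fraction,b_only_fraction fractions of the union
#' @export
setClass("PairwiseMaskComparison",
  representation(pearson_r = "numeric", common_fraction = "numeric",
                 a_only_fraction = "numeric", b_only_fraction = "numeric"),
  validity = function(object) {
    s <- object@common_fraction + object@a_only_fraction +
      object@b_only_fraction
    if (abs(s - 1) > 1e-9)
      return("fractions over the union must sum to 1")
    TRUE
  })

#' Micro-CT segmentation parameters
#'
#' Defaults follow the reference micro-CT evaluation chain: a discrete
#' Gaussian filter with sigma = 1.2 voxels truncated at +/- 1 voxel
#' (renormalised 3x3x3 kernel) and a closed attenuation window of
#' 0.9 to 2.2 1/cm.
#'
#' @slot sigma Gaussian sigma in voxels (> 0)
#' @slot support kernel truncation radius in voxels (integer >= 1)
#' @slot atten_lo,atten_hi attenuation window in 1/cm, lo < hi
#' @slot keep_largest_component drop all but the largest 26-connected piece
#' @export
setClass("CtSegmentationParams",
  representation(sigma = "numeric", support = "integer",
                 atten_lo = "numeric", atten_hi = "numeric",
                 keep_largest_component = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@support < 1L) msg <- c(msg, "support must be >= 1")
    if (object@atten_lo >= object@atten_hi)
      msg <- c(msg, "atten_lo must be < atten_hi")
    if (length(msg)) msg else TRUE
  })

#' @describeIn CtSegmentationParams-class constructor with reference defaults
#' @param sigma,support,atten_lo,atten_hi,keep_largest_component see slots
#' @export
ctParams <- function(sigma = 1.2, support = 1L, atten_lo = 0.9,
                     atten_hi = 2.2, keep_largest_component = FALSE) {
  new("CtSegmentationParams", sigma = sigma, support = as.integer(support),
      atten_lo = atten_lo, atten_hi = atten_hi,
      keep_largest_component = keep_largest_component)
}

#' Parametric phantom specification with analytic ground truth
#'
#' Shapes: `slab` (box), `spherical_shell` (wall of a sphere) and
#' `bent_sheet` (a sheet bent over a cylinder sector, the auricle-like
#' geometry). Truth for slab and shell is closed-form; bent-sheet truth is
#' computed by fine quadrature over the mid-surface and flagged as such.
#'
#' @slot shape one of "slab", "spherical_shell", "bent_sheet"
#' @slot thickness sheet/wall thickness in mm
#' @slot lateral_extent numeric(2) slab lateral size (mm); unused otherwise
#' @slot r_inner shell inner radius (mm)
#' @slot bend_radius,arc_length,axial_length bent-sheet geometry (mm);
#'   `bend_radius` is the mid-surface radius
#' @slot modulation list(amplitude, length_scale, phases) or empty list;
#'   smooth local thickness variation in mm
#' @export
setClass("PhantomSpec",
  representation(shape = "character", thickness = "numeric",
                 lateral_extent = "numeric", r_inner = "numeric",
                 bend_radius = "numeric", arc_length = "numeric",
                 axial_length = "numeric", modulation = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@shape %in% c("slab", "spherical_shell", "bent_sheet"))
      msg <- c(msg, "unknown shape")
    if (object@thickness <= 0) msg <- c(msg, "thickness must be > 0")
    if (object@shape == "spherical_shell" &&
        (length(object@r_inner) != 1L || object@r_inner <= object@thickness))
      msg <- c(msg, "shell radii must exceed thickness")
    if (object@shape == "bent_sheet" &&
        object@bend_radius <= object@thickness)
      msg <- c(msg, "bend radius must exceed thickness")
    if (length(object@modulation) &&
        object@modulation$amplitude >= object@thickness)
      msg <- c(msg, "modulation amplitude must be smaller than thickness")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PhantomSpec-class constructor
#' @param shape,thickness,lateral_extent,r_inner,bend_radius,arc_length,axial_length,modulation see slots
#' @export
phantomSpec <- function(shape = c("slab", "spherical_shell", "bent_sheet"),
                        thickness, lateral_extent = c(30, 30),
                        r_inner = 8, bend_radius = 12, arc_length = 20,
                        axial_length = 24, modulation = NULL) {
  shape <- match.arg(shape)
  new("PhantomSpec", shape = shape, thickness = thickness,
      lateral_extent = as.numeric(lateral_extent), r_inner = r_inner,
      bend_radius = bend_radius, arc_length = arc_length,
      axial_length = axial_length,
      modulation = if (is.null(modulation)) list() else modulation)
}

#' A rasterised phantom: mask, signed-distance field and ground truth
#'
#' @slot grid the rasterised [VoxelGrid-class]
#' @slot sdf numeric array of signed distances at voxel centres (mm,
#'   negative inside), same grid
#' @slot sdf_fun the analytic signed-distance closure `f(x, y, z)` in
#'   phantom coordinates
#' @slot truth list(cg_v, cg_s, cg_th, method)
#' @slot spec the generating [PhantomSpec-class]
#' @export
setClass("Phantom",
  representation(grid = "VoxelGrid", sdf = "array", sdf_fun = "function",
                 truth = "list", spec = "PhantomSpec"))

#' Simulated-rater model: correlated level-set boundary perturbation
#'
#' Manual contouring error is modelled as a systematic bias plus a smooth
#' zero-mean random displacement of the segmentation boundary, both in
#' units of the acquisition voxel (`voxel_mm`). The displacement field is
#' spatially correlated with length `noise_length_scale` because human
#' contouring errors are smooth along the boundary, not per-voxel flips.
#'
#' @slot bias signed voxels; positive = systematic over-segmentation
#' @slot noise_amplitude boundary perturbation SD in voxels (>= 0)
#' @slot noise_length_scale spatial correlation length in mm (> 0)
#' @slot voxel_mm physical size of one "voxel" unit in mm (the MRI
#'   in-plane voxel, 0.45 mm, by default)
#' @slot seed integer RNG seed for the displacement field
#' @export
setClass("RaterModel",
  representation(bias = "numeric", noise_amplitude = "numeric",
                 noise_length_scale = "numeric", voxel_mm = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@noise_amplitude < 0) msg <- c(msg, "noise_amplitude must be >= 0")
    if (object@noise_length_scale <= 0)
      msg <- c(msg, "noise_length_scale must be > 0")
    if (object@voxel_mm <= 0) msg <- c(msg, "voxel_mm must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn RaterModel-class constructor
#' @param bias,noise_amplitude,noise_length_scale,voxel_mm,seed see slots
#' @export
raterModel <- function(bias = 0, noise_amplitude = 0.45,
                       noise_length_scale = 14, voxel_mm = 0.45, seed = 1L) {
  new("RaterModel", bias = bias, noise_amplitude = noise_amplitude,
      noise_length_scale = noise_length_scale, voxel_mm = voxel_mm,
      seed = as.integer(seed))
}

#' Synthetic cohort specification
#'
#' Defaults emulate the volunteer study population: mean cartilage
#' thickness 1.15 mm with a between-subject SD of 0.10 mm, and a lateral
#' size-scale CV chosen so that cartilage volume varies about 18 percent
#' between subjects. `geometry` holds the desk-scale bent-sheet template
#' (arc length, axial length, bend radius, thickness modulation).
#'
#' @slot n_subjects number of subjects (>= 2)
#' @slot size_scale_cv CV of the lateral size multiplier
#' @slot th_mean,th_sd population thickness mean and SD (mm)
#' @slot seed integer master seed
#' @slot geometry list(arc_length, axial_length, bend_radius,
#'   mod_amplitude, mod_length) in mm
#' @export
setClass("PopulationSpec",
  representation(n_subjects = "integer", size_scale_cv = "numeric",
                 th_mean = "numeric", th_sd = "numeric", seed = "integer",
                 geometry = "list"),
  validity = function(object) {
    msg <- character()
    if (object@n_subjects < 2L) msg <- c(msg, "n_subjects must be >= 2")
    if (object@th_sd < 0) msg <- c(msg, "th_sd must be >= 0")
    if (object@th_mean <= 0) msg <- c(msg, "th_mean must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PopulationSpec-class constructor
#' @param n_subjects,size_scale_cv,th_mean,th_sd,seed,geometry see slots
#' @export
populationSpec <- function(n_subjects = 14L, size_scale_cv = 0.08,
                           th_mean = 1.15, th_sd = 0.10, seed = 1L,
                           geometry = list(arc_length = 20,
                                           axial_length = 24,
                                           bend_radius = 12,
                                           mod_amplitude = 0.2,
                                           mod_length = 6)) {
  new("PopulationSpec", n_subjects = as.integer(n_subjects),
      size_scale_cv = size_scale_cv, th_mean = th_mean, th_sd = th_sd,
      seed = as.integer(seed), geometry = geometry)
}
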