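#' Cartilage volume Cg.V
#'
#' Foreground voxel count times the physical voxel volume. An empty mask
#' yields 0.
#'
#' @param x a [VoxelGrid-class]
#' @return volume in mm^3
#' @export
setMethod("cartilageVolume", "VoxelGrid", function(x) {
  sum(voxelData(x)) * voxelVolume(x)
})

.gaussian_kernel1d <- function(sigma, support) {
  i <- seq.int(-support, support)
  w <- exp(-(i * i) / (2 * sigma * sigma))
  w / sum(w)
}

.smooth_indicator <- function(arr, sigma, support) {
  storage.mode(arr) <- "double"
  k <- .gaussian_kernel1d(sigma, support)
  for (axis in 0:2) arr <- cpp_conv_axis(arr, dim(arr), k, axis)
  arr
}

.pad_array <- function(arr, pad, value = 0) {
  d <- dim(arr)
  out <- array(value, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
  out
}

# triangulated 0.5-level isosurface of the (lightly smoothed) indicator;
# returns list(area, vertices?). Smoothing sigma in voxels per axis; the
# field is padded with background so surfaces close at array borders.
.isosurface <- function(x, smooth_sigma = 1, want_mesh = FALSE) {
  arr <- voxelData(x) + 0
  if (!any(arr > 0)) return(list(area = 0))
  support <- max(1L, ceiling(3 * smooth_sigma))
  arr <- .pad_array(arr, support + 1L)
  if (smooth_sigma > 0) {
    sm <- .smooth_indicator(arr, smooth_sigma, support)
    # tiny structures can be smoothed below the 0.5 level; fall back to
    # the raw indicator so they keep a surface
    if (max(sm) > 0.5) arr <- sm
  }
  res <- cpp_isosurface(arr, dim(arr), voxelSpacing(x), 0.5, want_mesh)
  if (want_mesh && !is.null(res$vertices)) {
    # vertices back into the unpadded frame (centre of voxel i at i * s)
    res$vertices <- res$vertices - (support + 1) * voxelSpacing(x)
  }
  res
}

#' Cartilage surface area Cg.S
#'
#' Area of the triangulated isosurface extracted at level 0.5 from the
#' binary field (marching tetrahedra with linear interpolation), in mm^2,
#' honouring anisotropic spacing. The indicator is first smoothed with a
#' small Gaussian (`smooth_sigma` voxels) so that the piecewise-linear
#' surface tracks the underlying smooth boundary instead of the voxel
#' staircase, which would systematically overestimate curved surfaces.
#' An empty mask yields 0.
#'
#' @param x a [VoxelGrid-class]
#' @param smooth_sigma pre-smoothing SD in voxels (default 1; 0 disables)
#' @return surface area in mm^2
#' @export
setMethod("cartilageSurface", "VoxelGrid",
          function(x, smooth_sigma = 1) {
  .isosurface(x, smooth_sigma)$area
})

#' Per-voxel thickness map (maximal inscribed spheres)
#'
#' Model-independent local thickness: every foreground voxel is assigned
#' the diameter of the largest sphere that contains its centre and fits
#' entirely inside the foreground solid. Computed from the Euclidean
#' distance transform with distance-ridge candidate spheres; anisotropic
#' input is resampled to an isotropic grid first (sphere fitting assumes
#' isotropy), which is reflected in the returned spacing.
#'
#' @param x a non-empty [VoxelGrid-class]
#' @param isotropic_target isotropic spacing used internally
#'   (default `min(voxelSpacing(x))`)
#' @return a [ThicknessMap-class]
#' @export
setMethod("thicknessMap", "VoxelGrid",
          function(x, isotropic_target = NULL) {
  if (!any(voxelData(x))) stop("no foreground")
  iso <- isotropicResample(x, isotropic_target)
  h <- voxelSpacing(iso)[1]
  arr <- .pad_array(voxelData(iso), 1L, FALSE)
  th <- cpp_local_thickness(as.logical(arr), dim(arr), h)
  d <- dim(voxelData(iso))
  idx <- lapply(d, function(n) 1L + seq_len(n))
  th <- th[idx[[1]], idx[[2]], idx[[3]]]
  new("ThicknessMap", values = th, mask = voxelData(iso),
      spacing = voxelSpacing(iso))
})

#' Mean cartilage thickness Cg.Th
#'
#' Volume-weighted mean of the thickness map, i.e. the unweighted mean
#' over foreground voxels on the isotropic grid.
#'
#' @param x a [ThicknessMap-class]
#' @return mean thickness in mm
#' @export
setMethod("meanThickness", "ThicknessMap", function(x) {
  if (!any(x@mask)) stop("empty map")
  mean(x@values[x@mask])
})

#' All three morphometric metrics of a mask
#'
#' Resamples the mask to an isotropic grid (default: the smallest input
#' spacing) and computes Cg.V, Cg.S and Cg.Th on that grid, recording the
#' spacing used. An empty mask yields (0, 0, 0).
#'
#' @param x a [VoxelGrid-class]
#' @param specimen_id label stored in the result
#' @param isotropic_target isotropic analysis spacing in mm (default
#'   `min(voxelSpacing(x))`)
#' @return a [MorphometryResult-class]
#' @export
setMethod("morphometryAll", "VoxelGrid",
          function(x, specimen_id = "specimen", isotropic_target = NULL) {
  if (!any(voxelData(x))) {
    return(new("MorphometryResult", specimen_id = specimen_id, cg_v = 0,
               cg_s = 0, cg_th = 0, spacing_used = voxelSpacing(x)))
  }
  iso <- isotropicResample(x, isotropic_target)
  new("MorphometryResult", specimen_id = specimen_id,
      cg_v = cartilageVolume(iso),
      cg_s = cartilageSurface(iso),
      cg_th = meanThickness(thicknessMap(iso)),
      spacing_used = voxelSpacing(iso))
})

#' Write the thickness map as a scalar volume
#'
#' Background voxels are written as 0; the explicit foreground mask can be
#' written alongside (`mask_path`).
#'
#' @param map a [ThicknessMap-class]
#' @param path output volume path (NIfTI or MetaImage)
#' @param mask_path optional path for the foreground mask
#' @export
writeThicknessMap <- function(map, path, mask_path = NULL) {
  writeVolume(GrayscaleVolume(map@values, map@spacing), path)
  if (!is.null(mask_path))
    writeVolume(VoxelGrid(map@mask, map@spacing), mask_path)
  invisible(path)
}

#' Export the cartilage surface as an ASCII PLY mesh
#'
#' Triangulated 0.5-level isosurface (see [cartilageSurface()]); when a
#' thickness map is supplied each vertex carries the local thickness
#' sampled at its position as a `quality` property, for thickness-map
#' rendering.
#'
#' @param x a [VoxelGrid-class]
#' @param path output `.ply` path
#' @param thickness optional [ThicknessMap-class] on the same grid
#' @param smooth_sigma passed to the isosurface extraction
#' @export
writeSurfacePLY <- function(x, path, thickness = NULL, smooth_sigma = 1) {
  iso <- .isosurface(x, smooth_sigma, want_mesh = TRUE)
  if (is.null(iso$vertices)) stop("no foreground")
  v <- iso$vertices                      # 3 x (3 * ntri)
  nv <- ncol(v)
  ntri <- nv / 3L
  qual <- NULL
  if (!is.null(thickness)) {
    sp <- thickness@spacing
    ijk <- pmin(pmax(round(v / sp) + 1, 1),
                matrix(dim(thickness@values), nrow = 3, ncol = nv))
    qual <- thickness@values[cbind(ijk[1, ], ijk[2, ], ijk[3, ])]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               if (!is.null(qual)) "property float quality",
               paste("element face", ntri),
               "property list uchar int vertex_indices", "end_header"), con)
  if (is.null(qual)) {
    writeLines(sprintf("%.6g %.6g %.6g", v[1, ], v[2, ], v[3, ]), con)
  } else {
    writeLines(sprintf("%.6g %.6g %.6g %.6g", v[1, ], v[2, ], v[3, ], qual),
               con)
  }
  f0 <- 3L * (seq_len(ntri) - 1L)
  writeLines(sprintf("3 %d %d %d", f0, f0 + 1L, f0 + 2L), con)
  invisible(path)
}
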