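#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' VoxelMap: one scalar per voxel on a 3D grid
#'
#' Holds a 3D scalar field together with its brain mask and voxel size.
#' Values are finite inside the mask and `NA` outside it. The `kind` slot
#' records what the scalars are: raw ALFF, mean-divided ALFF (`malff`),
#' z-standardized ALFF, or a statistic (`r`, `t`, `z`, `p`).
#'
#' @slot data numeric 3D array, `NA` outside the mask.
#' @slot mask logical 3D array of the same shape.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot kind character scalar in `alff, malff, z, r, t, p`.
#' @export
setClass("VoxelMap",
  representation(data = "array", mask = "array", voxelSize = "numeric",
                 kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
    if (!identical(dim(object@data), dim(object@mask)))
      msg <- c(msg, "mask shape must equal data shape")
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
    if (!object@kind %in% c("alff", "malff", "z", "r", "t", "p"))
      msg <- c(msg, "kind must be one of alff, malff, z, r, t, p")
    inm <- object@data[object@mask]
    if (length(inm) && any(!is.finite(inm)))
      msg <- c(msg, "in-mask values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a VoxelMap
#'
#' @param data numeric 3D array.
#' @param mask logical 3D array (default: all finite voxels).
#' @param voxelSize voxel edge lengths in mm.
#' @param kind value kind, see [VoxelMap-class].
#' @return a [VoxelMap-class].
#' @export
VoxelMap <- function(data, mask = NULL, voxelSize = c(3, 3, 3), kind = "alff") {
  if (is.null(mask)) mask <- array(is.finite(data), dim(data))
  if (!identical(dim(mask), dim(data)))
    stop("mask shape must equal data shape")
  data[!mask] <- NA_real_
  new("VoxelMap", data = data, mask = mask,
      voxelSize = as.numeric(voxelSize), kind = kind)
}

#' TimeSeriesImage: a 4D voxel time-series volume
#'
#' @slot data numeric 4D array (x, y, z, time); the series is assumed to have
#'   had any initial dummy volumes already discarded upstream.
#' @slot mask logical 3D brain mask matching the spatial shape.
#' @slot tr repetition time in seconds.
#' @slot voxelSize numeric length-3, mm.
#' @export
setClass("TimeSeriesImage",
  representation(data = "array", mask = "array", tr = "numeric",
                 voxelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4D")
    if (!identical(dim(object@data)[1:3], dim(object@mask)))
      msg <- c(msg, "mask shape must equal spatial shape")
    if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "TR must be > 0")
    if (dim(object@data)[4] < 64L)
      msg <- c(msg, "need >= 64 timepoints")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname TimeSeriesImage-class
#' @param data,mask,tr,voxelSize see slots.
#' @export
TimeSeriesImage <- function(data, mask = NULL, tr, voxelSize = c(3, 3, 3)) {
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  new("TimeSeriesImage", data = data, mask = mask, tr = as.numeric(tr),
      voxelSize = as.numeric(voxelSize))
}

#' Parcellation: integer atlas labels plus a region lookup table
#'
#' @slot labels integer 3D array, 0 = unlabelled.
#' @slot voxelSize numeric length-3, mm.
#' @slot regions data.frame with columns `id`, `name`, `hemisphere`
#'   (`"L"`, `"R"` or `"M"` for midline structures).
#' @export
setClass("Parcellation",
  representation(labels = "array", voxelSize = "numeric", regions = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be 3D")
    need <- c("id", "name", "hemisphere")
    if (!all(need %in% names(object@regions)))
      msg <- c(msg, "regions needs columns id, name, hemisphere")
    used <- setdiff(unique(as.integer(object@labels)), 0L)
    if (length(used) && !all(used %in% object@regions$id))
      msg <- c(msg, "every non-zero label must appear in the region table")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname Parcellation-class
#' @param labels,voxelSize,regions see slots.
#' @export
Parcellation <- function(labels, voxelSize = c(3, 3, 3), regions) {
  storage.mode(labels) <- "integer"
  new("Parcellation", labels = labels, voxelSize = as.numeric(voxelSize),
      regions = regions)
}

#' StatMap: a voxel-wise statistic field with its p-value field
#'
#' @slot stat [VoxelMap-class] of the statistic (kind `r` or `t`).
#' @slot p [VoxelMap-class] of two-tailed p-values.
#' @slot statKind `"r"` or `"t"`.
#' @slot df residual degrees of freedom.
#' @slot n number of subjects.
#' @export
setClass("StatMap",
  representation(stat = "VoxelMap", p = "VoxelMap", statKind = "character",
                 df = "numeric", n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@statKind %in% c("r", "t")) msg <- c(msg, "statKind must be r or t")
    pv <- object@p@data[object@p@mask]
    pv <- pv[is.finite(pv)]
    if (length(pv) && (any(pv <= 0) || any(pv > 1)))
      msg <- c(msg, "p values must lie in (0, 1]")
    if (object@df >= object@n) msg <- c(msg, "df must be < n")
    if (is.null(msg)) TRUE else msg
  })

#' ClusterResult: supra-threshold clusters after cluster-level correction
#'
#' @slot labels [VoxelMap-class] of integer cluster labels (0 = none);
#'   only clusters surviving the cluster-level threshold are labelled.
#' @slot table data.frame: `cluster`, `size`, `peak_x`, `peak_y`, `peak_z`
#'   (mm), `peak_stat`, `p` (cluster-level, corrected), `sign`.
#' @slot voxelP cluster-defining voxel-level p threshold.
#' @slot clusterP cluster-level p threshold.
#' @slot fwhm smoothness FWHM in mm on the 3 axes.
#' @export
setClass("ClusterResult",
  representation(labels = "VoxelMap", table = "data.frame", voxelP = "numeric",
                 clusterP = "numeric", fwhm = "numeric"))

#' DonorBundle: donor microarray samples with probe annotation
#'
#' One object covers all donors; the sample table's `donor` column says which
#' donor each array sample came from.
#'
#' @slot expr numeric matrix, probes x samples.
#' @slot probes data.frame: `probe_id`, `gene_id` (`NA` = invalid), `symbol`.
#' @slot samples data.frame: `donor`, `x`, `y`, `z` (mm, same space as the
#'   parcellation grid).
#' @slot background numeric or NULL; intensity below which a measurement
#'   counts as background for probe filtering.
#' @export
setClass("DonorBundle",
  representation(expr = "matrix", probes = "data.frame", samples = "data.frame",
                 background = "numericOrNULL"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@expr) != nrow(object@probes))
      msg <- c(msg, "probe annotation must cover every expression row")
    if (ncol(object@expr) != nrow(object@samples))
      msg <- c(msg, "sample table must cover every expression column")
    if (!all(c("probe_id", "gene_id", "symbol") %in% names(object@probes)))
      msg <- c(msg, "probes needs probe_id, gene_id, symbol")
    if (!all(c("donor", "x", "y", "z") %in% names(object@samples)))
      msg <- c(msg, "samples needs donor, x, y, z")
    if (any(!is.finite(as.matrix(object@samples[, c("x", "y", "z")]))))
      msg <- c(msg, "sample coordinates must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname DonorBundle-class
#' @param expr,probes,samples,background see slots.
#' @export
DonorBundle <- function(expr, probes, samples, background = NULL) {
  new("DonorBundle", expr = expr, probes = probes, samples = samples,
      background = background)
}

#' RegionalExpression: region x gene expression matrix
#'
#' The bridge between imaging and transcriptomics: one normalized expression
#' value per (atlas region, gene). Regions never sampled by any donor are
#' absent from the matrix, not zero-filled.
#'
#' @slot mat numeric matrix, regions x genes; rownames are region ids.
#' @slot sampleCounts integer matrix regions x donors: how many donor samples
#'   entered each region mean.
#' @slot state `"raw"`, `"sigmoid-scaled"` or `"z"`.
#' @export
setClass("RegionalExpression",
  representation(mat = "matrix", sampleCounts = "matrix", state = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@state %in% c("raw", "sigmoid-scaled", "z"))
      msg <- c(msg, "state must be raw, sigmoid-scaled or z")
    if (object@state == "z" && ncol(object@mat) > 0 && nrow(object@mat) > 1) {
      sds <- apply(object@mat, 2L, stats::sd, na.rm = TRUE)
      if (any(sds == 0, na.rm = TRUE))
        msg <- c(msg, "z state forbids constant gene columns")
    }
    if (is.null(msg)) TRUE else msg
  })

# ---- accessors ---------------------------------------------------------

#' @describeIn VoxelMap-class the 3D value array
#' @param object,x a VoxelMap
#' @export
setGeneric("mapData", function(object) standardGeneric("mapData"))
#' @export
setMethod("mapData", "VoxelMap", function(object) object@data)

#' @describeIn VoxelMap-class the logical mask
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))
#' @export
setMethod("mapMask", "VoxelMap", function(object) object@mask)

#' @describeIn VoxelMap-class voxel size in mm
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @export
setMethod("voxelSize", "VoxelMap", function(object) object@voxelSize)
#' @export
setMethod("voxelSize", "TimeSeriesImage", function(object) object@voxelSize)
#' @export
setMethod("voxelSize", "Parcellation", function(object) object@voxelSize)

#' @describeIn VoxelMap-class value kind
#' @export
setGeneric("mapKind", function(object) standardGeneric("mapKind"))
#' @export
setMethod("mapKind", "VoxelMap", function(object) object@kind)

#' @describeIn VoxelMap-class in-mask values as a vector
#' @export
setGeneric("inMask", function(object) standardGeneric("inMask"))
#' @export
setMethod("inMask", "VoxelMap", function(object) object@data[object@mask])

#' @describeIn Parcellation-class the region lookup table
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))
#' @export
setMethod("regionTable", "Parcellation", function(object) object@regions)

#' @describeIn Parcellation-class the integer label array
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))
#' @export
setMethod("parcelLabels", "Parcellation", function(object) object@labels)

#' @describeIn ClusterResult-class the per-cluster summary table
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))
#' @export
setMethod("clusterTable", "ClusterResult", function(object) object@table)

#' @describeIn RegionalExpression-class the region x gene matrix
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))
#' @export
setMethod("exprMatrix", "RegionalExpression", function(object) object@mat)

#' @describeIn RegionalExpression-class normalization state
#' @export
setGeneric("exprState", function(object) standardGeneric("exprState"))
#' @export
setMethod("exprState", "RegionalExpression", function(object) object@state)

# ---- show --------------------------------------------------------------

setMethod("show", "VoxelMap", function(object) {
  v <- inMask(object)
  cat(sprintf("VoxelMap [%s] %s, voxel %s mm, %d in-mask voxels, range [%.4g, %.4g]\n",
    object@kind, paste(dim(object@data), collapse = "x"),
    paste(object@voxelSize, collapse = "x"), length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "TimeSeriesImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("TimeSeriesImage %s, %d timepoints, TR %.3g s, %d in-mask voxels\n",
    paste(d[1:3], collapse = "x"), d[4], object@tr, sum(object@mask)))
})

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation %s: %d regions, %d labelled voxels\n",
    paste(dim(object@labels), collapse = "x"), nrow(object@regions),
    sum(object@labels != 0L)))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap [%s], df = %.4g, n = %d subjects\n",
    object@statKind, object@df, object@n))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d cluster(s) at voxel p < %g, cluster p < %g (FWHM %s mm)\n",
    nrow(object@table), object@voxelP, object@clusterP,
    paste(signif(object@fwhm, 3), collapse = "/")))
  if (nrow(object@table)) print(object@table)
})

setMethod("show", "DonorBundle", function(object) {
  cat(sprintf("DonorBundle: %d probes x %d samples, %d donor(s)\n",
    nrow(object@expr), ncol(object@expr), length(unique(object@samples$donor))))
})

setMethod("show", "RegionalExpression", function(object) {
  cat(sprintf("RegionalExpression [%s]: %d regions x %d genes\n",
    object@state, nrow(object@mat), ncol(object@mat)))
})
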