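#' Accessors for bbbflow containers
#'
#' Slot access goes through these generics; user code should never reach into
#' `@` slots directly.
#'
#' @param x a bbbflow S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))
#' @rdname accessors
#' @export
setGeneric("branchClass", function(x) standardGeneric("branchClass"))
#' @rdname accessors
#' @export
setGeneric("branchTangents", function(x) standardGeneric("branchTangents"))
#' @rdname accessors
#' @export
setGeneric("branchRadius", function(x) standardGeneric("branchRadius"))
#' @rdname accessors
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("psValue", function(x) standardGeneric("psValue"))
#' @rdname accessors
#' @export
setGeneric("vpValue", function(x) standardGeneric("vpValue"))
#' @rdname accessors
#' @export
setGeneric("plasmaCurve", function(x) standardGeneric("plasmaCurve"))
#' @rdname accessors
#' @export
setGeneric("bloodCurve", function(x) standardGeneric("bloodCurve"))
#' @rdname accessors
#' @export
setGeneric("vifCenterline", function(x) standardGeneric("vifCenterline"))
#' @rdname accessors
#' @export
setGeneric("t10Map", function(x) standardGeneric("t10Map"))
#' @rdname accessors
#' @export
setGeneric("m0Map", function(x) standardGeneric("m0Map"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("r1Values", function(x) standardGeneric("r1Values"))

#' @rdname accessors
#' @export
setMethod("voxelData", "VolumeGrid", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxelData", "DCESeries", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DCESeries", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CenterlineTree", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("frameTimes", "DCESeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("frameTimes", "RelaxationSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("frameTimes", "VIFExtraction", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("branches", "CenterlineTree", function(x) x@branches)
#' @rdname accessors
#' @export
setMethod("branchClass", "CenterlineTree", function(x) x@branchClass)
#' @rdname accessors
#' @export
setMethod("branchTangents", "CenterlineTree", function(x) x@tangents)
#' @rdname accessors
#' @export
setMethod("branchRadius", "CenterlineTree", function(x) x@radius)
#' @rdname accessors
#' @export
setMethod("flowValues", "FlowWaveform", function(x) x@flow)
#' @rdname accessors
#' @export
setMethod("isNormalized", "FlowWaveform", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("psValue", "PatlakResult", function(x) x@ps)
#' @rdname accessors
#' @export
setMethod("vpValue", "PatlakResult", function(x) x@vp)
#' @rdname accessors
#' @export
setMethod("plasmaCurve", "VIFExtraction", function(x) x@plasma)
#' @rdname accessors
#' @export
setMethod("bloodCurve", "VIFExtraction", function(x) x@blood)
#' @rdname accessors
#' @export
setMethod("vifCenterline", "VIFExtraction", function(x) x@centerline)
#' @rdname accessors
#' @export
setMethod("t10Map", "T1FitResult", function(x) x@t10)
#' @rdname accessors
#' @export
setMethod("m0Map", "T1FitResult", function(x) x@m0)
#' @rdname accessors
#' @export
setMethod("validMask", "T1FitResult", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "RelaxationSeries", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("r1Values", "RelaxationSeries", function(x) x@r1)
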