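#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @export
setGeneric("suvValues", function(x) standardGeneric("suvValues"))

#' @export
setGeneric("maskVoxels", function(x) standardGeneric("maskVoxels"))

#' @export
setGeneric("volumeCcm", function(x) standardGeneric("volumeCcm"))

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @export
setGeneric("manualMasks", function(x) standardGeneric("manualMasks"))

#' @export
setGeneric("autoMasks", function(x) standardGeneric("autoMasks"))
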