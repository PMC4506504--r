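#' @rdname TimeCourseExperiment-class
#' @param x an object.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname TimeCourseExperiment-class
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname TimeCourseExperiment-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname TimeCourseExperiment-class
#' @export
setGeneric("log2Intensities", function(x) standardGeneric("log2Intensities"))

#' @rdname TimeCourseExperiment-class
#' @param log logical; average on the log2 scale (`TRUE`, default) or the
#'   linear scale.
#' @export
setGeneric("replicateMeans",
    function(x, log = TRUE) standardGeneric("replicateMeans"))

#' @rdname TimeCourseExperiment-class
#' @export
setGeneric("syntheticTruth", function(x) standardGeneric("syntheticTruth"))

#' @rdname TimeCourseExperiment-class
#' @export
setGeneric("isTF", function(x) standardGeneric("isTF"))

#' @rdname ClusterResult-class
#' @param x an object.
#' @export
setGeneric("clusterAssignments",
    function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterCentres", function(x) standardGeneric("clusterCentres"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterSummary", function(x) standardGeneric("clusterSummary"))

#' @rdname PeriodEstimate-class
#' @param x an object.
#' @export
setGeneric("turningPoints", function(x) standardGeneric("turningPoints"))

#' @rdname PeriodEstimate-class
#' @export
setGeneric("periodHours", function(x) standardGeneric("periodHours"))
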