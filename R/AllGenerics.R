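#' @rdname AnnotatedNetwork-class
#' @param object,x an object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname AnnotatedNetwork-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname AnnotatedNetwork-class
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname AnnotatedNetwork-class
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname AnnotatedNetwork-class
#' @export
setGeneric("diseaseGenes", function(x) standardGeneric("diseaseGenes"))

#' @rdname AnnotatedNetwork-class
#' @export
setGeneric("essentialGenes", function(x) standardGeneric("essentialGenes"))

#' @rdname PropagationResult-class
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))

#' @rdname PriorVector-class
#' @export
setGeneric("priorValues", function(x) standardGeneric("priorValues"))

#' @rdname ShellProfile-class
#' @export
setGeneric("shellSets", function(x) standardGeneric("shellSets"))

#' @rdname ShellProfile-class
#' @export
setGeneric("shellProportionValues",
           function(x) standardGeneric("shellProportionValues"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("trialResults", function(x) standardGeneric("trialResults"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("enrichmentMeans", function(x) standardGeneric("enrichmentMeans"))

# -- accessors ---------------------------------------------------------------

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("networkNodes", "AnnotatedNetwork", function(x) x@nodes)

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("adjacencyMatrix", "AnnotatedNetwork", function(x) x@adjacency)

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("nodeDegrees", "AnnotatedNetwork", function(x) {
  d <- as.numeric(Matrix::rowSums(x@adjacency))
  names(d) <- x@nodes
  d
})

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("edgeCount", "AnnotatedNetwork", function(x) {
  as.integer(sum(x@adjacency) / 2)
})

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("diseaseGenes", "AnnotatedNetwork", function(x) x@diseaseGenes)

#' @rdname AnnotatedNetwork-class
#' @export
setMethod("essentialGenes", "AnnotatedNetwork", function(x) x@essentialGenes)

#' @rdname PropagationResult-class
#' @export
setMethod("flowValues", "PropagationResult", function(x) x@flow)

#' @rdname PriorVector-class
#' @export
setMethod("priorValues", "PriorVector", function(x) x@values)

#' @rdname ShellProfile-class
#' @export
setMethod("shellSets", "ShellProfile", function(x) x@shells)

#' @rdname ShellProfile-class
#' @export
setMethod("shellProportionValues", "ShellProfile", function(x) x@proportions)

#' @rdname EvaluationReport-class
#' @export
setMethod("trialResults", "EvaluationReport", function(x) x@trials)

#' @rdname EvaluationReport-class
#' @export
setMethod("enrichmentMeans", "EvaluationReport", function(x) {
  c(score1 = x@score1, score2 = x@score2)
})

# -- show methods ------------------------------------------------------------

setMethod("show", "AnnotatedNetwork", function(object) {
  cat(sprintf(
    "AnnotatedNetwork: %d nodes, %d edges\n",
    length(object@nodes), edgeCount(object)
  ))
  cat(sprintf(
    "  labels: %d disease, %d essential\n",
    length(object@diseaseGenes), length(object@essentialGenes)
  ))
})

setMethod("show", "GenePartition", function(object) {
  cat("GenePartition\n")
  cat(sprintf(
    "  D-: %d  E-: %d  E&D: %d  O: %d  (off-network: %d)\n",
    length(object@dMinus), length(object@eMinus), length(object@both),
    length(object@other), length(object@offNetwork)
  ))
})

setMethod("show", "PropagationConfig", function(object) {
  cat(sprintf(
    "PropagationConfig: alpha=%.3g, normalization=%s, priorMode=%s, solver=%s\n",
    object@alpha, object@normalization, object@priorMode, object@solver
  ))
})

setMethod("show", "PriorVector", function(object) {
  cat(sprintf(
    "PriorVector (%s): %d positive, %d negative genes; total %.4g\n",
    object@mode, length(object@positiveSet), length(object@negativeSet),
    sum(object@values)
  ))
})

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf(
    "PropagationResult: %d nodes, %s after %d iterations (residual %.3g)\n",
    length(object@flow),
    if (object@converged) "converged" else "NOT converged",
    object@iterationsUsed, object@residual
  ))
})

setMethod("show", "ShellProfile", function(object) {
  cat(sprintf(
    "ShellProfile of '%s': %d shells, component size %d\n",
    object@node, length(object@shells), sum(object@shellSizes) + 1L
  ))
})

setMethod("show", "ShellComparison", function(object) {
  cat(sprintf(
    "Shell n=%d: Md[%s]=%.2f%%  Md[%s]=%.2f%%  rank-sum p=%.4g (%s)\n",
    object@n, object@classA, 100 * object@medianA,
    object@classB, 100 * object@medianB, object@pValue, object@method
  ))
})

setMethod("show", "CandidateList", function(object) {
  cat(sprintf(
    "CandidateList: test gene '%s' among %d candidates\n",
    object@testGene, length(object@candidates)
  ))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport (%s): %d trials over %d diseases\n",
    object@mode, nrow(object@trials), nrow(object@perDisease)
  ))
  cat(sprintf(
    "  mean enrichment score 1 = %.3f, score 2 = %.3f\n",
    object@score1, object@score2
  ))
  if (!is.null(object@auc)) cat(sprintf("  AUC = %.4f\n", object@auc))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d nodes (m=%d), %d x %d disease modules, %d essentials, %d decoys, seed %d\n",
    object@nNodes, object@attachment, object@nDiseases, object@moduleSize,
    object@nEssentials, object@decoyHubs, object@seed
  ))
})
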