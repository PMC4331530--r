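#' @import methods
#' @importFrom Matrix Matrix Diagonal rowSums colSums t solve drop0
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Annotated protein-interaction network
#'
#' An undirected, unweighted interaction graph with optional node class
#' labels.  Nodes are opaque case-sensitive gene/protein identifiers; the
#' adjacency matrix is a symmetric sparse 0/1 matrix with an empty diagonal
#' (no self-loops).  Disease and essential labels are stored as identifier
#' sets and are allowed to overlap (genes both essential and disease-causing
#' exist; the class partition is derived by [partitionGenes()]).
#'
#' @slot nodes character vector of node identifiers, in network order.
#' @slot adjacency symmetric sparse 0/1 `Matrix` with `dimnames == nodes`.
#' @slot diseaseGenes identifiers labelled as disease genes (may include
#'   genes absent from the network).
#' @slot essentialGenes identifiers labelled as essential genes.
#'
#' @seealso [loadEdgeList()], [annotatedNetwork()], [largestComponent()]
#' @export
setClass("AnnotatedNetwork",
  representation(
    nodes = "character",
    adjacency = "Matrix",
    diseaseGenes = "character",
    essentialGenes = "character"
  )
)

setValidity("AnnotatedNetwork", function(object) {
  a <- object@adjacency
  n <- length(object@nodes)
  if (!all(dim(a) == c(n, n))) {
    return("adjacency dimensions do not match the number of nodes")
  }
  if (n > 0L) {
    if (is.null(rownames(a)) || !identical(rownames(a), object@nodes)) {
      return("adjacency dimnames must equal the node vector")
    }
    if (anyDuplicated(object@nodes)) return("duplicated node identifiers")
    if (!Matrix::isSymmetric(a)) return("adjacency must be symmetric")
    if (any(Matrix::diag(a) != 0)) return("self-loops are not allowed")
    vals <- a@x
    if (length(vals) && !all(vals %in% c(0, 1))) {
      return("adjacency entries must be 0/1 (unweighted network)")
    }
  }
  TRUE
})

#' Partition of network genes into disease/essential classes
#'
#' Splits the universe `D | E | O` into the pairwise-disjoint classes
#' `E-` (essential, not disease), `D-` (disease, not essential), `E & D`,
#' and `O` (neither).  Input sets may contain identifiers absent from the
#' network; those are kept and flagged off-network.
#'
#' @slot disease,essential the input identifier sets D and E.
#' @slot dMinus,eMinus,both,other the derived classes restricted to nothing:
#'   they keep off-network members of D and E; `other` contains network
#'   nodes only.
#' @slot offNetwork identifiers of D union E absent from the network.
#' @seealso [partitionGenes()]
#' @export
setClass("GenePartition",
  representation(
    disease = "character",
    essential = "character",
    dMinus = "character",
    eMinus = "character",
    both = "character",
    other = "character",
    offNetwork = "character"
  )
)

setValidity("GenePartition", function(object) {
  classes <- list(object@dMinus, object@eMinus, object@both, object@other)
  ids <- unlist(classes)
  if (anyDuplicated(ids)) return("derived classes must be pairwise disjoint")
  if (!setequal(object@dMinus, setdiff(object@disease, object@essential))) {
    return("dMinus must equal D \\ E")
  }
  if (!setequal(object@eMinus, setdiff(object@essential, object@disease))) {
    return("eMinus must equal E \\ D")
  }
  TRUE
})

#' Propagation configuration
#'
#' Tunable parameters of the flow-propagation solver.  `alpha` is the
#' restart fraction in (0, 1] balancing prior information against network
#' smoothing (alpha = 1 returns the prior unchanged).  `normalization`
#' selects the operator: `"pump"` (each node distributes its flow equally
#' to its neighbors; conserves total flow), `"average"` (each node adopts
#' the mean of its neighbors), or `"symmetric"`
#' (\eqn{A(x,y)/\sqrt{k(x)k(y)}}).  `priorMode` `"normalized"` scales each
#' side of the prior to total +1/-1; `"unit"` assigns +1/-1 per gene.
#'
#' @slot alpha numeric in (0, 1].
#' @slot solver `"auto"`, `"iterative"` or `"direct"`.
#' @slot tolerance L1 convergence bound for the iterative solver.
#' @slot maxIterations iteration cap for the iterative solver.
#' @slot normalization `"pump"`, `"average"` or `"symmetric"`.
#' @slot priorMode `"normalized"` or `"unit"`.
#' @seealso [propagationConfig()], [propagateFlow()]
#' @export
setClass("PropagationConfig",
  representation(
    alpha = "numeric",
    solver = "character",
    tolerance = "numeric",
    maxIterations = "integer",
    normalization = "character",
    priorMode = "character"
  )
)

setValidity("PropagationConfig", function(object) {
  if (length(object@alpha) != 1 || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha > 1) {
    return("alpha must be a single value in (0, 1]")
  }
  if (!object@solver %in% c("auto", "iterative", "direct")) {
    return("solver must be 'auto', 'iterative' or 'direct'")
  }
  if (!object@normalization %in% c("pump", "average", "symmetric")) {
    return("normalization must be 'pump', 'average' or 'symmetric'")
  }
  if (!object@priorMode %in% c("normalized", "unit")) {
    return("priorMode must be 'normalized' or 'unit'")
  }
  if (object@solver != "direct" && object@tolerance <= 0) {
    return("tolerance must be positive for the iterative solver")
  }
  if (object@maxIterations < 1L) return("maxIterations must be positive")
  TRUE
})

#' Signed prior flow vector
#'
#' Prior information Y over network nodes: positive entries on the disease
#' training genes, negative entries on non-disease essential genes.  Support
#' is restricted to the recorded generating sets.
#'
#' @slot values named numeric vector over all network nodes.
#' @slot positiveSet disease training genes used (on-network).
#' @slot negativeSet non-disease essential genes used (on-network).
#' @slot mode one of `"NP_D"`, `"NP_E"`, `"NP_DE"`.
#' @seealso [buildPrior()]
#' @export
setClass("PriorVector",
  representation(
    values = "numeric",
    positiveSet = "character",
    negativeSet = "character",
    mode = "character"
  )
)

setValidity("PriorVector", function(object) {
  support <- names(object@values)[object@values != 0]
  if (!all(support %in% c(object@positiveSet, object@negativeSet))) {
    return("nonzero prior entries outside the generating gene sets")
  }
  TRUE
})

#' Steady-state propagation result
#'
#' @slot flow named numeric vector of steady-state flow per node.
#' @slot iterationsUsed iterations taken (0 for the direct solver).
#' @slot residual final L1 change between successive iterates (0 for direct).
#' @slot converged logical.
#' @slot config the [PropagationConfig-class] used.
#' @seealso [propagateFlow()]
#' @export
setClass("PropagationResult",
  representation(
    flow = "numeric",
    iterationsUsed = "integer",
    residual = "numeric",
    converged = "logical",
    config = "PropagationConfig"
  )
)

#' Breadth-first shell profile of a node
#'
#' The n-neighbor shells of node i: `shells[[n]]` holds the nodes at
#' shortest-path distance exactly n from i.  `proportions[n]` is the
#' fraction of shell n occupied by non-disease essential genes (`NA` where
#' the shell is empty).
#'
#' @slot node the focal node identifier.
#' @slot shells list of character vectors, indexed by distance n.
#' @slot shellSizes integer vector `q_n`.
#' @slot essentialCounts integer vector, members of E- per shell.
#' @slot proportions numeric vector `q^E_n / q_n`.
#' @seealso [computeShells()]
#' @export
setClass("ShellProfile",
  representation(
    node = "character",
    shells = "list",
    shellSizes = "integer",
    essentialCounts = "integer",
    proportions = "numeric"
  )
)

#' Two-class shell-proportion comparison
#'
#' Medians of the non-disease essential shell proportions for two protein
#' classes at a fixed shell index, with a two-sided rank-sum p-value.
#'
#' @slot n shell index.
#' @slot classA,classB class names.
#' @slot medianA,medianB medians of the defined proportions (fractions).
#' @slot nA,nB sample sizes.
#' @slot pValue two-sided rank-sum p-value.
#' @slot method `"exact"` (permutation enumeration) or `"normal"`
#'   (tie-corrected normal approximation).
#' @seealso [compareClasses()]
#' @export
setClass("ShellComparison",
  representation(
    n = "integer",
    classA = "character",
    classB = "character",
    medianA = "numeric",
    medianB = "numeric",
    nA = "integer",
    nB = "integer",
    pValue = "numeric",
    method = "character"
  )
)

#' Chromosome-local candidate gene list
#'
#' The test gene together with its closest genes on the same chromosome
#' (at most 100 in total, fewer on short chromosomes).
#'
#' @slot testGene identifier of the held-out gene.
#' @slot candidates ordered identifier vector including the test gene.
#' @seealso [buildCandidateList()]
#' @export
setClass("CandidateList",
  representation(testGene = "character", candidates = "character")
)

setValidity("CandidateList", function(object) {
  if (!object@testGene %in% object@candidates) {
    return("test gene must be among the candidates")
  }
  if (anyDuplicated(object@candidates)) return("duplicated candidates")
  TRUE
})

#' Evaluation report
#'
#' Collected results of a cross-validation or train/test evaluation:
#' one trial per (disease, test gene) with the test gene's rank inside its
#' candidate list and the enrichment score 50/rank; per-disease and overall
#' means ("score 1" over all trials, "score 2" over on-network trials
#' only); ROC points and AUC over on-network trials.
#'
#' @slot trials data.frame with columns disease, gene, rank, enrichment,
#'   onNetwork, candidateSize.
#' @slot perDisease data.frame with per-disease mean score1/score2.
#' @slot score1,score2 overall means (disease as the averaging unit).
#' @slot roc data.frame with columns threshold, fpr, sensitivity (or NULL).
#' @slot auc numeric or NULL.
#' @slot mode the prioritization mode used.
#' @seealso [loocv()], [timeSplitEvaluate()], [rocAuc()]
#' @export
setClass("EvaluationReport",
  representation(
    trials = "data.frame",
    perDisease = "data.frame",
    score1 = "numeric",
    score2 = "numeric",
    roc = "dfOrNULL",
    auc = "numericOrNULL",
    mode = "character"
  )
)

#' Synthetic network specification
#'
#' Parameters of the synthetic benchmark generator: a preferential-attachment
#' base graph with planted, densely interlinked disease modules kept away
#' from an interconnected high-degree essential core, plus decoy hubs wired
#' to both disease modules and essentials.  All randomness flows from
#' `seed`.
#'
#' @slot nNodes total nodes.
#' @slot attachment preferential-attachment edges per new node.
#' @slot nDiseases number of planted disease modules.
#' @slot moduleSize genes per disease module.
#' @slot moduleDensity within-module extra-edge probability.
#' @slot nEssentials size of the essential hub core.
#' @slot essentialInterconnect essential-essential extra-edge probability.
#' @slot decoyHubs number of decoy non-disease hubs.
#' @slot nChromosomes chromosomes used for the gene-position table.
#' @slot seed integer seed.
#' @seealso [syntheticSpec()], [generateSynthetic()]
#' @export
setClass("SyntheticSpec",
  representation(
    nNodes = "integer",
    attachment = "integer",
    nDiseases = "integer",
    moduleSize = "integer",
    moduleDensity = "numeric",
    nEssentials = "integer",
    essentialInterconnect = "numeric",
    decoyHubs = "integer",
    nChromosomes = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  probs <- c(object@moduleDensity, object@essentialInterconnect)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  needed <- object@nDiseases * object@moduleSize + object@nEssentials +
    object@decoyHubs
  if (needed > object@nNodes) {
    return("disease modules, essentials and decoys exceed nNodes")
  }
  if (object@nNodes < 2L || object@attachment < 1L) {
    return("need at least 2 nodes and attachment >= 1")
  }
  TRUE
})
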