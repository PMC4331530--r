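#' Build a chromosome-local candidate gene list
#'
#' Selects the genes closest to the test gene on its own chromosome, by
#' absolute difference of the per-gene coordinate, and returns them
#' together with the test gene (at most `size` genes in total; fewer on
#' short chromosomes).  Distance ties at the cutoff are broken by
#' identifier order, so the list is deterministic.
#'
#' @param testGene identifier; must appear in `positions`.
#' @param positions data.frame with columns `gene`, `chromosome`,
#'   `position` (one numeric coordinate per gene; users may supply start
#'   positions or midpoints).
#' @param size maximum list size including the test gene (default 100).
#' @return a [CandidateList-class].
#' @export
buildCandidateList <- function(testGene, positions, size = 100L) {
  idx <- match(testGene, positions$gene)
  if (is.na(idx)) stop("test gene '", testGene, "' absent from positions")
  chr <- positions$chromosome[idx]
  same <- positions[positions$chromosome == chr & positions$gene != testGene, ]
  dist <- abs(same$position - positions$position[idx])
  ord <- order(dist, same$gene)
  picked <- same$gene[ord][seq_len(min(size - 1L, nrow(same)))]
  new("CandidateList", testGene = testGene,
      candidates = c(testGene, picked))
}

#' Random decoy candidate list
#'
#' Position-free fallback: the test gene plus decoys sampled uniformly
#' from non-disease network genes.  Used when no gene-position table is
#' available; the sampling seed must be supplied so runs are reproducible.
#'
#' @param testGene identifier.
#' @param net an [AnnotatedNetwork-class].
#' @param diseaseIds disease genes excluded from the decoy pool.
#' @param size maximum list size including the test gene.
#' @return a [CandidateList-class].
#' @keywords internal
randomCandidateList <- function(testGene, net, diseaseIds, size = 100L) {
  pool <- setdiff(net@nodes, c(diseaseIds, testGene))
  picked <- sample(pool, min(size - 1L, length(pool)))
  new("CandidateList", testGene = testGene,
      candidates = c(testGene, picked))
}

# Rank of the test gene within its scored candidate list, with the
# pessimistic tie rule (equal flow => ranked last among the tied group).
.testGeneRank <- function(scored, testGene) {
  scored$rank[match(testGene, scored$gene)]
}

.evaluateTrials <- function(net, partition, config, diseaseMap, trainSets,
                            testGenes, mode, positions, candidateSize,
                            offNetworkRank = 100L) {
  eMinus <- classMembers(net, partition, "Eminus")
  diseases <- names(testGenes)
  w <- buildOperator(net, config@normalization)

  rows <- list()
  for (h in diseases) {
    for (g in testGenes[[h]]) {
      train <- setdiff(trainSets[[h]], g)
      onNet <- g %in% net@nodes
      if (!onNet) {
        rows[[length(rows) + 1L]] <- data.frame(
          disease = h, gene = g, rank = offNetworkRank,
          enrichment = 50 / offNetworkRank, onNetwork = FALSE,
          candidateSize = candidateSize, stringsAsFactors = FALSE
        )
        next
      }
      cand <- if (is.null(positions)) {
        randomCandidateList(g, net, partition@disease, candidateSize)
      } else {
        buildCandidateList(g, positions, candidateSize)
      }
      trainOn <- intersect(train, net@nodes)
      if (length(trainOn) == 0L && mode != "NP_E") {
        warning("disease '", h, "': no on-network training gene for test '",
                g, "'; trial skipped")
        next
      }
      prior <- buildPrior(net, mode, trainOn, eMinus,
                          priorMode = config@priorMode)
      flow <- flowValues(propagateFlow(net, prior, config, operator = w))
      scored <- rankCandidates(flow, cand@candidates)
      r <- .testGeneRank(scored, g)
      rows[[length(rows) + 1L]] <- data.frame(
        disease = h, gene = g, rank = r, enrichment = 50 / r,
        onNetwork = TRUE, candidateSize = length(cand@candidates),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

.summarizeTrials <- function(trials, mode, candidateSize) {
  perDisease <- do.call(rbind, lapply(split(trials, trials$disease), function(d) {
    data.frame(
      disease = d$disease[1L],
      nTrials = nrow(d),
      score1 = mean(d$enrichment),
      score2 = if (any(d$onNetwork)) mean(d$enrichment[d$onNetwork]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(perDisease) <- NULL
  roc <- NULL
  auc <- NULL
  if (any(trials$onNetwork)) {
    ra <- rocAuc(trials, candidateSize)
    roc <- ra$roc
    auc <- ra$auc
  }
  new("EvaluationReport",
    trials = trials,
    perDisease = perDisease,
    score1 = mean(perDisease$score1),
    score2 = mean(perDisease$score2, na.rm = TRUE),
    roc = roc, auc = auc, mode = mode
  )
}

#' Leave-one-out cross-validation of gene prioritization
#'
#' For every disease with at least two genes, each disease gene is held
#' out in turn: the remaining genes form the training prior, the held-out
#' gene is re-ranked within its chromosome-local candidate list, and the
#' enrichment score 50/rank is recorded.  A held-out gene whose protein is
#' absent from the network receives rank 100 (enrichment 0.5).  Per the
#' pessimistic tie rule, a test gene with the same flow as other
#' candidates is ranked last among them.  The non-disease essential set
#' `E-` is derived from the full disease annotation once and is not
#' recomputed per fold.
#'
#' "Enrichment score 1" averages over all trials, "score 2" over
#' on-network trials only; both are averaged per disease first, then over
#' diseases.
#'
#' @param diseaseMap data.frame with columns `disease`, `gene` (and
#'   optionally `year`, ignored here).
#' @param net an [AnnotatedNetwork-class].
#' @param partition a [GenePartition-class]; its `E-` class feeds the
#'   negative prior.
#' @param config a [PropagationConfig-class].
#' @param positions optional gene-position data.frame for
#'   [buildCandidateList()]; when `NULL`, random decoy lists are drawn
#'   (set a seed for reproducibility).
#' @param mode `"NP_DE"`, `"NP_D"` or `"NP_E"`.
#' @param candidateSize candidate list size (default 100).
#' @return an [EvaluationReport-class].
#' @export
loocv <- function(diseaseMap, net, partition, config = propagationConfig(),
                  positions = NULL, mode = "NP_DE", candidateSize = 100L) {
  genes <- split(as.character(diseaseMap$gene), as.character(diseaseMap$disease))
  genes <- lapply(genes, unique)
  small <- names(genes)[lengths(genes) < 2L]
  if (length(small)) {
    warning("skipping disease(s) with fewer than 2 genes: ",
            paste(small, collapse = ", "))
    genes <- genes[lengths(genes) >= 2L]
  }
  if (length(genes) == 0L) stop("no disease with at least 2 genes")
  trials <- .evaluateTrials(net, partition, config, diseaseMap,
                            trainSets = genes, testGenes = genes,
                            mode = mode, positions = positions,
                            candidateSize = candidateSize)
  .summarizeTrials(trials, mode, candidateSize)
}

#' Evaluate with a fixed train/test split
#'
#' Same scoring as [loocv()], but the training set per disease is fixed
#' (e.g. genes verified before a cutoff year) and every test gene is
#' ranked against it.  Train and test sets must be disjoint within each
#' disease; diseases with an empty test or training set are skipped with a
#' warning.
#'
#' @param trainMap,testMap data.frames with columns `disease`, `gene`.
#' @inheritParams loocv
#' @return an [EvaluationReport-class].
#' @export
timeSplitEvaluate <- function(trainMap, testMap, net, partition,
                              config = propagationConfig(),
                              positions = NULL, mode = "NP_DE",
                              candidateSize = 100L) {
  train <- lapply(split(as.character(trainMap$gene),
                        as.character(trainMap$disease)), unique)
  test <- lapply(split(as.character(testMap$gene),
                       as.character(testMap$disease)), unique)
  shared <- intersect(names(train), names(test))
  for (h in shared) {
    ov <- intersect(train[[h]], test[[h]])
    if (length(ov)) {
      stop("disease '", h, "': train and test sets overlap (",
           paste(ov, collapse = ", "), ")")
    }
  }
  dropped <- setdiff(names(test), shared)
  if (length(dropped)) {
    warning("skipping disease(s) with no training genes: ",
            paste(dropped, collapse = ", "))
  }
  if (length(shared) == 0L) stop("no disease with both train and test genes")
  trials <- .evaluateTrials(net, partition, config, NULL,
                            trainSets = train[shared],
                            testGenes = test[shared],
                            mode = mode, positions = positions,
                            candidateSize = candidateSize)
  # held-out genes are fixed test genes here: nothing is removed from train
  .summarizeTrials(trials, mode, candidateSize)
}

#' Split a disease-gene table by year
#'
#' @param diseaseMap data.frame with columns `disease`, `gene`, `year`.
#' @param year cutoff: genes with `year < year` train, the rest test.
#' @return list with elements `train` and `test`.
#' @export
splitByYear <- function(diseaseMap, year) {
  stopifnot("year" %in% names(diseaseMap))
  list(
    train = diseaseMap[diseaseMap$year < year, c("disease", "gene")],
    test = diseaseMap[diseaseMap$year >= year, c("disease", "gene")]
  )
}

#' ROC curve and AUC over prioritization trials
#'
#' Treats prioritization as binary classification under a rank threshold
#' t: within each trial's candidate list the test gene is the positive,
#' the remaining candidates negatives.  For t = 0..candidateSize,
#' sensitivity is the fraction of test genes ranked at or above t, and
#' specificity the mean over trials of the fraction of non-test candidates
#' ranked below t.  The curve runs from (0, 0) to (1, 1); AUC is computed
#' by trapezoidal integration over (1 - specificity, sensitivity).
#' Off-network trials are excluded.
#'
#' @param trials data.frame as in [EvaluationReport-class] `trials` (needs
#'   columns `rank`, `onNetwork`, `candidateSize`).
#' @param candidateSize largest rank threshold considered.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `sensitivity`)
#'   and `auc`.
#' @export
rocAuc <- function(trials, candidateSize = 100L) {
  tr <- trials[trials$onNetwork, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no on-network trial for ROC analysis")
  thr <- 0:candidateSize
  sens <- vapply(thr, function(t) mean(tr$rank <= t), numeric(1))
  fpr <- vapply(thr, function(t) {
    # non-test candidates occupy the ranks 1..c other than the test rank
    mean((pmin(t, tr$candidateSize) - (tr$rank <= t)) / (tr$candidateSize - 1))
  }, numeric(1))
  ord <- order(fpr, sens)
  x <- fpr[ord]; y <- sens[ord]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(
    roc = data.frame(threshold = thr, fpr = fpr, sensitivity = sens),
    auc = auc
  )
}

#' Pairwise (Mann-Whitney style) AUC over trials
#'
#' Independent cross-check of [rocAuc()]: the probability that the test
#' gene outranks a randomly chosen decoy from its candidate list, averaged
#' over on-network trials, counting rank ties as half.
#'
#' @inheritParams rocAuc
#' @return numeric AUC.
#' @export
pairwiseAuc <- function(trials) {
  tr <- trials[trials$onNetwork, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no on-network trial")
  mean((tr$candidateSize - tr$rank) / (tr$candidateSize - 1))
}
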