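#' Create a synthetic benchmark specification
#'
#' Defaults describe the benchmark used throughout the test suite: a
#' 2000-node preferential-attachment graph (hub-dominated, as protein
#' interaction networks are), five planted disease modules of six genes
#' each, a 150-gene interconnected essential hub core that the disease
#' modules avoid, and three decoy hubs wired to both a disease module and
#' the essential core.
#'
#' @param nNodes total nodes.
#' @param attachment edges per node in the preferential-attachment base.
#' @param nDiseases number of disease modules.
#' @param moduleSize genes per module.
#' @param moduleDensity probability of each extra within-module edge.
#' @param nEssentials essential core size.
#' @param essentialInterconnect probability of each essential-essential
#'   extra edge.
#' @param decoyHubs number of decoy non-disease hubs.
#' @param nChromosomes chromosomes in the generated position table.
#' @param seed integer seed driving all randomness.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nNodes = 2000L, attachment = 2L, nDiseases = 5L,
                          moduleSize = 6L, moduleDensity = 0.5,
                          nEssentials = 150L, essentialInterconnect = 0.1,
                          decoyHubs = 3L, nChromosomes = 8L, seed = 1L) {
  new("SyntheticSpec",
    nNodes = as.integer(nNodes), attachment = as.integer(attachment),
    nDiseases = as.integer(nDiseases), moduleSize = as.integer(moduleSize),
    moduleDensity = moduleDensity, nEssentials = as.integer(nEssentials),
    essentialInterconnect = essentialInterconnect,
    decoyHubs = as.integer(decoyHubs),
    nChromosomes = as.integer(nChromosomes), seed = as.integer(seed)
  )
}

# random extra edges among a node set: each unordered pair kept with prob p
.pairSample <- function(ids, p) {
  if (length(ids) < 2L || p <= 0) {
    return(matrix(character(), ncol = 2))
  }
  pairs <- t(utils::combn(ids, 2L))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

#' Generate a synthetic annotated network and gene tables
#'
#' Builds the benchmark an evaluation needs end to end, entirely from the
#' seed in `spec`:
#' \enumerate{
#'   \item a connected preferential-attachment base graph;
#'   \item essential genes sampled degree-weighted (essential proteins are
#'     enriched among hubs), with extra essential-essential edges so the
#'     essential set forms an interconnected core;
#'   \item disease modules also sampled degree-weighted (disease proteins
#'     are topologically central), then decoupled from the essentials:
#'     edges between a module's avoidance region and essential genes are
#'     rewired to ordinary nodes.  The avoidance radius cycles 0/1/2 over
#'     modules, so the disease class is heterogeneous — median shell
#'     proportions of essentials around disease genes stay below those of
#'     ordinary genes over a range of distances rather than at a single
#'     one; each module is densified with a spanning cycle plus random
#'     extra edges;
#'   \item decoy hubs (the reserved top-degree nodes), each wired to at
#'     least half of one disease module and to several essentials — the
#'     adversarial pattern that pure positive propagation over-ranks;
#'   \item a gene-position table assigning genes to chromosomes in
#'     contiguous blocks, so chromosome-local candidate lists are
#'     nontrivial.
#' }
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `network` ([AnnotatedNetwork-class] with
#'   disease/essential labels), `diseaseMap` (data.frame `disease`,
#'   `gene`), `essentials` (character), `positions` (data.frame `gene`,
#'   `chromosome`, `position`), `decoys` (character), `modules` (list),
#'   and `spec`.
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  validObject(spec)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed)

  n <- spec@nNodes
  ids <- sprintf("G%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = 1, m = spec@attachment,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- cbind(ids[el[, 1]], ids[el[, 2]])

  deg <- igraph::degree(g)
  top <- order(deg, decreasing = TRUE)
  decoys <- ids[top[seq_len(spec@decoyHubs)]]
  rest <- setdiff(seq_len(n), top[seq_len(spec@decoyHubs)])
  essentials <- ids[sample(rest, spec@nEssentials, prob = deg[rest])]

  pool <- setdiff(seq_len(n), c(top[seq_len(spec@decoyHubs)],
                                match(essentials, ids)))
  need <- spec@nDiseases * spec@moduleSize
  if (length(pool) < need) {
    stop("infeasible spec: only ", length(pool),
         " nodes available for ", need, " disease-module genes")
  }
  moduleGenes <- ids[sample(pool, need, prob = deg[pool])]
  modules <- split(moduleGenes,
                   rep(seq_len(spec@nDiseases), each = spec@moduleSize))
  names(modules) <- sprintf("disease%02d", seq_len(spec@nDiseases))

  # decouple disease modules from essentials: edges between a module's
  # avoidance region and an essential are rewired onto ordinary nodes;
  # the radius cycles over modules so the disease class is heterogeneous
  others <- setdiff(ids, c(essentials, moduleGenes, decoys))
  rewireEssential <- function(el, region) {
    isDE <- (el[, 1] %in% region & el[, 2] %in% essentials) |
            (el[, 2] %in% region & el[, 1] %in% essentials)
    rew <- el[isDE, , drop = FALSE]
    if (nrow(rew)) {
      keepEnd <- ifelse(rew[, 1] %in% essentials, rew[, 2], rew[, 1])
      rew <- cbind(keepEnd, sample(others, nrow(rew), replace = TRUE))
      rew <- rew[rew[, 1] != rew[, 2], , drop = FALSE]
    }
    rbind(el[!isDE, , drop = FALSE], rew)
  }
  radius <- rep(0:2, length.out = spec@nDiseases)
  for (j in seq_len(spec@nDiseases)) {
    if (radius[j] >= 1L) {
      region <- modules[[j]]
      if (radius[j] >= 2L) {
        nb <- unique(c(el[el[, 1] %in% region, 2],
                       el[el[, 2] %in% region, 1]))
        region <- union(region, setdiff(nb, essentials))
      }
      el <- rewireEssential(el, region)
    }
  }

  extra <- list()
  for (mod in modules) {
    ring <- cbind(mod, mod[c(2:length(mod), 1L)])  # keep the module connected
    extra[[length(extra) + 1L]] <- ring
    extra[[length(extra) + 1L]] <- .pairSample(mod, spec@moduleDensity)
  }
  extra[[length(extra) + 1L]] <-
    .pairSample(essentials, spec@essentialInterconnect)
  for (j in seq_along(decoys)) {
    mod <- modules[[((j - 1L) %% spec@nDiseases) + 1L]]
    toModule <- sample(mod, ceiling(length(mod) / 2))
    toEss <- sample(essentials, min(5L, length(essentials)))
    extra[[length(extra) + 1L]] <- cbind(decoys[j], c(toModule, toEss))
  }

  allEdges <- rbind(el, do.call(rbind, extra))
  net <- annotatedNetwork(allEdges, nodes = ids,
                          diseaseGenes = moduleGenes,
                          essentialGenes = essentials)

  diseaseMap <- data.frame(
    disease = rep(names(modules), lengths(modules)),
    gene = unlist(modules, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  blockSize <- ceiling(n / spec@nChromosomes)
  chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %/% blockSize) + 1L)
  positions <- data.frame(
    gene = ids,
    chromosome = chrom,
    position = as.numeric(((seq_len(n) - 1L) %% blockSize) * 10000),
    stringsAsFactors = FALSE
  )
  list(
    network = net, diseaseMap = diseaseMap, essentials = essentials,
    positions = positions, decoys = decoys, modules = modules, spec = spec
  )
}

#' Fixed toy network: disease module versus a decoy hub
#'
#' A 12-node regression fixture encoding the mechanism the dual-flow
#' method exists for.  Disease genes `a` and `b` (training) form a small
#' module with the held-out disease gene `c`; the non-disease hub `e` has
#' more interactions with the training genes than `c` does and sits on an
#' interconnected ring of essential genes `s1..s5`; `d`, `o1`, `o2` are
#' bystanders.  Positive-only propagation (`NP_D`) over-ranks the hub `e`;
#' adding negative flow from the essentials (`NP_DE`) drains `e` and
#' recovers `c`.
#'
#' @return list with `network` (labelled [AnnotatedNetwork-class]),
#'   `train` (c("a", "b")), `test` ("c"), `decoy` ("e"), and `essentials`.
#' @export
decoyHubToy <- function() {
  edges <- rbind(
    c("a", "b"), c("a", "c"), c("b", "c"),        # the disease module triangle
    c("e", "a"), c("e", "b"),                     # decoy touches both training genes
    c("e", "s1"), c("e", "s2"), c("e", "s3"), c("e", "s4"), c("e", "s5"),
    c("s1", "s2"), c("s2", "s3"), c("s3", "s4"), c("s4", "s5"), c("s5", "s1"),
    c("d", "a"),                                  # local bystander on the module
    c("o1", "s1"), c("o1", "o2")
  )
  net <- annotatedNetwork(edges,
    diseaseGenes = c("a", "b", "c"),
    essentialGenes = c("s1", "s2", "s3", "s4", "s5")
  )
  list(
    network = net, train = c("a", "b"), test = "c", decoy = "e",
    essentials = c("s1", "s2", "s3", "s4", "s5")
  )
}
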