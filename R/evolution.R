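# Genetic-algorithm engine over spanning-tree genomes: edge-rewiring
# mutation, tree-merging crossover, within-generation greedy RMSD
# clustering, truncation selection, and the generation loop. All randomness
# comes from R's global RNG; runGA() seeds it from its config, so a seed
# fully determines a run.

#' Construct an assembly genome
#'
#' @param nSubunits number of subunits.
#' @param edges matrix (or data.frame) with columns `i`, `j`, `decoy`
#'   (i < j) forming a spanning tree.
#' @return A validated [AssemblyGenome-class].
#' @export
assemblyGenome <- function(nSubunits, edges) {
  e <- as.matrix(edges)
  storage.mode(e) <- "integer"
  colnames(e) <- c("i", "j", "decoy")
  new("AssemblyGenome", nSubunits = as.integer(nSubunits),
      edges = .canonicalEdges(e))
}

#' Draw a uniformly random genome
#'
#' A uniformly random labeled spanning tree (random Pruefer sequence) with
#' each edge's decoy drawn uniformly from its pair's pool.
#'
#' @param nSubunits number of subunits (>= 2).
#' @param library a [DecoyLibrary-class] covering all pairs.
#' @return An [AssemblyGenome-class].
#' @export
randomGenome <- function(nSubunits, library) {
  n <- as.integer(nSubunits)
  if (n < 2L) stop("need at least 2 subunits")
  pairs <- if (n == 2L) matrix(c(1L, 2L), 1, 2)
           else .pruferDecode(sample.int(n, n - 2L, replace = TRUE), n)
  decoys <- vapply(seq_len(nrow(pairs)), function(r) {
    sz <- length(decoyPool(library, pairs[r, 1], pairs[r, 2])$score)
    sample.int(sz, 1L)
  }, integer(1))
  assemblyGenome(n, cbind(pairs, decoys))
}

#' Mutate a genome
#'
#' Deletes one uniformly chosen tree edge, splitting the tree into two
#' components, then reconnects with an edge drawn uniformly from all
#' component-crossing pairs (re-selecting the deleted pair is allowed) and a
#' decoy drawn uniformly from that pair's pool. All other edges are
#' unaltered.
#'
#' @param genome an [AssemblyGenome-class].
#' @param library the [DecoyLibrary-class].
#' @return A mutated [AssemblyGenome-class].
#' @export
mutateGenome <- function(genome, library) {
  n <- genome@nSubunits
  e <- genome@edges
  drop <- sample.int(nrow(e), 1L)
  comps <- .splitComponents(e[, 1:2, drop = FALSE], n, drop)
  A <- comps[[1]]; B <- comps[[2]]
  # uniform over all component-crossing pairs (A x B product measure)
  a <- A[sample.int(length(A), 1L)]
  b <- B[sample.int(length(B), 1L)]
  i <- min(a, b); j <- max(a, b)
  sz <- length(decoyPool(library, i, j)$score)
  d <- sample.int(sz, 1L)
  assemblyGenome(n, rbind(e[-drop, , drop = FALSE], c(i, j, d)))
}

#' Crossover of two genomes
#'
#' Builds a child from an empty edge set by drawing candidate edges (with
#' their decoy indices) uniformly without replacement from the multiset
#' union of both parents' edges; a drawn edge is accepted iff its pair is
#' not already used and it does not create a cycle; the loop ends when the
#' child is a spanning tree. The union of two spanning trees is connected,
#' so termination is guaranteed and every child edge traces to a parent.
#'
#' @param parentA,parentB [AssemblyGenome-class] objects over the same
#'   subunits and library.
#' @return A child [AssemblyGenome-class].
#' @export
crossoverGenomes <- function(parentA, parentB) {
  n <- parentA@nSubunits
  if (n != parentB@nSubunits) stop("parents cover different subunit sets")
  pool <- rbind(parentA@edges, parentB@edges)
  ord <- sample.int(nrow(pool))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  child <- matrix(0L, 0, 3)
  usedPair <- character(0)
  for (r in ord) {
    if (nrow(child) == n - 1L) break
    i <- pool[r, 1]; j <- pool[r, 2]
    key <- paste(i, j)
    if (key %in% usedPair) next
    a <- find(i); b <- find(j)
    if (a == b) next
    parent[a] <- b
    child <- rbind(child, pool[r, ])
    usedPair <- c(usedPair, key)
  }
  if (nrow(child) != n - 1L) stop("crossover failed to span (invalid parents)")
  assemblyGenome(n, child)
}

#' Superposed RMSD between two genomes' assembled models
#'
#' Global C-alpha RMSD after optimal superposition between the complexes the
#' two genomes encode; the distance used by the within-generation
#' clustering.
#'
#' @param a,b [AssemblyGenome-class] objects.
#' @param subunits list of [Subunit-class].
#' @param library the [DecoyLibrary-class].
#' @return RMSD in Angstrom.
#' @export
complexRmsdMetric <- function(a, b, subunits, library) {
  subCa <- lapply(subunits, caCoords)
  m <- sum(vapply(subCa, nrow, integer(1)))
  fa <- .genomeCaFlat(a, subCa, library)
  fb <- .genomeCaFlat(b, subCa, library)
  .cppKabschRmsd(matrix(fa, m, 3, byrow = TRUE), matrix(fb, m, 3, byrow = TRUE))
}

#' GA configuration
#'
#' @param populationSize M, the survivors per generation (the original
#'   setting is 200).
#' @param useCrossover apply the crossover stage before mutation.
#' @param crossoverGrowth fractional pool growth of the crossover stage
#'   (default 0.5: M -> 1.5 M).
#' @param mutationGrowth fractional pool growth of the mutation stage
#'   (default 1: pool doubles, one mutant per member).
#' @param generationClusterCutoff Angstrom cutoff of the within-generation
#'   clustering (default 10; `NULL` disables clustering).
#' @param maxGenerations generation budget.
#' @param seed RNG seed for the whole run.
#' @param targetRmsdStop optional early stop: halt once the best model's
#'   RMSD to the native (when given) is at or below this, Angstrom.
#' @return a `gaConfig` list.
#' @export
gaConfig <- function(populationSize = 200L, useCrossover = TRUE,
                     crossoverGrowth = 0.5, mutationGrowth = 1,
                     generationClusterCutoff = 10, maxGenerations = 100L,
                     seed = 1L, targetRmsdStop = NULL) {
  stopifnot(populationSize >= 2, crossoverGrowth > 0, mutationGrowth > 0,
            is.null(generationClusterCutoff) || generationClusterCutoff > 0)
  structure(list(populationSize = as.integer(populationSize),
                 useCrossover = isTRUE(useCrossover),
                 crossoverGrowth = crossoverGrowth,
                 mutationGrowth = mutationGrowth,
                 generationClusterCutoff = generationClusterCutoff,
                 maxGenerations = as.integer(maxGenerations),
                 seed = as.integer(seed), targetRmsdStop = targetRmsdStop),
            class = "gaConfig")
}

# internal individual bookkeeping: parallel lists of genomes, fitness,
# flattened C-alpha rows

#' Cluster-then-truncate selection
#'
#' De-duplicates an expanded pool by the same greedy clustering rules as the
#' pairwise decoy clustering — distance is the superposed global C-alpha
#' RMSD between assembled models, the representative criterion is the
#' fitness total (lower = better) — then ranks representatives by ascending
#' fitness and keeps the best `M`. With `cutoff = NULL`, plain truncation
#' selection.
#'
#' @param genomes list of [AssemblyGenome-class].
#' @param fitness numeric fitness totals (lower = better).
#' @param caFlat matrix of flattened model C-alpha coordinates, one row per
#'   genome.
#' @param M survivors to keep.
#' @param cutoff clustering cutoff in Angstrom, or `NULL`.
#' @return integer indices of the survivors, in ascending fitness order.
#' @export
selectPopulation <- function(genomes, fitness, caFlat, M, cutoff = 10) {
  stopifnot(length(genomes) >= 1)
  if (is.null(cutoff)) {
    keep <- order(fitness)[seq_len(min(M, length(fitness)))]
    return(keep)
  }
  m <- ncol(caFlat) / 3L
  D <- .cppPairwiseKabschRmsd(caFlat, m)
  reps <- .greedyCluster(D, cutoff, -fitness)
  reps[order(fitness[reps])][seq_len(min(M, length(reps)))]
}

.evalIndividuals <- function(genomes, subCa, library, fitnessFun, cache) {
  k <- length(genomes)
  fit <- numeric(k)
  flat <- matrix(0, k, 3 * sum(vapply(subCa, nrow, integer(1))))
  for (idx in seq_len(k)) {
    key <- .genomeKey(genomes[[idx]])
    hit <- cache[[key]]
    if (is.null(hit)) {
      f <- .genomeCaFlat(genomes[[idx]], subCa, library)
      hit <- list(fit = fitnessFun(genomes[[idx]], f), flat = f)
      cache[[key]] <- hit
    }
    fit[idx] <- hit$fit
    flat[idx, ] <- hit$flat
  }
  list(fitness = fit, caFlat = flat)
}

#' One GA generation
#'
#' Expands the population (crossover stage, then mutation stage, per the
#' configured growth fractions), evaluates the new individuals, and applies
#' cluster-then-truncate selection back down to M. With the default growths
#' and M = 200 the pool sizes trace 200 -> 300 -> 600 -> (<= 200) with
#' crossover and 200 -> 400 -> (<= 200) without.
#'
#' @param population a [Population-class].
#' @param config a [gaConfig()].
#' @param subunits,library the assembly context.
#' @param fitnessFun function(genome, caFlat) -> fitness total.
#' @param cache environment used as fitness/coordinate cache.
#' @return list `population` (next [Population-class]) and `stats` (pool
#'   sizes and clustering distance evaluations of this step).
#' @export
stepGeneration <- function(population, config, subunits, library, fitnessFun,
                           cache = new.env(parent = emptyenv())) {
  subCa <- lapply(subunits, caCoords)
  genomes <- population@genomes
  fitness <- population@fitness
  caFlat <- population@caFlat
  poolAfterCross <- length(genomes)
  if (config$useCrossover) {
    nC <- round(config$crossoverGrowth * length(genomes))
    kids <- vector("list", nC)
    for (c in seq_len(nC)) {
      pr <- sample.int(length(genomes), 2L)
      kids[[c]] <- crossoverGenomes(genomes[[pr[1]]], genomes[[pr[2]]])
    }
    ev <- .evalIndividuals(kids, subCa, library, fitnessFun, cache)
    genomes <- c(genomes, kids)
    fitness <- c(fitness, ev$fitness)
    caFlat <- rbind(caFlat, ev$caFlat)
    poolAfterCross <- length(genomes)
  }
  nM <- round(config$mutationGrowth * length(genomes))
  src <- if (nM == length(genomes)) seq_len(nM)
         else if (nM < length(genomes)) sample.int(length(genomes), nM)
         else c(rep(seq_len(length(genomes)), nM %/% length(genomes)),
                sample.int(length(genomes), nM %% length(genomes)))
  muts <- lapply(src, function(s) mutateGenome(genomes[[s]], library))
  ev <- .evalIndividuals(muts, subCa, library, fitnessFun, cache)
  genomes <- c(genomes, muts)
  fitness <- c(fitness, ev$fitness)
  caFlat <- rbind(caFlat, ev$caFlat)
  poolPre <- length(genomes)
  before <- distanceEvalCount()
  keep <- selectPopulation(genomes, fitness, caFlat, config$populationSize,
                           config$generationClusterCutoff)
  distEvals <- distanceEvalCount() - before
  pop <- new("Population", generation = population@generation + 1L,
             genomes = genomes[keep], fitness = fitness[keep],
             caFlat = caFlat[keep, , drop = FALSE])
  list(population = pop,
       stats = list(poolAfterCrossover = poolAfterCross,
                    poolPreSelection = poolPre,
                    survivors = length(keep), distEvals = distEvals))
}

#' Run the genetic algorithm
#'
#' Initializes `populationSize` random genomes, then iterates
#' [stepGeneration()] until the generation budget is exhausted or, when a
#' native complex is supplied with `targetRmsdStop`, the best model reaches
#' the target RMSD. Fully reproducible given the config seed.
#'
#' @param subunits list of [Subunit-class].
#' @param library a [DecoyLibrary-class].
#' @param config a [gaConfig()].
#' @param native optional native [AssembledComplex-class]; enables the RMSD
#'   trace column, the early stop, and `fitness = "oracle"`.
#' @param fitness `"energy"` (default; [scoreComplex()] total with `params`
#'   and `weights`), `"oracle"` (RMSD to `native`), or a function
#'   `(genome, caFlat) -> numeric` (lower = better).
#' @param params,weights scoring parameters for `fitness = "energy"`.
#' @return list with `population` (final, fitness-sorted) and `trace`
#'   (data.frame: generation, poolAfterCrossover, poolPreSelection,
#'   survivors, bestFitness, bestRmsd, distEvals).
#' @examples
#' fx <- standardFixture(seed = 1, nSubunits = 3, atomsPerSubunit = 12,
#'                       poolSize = 8)
#' run <- runGA(fx$subunits, fx$library,
#'              gaConfig(populationSize = 10, maxGenerations = 3, seed = 1),
#'              native = fx$native, fitness = "oracle")
#' run$trace
#' @export
runGA <- function(subunits, library, config, native = NULL,
                  fitness = c("energy", "oracle"), params = NULL,
                  weights = NULL) {
  if (any(poolSizes(library) < 1L)) stop("library has an empty pool")
  set.seed(config$seed)
  n <- length(subunits)
  subCa <- lapply(subunits, caCoords)
  mTot <- sum(vapply(subCa, nrow, integer(1)))
  nativeCa <- if (!is.null(native)) caCoords(native)
  fitnessFun <- if (is.function(fitness)) {
    fitness
  } else {
    mode <- match.arg(fitness)
    if (mode == "oracle") {
      if (is.null(native)) stop("oracle fitness requires a native complex")
      function(genome, caFlat)
        .cppKabschRmsd(matrix(caFlat, mTot, 3, byrow = TRUE), nativeCa)
    } else {
      if (is.null(params)) params <- defaultScoreParams()
      if (is.null(weights)) weights <- params$weights
      function(genome, caFlat) {
        cx <- assembleComplex(genome, subunits, library)
        scoreComplex(cx, params, weights)@total
      }
    }
  }
  cache <- new.env(parent = emptyenv())
  genomes <- replicate(config$populationSize, randomGenome(n, library),
                       simplify = FALSE)
  ev <- .evalIndividuals(genomes, subCa, library, fitnessFun, cache)
  ord <- order(ev$fitness)
  pop <- new("Population", generation = 0L, genomes = genomes[ord],
             fitness = ev$fitness[ord],
             caFlat = ev$caFlat[ord, , drop = FALSE])
  bestRmsd <- function(p) {
    if (is.null(native)) return(NA_real_)
    min(.cppKabschRmsdToRef(p@caFlat, nativeCa))
  }
  trace <- data.frame(generation = 0L, poolAfterCrossover = NA_integer_,
                      poolPreSelection = NA_integer_,
                      survivors = length(pop@genomes),
                      bestFitness = pop@fitness[1], bestRmsd = bestRmsd(pop),
                      distEvals = 0)
  stopNow <- function(r) !is.null(native) && !is.null(config$targetRmsdStop) &&
    !is.na(r) && r <= config$targetRmsdStop
  g <- 0L
  while (g < config$maxGenerations && !stopNow(trace$bestRmsd[nrow(trace)])) {
    st <- stepGeneration(pop, config, subunits, library, fitnessFun, cache)
    pop <- st$population
    g <- g + 1L
    trace <- rbind(trace, data.frame(
      generation = g, poolAfterCrossover = st$stats$poolAfterCrossover,
      poolPreSelection = st$stats$poolPreSelection,
      survivors = st$stats$survivors, bestFitness = pop@fitness[1],
      bestRmsd = bestRmsd(pop), distEvals = st$stats$distEvals))
  }
  list(population = pop, trace = trace)
}
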