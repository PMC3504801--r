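# Genome operators, selection, and the generation loop.

tinyLibraries <- function(sizes = 2:6) {
  out <- list()
  for (n in sizes)
    out[[as.character(n)]] <- makeConsistentLibrary(n, poolSize = 4,
                                                    seed = 100 + n)
  out
}

test_that("random genomes are valid spanning trees with in-range decoys", {
  libs <- tinyLibraries()
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(2:6, 1)
    g <- randomGenome(n, libs[[as.character(n)]])
    expect_true(validObject(g))
    expect_equal(nrow(g@edges), n - 1L)
    expect_true(all(g@edges[, 3] >= 1 & g@edges[, 3] <= 4))
  }
  # n = 2 forces the unique single-edge tree
  g2 <- randomGenome(2, libs[["2"]])
  expect_equal(g2@edges[, 1:2], c(i = 1L, j = 2L))
  expect_error(randomGenome(1, libs[["2"]]), "at least 2")
})

test_that("mutation follows the delete-and-reconnect distribution", {
  lib <- makeConsistentLibrary(4, poolSize = 4, seed = 52)
  chain <- assemblyGenome(4, cbind(1:3, 2:4, 1L))
  # enumeration oracle: P(resulting pair set) from uniform edge deletion and
  # uniform component-crossing reconnection
  cuts <- list(
    "1-2" = c("1-2", "1-3", "1-4"),          # components {1} | {2,3,4}
    "2-3" = c("1-3", "1-4", "2-3", "2-4"),   # {1,2} | {3,4}
    "3-4" = c("1-4", "2-4", "3-4"))          # {1,2,3} | {4}
  expected <- c()
  for (del in names(cuts)) {
    for (np in cuts[[del]]) {
      key <- paste(sort(c(setdiff(names(cuts), del), np)), collapse = "|")
      prev <- if (key %in% names(expected)) expected[[key]] else 0
      expected[key] <- prev + (1 / 3) * (1 / length(cuts[[del]]))
    }
  }
  set.seed(53)
  nTrial <- 20000
  got <- table(replicate(nTrial, {
    m <- mutateGenome(chain, lib)
    paste(sort(sprintf("%d-%d", m@edges[, 1], m@edges[, 2])), collapse = "|")
  }))
  for (key in names(expected)) {
    p <- expected[[key]]
    emp <- if (key %in% names(got)) got[[key]] / nTrial else 0
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / nTrial) + 1e-12)
  }
  expect_equal(sum(got), nTrial)
  expect_true(all(names(got) %in% names(expected)))
})

test_that("2-subunit mutation redraws the decoy on the forced topology", {
  lib <- makeConsistentLibrary(2, poolSize = 10, seed = 54)
  g <- assemblyGenome(2, matrix(c(1, 2, 3), 1))
  set.seed(55)
  seen <- replicate(200, mutateGenome(g, lib)@edges[1, 3])
  expect_true(all(replicate(50, {
    m <- mutateGenome(g, lib)
    identical(m@edges[, 1:2], g@edges[, 1:2])
  })))
  expect_gt(length(unique(seen)), 5)  # decoys really are redrawn
})

test_that("crossover of identical parents returns the parent", {
  lib <- makeConsistentLibrary(4, seed = 56)
  set.seed(57)
  g <- randomGenome(4, lib)
  child <- crossoverGenomes(g, g)
  expect_equal(child@edges, g@edges)
})

test_that("crossover children match the exhaustive draw-order oracle", {
  # parents: chain 1-2-3-4 (decoys 1) and star at 1 (decoys 2); the shared
  # pair (1,2) appears once per parent with its own decoy
  chain <- assemblyGenome(4, cbind(1:3, 2:4, 1L))
  star <- assemblyGenome(4, cbind(1L, 2:4, 2L))
  pool <- rbind(chain@edges, star@edges)
  childKey <- function(e) paste(sprintf("%d-%d:%d", e[, 1], e[, 2], e[, 3]),
                                collapse = "|")
  # exhaustive enumeration over all 6! draw orders of the acceptance process
  exp_counts <- new.env(parent = emptyenv())
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], rest)
    out
  }
  for (ord in perms(1:6)) {
    parent <- 1:4
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    child <- matrix(0L, 0, 3)
    used <- character(0)
    for (r in ord) {
      if (nrow(child) == 3) break
      i <- pool[r, 1]; j <- pool[r, 2]
      if (paste(i, j) %in% used) next
      a <- find(i); b <- find(j)
      if (a == b) next
      parent[a] <- b
      child <- rbind(child, pool[r, ])
      used <- c(used, paste(i, j))
    }
    key <- childKey(child[order(child[, 1], child[, 2]), , drop = FALSE])
    exp_counts[[key]] <- (if (is.null(exp_counts[[key]])) 0
                          else exp_counts[[key]]) + 1
  }
  expected <- unlist(as.list(exp_counts)) / factorial(6)
  set.seed(58)
  nTrial <- 20000
  got <- table(replicate(nTrial, childKey(crossoverGenomes(chain, star)@edges)))
  expect_true(all(names(got) %in% names(expected)))
  for (key in names(expected)) {
    emp <- if (key %in% names(got)) got[[key]] / nTrial else 0
    p <- expected[[key]]
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / nTrial) + 1e-12)
  }
})

test_that("crossover children only use parental edges", {
  libs <- tinyLibraries()
  set.seed(59)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    lib <- libs[[as.character(n)]]
    pa <- randomGenome(n, lib)
    pb <- randomGenome(n, lib)
    ch <- crossoverGenomes(pa, pb)
    expect_true(validObject(ch))
    union_keys <- c(sprintf("%d-%d:%d", pa@edges[, 1], pa@edges[, 2], pa@edges[, 3]),
                    sprintf("%d-%d:%d", pb@edges[, 1], pb@edges[, 2], pb@edges[, 3]))
    child_keys <- sprintf("%d-%d:%d", ch@edges[, 1], ch@edges[, 2], ch@edges[, 3])
    expect_true(all(child_keys %in% union_keys))
  }
})

test_that("the genome RMSD metric agrees with the evaluation module", {
  fx <- smallFixture(seed = 60)
  set.seed(61)
  a <- randomGenome(4, fx$library)
  b <- randomGenome(4, fx$library)
  expect_lt(complexRmsdMetric(a, a, fx$subunits, fx$library), 1e-6)
  cxa <- assembleComplex(a, fx$subunits, fx$library)
  cxb <- assembleComplex(b, fx$subunits, fx$library)
  expect_equal(complexRmsdMetric(a, b, fx$subunits, fx$library),
               superposedCaRmsd(cxa, cxb), tolerance = 1e-9)
})

test_that("selection clusters then truncates by fitness", {
  fx <- smallFixture(seed = 62)
  subCa <- lapply(fx$subunits, caCoords)
  flatOf <- function(g) TreeDock:::.genomeCaFlat(g, subCa, fx$library)
  # all individuals identical -> one survivor
  g <- fx$nativeGenome
  flat <- do.call(rbind, replicate(5, flatOf(g), simplify = FALSE))
  keep <- selectPopulation(rep(list(g), 5), c(3, 1, 2, 5, 4), flat, M = 4,
                           cutoff = 10)
  expect_length(keep, 1)
  expect_equal(keep, 2L)  # the best-fitness copy represents the cluster
  # three well-separated bundles (constructed conformations, two identical
  # members each), M = 2 -> the two best-fitness bundle representatives
  set.seed(63)
  m <- 40
  bases <- replicate(3, matrix(rnorm(3 * m, sd = 12), m, 3),
                     simplify = FALSE)
  flat6 <- do.call(rbind, lapply(rep(bases, each = 2),
                                 function(x) as.vector(t(x))))
  genomes <- rep(list(g), 6)
  fitness <- c(4, 3, 6, 5, 2, 1)
  D <- TreeDock:::.cppPairwiseKabschRmsd(flat6, m)
  expect_gt(min(D[D > 1e-6]), 10)  # bundles are far apart in RMSD
  keep2 <- selectPopulation(genomes, fitness, flat6, M = 2, cutoff = 10)
  expect_equal(sort(fitness[keep2]), c(1, 3))
  # cutoff NULL -> plain top-M
  keep3 <- selectPopulation(genomes, fitness, flat6, M = 3, cutoff = NULL)
  expect_equal(fitness[keep3], c(1, 2, 3))
})

test_that("a generation step follows the configured pool arithmetic", {
  fx <- smallFixture(seed = 64, poolSize = 10)
  subCa <- lapply(fx$subunits, caCoords)
  set.seed(65)
  genomes <- replicate(20, randomGenome(4, fx$library), simplify = FALSE)
  nativeCa <- caCoords(fx$native)
  m <- nrow(nativeCa)
  fitFun <- function(genome, caFlat)
    TreeDock:::.cppKabschRmsd(matrix(caFlat, m, 3, byrow = TRUE), nativeCa)
  flat <- do.call(rbind, lapply(genomes, function(g)
    TreeDock:::.genomeCaFlat(g, subCa, fx$library)))
  fit <- vapply(seq_along(genomes), function(i) fitFun(NULL, flat[i, ]),
                numeric(1))
  ord <- order(fit)
  pop <- new("Population", generation = 0L, genomes = genomes[ord],
             fitness = fit[ord], caFlat = flat[ord, ])
  cfg <- gaConfig(populationSize = 20, useCrossover = TRUE, maxGenerations = 1,
                  seed = 66)
  st <- stepGeneration(pop, cfg, fx$subunits, fx$library, fitFun)
  expect_equal(st$stats$poolAfterCrossover, 30)
  expect_equal(st$stats$poolPreSelection, 60)
  expect_lte(length(st$population@genomes), 20)
  expect_equal(st$population@generation, 1L)
  expect_false(is.unsorted(st$population@fitness))
  cfg2 <- gaConfig(populationSize = 20, useCrossover = FALSE,
                   maxGenerations = 1, seed = 66)
  st2 <- stepGeneration(pop, cfg2, fx$subunits, fx$library, fitFun)
  expect_equal(st2$stats$poolPreSelection, 40)
})

test_that("runGA is reproducible and respects its stopping rules", {
  fx <- smallFixture(seed = 67, poolSize = 8)
  cfg0 <- gaConfig(populationSize = 12, maxGenerations = 0, seed = 68)
  r0 <- runGA(fx$subunits, fx$library, cfg0, native = fx$native,
              fitness = "oracle")
  expect_equal(nrow(r0$trace), 1L)
  expect_equal(r0$trace$generation, 0L)

  cfg <- gaConfig(populationSize = 12, maxGenerations = 5, seed = 69)
  r1 <- runGA(fx$subunits, fx$library, cfg, native = fx$native,
              fitness = "oracle")
  r2 <- runGA(fx$subunits, fx$library, cfg, native = fx$native,
              fitness = "oracle")
  expect_identical(r1$trace, r2$trace)
  expect_equal(r1$population@fitness, r2$population@fitness)

  # every surviving genome is a valid spanning tree
  for (g in r1$population@genomes) expect_true(validObject(g))
})

test_that("best fitness is non-increasing under pure truncation selection", {
  fx <- smallFixture(seed = 70, poolSize = 8)
  cfg <- gaConfig(populationSize = 15, maxGenerations = 10, seed = 71,
                  generationClusterCutoff = NULL)
  r <- runGA(fx$subunits, fx$library, cfg, native = fx$native,
             fitness = "oracle")
  expect_true(all(diff(r$trace$bestFitness) <= 1e-12))
})
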