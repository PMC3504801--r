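# Synthetic fixtures: compact blob-shaped rigid subunits arranged into a
# native complex with guaranteed pairwise interfaces, plus decoy libraries
# with planted near-native transforms buried among random surface
# placements. Everything is deterministic per seed, so the whole pipeline is
# testable with no external data. The subunits are abstract rigid point
# clouds, not real folds: the search and clustering machinery depends only
# on rigid geometry, C-alpha subsets and contacts.

#' Synthetic fixture specification
#'
#' @param nSubunits number of subunits (3-6 typical).
#' @param atomsPerSubunit residues per subunit (each contributes a C-alpha
#'   plus one side-chain heavy atom).
#' @param poolSize decoys per pair.
#' @param nativePlanted plant the (noised) native transform at decoy index 1
#'   of every contacting pair's pool.
#' @param nativeNoiseRot rotation noise on the planted decoy, degrees.
#' @param nativeNoiseTrans translation noise on the planted decoy, Angstrom.
#' @param scoreSignal in `[0, 1]`: correlation strength between shape score
#'   and nativeness (1 = planted decoy scores best; 0 = uninformative).
#' @param seed RNG seed.
#' @return a `syntheticSpec` list.
#' @export
syntheticSpec <- function(nSubunits = 4L, atomsPerSubunit = 60L,
                          poolSize = 200L, nativePlanted = TRUE,
                          nativeNoiseRot = 0, nativeNoiseTrans = 0,
                          scoreSignal = 0.5, seed = 1L) {
  stopifnot(nSubunits >= 2, atomsPerSubunit >= 3, poolSize >= 1,
            nativeNoiseRot >= 0, nativeNoiseTrans >= 0,
            scoreSignal >= 0, scoreSignal <= 1)
  structure(list(nSubunits = as.integer(nSubunits),
                 atomsPerSubunit = as.integer(atomsPerSubunit),
                 poolSize = as.integer(poolSize),
                 nativePlanted = isTRUE(nativePlanted),
                 nativeNoiseRot = nativeNoiseRot,
                 nativeNoiseTrans = nativeNoiseTrans,
                 scoreSignal = scoreSignal, seed = as.integer(seed)),
            class = "syntheticSpec")
}

# one blob subunit in its local frame (C-alpha centroid at the origin)
.makeBlob <- function(id, nRes, radius) {
  types <- sample(c("ALA", "ASP", "LYS"), nRes, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  dir <- matrix(rnorm(3 * nRes), nRes, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  ca <- dir * radius * runif(nRes)^(1 / 3)
  ca <- sweep(ca, 2, colMeans(ca))
  sdir <- matrix(rnorm(3 * nRes), nRes, 3)
  sdir <- sdir / sqrt(rowSums(sdir^2))
  side <- ca + 1.5 * sdir
  sideName <- c(ALA = "CB", ASP = "OD1", LYS = "NZ")[types]
  sideElem <- c(ALA = "C", ASP = "O", LYS = "N")[types]
  df <- data.frame(
    serial = seq_len(2 * nRes),
    name = as.vector(rbind("CA", sideName)),
    element = as.vector(rbind("C", sideElem)),
    resname = rep(types, each = 2),
    resno = rep(seq_len(nRes), each = 2),
    inscode = "", chain = LETTERS[id],
    x = as.vector(rbind(ca[, 1], side[, 1])),
    y = as.vector(rbind(ca[, 2], side[, 2])),
    z = as.vector(rbind(ca[, 3], side[, 3])),
    stringsAsFactors = FALSE)
  df$isCa <- df$name == "CA"
  new("Subunit", id = as.integer(id), label = LETTERS[id], atoms = df)
}

# residue contacts / closest approach between two placed coordinate sets
.interfaceStats <- function(atomsA, resA, atomsB, resB, cutoff = 5) {
  d2 <- outer(rowSums(atomsA^2), rowSums(atomsB^2), "+") -
    2 * atomsA %*% t(atomsB)
  d2 <- pmax(d2, 0)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  nContacts <- if (nrow(hit))
    length(unique(paste(resA[hit[, 1]], resB[hit[, 2]]))) else 0L
  list(contacts = nContacts, minDist = sqrt(min(d2)))
}

#' Generate a synthetic native complex
#'
#' Builds `nSubunits` compact, non-overlapping blob subunits (random points
#' in a ball; C-alpha plus one side-chain heavy atom per residue, with a
#' sprinkling of charged Asp/Lys residues) and arranges them in a chain so
#' that every adjacent pair shares at least 5 residue contacts at 5 Angstrom
#' without steric overlap. Subunits are returned in their own local frames
#' (as individually solved structures would be); the native complex carries
#' the placed coordinates.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `subunits` (list of [Subunit-class], local frames) and
#'   `native` (the [AssembledComplex-class]).
#' @export
makeToyComplex <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  n <- spec$nSubunits
  # ball radius chosen so the blob's radius of gyration matches the
  # empirical scaling for globular domains, Rg ~ 2.2 N^0.38 (a uniform ball
  # of radius R has Rg = sqrt(3/5) R)
  radius <- 2.2 * spec$atomsPerSubunit^0.38 / sqrt(3 / 5)
  subunits <- lapply(seq_len(n), .makeBlob, nRes = spec$atomsPerSubunit,
                     radius = radius)
  rot <- replicate(n, randomRotation(), simplify = FALSE)
  centers <- matrix(0, n, 3)
  placed <- vector("list", n)
  placeAt <- function(s, center) {
    xyz <- atomCoords(subunits[[s]]) %*% t(rot[[s]])
    sweep(xyz, 2, center, "+")
  }
  placed[[1]] <- placeAt(1, c(0, 0, 0))
  for (s in seq_len(n)[-1]) {
    res <- subunits[[s]]@atoms$resno
    resPrev <- subunits[[s - 1]]@atoms$resno
    ok <- FALSE
    for (try in seq_len(40)) {
      for (d in seq(1.9 * radius, 0.9 * radius, by = -0.25)) {
        center <- centers[s - 1, ] + c(d, 0, 0)
        cand <- placeAt(s, center)
        st <- .interfaceStats(placed[[s - 1]], resPrev, cand, res)
        # closest heavy-atom approach must stay at a physical contact
        # distance; below 3 A the interface is sterically clashed
        if (st$minDist < 3.0) break
        if (st$contacts >= 5) {
          centers[s, ] <- center
          placed[[s]] <- cand
          ok <- TRUE
          break
        }
      }
      if (ok) break
      rot[[s]] <- randomRotation()  # re-orient and retry
    }
    if (!ok)
      stop("could not build a clash-free interface for pair (", s - 1, ",",
           s, "); increase atomsPerSubunit or spacing")
  }
  atoms <- vector("list", n)
  for (s in seq_len(n)) {
    df <- subunits[[s]]@atoms
    df$x <- placed[[s]][, 1]; df$y <- placed[[s]][, 2]
    df$z <- placed[[s]][, 3]
    atoms[[s]] <- df
  }
  native <- new("AssembledComplex",
                subunitIds = seq_len(n), labels = LETTERS[seq_len(n)],
                atoms = atoms, genome = NULL)
  list(subunits = subunits, native = native)
}

# exact rigid transform X -> Y (Kabsch), assuming Y = R X + t exactly
.kabschTransform <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, cy - as.vector(R %*% cx))
}

#' Generate a synthetic decoy library
#'
#' For every subunit pair in contact in the native complex, the pool's first
#' decoy is the exact native relative transform perturbed by the spec's
#' rotation/translation noise (when `nativePlanted`); the remaining decoys
#' are random rigid placements of the ligand subunit on the receptor surface
#' without deep overlap. Non-contacting pairs get all-random pools. Shape
#' scores mix a standardized negative ligand-RMSD-to-native with Gaussian
#' noise in proportion `scoreSignal`, so `scoreSignal = 1` ranks the planted
#' decoy first and 0 is uninformative.
#'
#' @param subunits,native output of [makeToyComplex()].
#' @param spec the same [syntheticSpec()].
#' @return A [DecoyLibrary-class] with `poolSize` decoys per pair.
#' @export
makeDecoyLibrary <- function(subunits, native, spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed + 1L)
  n <- length(subunits)
  k <- spec$poolSize
  placements <- lapply(seq_len(n), function(s) {
    natdf <- native@atoms[[s]]
    .kabschTransform(atomCoords(subunits[[s]]),
                     cbind(natdf$x, natdf$y, natdf$z))
  })
  subCa <- lapply(subunits, caCoords)
  radius <- vapply(subunits, function(s) max(sqrt(rowSums(atomCoords(s)^2))),
                   numeric(1))
  contacts <- .contactSet(native, 5)
  pairInContact <- function(i, j)
    any(grepl(paste0("^", i, ":[^|]*\\|", j, ":"), contacts))
  pools <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      tNat <- composeTransforms(invertTransform(placements[[i]]),
                                placements[[j]])
      rot <- array(0, c(3, 3, k))
      tra <- matrix(0, k, 3)
      inContact <- pairInContact(i, j)
      plant <- inContact && spec$nativePlanted
      start <- 1L
      if (plant) {
        axis <- rnorm(3)
        Rn <- rotationAboutAxis(axis, spec$nativeNoiseRot * pi / 180)
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p <- tNat@translation  # placed ligand centroid (local centroid is 0)
        rot[, , 1] <- Rn %*% tNat@rotation
        tra[1, ] <- as.vector(Rn %*% (tNat@translation - p)) + p +
          spec$nativeNoiseTrans * u
        start <- 2L
      }
      if (start <= k) for (d in seq(start, k)) {
        for (try in seq_len(20)) {
          R <- randomRotation()
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          tr <- (radius[i] + radius[j] - 2) * u
          placedCa <- subCa[[j]] %*% t(R) +
            matrix(tr, nrow(subCa[[j]]), 3, byrow = TRUE)
          dmin <- sqrt(min(pmax(outer(rowSums(subCa[[i]]^2),
                                      rowSums(placedCa^2), "+") -
                                  2 * subCa[[i]] %*% t(placedCa), 0)))
          if (dmin >= 2.0 || try == 20L) {
            rot[, , d] <- R
            tra[d, ] <- tr
            break
          }
        }
      }
      score <- if (inContact) {
        rnat <- vapply(seq_len(k), function(d)
          ligandRmsd(rigidTransform(rot[, , d], tra[d, ]), tNat, subCa[[j]]),
          numeric(1))
        z <- -rnat
        zs <- if (length(z) > 1 && sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
        spec$scoreSignal * zs + (1 - spec$scoreSignal) * rnorm(k)
      } else rnorm(k)
      pools[[.pairKey(i, j)]] <- list(rotation = rot, translation = tra,
                                      score = score)
    }
  }
  decoyLibrary(n, pools)
}

#' Standard synthetic fixture
#'
#' The package's reference test problem: a 4-subunit complex of 60-residue
#' blob subunits with 200 decoys per pair, the exact native transform
#' planted (noise 0) at index 1 of every interface pool, and half-informative
#' shape scores (`scoreSignal` 0.5). The native genome is the chain spanning
#' tree whose edges all use decoy 1.
#'
#' @param seed RNG seed.
#' @param nSubunits,atomsPerSubunit,poolSize,scoreSignal override the
#'   standard settings (used to scale the fixture down).
#' @return list with `spec`, `subunits`, `native`, `library`,
#'   `nativeGenome`.
#' @export
standardFixture <- function(seed = 1L, nSubunits = 4L, atomsPerSubunit = 60L,
                            poolSize = 200L, scoreSignal = 0.5) {
  spec <- syntheticSpec(nSubunits = nSubunits,
                        atomsPerSubunit = atomsPerSubunit,
                        poolSize = poolSize, nativePlanted = TRUE,
                        nativeNoiseRot = 0, nativeNoiseTrans = 0,
                        scoreSignal = scoreSignal, seed = seed)
  toy <- makeToyComplex(spec)
  library <- makeDecoyLibrary(toy$subunits, toy$native, spec)
  edges <- cbind(seq_len(nSubunits - 1), seq(2, nSubunits), 1L)
  genome <- assemblyGenome(nSubunits, edges)
  list(spec = spec, subunits = toy$subunits, native = toy$native,
       library = library, nativeGenome = genome)
}
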