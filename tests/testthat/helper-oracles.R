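# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive results by brute force (explicit loops,
# numeric minimization) so they stay independent of the package's own
# computational paths.

# per-atom ligand RMSD, explicit loop
bruteLigandRmsd <- function(t1, t2, ca) {
  acc <- 0
  for (a in seq_len(nrow(ca))) {
    p1 <- as.vector(t1@rotation %*% ca[a, ]) + t1@translation
    p2 <- as.vector(t2@rotation %*% ca[a, ]) + t2@translation
    acc <- acc + sum((p1 - p2)^2)
  }
  sqrt(acc / nrow(ca))
}

# Brute-force transcription of the greedy clustering rules: neighbor counts
# from per-pair ligand RMSDs, center = max count (ties: better score, lower
# index), representative = best score (ties: lower index). Returns
# representative indices in extraction order.
bruteClusterPool <- function(pool, ligandCa, cutoff) {
  k <- length(pool$score)
  tr <- lapply(seq_len(k), function(d)
    rigidTransform(pool$rotation[, , d], pool$translation[d, ]))
  D <- matrix(0, k, k)
  for (x in seq_len(k)) for (y in seq_len(k))
    D[x, y] <- bruteLigandRmsd(tr[[x]], tr[[y]], ligandCa)
  active <- rep(TRUE, k)
  reps <- integer(0)
  centers <- integer(0)
  while (any(active)) {
    idx <- which(active)
    bestCenter <- NA
    bestKey <- NULL
    for (i in idx) {
      cnt <- sum(D[i, idx] < cutoff)
      key <- c(cnt, pool$score[i], -i)
      if (is.null(bestKey) || cnt > bestKey[1] ||
          (cnt == bestKey[1] && (key[2] > bestKey[2] ||
            (key[2] == bestKey[2] && key[3] > bestKey[3])))) {
        bestKey <- key
        bestCenter <- i
      }
    }
    members <- idx[D[bestCenter, idx] < cutoff]
    rep_i <- members[1]
    for (mi in members)
      if (pool$score[mi] > pool$score[rep_i]) rep_i <- mi
    reps <- c(reps, rep_i)
    centers <- c(centers, bestCenter)
    active[members] <- FALSE
  }
  attr(reps, "centers") <- centers
  reps
}

# random decoy pool with controllable bundles: each bundle is a base
# transform plus small translations
makeRandomPool <- function(k, seed = 1) {
  set.seed(seed)
  rot <- array(0, c(3, 3, k))
  tra <- matrix(rnorm(3 * k, sd = 15), k, 3)
  for (d in seq_len(k)) rot[, , d] <- randomRotation()
  list(rotation = rot, translation = tra, score = rnorm(k))
}

# numeric-minimization RMSD oracle: minimize over axis-angle + translation
# with multi-start BFGS (independent of the closed-form Kabsch solution)
numericRmsdOracle <- function(A, B, nStarts = 12) {
  obj <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    R <- if (ang < 1e-12) diag(3) else rotationAboutAxis(par[1:3], ang)
    M <- sweep(A %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((M - B)^2)))
  }
  best <- Inf
  set.seed(424242)
  for (s in seq_len(nStarts)) {
    start <- c(rnorm(3, sd = if (s == 1) 1e-4 else 2),
               colMeans(B) - colMeans(A))
    fit <- optim(start, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# small consistent library: decoy 1 of EVERY pair is the exact relative
# native transform of random placements, remaining decoys random; lets
# chain/star genomes encode the same complex
makeConsistentLibrary <- function(nSubunits, poolSize = 4, seed = 7) {
  set.seed(seed)
  placements <- lapply(seq_len(nSubunits), function(s)
    rigidTransform(randomRotation(), rnorm(3, sd = 20)))
  pools <- list()
  for (i in seq_len(nSubunits - 1)) {
    for (j in seq((i + 1), nSubunits)) {
      tn <- composeTransforms(invertTransform(placements[[i]]),
                              placements[[j]])
      rot <- array(0, c(3, 3, poolSize))
      tra <- matrix(rnorm(3 * poolSize, sd = 20), poolSize, 3)
      rot[, , 1] <- tn@rotation
      tra[1, ] <- tn@translation
      for (d in seq(2, length.out = poolSize - 1)) rot[, , d] <- randomRotation()
      pools[[paste0(i, "-", j)]] <- list(rotation = rot, translation = tra,
                                         score = rnorm(poolSize))
    }
  }
  decoyLibrary(nSubunits, pools)
}

# tiny Subunit built from explicit coordinates (all C-alpha carbons unless
# overridden); resno one per atom
makeBareSubunit <- function(id, coords, name = "CA", element = "C",
                            resname = "ALA") {
  k <- nrow(coords)
  df <- data.frame(serial = seq_len(k),
                   name = rep_len(name, k), element = rep_len(element, k),
                   resname = rep_len(resname, k), resno = seq_len(k),
                   inscode = "", chain = LETTERS[id],
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   stringsAsFactors = FALSE)
  df$isCa <- df$name == "CA"
  if (!any(df$isCa)) {
    # a far-away anchor CA so the subunit is valid without perturbing any
    # interaction term (all cutoffs << 1000 A)
    df <- rbind(df, data.frame(serial = k + 1L, name = "CA", element = "C",
                               resname = "ALA", resno = k + 1L, inscode = "",
                               chain = LETTERS[id], x = 1000 * id, y = 1000,
                               z = 1000, isCa = TRUE))
  }
  new("Subunit", id = as.integer(id), label = LETTERS[id], atoms = df)
}

# small standard fixture used by most integration tests (fast to build)
smallFixture <- function(seed = 1, nSubunits = 4, atomsPerSubunit = 15,
                         poolSize = 12) {
  standardFixture(seed = seed, nSubunits = nSubunits,
                  atomsPerSubunit = atomsPerSubunit, poolSize = poolSize)
}
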