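# Realizing a genome as a concrete complex: compose edge transforms along
# the unique tree path from the root subunit.

# Per-subunit placement transforms for a genome, as plain (R, t) pairs for
# speed (this sits under every fitness evaluation). The root (default:
# lowest subunit index) keeps the identity; an edge stored for ordered pair
# (i, j) places j in i's frame, and traversing it j -> i uses the inverse.
# Rotations are re-orthonormalized if composition drift exceeds 1e-6.
.genomeTransforms <- function(genome, library, root = NULL) {
  n <- genome@nSubunits
  if (is.null(root)) root <- 1L
  e <- genome@edges
  nbr <- vector("list", n)  # per node: rbind of (neighbor, edge row)
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1]; j <- e[r, 2]
    nbr[[i]] <- rbind(nbr[[i]], c(j, r))
    nbr[[j]] <- rbind(nbr[[j]], c(i, r))
  }
  rot <- vector("list", n)
  tra <- vector("list", n)
  rot[[root]] <- diag(3)
  tra[[root]] <- c(0, 0, 0)
  queue <- root
  seen <- rep(FALSE, n)
  seen[root] <- TRUE
  pools <- library@pools
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    nb <- nbr[[u]]
    for (k in seq_len(NROW(nb))) {
      v <- nb[k, 1]
      if (seen[v]) next
      r <- nb[k, 2]
      i <- e[r, 1]; j <- e[r, 2]; d <- e[r, 3]
      p <- pools[[.pairKey(i, j)]]
      if (is.null(p) || d > length(p$score))
        stop("dangling decoy reference (", i, ",", j, "):", d)
      Re <- p$rotation[, , d]
      te <- p$translation[d, ]
      if (u != i) {  # traversing j -> i: inverse transform
        Re <- t(Re)
        te <- -as.vector(Re %*% te)
      }
      R <- rot[[u]] %*% Re
      if (max(abs(crossprod(R) - diag(3))) > 1e-6) R <- .nearestRotation(R)
      rot[[v]] <- R
      tra[[v]] <- as.vector(rot[[u]] %*% te) + tra[[u]]
      seen[v] <- TRUE
      queue <- c(queue, v)
    }
  }
  if (!all(seen)) stop("genome is not connected")
  list(rotation = rot, translation = tra)
}

#' Assemble a complex from a genome
#'
#' Composes the genome's edge transforms along the unique tree path from the
#' root subunit (lowest index by default, which keeps its input coordinates)
#' and applies them to every subunit's atoms. Placement is deterministic
#' given the genome and root convention; any root yields the same complex up
#' to a global rigid motion.
#'
#' @param genome an [AssemblyGenome-class].
#' @param subunits list of [Subunit-class] in index order.
#' @param library the [DecoyLibrary-class] the genome's edges reference.
#' @param root root subunit index (default lowest index).
#' @return An [AssembledComplex-class].
#' @examples
#' fx <- standardFixture(seed = 1, nSubunits = 3, atomsPerSubunit = 12,
#'                       poolSize = 5)
#' cx <- assembleComplex(fx$nativeGenome, fx$subunits, fx$library)
#' superposedCaRmsd(cx, fx$native)
#' @export
assembleComplex <- function(genome, subunits, library, root = NULL) {
  validObject(genome)
  n <- genome@nSubunits
  if (length(subunits) != n)
    stop("genome covers ", n, " subunits but ", length(subunits), " given")
  trans <- .genomeTransforms(genome, library, root)
  atoms <- vector("list", n)
  for (s in seq_len(n)) {
    df <- subunits[[s]]@atoms
    xyz <- cbind(df$x, df$y, df$z) %*% t(trans$rotation[[s]])
    xyz <- sweep(xyz, 2, trans$translation[[s]], "+")
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    atoms[[s]] <- df
  }
  new("AssembledComplex",
      subunitIds = vapply(subunits, function(s) s@id, integer(1)),
      labels = vapply(subunits, function(s) s@label, character(1)),
      atoms = atoms, genome = genome)
}

# Fast path for GA internals: flattened (atom-major) C-alpha coordinates of
# the assembled model, subunit order fixed regardless of tree shape.
.genomeCaFlat <- function(genome, subCa, library, root = NULL) {
  trans <- .genomeTransforms(genome, library, root)
  n <- genome@nSubunits
  parts <- vector("list", n)
  for (s in seq_len(n)) {
    xyz <- subCa[[s]] %*% t(trans$rotation[[s]])
    parts[[s]] <- sweep(xyz, 2, trans$translation[[s]], "+")
  }
  as.vector(t(do.call(rbind, parts)))
}
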