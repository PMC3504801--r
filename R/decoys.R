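# Decoy-library data model, transform-file I/O, and greedy RMSD clustering
# of pairwise decoy pools (best-shape-score representatives).

.pairKey <- function(i, j) paste0(i, "-", j)

# Package-level counter of clustering distance evaluations; the quadratic
# cost accounting of the clustering step (n^2 ordered comparisons per pass).
.counters <- new.env(parent = emptyenv())
.counters$distEvals <- 0

#' Clustering distance-evaluation counter
#'
#' Every greedy clustering pass (pairwise-decoy or within-generation) counts
#' n^2 distance evaluations for a pool of n members: each member's neighbor
#' row scans the whole pool. This hardware-independent count exposes the
#' quadratic cost of the clustering step.
#'
#' @return `distanceEvalCount()` returns the running total;
#'   `resetDistanceEvalCount()` zeroes it (invisibly returning the old total).
#' @export
distanceEvalCount <- function() .counters$distEvals

#' @rdname distanceEvalCount
#' @export
resetDistanceEvalCount <- function() {
  old <- .counters$distEvals
  .counters$distEvals <- 0
  invisible(old)
}

.countDistEvals <- function(n) {
  .counters$distEvals <- .counters$distEvals + as.numeric(n)^2
}

#' Build a decoy library from pool components
#'
#' @param nSubunits number of subunits.
#' @param pools named list keyed `"i-j"`; each element a list with
#'   `rotation` (3 x 3 x k), `translation` (k x 3), `score` (length k).
#' @return A [DecoyLibrary-class].
#' @export
decoyLibrary <- function(nSubunits, pools) {
  new("DecoyLibrary", nSubunits = as.integer(nSubunits), pools = pools)
}

#' Access one pair's decoy pool
#'
#' @param library a [DecoyLibrary-class].
#' @param i,j subunit indices, `i < j`.
#' @return list with `rotation`, `translation`, `score`.
#' @export
decoyPool <- function(library, i, j) {
  if (i >= j) stop("decoy pools are stored for ordered pairs i < j")
  p <- library@pools[[.pairKey(i, j)]]
  if (is.null(p)) stop("no pool for pair (", i, ",", j, ")")
  p
}

#' Pool sizes of a decoy library
#' @param library a [DecoyLibrary-class].
#' @return named integer vector, one entry per pair.
#' @export
poolSizes <- function(library) {
  vapply(library@pools, function(p) length(p$score), integer(1))
}

#' Fetch one decoy's transform
#'
#' @param library a [DecoyLibrary-class].
#' @param i,j subunit indices, `i < j`.
#' @param index decoy index within the pool.
#' @return A [RigidTransform-class] placing subunit `j` in subunit `i`'s frame.
#' @export
getDecoy <- function(library, i, j, index) {
  p <- decoyPool(library, i, j)
  if (index < 1L || index > length(p$score))
    stop("decoy index ", index, " out of range for pair (", i, ",", j, ")")
  rigidTransform(p$rotation[, , index], p$translation[index, ])
}

#' Read a decoy library from a transform file
#'
#' Format, one file per complex: a header line `#pair i j` opens each pool
#' (1-based subunit indices, i < j), followed by one decoy per line with 13
#' whitespace-separated reals: the rotation matrix in row-major order (9),
#' the translation (3), and the shape score. Other `#` lines are comments.
#' Rotation rows are re-orthonormalized when drift is below 1e-4; beyond
#' that, or for improper rotations, the row is an error.
#'
#' @param path transform file path.
#' @param nSubunits number of subunits the library must cover.
#' @return A [DecoyLibrary-class].
#' @seealso [writeDecoyFile()]
#' @export
readDecoyFile <- function(path, nSubunits) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  lines <- readLines(path)
  pools <- list()
  cur <- NULL
  rows <- list()
  flush <- function() {
    if (is.null(cur)) return()
    if (!length(rows)) stop("empty pool for pair (", cur[1], ",", cur[2], ")")
    k <- length(rows)
    rot <- array(0, c(3, 3, k))
    tra <- matrix(0, k, 3)
    sc <- numeric(k)
    for (d in seq_len(k)) {
      v <- rows[[d]]
      R <- matrix(v[1:9], 3, 3, byrow = TRUE)
      drift <- max(abs(crossprod(R) - diag(3)))
      if (det(R) < 0) stop("improper rotation in pool (", cur[1], ",", cur[2],
                           ") decoy ", d)
      if (drift > 1e-4) stop("rotation fails orthonormality in pool (",
                             cur[1], ",", cur[2], ") decoy ", d)
      if (drift > 1e-9) R <- .nearestRotation(R)
      rot[, , d] <- R
      tra[d, ] <- v[10:12]
      sc[d] <- v[13]
    }
    pools[[.pairKey(cur[1], cur[2])]] <<- list(rotation = rot,
                                               translation = tra, score = sc)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#pair")) {
      flush()
      ij <- as.integer(strsplit(ln, "\\s+")[[1]][2:3])
      if (anyNA(ij) || ij[1] >= ij[2] || ij[1] < 1L || ij[2] > nSubunits)
        stop("bad pair header: ", ln)
      cur <- ij
      rows <- list()
    } else if (startsWith(ln, "#")) {
      next
    } else {
      if (is.null(cur)) stop("decoy row before any #pair header")
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(v) != 13L || anyNA(v)) stop("malformed decoy row: ", ln)
      rows[[length(rows) + 1L]] <- v
    }
  }
  flush()
  decoyLibrary(nSubunits, pools)
}

#' Write a decoy library to a transform file
#'
#' @param library a [DecoyLibrary-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readDecoyFile()] for the format.
#' @export
writeDecoyFile <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# decoy transform library (rotation row-major 9, translation 3, shape score)", con)
  for (key in names(library@pools)) {
    ij <- as.integer(strsplit(key, "-")[[1]])
    writeLines(sprintf("#pair %d %d", ij[1], ij[2]), con)
    p <- library@pools[[key]]
    for (d in seq_along(p$score)) {
      v <- c(as.vector(t(p$rotation[, , d])), p$translation[d, ], p$score[d])
      writeLines(paste(sprintf("%.10g", v), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Ligand C-alpha RMSD between two decoy placements
#'
#' Distance between two rigid placements of the same (ligand) subunit in the
#' shared receptor frame: the RMSD over its C-alpha atoms placed by the two
#' transforms, with no re-superposition.
#'
#' @param t1,t2 [RigidTransform-class] placements of the ligand subunit.
#' @param ligandCa m x 3 matrix of the ligand subunit's C-alpha coordinates
#'   (its own frame).
#' @return RMSD in Angstrom.
#' @export
ligandRmsd <- function(t1, t2, ligandCa) {
  a <- applyTransform(t1, ligandCa)
  b <- applyTransform(t2, ligandCa)
  sqrt(mean(rowSums((a - b)^2)))
}

# All pairwise no-superposition RMSDs of a pool: each decoy placement is
# flattened so squared distances reduce to Euclidean distances / m.
.poolLigandRmsdMatrix <- function(pool, ligandCa) {
  k <- length(pool$score)
  m <- nrow(ligandCa)
  flat <- matrix(0, k, 3 * m)
  for (d in seq_len(k)) {
    placed <- ligandCa %*% t(pool$rotation[, , d]) +
      matrix(pool$translation[d, ], m, 3, byrow = TRUE)
    flat[d, ] <- as.vector(t(placed))
  }
  D <- as.matrix(dist(flat)) / sqrt(m)
  D
}

# Greedy neighbor-count clustering shared by decoy pools and GA generations.
# D: symmetric distance matrix; quality: higher-is-better representative
# criterion. Centers are picked by largest neighbor count (ties: better
# quality, then lower index); the cluster is the center plus its unclustered
# neighbors; the representative is the member with the best quality (ties:
# lowest index). Returns representative indices in extraction order.
.greedyCluster <- function(D, cutoff, quality) {
  n <- nrow(D)
  .countDistEvals(n)
  adj <- D < cutoff
  active <- rep(TRUE, n)
  reps <- integer(0)
  while (any(active)) {
    idx <- which(active)
    counts <- vapply(idx, function(i) sum(adj[i, idx]), integer(1))
    best <- order(-counts, -quality[idx], idx)[1]
    center <- idx[best]
    members <- idx[adj[center, idx]]
    rep_i <- members[order(-quality[members], members)[1]]
    reps <- c(reps, rep_i)
    active[members] <- FALSE
  }
  reps
}

#' Cluster one pair's decoy pool
#'
#' Greedy RMSD clustering of a pairwise decoy pool: decoys are neighbors if
#' their ligand C-alpha RMSD (shared receptor frame, no re-superposition) is
#' strictly below `cutoff`. Clusters are extracted largest-neighbor-count
#' first and each is represented by its best-shape-score member; all other
#' members are deleted. With `cutoff = NULL` the pool is returned unchanged.
#'
#' @param pool a pool list (`rotation`, `translation`, `score`).
#' @param ligandCa m x 3 C-alpha coordinates of the ligand (second) subunit.
#' @param cutoff clustering cutoff in Angstrom, or `NULL` for no clustering.
#' @return The reduced pool, representatives in extraction order, with an
#'   attribute `origIndex` giving each representative's index in the input
#'   pool.
#' @seealso [clusterLibrary()]
#' @export
clusterDecoys <- function(pool, ligandCa, cutoff) {
  k <- length(pool$score)
  if (k == 0L) stop("empty decoy pool")
  if (is.null(cutoff)) {
    attr(pool, "origIndex") <- seq_len(k)
    return(pool)
  }
  stopifnot(cutoff > 0)
  D <- .poolLigandRmsdMatrix(pool, ligandCa)
  reps <- .greedyCluster(D, cutoff, pool$score)
  out <- list(rotation = pool$rotation[, , reps, drop = FALSE],
              translation = pool$translation[reps, , drop = FALSE],
              score = pool$score[reps])
  attr(out, "origIndex") <- reps
  out
}

#' Cluster every pool of a decoy library
#'
#' Applies [clusterDecoys()] to each pair's pool, using that pair's ligand
#' (higher-index) subunit C-alpha coordinates.
#'
#' @param library a [DecoyLibrary-class].
#' @param subunits list of [Subunit-class] (provides ligand C-alpha sets).
#' @param cutoff Angstrom cutoff (typically 5 or 10), or `NULL` to skip
#'   clustering.
#' @return A reduced [DecoyLibrary-class].
#' @export
clusterLibrary <- function(library, subunits, cutoff) {
  if (is.null(cutoff)) return(library)
  subCa <- lapply(subunits, caCoords)
  pools <- library@pools
  for (key in names(pools)) {
    j <- as.integer(strsplit(key, "-")[[1]][2])
    p <- clusterDecoys(pools[[key]], subCa[[j]], cutoff)
    attr(p, "origIndex") <- NULL
    pools[[key]] <- p
  }
  decoyLibrary(library@nSubunits, pools)
}
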