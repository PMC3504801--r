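#' @import methods
#' @importFrom stats rnorm runif setNames median dist sd
#' @importFrom utils head read.table write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib TreeDock, .registration = TRUE
NULL

#' Rigid-body transform
#'
#' A proper rotation plus translation, the currency of a pairwise docking
#' decoy library: applied to coordinates `x` it yields
#' `rotation %*% x + translation` (coordinates in Angstrom).
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1 (tolerance 1e-6).
#' @slot translation numeric length-3 translation vector, Angstrom.
#'
#' @seealso [rigidTransform()], [composeTransforms()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    t <- object@translation
    if (!is.numeric(R) || !identical(dim(R), c(3L, 3L)))
      return("rotation must be a numeric 3x3 matrix")
    if (length(t) != 3L) return("translation must have length 3")
    if (!all(is.finite(R)) || !all(is.finite(t)))
      return("rotation and translation must be finite")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      return("rotation is not orthonormal (tolerance 1e-6)")
    if (abs(det(R) - 1) > 1e-6)
      return("rotation must be proper (det +1); improper rotation")
    TRUE
  }
)

#' Rigid protein subunit
#'
#' One chain of a complex, treated as a rigid body. Atoms are kept in a
#' data frame in file order; `isCa` flags C-alpha atoms, which carry the
#' RMSD metrics used throughout.
#'
#' @slot id integer subunit index (1-based).
#' @slot label chain/file identifier.
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `inscode`, `chain`, `x`, `y`, `z`, `isCa`.
#'
#' @seealso [readPdb()], [caCoords()]
#' @export
setClass("Subunit",
  representation(id = "integer", label = "character", atoms = "data.frame"),
  validity = function(object) {
    need <- c("serial", "name", "element", "resname", "resno", "inscode",
              "chain", "x", "y", "z", "isCa")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms must contain columns:", paste(need, collapse = ", ")))
    if (nrow(object@atoms) < 1L) return("subunit has no atoms")
    if (!any(object@atoms$isCa)) return("subunit has no C-alpha atoms")
    if (!all(is.finite(object@atoms$x)) || !all(is.finite(object@atoms$y)) ||
        !all(is.finite(object@atoms$z)))
      return("atom coordinates must be finite")
    TRUE
  }
)

#' Pairwise decoy library
#'
#' For every ordered subunit pair (i, j) with i < j, a pool of scored
#' rigid-body transforms placing subunit j in subunit i's frame. Each pool is
#' a list with elements `rotation` (3 x 3 x k array), `translation` (k x 3
#' matrix) and `score` (numeric k, shape-complementarity score, higher is
#' better). Pools are the gene pool of the genetic algorithm.
#'
#' @slot nSubunits integer number of subunits.
#' @slot pools named list, one entry per pair, keyed `"i-j"`.
#'
#' @seealso [readDecoyFile()], [clusterLibrary()], [decoyPool()]
#' @export
setClass("DecoyLibrary",
  representation(nSubunits = "integer", pools = "list"),
  validity = function(object) {
    n <- object@nSubunits
    if (length(n) != 1L || n < 2L) return("nSubunits must be >= 2")
    keys <- outer(seq_len(n), seq_len(n), function(i, j) paste0(i, "-", j))
    keys <- keys[upper.tri(keys)]
    miss <- setdiff(keys, names(object@pools))
    if (length(miss))
      return(paste("missing pools for pairs:", paste(miss, collapse = ", ")))
    for (k in keys) {
      p <- object@pools[[k]]
      if (!is.list(p) || is.null(p$rotation) || is.null(p$translation) ||
          is.null(p$score))
        return(paste("pool", k, "must have rotation, translation, score"))
      sz <- length(p$score)
      if (sz < 1L) return(paste("pool", k, "is empty"))
      if (!identical(dim(p$rotation), c(3L, 3L, sz)) ||
          !identical(dim(p$translation), c(sz, 3L)))
        return(paste("pool", k, "has inconsistent dimensions"))
    }
    TRUE
  }
)

#' Spanning-tree assembly genome
#'
#' One individual of the genetic algorithm: a spanning tree over the subunit
#' index set whose edges each reference one pairwise decoy, uniquely
#' determining the geometry of the assembled complex.
#'
#' @slot nSubunits integer number of subunits (tree nodes).
#' @slot edges integer matrix with `nSubunits - 1` rows and columns
#'   `i`, `j`, `decoy` (i < j; `decoy` indexes the pool of pair (i, j)).
#'
#' @seealso [randomGenome()], [mutateGenome()], [crossoverGenomes()],
#'   [assembleComplex()]
#' @export
setClass("AssemblyGenome",
  representation(nSubunits = "integer", edges = "matrix"),
  validity = function(object) {
    n <- object@nSubunits
    e <- object@edges
    if (length(n) != 1L || n < 2L) return("nSubunits must be >= 2")
    if (!is.numeric(e) || ncol(e) != 3L)
      return("edges must be a matrix with columns i, j, decoy")
    if (nrow(e) != n - 1L)
      return("a spanning tree over n subunits needs exactly n - 1 edges")
    if (any(e[, 1] >= e[, 2])) return("edges must satisfy i < j")
    if (any(e[, 1:2] < 1L) || any(e[, 1:2] > n))
      return("edge endpoints out of range")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) return("duplicate edge pair")
    if (!.isSpanningTree(e[, 1:2, drop = FALSE], n))
      return("edges do not form a connected spanning tree")
    if (any(e[, 3] < 1L)) return("decoy indices must be >= 1")
    TRUE
  }
)

#' Assembled complex
#'
#' Concrete all-atom coordinates of a multimeric model, obtained by composing
#' a genome's edge transforms along the tree from the root subunit (the
#' lowest index, which keeps its input coordinates), or read directly from a
#' multi-chain PDB file.
#'
#' @slot subunitIds integer ids of the subunits, in order.
#' @slot labels character labels of the subunits.
#' @slot atoms list of per-subunit atom data frames (same columns as
#'   [Subunit-class]), coordinates in the root frame.
#' @slot genome the [AssemblyGenome-class] that produced the model, or `NULL`.
#'
#' @seealso [assembleComplex()], [writePdb()], [superposedCaRmsd()], [fnat()]
#' @export
setClass("AssembledComplex",
  representation(subunitIds = "integer", labels = "character",
                 atoms = "list", genome = "ANY"),
  validity = function(object) {
    if (length(object@atoms) != length(object@subunitIds))
      return("one atom table per subunit required")
    if (length(object@labels) != length(object@subunitIds))
      return("one label per subunit required")
    TRUE
  }
)

#' GA population
#'
#' A generation's genomes with cached fitness (ascending; lower is better)
#' and, internally, the flattened C-alpha coordinates of each assembled
#' model used by the within-generation clustering.
#'
#' @slot generation integer generation counter (0 = initial population).
#' @slot genomes list of [AssemblyGenome-class].
#' @slot fitness numeric fitness totals, sorted ascending.
#' @slot caFlat matrix, one row per individual, flattened C-alpha
#'   coordinates (atom-major) in the root frame.
#'
#' @seealso [runGA()], [selectPopulation()]
#' @export
setClass("Population",
  representation(generation = "integer", genomes = "list",
                 fitness = "numeric", caFlat = "matrix"),
  validity = function(object) {
    if (length(object@genomes) != length(object@fitness))
      return("one fitness value per genome required")
    if (is.unsorted(object@fitness)) return("fitness must be sorted ascending")
    TRUE
  }
)

#' Fitness score breakdown
#'
#' The three interaction terms of the fitness function and their weighted
#' total (arbitrary energy-like units; lower is better).
#'
#' @slot vdw soft 12-6 van der Waals term.
#' @slot elec distance-dependent-dielectric electrostatic term.
#' @slot contact knowledge-based atom-contact term.
#' @slot total weighted sum `w_vdw*vdw + w_elec*elec + w_contact*contact`.
#' @slot weights the weights used, named `vdw`, `elec`, `contact`.
#'
#' @seealso [scoreComplex()]
#' @export
setClass("ScoreBreakdown",
  representation(vdw = "numeric", elec = "numeric", contact = "numeric",
                 total = "numeric", weights = "numeric"),
  validity = function(object) {
    w <- object@weights
    if (length(w) != 3L) return("weights must have length 3")
    if (all(w == 0)) return("at least one weight must be non-zero")
    tot <- sum(w * c(object@vdw, object@elec, object@contact))
    ref <- max(1, abs(tot))
    if (abs(tot - object@total) > 1e-9 * ref)
      return("total does not equal the weighted sum of terms")
    TRUE
  }
)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 4))
  cat("  translation:", paste(sprintf("%.3f", object@translation), collapse = " "),
      "A\n")
})

setMethod("show", "Subunit", function(object) {
  cat(sprintf("Subunit %d ('%s'): %d atoms, %d C-alpha\n",
              object@id, object@label, nrow(object@atoms),
              sum(object@atoms$isCa)))
})

setMethod("show", "DecoyLibrary", function(object) {
  sz <- vapply(object@pools, function(p) length(p$score), integer(1))
  cat(sprintf("DecoyLibrary: %d subunits, %d pairs, pool sizes %s\n",
              object@nSubunits, length(object@pools),
              paste(range(sz), collapse = "-")))
})

setMethod("show", "AssemblyGenome", function(object) {
  e <- object@edges
  cat(sprintf("AssemblyGenome over %d subunits:\n", object@nSubunits))
  cat(paste(sprintf("  (%d,%d) decoy %d", e[, 1], e[, 2], e[, 3]),
            collapse = "\n"), "\n")
})

setMethod("show", "AssembledComplex", function(object) {
  na <- vapply(object@atoms, nrow, integer(1))
  cat(sprintf("AssembledComplex: %d subunits (%s), %d atoms\n",
              length(object@subunitIds),
              paste(object@labels, collapse = ","), sum(na)))
})

setMethod("show", "Population", function(object) {
  cat(sprintf("Population: generation %d, %d individuals, best fitness %.4g\n",
              object@generation, length(object@genomes),
              if (length(object@fitness)) object@fitness[1] else NA_real_))
})

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown: vdw %.4g, elec %.4g, contact %.4g -> total %.4g\n",
              object@vdw, object@elec, object@contact, object@total))
})
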