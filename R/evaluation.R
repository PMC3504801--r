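# Accuracy metrics against a native complex: optimally superposed global
# C-alpha RMSD, CAPRI fnat, near-native classification, ranking summaries.

#' Near-native RMSD threshold (Angstrom)
#'
#' A model is classed near-native when its superposed global C-alpha RMSD to
#' the native complex is at most this value (2.5 Angstrom).
#' @export
NEAR_NATIVE_RMSD <- 2.5

.checkComposition <- function(model, native) {
  if (length(model@atoms) != length(native@atoms))
    stop("subunit composition mismatch")
  ma <- vapply(model@atoms, function(df) sum(df$isCa), integer(1))
  na <- vapply(native@atoms, function(df) sum(df$isCa), integer(1))
  if (!all(ma == na))
    stop("C-alpha correspondence mismatch between model and native")
}

#' Superposed global C-alpha RMSD
#'
#' Least-squares optimal rigid superposition (closed-form Kabsch/SVD
#' solution) of all C-alpha atoms jointly, then RMSD. Correspondence is
#' positional: the i-th C-alpha of the i-th subunit. Invariant to any rigid
#' motion of either input.
#'
#' @param model,native [AssembledComplex-class] objects with the same
#'   subunit composition.
#' @return RMSD in Angstrom.
#' @export
superposedCaRmsd <- function(model, native) {
  .checkComposition(model, native)
  .cppKabschRmsd(caCoords(model), caCoords(native))
}

# Inter-subunit residue contact set: residue pairs of distinct subunits with
# any heavy-atom distance <= cutoff. Returned as a character vector of keys.
.contactSet <- function(complex, cutoff) {
  n <- length(complex@atoms)
  heavy <- lapply(complex@atoms, function(df)
    df[toupper(df$element) != "H", , drop = FALSE])
  keys <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      A <- heavy[[i]]; B <- heavy[[j]]
      ax <- cbind(A$x, A$y, A$z); bx <- cbind(B$x, B$y, B$z)
      d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
      hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        ra <- paste0(A$resno, A$inscode)[hit[, 1]]
        rb <- paste0(B$resno, B$inscode)[hit[, 2]]
        keys <- c(keys, unique(paste0(i, ":", ra, "|", j, ":", rb)))
      }
    }
  }
  unique(keys)
}

#' Fraction of native contacts (fnat)
#'
#' Native contacts are inter-subunit residue pairs with any heavy-atom
#' distance at most `contactCutoff` in the native complex; fnat is the
#' fraction of them reproduced by the model (CAPRI definition). Returns 1
#' with a warning if the native has no inter-subunit contacts.
#'
#' @param model,native [AssembledComplex-class] objects, same composition.
#' @param contactCutoff heavy-atom contact cutoff, Angstrom (default 5).
#' @return fraction in `[0, 1]`.
#' @export
fnat <- function(model, native, contactCutoff = 5.0) {
  .checkComposition(model, native)
  nat <- .contactSet(native, contactCutoff)
  if (!length(nat)) {
    warning("native complex has no inter-subunit contacts; fnat = 1")
    return(1.0)
  }
  mod <- .contactSet(model, contactCutoff)
  length(intersect(mod, nat)) / length(nat)
}

#' Evaluate a final population against the native complex
#'
#' One row per individual, in fitness order: superposed C-alpha RMSD, fnat,
#' fitness rank, and the near-native flag (RMSD <= 2.5 Angstrom). The
#' attribute `bestRmsdRank` gives the fitness rank of the lowest-RMSD model,
#' the usual headline "Rank" of a docking summary table.
#'
#' @param population a fitness-sorted [Population-class].
#' @param native the native [AssembledComplex-class].
#' @param subunits list of [Subunit-class].
#' @param library the [DecoyLibrary-class].
#' @return data.frame with columns `rank`, `fitness`, `rmsd`, `fnat`,
#'   `nearNative`; attribute `bestRmsdRank`.
#' @export
evaluatePopulation <- function(population, native, subunits, library) {
  k <- length(population@genomes)
  if (!k) stop("empty population")
  res <- data.frame(rank = seq_len(k), fitness = population@fitness,
                    rmsd = NA_real_, fnat = NA_real_, nearNative = NA)
  for (idx in seq_len(k)) {
    cx <- assembleComplex(population@genomes[[idx]], subunits, library)
    res$rmsd[idx] <- superposedCaRmsd(cx, native)
    res$fnat[idx] <- fnat(cx, native)
  }
  res$nearNative <- res$rmsd <= NEAR_NATIVE_RMSD
  attr(res, "bestRmsdRank") <- which.min(res$rmsd)
  res
}
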