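# Fitness function for assembled complexes: a configurable linear
# combination of a soft 12-6 van der Waals term, a distance-dependent
# dielectric electrostatic term, and a knowledge-based atom-contact term.
# Lower total = better. All parameters live in an editable key-value file so
# published parameter sets can be substituted; only inter-subunit pairs are
# scored (rigid subunits make intra-subunit energies constant).

# side-chain carbons adjacent to a polar heteroatom -> class "Cp"
# (the backbone carbonyl carbon "C" is Cp for every residue)
.polarCarbons <- c(
  "ASP:CG", "GLU:CD", "ASN:CG", "GLN:CD", "ARG:CZ",
  "SER:CB", "THR:CB", "CYS:CB", "TYR:CZ",
  "HIS:CG", "HIS:CD2", "HIS:CE1")

#' Read a scoring parameter file
#'
#' Structured key-value text: `vdw ELEMENT sigma epsilon`,
#' `charge RESNAME ATOM q`, `contact CLASS1 CLASS2 value` (classes `Cn`,
#' `Cp`, `N`, `O`, `S`), `cutoff {vdw|elec|contact} value`,
#' `clash_cap_frac value`, `weight {vdw|elec|contact} value`. `#` lines are
#' comments.
#'
#' @param path parameter file; default the parameter set shipped with the
#'   package.
#' @return list with elements `vdw` (named sigma/epsilon), `charges`,
#'   `contact` (5x5 matrix), `cutoffs`, `clashCapFrac`, `weights`.
#' @export
readScoreParams <- function(path = system.file("extdata", "score_params.txt",
                                               package = "TreeDock")) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  classes <- c("Cn", "Cp", "N", "O", "S")
  out <- list(vdw = list(sigma = c(), epsilon = c()),
              charges = c(),
              contact = matrix(0, 5, 5, dimnames = list(classes, classes)),
              cutoffs = c(vdw = 8, elec = 12, contact = 4.5),
              clashCapFrac = 0.6,
              weights = c(vdw = 1, elec = 1, contact = 1))
  for (ln in lines) {
    ln <- trimws(sub("#.*", "", ln))
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    key <- tok[1]
    if (key == "vdw") {
      out$vdw$sigma[tok[2]] <- as.numeric(tok[3])
      out$vdw$epsilon[tok[2]] <- as.numeric(tok[4])
    } else if (key == "charge") {
      out$charges[paste0(tok[2], ":", tok[3])] <- as.numeric(tok[4])
    } else if (key == "contact") {
      if (!all(tok[2:3] %in% classes)) stop("unknown contact class in: ", ln)
      v <- as.numeric(tok[4])
      out$contact[tok[2], tok[3]] <- v
      out$contact[tok[3], tok[2]] <- v
    } else if (key == "cutoff") {
      out$cutoffs[tok[2]] <- as.numeric(tok[3])
    } else if (key == "clash_cap_frac") {
      out$clashCapFrac <- as.numeric(tok[2])
    } else if (key == "weight") {
      out$weights[tok[2]] <- as.numeric(tok[3])
    } else stop("unknown parameter key: ", key)
  }
  out
}

.defaultParamsCache <- new.env(parent = emptyenv())

#' Default scoring parameters
#' @return The shipped parameter set, parsed once and cached.
#' @export
defaultScoreParams <- function() {
  if (is.null(.defaultParamsCache$p)) .defaultParamsCache$p <- readScoreParams()
  .defaultParamsCache$p
}

# per-subunit coordinate/annotation extraction used by all three terms
.scoreTables <- function(complex) {
  lapply(complex@atoms, function(df) {
    el <- toupper(df$element)
    list(xyz = cbind(df$x, df$y, df$z), element = el,
         resname = df$resname, name = df$name,
         heavy = el != "H")
  })
}

.pairDist <- function(ax, bx) {
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  sqrt(pmax(d2, 0))
}

.vdwParamsFor <- function(elements, params) {
  sig <- params$vdw$sigma[elements]
  eps <- params$vdw$epsilon[elements]
  # unknown elements fall back to carbon parameters
  sig[is.na(sig)] <- params$vdw$sigma["C"]
  eps[is.na(eps)] <- params$vdw$epsilon["C"]
  list(sigma = unname(sig), epsilon = unname(eps))
}

#' Soft van der Waals energy
#'
#' Sum over inter-subunit atom pairs within the vdW cutoff (default 8
#' Angstrom) of a 12-6 Lennard-Jones term with per-element radii and well
#' depths (Lorentz-Berthelot combination). Below `clash_cap_frac * sigma`
#' (default 0.6) the term continues linearly so a single deep clash cannot
#' dominate the total.
#'
#' @param complex an [AssembledComplex-class].
#' @param params parameter list from [readScoreParams()].
#' @return energy in arbitrary kcal/mol-like units.
#' @export
vdwEnergy <- function(complex, params = defaultScoreParams()) {
  tabs <- .scoreTables(complex)
  n <- length(tabs)
  cutoff <- params$cutoffs[["vdw"]]
  total <- 0
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      A <- tabs[[i]]; B <- tabs[[j]]
      r <- .pairDist(A$xyz, B$xyz)
      sel <- which(r <= cutoff, arr.ind = TRUE)
      if (!nrow(sel)) next
      pa <- .vdwParamsFor(A$element, params)
      pb <- .vdwParamsFor(B$element, params)
      sig <- (pa$sigma[sel[, 1]] + pb$sigma[sel[, 2]]) / 2
      eps <- sqrt(pa$epsilon[sel[, 1]] * pb$epsilon[sel[, 2]])
      rr <- r[sel]
      rc <- params$clashCapFrac * sig
      lj <- function(d, s, e) {
        sr6 <- (s / d)^6
        4 * e * (sr6^2 - sr6)
      }
      e <- lj(pmax(rr, rc), sig, eps)
      deep <- rr < rc
      if (any(deep)) {
        # linear continuation below the cap radius
        d <- rc[deep]; s <- sig[deep]; ee <- eps[deep]
        slope <- 4 * ee * (-12 * s^12 / d^13 + 6 * s^6 / d^7)
        e[deep] <- lj(d, s, ee) + slope * (rr[deep] - d)
      }
      total <- total + sum(e)
    }
  }
  total
}

#' Electrostatic energy (distance-dependent dielectric)
#'
#' Sum over inter-subunit pairs of charged atoms within the electrostatic
#' cutoff (default 12 Angstrom) of `q_i q_j / (4 r^2)`, i.e. a Coulomb term
#' with dielectric `eps = 4 r`. Charges are assigned from the parameter
#' file's residue/atom table (carboxylate oxygens -0.5 each, Lys NZ +1,
#' Arg NH1/NH2 +0.5 each, His neutral).
#'
#' @inheritParams vdwEnergy
#' @return energy in internal units.
#' @export
elecEnergy <- function(complex, params = defaultScoreParams()) {
  tabs <- .scoreTables(complex)
  n <- length(tabs)
  cutoff <- params$cutoffs[["elec"]]
  q <- lapply(tabs, function(t) {
    qq <- params$charges[paste0(t$resname, ":", t$name)]
    qq[is.na(qq)] <- 0
    unname(qq)
  })
  total <- 0
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      qi <- q[[i]]; qj <- q[[j]]
      ci <- which(qi != 0); cj <- which(qj != 0)
      if (!length(ci) || !length(cj)) next
      r <- .pairDist(tabs[[i]]$xyz[ci, , drop = FALSE],
                     tabs[[j]]$xyz[cj, , drop = FALSE])
      qprod <- outer(qi[ci], qj[cj])
      keep <- r <= cutoff
      total <- total + sum((qprod / (4 * r^2))[keep])
    }
  }
  total
}

.atomClass <- function(element, resname, name) {
  cls <- rep("Cn", length(element))
  cls[element == "N"] <- "N"
  cls[element == "O"] <- "O"
  cls[element == "S"] <- "S"
  isC <- element == "C"
  polar <- paste0(resname, ":", name) %in% .polarCarbons | name == "C"
  cls[isC & polar] <- "Cp"
  unknown <- !element %in% c("C", "N", "O", "S", "H")
  if (any(unknown))
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ","),
            " classed as C-nonpolar")
  cls
}

#' Knowledge-based atom-contact energy
#'
#' Sum over inter-subunit heavy-atom pairs within the contact cutoff
#' (default 4.5 Angstrom) of the contact-potential matrix entry for the two
#' atoms' classes (`Cn` nonpolar carbon, `Cp` polar-adjacent carbon, `N`,
#' `O`, `S`). Unknown elements are classed `Cn` with a warning.
#'
#' @inheritParams vdwEnergy
#' @return energy in internal units.
#' @export
contactEnergy <- function(complex, params = defaultScoreParams()) {
  tabs <- .scoreTables(complex)
  n <- length(tabs)
  cutoff <- params$cutoffs[["contact"]]
  cls <- lapply(tabs, function(t)
    .atomClass(t$element, t$resname, t$name)[t$heavy])
  total <- 0
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq((i + 1), n)) {
      A <- tabs[[i]]; B <- tabs[[j]]
      ax <- A$xyz[A$heavy, , drop = FALSE]
      bx <- B$xyz[B$heavy, , drop = FALSE]
      r <- .pairDist(ax, bx)
      sel <- which(r <= cutoff, arr.ind = TRUE)
      if (!nrow(sel)) next
      total <- total + sum(params$contact[cbind(cls[[i]][sel[, 1]],
                                                cls[[j]][sel[, 2]])])
    }
  }
  total
}

#' Fitness of an assembled complex
#'
#' Weighted linear combination of the van der Waals, electrostatic and
#' contact terms; lower total = better model.
#'
#' @inheritParams vdwEnergy
#' @param weights numeric length 3, named or in order `vdw`, `elec`,
#'   `contact`.
#' @return A [ScoreBreakdown-class].
#' @export
scoreComplex <- function(complex, params = defaultScoreParams(),
                         weights = params$weights) {
  w <- unname(weights[c("vdw", "elec", "contact")])
  if (anyNA(w)) w <- unname(weights)[1:3]
  v <- vdwEnergy(complex, params)
  e <- elecEnergy(complex, params)
  k <- contactEnergy(complex, params)
  new("ScoreBreakdown", vdw = v, elec = e, contact = k,
      total = sum(w * c(v, e, k)),
      weights = setNames(w, c("vdw", "elec", "contact")))
}

#' Oracle fitness: RMSD to the native complex
#'
#' A validation-mode fitness that scores a model by its superposed global
#' C-alpha RMSD to a known native structure, decoupling tests of the search
#' engine from the physics stand-in.
#'
#' @param complex model [AssembledComplex-class].
#' @param native native [AssembledComplex-class], same composition.
#' @return RMSD in Angstrom (lower = better).
#' @export
oracleFitness <- function(complex, native) superposedCaRmsd(complex, native)
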