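# PDB input/output, delegated to bio3d. One Subunit per chain; ATOM records
# only, altloc blank or 'A', first model of multi-model files.

.atomCols <- c("serial", "name", "element", "resname", "resno", "inscode",
               "chain", "x", "y", "z", "isCa")

#' Read subunits from a PDB file
#'
#' Parses ATOM records (HETATM skipped; alternate locations other than blank
#' or `'A'` skipped; insertion codes preserved in residue identity) and
#' returns one [Subunit-class] per chain identifier, in order of first
#' appearance.
#'
#' @param path path to a PDB file.
#' @return list of [Subunit-class].
#' @seealso [writePdb()]
#' @export
readPdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no polymer chains in ", path)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  chains <- unique(at$chain)
  subs <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    ak <- at[at$chain == chains[k], , drop = FALSE]
    elem <- ak$elesy
    bad <- is.na(elem) | elem == ""
    elem[bad] <- substr(trimws(ak$elety[bad]), 1, 1)
    ins <- ak$insert
    ins[is.na(ins)] <- ""
    df <- data.frame(
      serial = ak$eleno, name = trimws(ak$elety), element = trimws(elem),
      resname = trimws(ak$resid), resno = ak$resno, inscode = ins,
      chain = ak$chain, x = ak$x, y = ak$y, z = ak$z,
      stringsAsFactors = FALSE)
    df$isCa <- df$name == "CA" & toupper(df$element) == "C"
    if (!any(df$isCa))
      stop("chain '", chains[k], "' has no C-alpha atoms")
    subs[[k]] <- new("Subunit", id = k, label = as.character(chains[k]),
                     atoms = df)
  }
  subs
}

#' Write an assembled complex (or subunit list) to a PDB file
#'
#' One chain per subunit with chain identifiers `A`, `B`, `C`, ... in subunit
#' order, TER records between chains, coordinates at PDB precision
#' (3 decimals).
#'
#' @param x an [AssembledComplex-class] or a list of [Subunit-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePdb <- function(x, path) {
  tabs <- if (is(x, "AssembledComplex")) x@atoms
          else lapply(x, function(s) s@atoms)
  at <- do.call(rbind, lapply(seq_along(tabs), function(k) {
    df <- tabs[[k]]
    df$chain <- LETTERS[k]
    df
  }))
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(at)),
                   resno = at$resno, resid = at$resname,
                   eleno = seq_len(nrow(at)), elety = at$name,
                   chain = at$chain, insert = at$inscode,
                   elesy = at$element, chainter = TRUE, end = TRUE)
  invisible(path)
}

#' Atom coordinates of a subunit or complex
#'
#' @param x a [Subunit-class] or [AssembledComplex-class].
#' @return n x 3 coordinate matrix (all atoms, subunit order for complexes).
#' @export
atomCoords <- function(x) {
  tabs <- if (is(x, "AssembledComplex")) x@atoms else list(x@atoms)
  do.call(rbind, lapply(tabs, function(df) cbind(df$x, df$y, df$z)))
}

#' C-alpha coordinates of a subunit or complex
#'
#' @param x a [Subunit-class] or [AssembledComplex-class].
#' @return m x 3 coordinate matrix of C-alpha atoms in subunit order.
#' @export
caCoords <- function(x) {
  tabs <- if (is(x, "AssembledComplex")) x@atoms else list(x@atoms)
  do.call(rbind, lapply(tabs, function(df) {
    i <- df$isCa
    cbind(df$x[i], df$y[i], df$z[i])
  }))
}

#' Number of subunits of a complex-like object
#' @param x an [AssembledComplex-class], [DecoyLibrary-class],
#'   [AssemblyGenome-class] or list of [Subunit-class].
#' @return integer.
#' @export
nSubunits <- function(x) {
  if (is(x, "AssembledComplex")) length(x@subunitIds)
  else if (is(x, "DecoyLibrary")) x@nSubunits
  else if (is(x, "AssemblyGenome")) x@nSubunits
  else length(x)
}
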