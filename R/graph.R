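# Spanning-tree utilities shared by the genome operators.

# Connectivity check for an undirected edge list over n nodes.
.isSpanningTree <- function(pairs, n) {
  if (nrow(pairs) != n - 1L) return(FALSE)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a == b) return(FALSE)
    parent[a] <- b
  }
  TRUE
}

# Decode a Pruefer sequence (length n-2, values in 1..n) into the edge list
# of the labeled tree it encodes.
.pruferDecode <- function(seq, n) {
  if (n == 2L) return(matrix(c(1L, 2L), 1, 2))
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2)
  for (k in seq_along(seq)) {
    leaf <- min(which(degree == 1L))
    v <- seq[k]
    edges[k, ] <- c(min(leaf, v), max(leaf, v))
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- c(min(last), max(last))
  edges
}

# Connected components after deleting edge `drop` (row index) from a tree.
.splitComponents <- function(pairs, n, drop) {
  keep <- pairs[-drop, , drop = FALSE]
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(keep))) {
      a <- keep[r, 1]; b <- keep[r, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), comp)
}

# Canonical ordering of an edge matrix: by (i, j).
.canonicalEdges <- function(e) {
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Canonical serialization of a genome; fitness-cache key.
.genomeKey <- function(genome) {
  e <- .canonicalEdges(genome@edges)
  paste(sprintf("%d-%d:%d", e[, 1], e[, 2], e[, 3]), collapse = ";")
}

# Topology-only serialization (ignores decoy choices).
.topologyKey <- function(genome) {
  e <- .canonicalEdges(genome@edges)
  paste(sprintf("%d-%d", e[, 1], e[, 2]), collapse = ";")
}
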