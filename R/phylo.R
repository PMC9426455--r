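#' Construct a labeled symmetric distance matrix
#'
#' @param values n x n numeric matrix (RMSD in Angstrom), symmetric with
#'   zero diagonal.
#' @param labels Taxon labels; taken from dimnames if missing.
#' @param tol Symmetry tolerance.
#' @return A `distance_matrix` (a plain labeled matrix with a class tag).
#' @export
distance_matrix <- function(values, labels = rownames(values), tol = 1e-8) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("labels required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (nrow(values) != ncol(values) || nrow(values) != length(labels)) {
    stop("matrix must be square with one row per label")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite distance for pair (", labels[bad[1]], ", ",
         labels[bad[2]], ")")
  }
  if (max(abs(values - t(values))) > tol) stop("matrix is not symmetric")
  if (max(abs(diag(values))) > tol) stop("diagonal must be zero")
  if (min(values) < -tol) stop("distances must be non-negative")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

#' All-vs-all RMSD matrix from a multiple alignment
#'
#' Entry (i, j) is the pairwise optimal-superposition RMSD of structures i
#' and j restricted to the common-core columns of the alignment; the
#' diagonal is zero.
#'
#' @param alignment A `multiple_alignment` from [multiple_superpose()].
#' @return A `distance_matrix`.
#' @export
build_distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "multiple_alignment"))
  labels <- alignment$labels
  k <- length(labels)
  common <- alignment$common_columns
  vals <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    Xi <- alignment$traces[[i]]$xyz[alignment$columns[common, i], , drop = FALSE]
    for (j in (i + 1):k) {
      Xj <- alignment$traces[[j]]$xyz[alignment$columns[common, j], , drop = FALSE]
      r <- kabsch(Xi, Xj)$rmsd
      if (!is.finite(r)) {
        stop("non-finite RMSD for pair (", labels[i], ", ", labels[j], ")")
      }
      vals[i, j] <- vals[j, i] <- r
    }
  }
  distance_matrix(vals, labels)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, branch
#' lengths follow the standard formulas, and the joined pair is replaced by
#' a node at distance `(d(i,k) + d(j,k) - d(i,j)) / 2` from every other
#' node. Ties in Q are broken by the lexicographically smallest pair of
#' cluster labels (a cluster is labeled by its alphabetically first leaf),
#' so repeated runs are identical. Negative branch lengths are clamped to
#' zero. For additive matrices the generating topology and every edge
#' length are recovered exactly.
#'
#' @param d A `distance_matrix` (or plain labeled symmetric matrix).
#' @return An unrooted `ape::phylo` tree whose root is a trifurcation.
#' @examples
#' d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighbor_joining(distance_matrix(d))
#' @export
neighbor_joining <- function(d) {
  if (!inherits(d, "distance_matrix")) d <- distance_matrix(d)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  D <- unclass(d)

  # each active cluster: its newick fragment and representative leaf label
  frag <- labels
  rep_lab <- labels
  fmt <- function(x) sprintf("%.17g", max(x, 0))

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    key <- apply(ties, 1, function(p) {
      lab <- sort(c(rep_lab[p[1]], rep_lab[p[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- ties[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
                c(dnew, 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
  }

  # final trifurcation
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb),
                   ",", frag[3], ":", fmt(lc), ");")
  ape::read.tree(text = newick)
}

#' Leaf bipartitions (splits) of a tree
#'
#' Each edge of an unrooted tree splits the leaves in two. Splits are
#' reported canonically as the side NOT containing the alphabetically first
#' leaf, as sorted character vectors; trivial splits (single leaves) are
#' excluded unless requested.
#'
#' @param tree An `ape::phylo`.
#' @param include_trivial Include the n leaf edges.
#' @return Named list of splits; names are the canonical
#'   `"|"`-joined leaf sets, values carry the edge length as attribute
#'   `"length"`.
#' @export
tree_splits <- function(tree, include_trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  anchor <- min(tips)
  ntip <- length(tips)
  desc <- descendant_tips(tree)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    side <- sort(tips[desc[[child]]])
    if (!include_trivial && (length(side) <= 1 || length(side) >= ntip - 1)) next
    if (length(side) == 0 || length(side) == ntip) next
    if (anchor %in% side) side <- sort(setdiff(tips, side))
    key <- paste(side, collapse = "|")
    val <- side
    attr(val, "length") <- if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[e]
    out[[key]] <- val
  }
  out
}

descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # edges in postorder so children are resolved before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Test monophyly of a taxon set on an unrooted tree
#'
#' In the unrooted sense, a taxon set is monophyletic when some edge
#' bipartitions the leaves into exactly (taxa, rest); singletons and the
#' full leaf set are trivially monophyletic.
#'
#' @param tree An `ape::phylo`.
#' @param taxa Character vector of leaf labels.
#' @return Logical scalar, with the matched split (if any) as attribute
#'   `"edge_split"`.
#' @export
is_monophyletic <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  taxa <- sort(unique(taxa))
  if (length(taxa) <= 1 || length(taxa) == length(tips)) {
    return(structure(TRUE, edge_split = taxa))
  }
  splits <- tree_splits(tree, include_trivial = TRUE)
  for (s in splits) {
    side <- as.character(s)
    other <- sort(setdiff(tips, side))
    if (identical(side, taxa) || identical(other, taxa)) {
      return(structure(TRUE, edge_split = side))
    }
  }
  structure(FALSE, edge_split = NULL)
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Number of nontrivial bipartitions present in exactly one of the trees.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  s1 <- names(tree_splits(t1))
  s2 <- names(tree_splits(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Read and write Newick trees
#'
#' Branch lengths are serialised with 6 significant digits; the round trip
#' preserves labels, topology, and branch lengths to that precision.
#'
#' @param tree An `ape::phylo`.
#' @param path Output file; if `NULL`, the Newick string is returned.
#' @return `write_newick`: the path (or string) invisibly;
#'   `read_newick`: an `ape::phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length)) {
    tree$edge.length <- signif(tree$edge.length, 6)
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_newick
#' @param text A Newick string (or `NULL` to read from `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) readLines(path, warn = FALSE) else text
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = paste(src, collapse = ""))),
    error = function(e) NULL
  )
  if (is.null(tr)) {
    stop("malformed Newick near character ",
         regexpr("[^(),:;A-Za-z0-9_. '-]", paste(src, collapse = ""))[1])
  }
  tr
}

#' Read and write square PHYLIP distance matrices
#'
#' Relaxed dialect: first line is the number of taxa, each following line is
#' a label (no 10-character truncation) followed by the full row of
#' distances, whitespace-separated.
#'
#' @param d A `distance_matrix`.
#' @param path File path; `write_phylip` returns the text invisibly when
#'   `path` is `NULL`.
#' @export
write_phylip <- function(d, path = NULL) {
  if (!inherits(d, "distance_matrix")) d <- distance_matrix(d)
  labels <- rownames(d)
  lines <- c(
    format(length(labels)),
    vapply(seq_along(labels), function(i) {
      paste(c(labels[i], sprintf("%.6f", d[i, ])), collapse = "  ")
    }, character(1))
  )
  if (is.null(path)) {
    return(invisible(paste(lines, collapse = "\n")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path = NULL, text = NULL) {
  src <- if (is.null(text)) readLines(path, warn = FALSE) else
    strsplit(text, "\n")[[1]]
  src <- src[nzchar(trimws(src))]
  n <- suppressWarnings(as.integer(trimws(src[1])))
  if (is.na(n)) stop("malformed PHYLIP at line 1: expected taxon count")
  if (length(src) < n + 1) stop("malformed PHYLIP: expected ", n, " rows")
  labels <- character(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(src[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1) {
      stop("malformed PHYLIP at line ", i + 1, ": expected label + ",
           n, " values, got ", length(parts), " fields")
    }
    labels[i] <- parts[1]
    vals[i, ] <- as.numeric(parts[-1])
  }
  if (anyNA(vals)) stop("malformed PHYLIP: non-numeric distance")
  dimnames(vals) <- list(labels, labels)
  distance_matrix(vals, labels, tol = 1e-5)
}

#' Write a distance matrix as CSV
#'
#' @param d A `distance_matrix`.
#' @param path Output file.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(unclass(d)), path)
  invisible(path)
}
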