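#' Parameters for sequence-independent structural alignment
#'
#' Tuning constants of the iterative correspondence search. All defaults are
#' fixed; the procedure is fully deterministic.
#'
#' @param mode `"auto"` runs the seed-and-iterate search; `"one_to_one"`
#'   forces the positional identity correspondence (equal-length traces
#'   only), which is what rigid-noise simulations and Procrustes-metric
#'   checks use.
#' @param d0 Distance scale (Angstrom) of the similarity score
#'   `s = 1 / (1 + (d/d0)^2)`.
#' @param pair_cutoff Post-superposition distance (Angstrom) above which an
#'   aligned pair is discarded when rebuilding the correspondence.
#' @param seed_window,seed_stride Length and stride of the gapless windows
#'   exhaustively superposed to seed the search.
#' @param gap_frac Gap penalty as a fraction of the maximum similarity score
#'   in the current iteration.
#' @param max_iter Iteration cap for the refine loop.
#' @param min_pairs Alignments with fewer accepted pairs are flagged
#'   low-confidence.
#' @return A list of class `align_params`.
#' @export
align_params <- function(mode = c("auto", "one_to_one"), d0 = 3.0,
                         pair_cutoff = 6.0, seed_window = 30L,
                         seed_stride = 4L, gap_frac = 0.6,
                         max_iter = 20L, min_pairs = 30L) {
  mode <- match.arg(mode)
  stopifnot(d0 > 0, pair_cutoff > 0, seed_window >= 3, seed_stride >= 1,
            gap_frac >= 0, max_iter >= 1)
  structure(list(mode = mode, d0 = d0, pair_cutoff = pair_cutoff,
                 seed_window = as.integer(seed_window),
                 seed_stride = as.integer(seed_stride),
                 gap_frac = gap_frac, max_iter = as.integer(max_iter),
                 min_pairs = as.integer(min_pairs)),
            class = "align_params")
}

all_pair_dists <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Find a residue correspondence between two CA traces
#'
#' Sequence-independent alignment in the spirit of iterative
#' superposition/dynamic-programming aligners. Gapless windows of both
#' traces are exhaustively superposed; the best window per diagonal-offset
#' band becomes a candidate seed, and candidates compete on how many
#' residues one refinement round brings within the pair cutoff. From the
#' winning seed the loop alternates (a) superposing on the current pair
#' set, (b) scoring all residue pairs by `1/(1 + (d/d0)^2)` on
#' post-superposition distances, (c) global sequential dynamic programming
#' with a linear gap penalty (end gaps free), and (d) keeping aligned pairs
#' closer than `pair_cutoff`, until the pair set is stable. The result is
#' deterministic for fixed inputs and parameters; correspondences are
#' strictly increasing in both traces (no crossings).
#'
#' @param a,b `core_trace` objects.
#' @param params An [align_params()] list.
#' @return Integer matrix of class `correspondence` with columns `i` (index
#'   into `a`) and `j` (index into `b`).
#' @export
find_correspondence <- function(a, b, params = align_params()) {
  stopifnot(inherits(a, "core_trace"), inherits(b, "core_trace"))
  A <- a$xyz
  B <- b$xyz
  if (params$mode == "one_to_one") {
    if (nrow(A) != nrow(B)) {
      stop("one_to_one mode requires equal-length traces")
    }
    return(new_correspondence(cbind(seq_len(nrow(A)), seq_len(nrow(A)))))
  }
  w <- min(params$seed_window, nrow(A), nrow(B))
  if (w < 3) stop("alignment failed: traces too short to seed")
  seeds <- seed_search_cpp(A, B, w, params$seed_stride)
  # repetitive folds make the single best-RMSD window ambiguous (strand
  # windows all look alike), so every diagonal-offset band fields its best
  # window and the candidates compete on refined coverage: the winner is
  # the seed whose one-round refinement keeps the most residues within the
  # pair cutoff (ties broken toward lower RMSD)
  offset_band <- floor(outer(seeds$starts_a, seeds$starts_b, "-") /
                         (2 * params$seed_stride))
  best_pairs <- NULL
  best_score <- -Inf
  for (bb in sort(unique(as.vector(offset_band)))) {
    idx <- which(offset_band == bb)
    o <- idx[which.min(seeds$rmsd[idx])]
    if (!is.finite(seeds$rmsd[o])) next
    wi <- arrayInd(o, dim(seeds$rmsd))
    cand <- cbind(seeds$starts_a[wi[1]] + 0:(w - 1),
                  seeds$starts_b[wi[2]] + 0:(w - 1))
    cand <- refine_pairs(A, B, cand, params)
    score <- if (nrow(cand) < 3) -Inf else {
      fit <- kabsch(A[cand[, 1], , drop = FALSE], B[cand[, 2], , drop = FALSE])
      nrow(cand) - fit$rmsd / params$pair_cutoff
    }
    if (score > best_score) {
      best_score <- score
      best_pairs <- cand
    }
  }
  if (is.null(best_pairs) || nrow(best_pairs) < 3) {
    stop("alignment failed: fewer than 3 stable pairs")
  }
  pairs <- best_pairs

  for (iter in seq_len(params$max_iter)) {
    new_pairs <- refine_pairs(A, B, pairs, params)
    if (nrow(new_pairs) < 3) break
    if (nrow(new_pairs) == nrow(pairs) && all(new_pairs == pairs)) {
      pairs <- new_pairs
      break
    }
    pairs <- new_pairs
  }
  if (nrow(pairs) < 3) stop("alignment failed: fewer than 3 stable pairs")
  new_correspondence(pairs)
}

# one refinement round: superpose on the current pairs, rescore all residue
# pairs, realign by global DP, keep matches within the distance cutoff
refine_pairs <- function(A, B, pairs, params) {
  fit <- kabsch(A[pairs[, 1], , drop = FALSE], B[pairs[, 2], , drop = FALSE])
  Bt <- apply_transform(fit, B)
  D <- all_pair_dists(A, Bt)
  S <- 1 / (1 + (D / params$d0)^2)
  gap <- params$gap_frac * max(S)
  cand <- nw_align_cpp(S, gap)
  cand[D[cand] < params$pair_cutoff, , drop = FALSE]
}

new_correspondence <- function(pairs) {
  colnames(pairs) <- c("i", "j")
  storage.mode(pairs) <- "integer"
  structure(pairs, class = c("correspondence", class(pairs)))
}

#' Pairwise core RMSD between two traces
#'
#' Optimal-superposition RMSD over the residue correspondence found by
#' [find_correspondence()]. Inputs are ordered by label before aligning so
#' the value is exactly symmetric under argument swap.
#'
#' @inheritParams find_correspondence
#' @return RMSD in Angstrom, with attributes `n_pairs` and `low_confidence`
#'   (TRUE when fewer than `params$min_pairs` pairs were aligned).
#' @export
pairwise_core_rmsd <- function(a, b, params = align_params()) {
  if (a$label > b$label) {
    tmp <- a
    a <- b
    b <- tmp
  }
  pairs <- find_correspondence(a, b, params)
  fit <- kabsch(a$xyz[pairs[, 1], , drop = FALSE],
                b$xyz[pairs[, 2], , drop = FALSE])
  out <- fit$rmsd
  attr(out, "n_pairs") <- nrow(pairs)
  attr(out, "low_confidence") <- nrow(pairs) < params$min_pairs
  out
}

#' Progressive multiple superposition onto a common core
#'
#' Aligns every trace to a reference (the trace with the lowest mean
#' pairwise RMSD to all others), collects the reference residues matched by
#' every structure into the common core, and refines a consensus by
#' iterating mean-coordinate superposition until the consensus moves less
#' than `tol` (or 50 iterations).
#'
#' @param traces List of >= 3 `core_trace` objects with unique labels.
#' @param params An [align_params()] list.
#' @param tol Consensus convergence tolerance, Angstrom.
#' @return A `multiple_alignment`: `labels`, `reference` (label),
#'   `columns` (n_ref x n_structures integer matrix mapping each reference
#'   residue to a residue index per structure, NA where unmatched),
#'   `common_columns` (rows of `columns` with no NA), `transforms` (per
#'   structure, the [kabsch()] fit onto the consensus), `consensus`
#'   (m x 3 consensus coordinates on the common core) and `traces`.
#' @export
multiple_superpose <- function(traces, params = align_params(), tol = 1e-6) {
  if (length(traces) < 3) stop("need at least 3 traces")
  labels <- vapply(traces, function(t) t$label, character(1))
  if (anyDuplicated(labels)) stop("trace labels must be unique")
  names(traces) <- labels
  k <- length(traces)

  # reference = minimiser of mean pairwise RMSD
  rms <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- pairwise_core_rmsd(traces[[i]], traces[[j]], params)
      rms[i, j] <- rms[j, i] <- as.numeric(r)
    }
  }
  ref_idx <- which.min(rowSums(rms) / (k - 1))
  ref <- traces[[ref_idx]]

  n_ref <- nrow(ref$xyz)
  columns <- matrix(NA_integer_, n_ref, k, dimnames = list(NULL, labels))
  columns[, ref_idx] <- seq_len(n_ref)
  for (s in seq_len(k)) {
    if (s == ref_idx) next
    pairs <- find_correspondence(ref, traces[[s]], params)
    columns[pairs[, 1], s] <- pairs[, 2]
  }
  common <- which(rowSums(is.na(columns)) == 0)
  if (length(common) < 3) stop("no common core")

  # consensus refinement on the common core
  coords <- lapply(seq_len(k), function(s) {
    traces[[s]]$xyz[columns[common, s], , drop = FALSE]
  })
  consensus <- coords[[ref_idx]]
  transforms <- vector("list", k)
  for (it in seq_len(50)) {
    placed <- lapply(seq_len(k), function(s) {
      fit <- kabsch(consensus, coords[[s]])
      transforms[[s]] <<- fit
      apply_transform(fit, coords[[s]])
    })
    new_consensus <- Reduce(`+`, placed) / k
    shift <- mean(sqrt(rowSums((new_consensus - consensus)^2)))
    consensus <- new_consensus
    if (shift < tol) break
  }
  names(transforms) <- labels

  structure(
    list(labels = labels, reference = labels[ref_idx], columns = columns,
         common_columns = common, transforms = transforms,
         consensus = consensus, traces = traces, params = params),
    class = "multiple_alignment"
  )
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment>", length(x$labels), "structures, common core of",
      length(x$common_columns), "positions (reference:", x$reference, ")\n")
  invisible(x)
}

#' Write a pairwise correspondence table
#'
#' Tab-separated columns: `label_a`, `res_a`, `label_b`, `res_b`,
#' `distance` (Angstrom, after superposing b onto a over the
#' correspondence).
#'
#' @param a,b `core_trace` objects.
#' @param pairs A `correspondence` from [find_correspondence()].
#' @param path Output file.
#' @return The table, invisibly, as a tibble.
#' @export
write_correspondence <- function(a, b, pairs, path) {
  fit <- kabsch(a$xyz[pairs[, 1], , drop = FALSE],
                b$xyz[pairs[, 2], , drop = FALSE])
  Bt <- apply_transform(fit, b$xyz)
  d <- sqrt(rowSums((a$xyz[pairs[, 1], , drop = FALSE] -
                       Bt[pairs[, 2], , drop = FALSE])^2))
  tab <- tibble::tibble(
    label_a = a$label, res_a = a$tags$resno[pairs[, 1]],
    label_b = b$label, res_b = b$tags$resno[pairs[, 2]],
    distance = round(d, 3)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
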