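#' Read an atomic structure and extract its C-alpha trace
#'
#' Parses a PDB or mmCIF coordinate file and returns a `structure_model`:
#' one record per residue that carries a C-alpha atom, ordered within each
#' chain by author residue number and insertion code. Waters and non-polymer
#' heteroatoms are discarded; non-standard amino acids are retained as long
#' as they contribute a carbon atom named CA (metal ions whose atom name is
#' also "CA" are excluded by the element symbol). Alternate locations are
#' resolved to a single conformer: the highest-occupancy altloc wins, ties
#' go to altloc "A".
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. `"auto"` decides from
#'   the file extension (`.cif`/`.mmcif` vs anything else).
#' @return An object of class `structure_model`: a list with `structure_id`
#'   (the file stem) and `residues`, a tibble with columns `chain`, `resno`
#'   (author numbering), `ins` (insertion code, `""` if none), `aa`
#'   (3-letter code) and `x`, `y`, `z` (CA coordinates, Angstrom).
#' @examples
#' pdb <- system.file("extdata", "synthetic_minicore.pdb", package = "foldphylo")
#' m <- load_structure(pdb)
#' nrow(m$residues)
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atoms <- parsed$atom
  all_chains <- unique(atoms$chain[!(atoms$resid %in% c("HOH", "WAT", "DOD"))])
  # CA carbons only; drop waters and calcium ions (element symbol "CA")
  is_ca <- atoms$elety == "CA" & !(atoms$resid %in% c("HOH", "WAT", "DOD"))
  elesy <- toupper(trimws(as.character(atoms$elesy)))
  is_ca <- is_ca & (is.na(elesy) | elesy %in% c("C", ""))
  atoms <- atoms[is_ca, , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("no polymer CA atoms in ", path)
  }
  dropped <- setdiff(all_chains, unique(atoms$chain))
  if (length(dropped) > 0) {
    warning("chain(s) without CA atoms dropped: ",
            paste(dropped, collapse = ", "))
  }
  atoms$ins <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  atoms$alt <- ifelse(is.na(atoms$alt), "", as.character(atoms$alt))
  atoms$o[is.na(atoms$o)] <- 1

  # altloc resolution: keep highest occupancy; tie -> altloc "A" (blank
  # altlocs sort with "A" so single-conformer records always survive)
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  alt_rank <- ifelse(atoms$alt == "", "A", atoms$alt)
  ord <- order(key, -atoms$o, alt_rank)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]

  ord <- order(atoms$chain, atoms$resno, atoms$ins)
  atoms <- atoms[ord, , drop = FALSE]
  res <- tibble::tibble(
    chain = as.character(atoms$chain),
    resno = as.integer(atoms$resno),
    ins = atoms$ins,
    aa = as.character(atoms$resid),
    x = atoms$x, y = atoms$y, z = atoms$z
  )
  if (any(!is.finite(as.matrix(res[, c("x", "y", "z")])))) {
    stop("non-finite CA coordinates in ", path)
  }
  structure(
    list(
      structure_id = sub("\\.(pdb|ent|cif|mmcif)$", "",
                         basename(path), ignore.case = TRUE),
      residues = res
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$structure_id, "-",
      nrow(x$residues), "CA residues in",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Count residues with modeled CA atoms in a chain
#'
#' @param model A `structure_model`.
#' @param chain_id Chain identifier.
#' @return Integer count of residues carrying a CA atom.
#' @export
count_modeled_residues <- function(model, chain_id) {
  stopifnot(inherits(model, "structure_model"))
  chains <- unique(model$residues$chain)
  if (!chain_id %in% chains) {
    stop("unknown chain '", chain_id, "'; available: ",
         paste(chains, collapse = ", "))
  }
  sum(model$residues$chain == chain_id)
}

#' Define a fold core by chain and residue ranges
#'
#' A core definition names, for one structure, the chain and the inclusive
#' author-numbered residue ranges that make up the conserved fold core used
#' for superposition (for viral capsid proteins, typically the eight-stranded
#' jelly-roll beta-sandwich), plus the taxon label used in trees.
#'
#' @param structure_id Structure identifier matching the loaded model.
#' @param chain_id Chain to extract from.
#' @param ranges Either a list of length-2 integer vectors, or a string like
#'   `"64-371"` or `"60-365,378-384"`.
#' @param label Taxon label; defaults to `structure_id`.
#' @return A `core_definition` object.
#' @export
core_definition <- function(structure_id, chain_id, ranges, label = structure_id) {
  if (is.character(ranges)) ranges <- parse_ranges(ranges)
  if (is.numeric(ranges)) ranges <- list(ranges)
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || anyNA(r)) stop("each range must be two integers")
    if (r[1] > r[2]) stop("range start ", r[1], " exceeds end ", r[2])
    r
  })
  starts <- vapply(ranges, `[`, integer(1), 1)
  ends <- vapply(ranges, `[`, integer(1), 2)
  o <- order(starts)
  ranges <- ranges[o]
  if (length(ranges) > 1 &&
      any(starts[o][-1] <= ends[o][-length(ranges)])) {
    stop("residue ranges overlap")
  }
  structure(
    list(structure_id = structure_id, chain_id = chain_id,
         ranges = ranges, label = label),
    class = "core_definition"
  )
}

parse_ranges <- function(text) {
  parts <- strsplit(trimws(text), ",")[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", p))[[1]]
    if (length(m) != 3) stop("cannot parse range '", p, "'")
    as.integer(m[2:3])
  })
}

#' Read a core-definition table
#'
#' Tab-separated file with header `structure_id  chain  ranges  label`,
#' ranges written as `64-371` or `60-365,378-384`.
#'
#' @param path Path to the table.
#' @return A named list of `core_definition` objects (named by label), with
#'   the source tibble as attribute `"table"`.
#' @export
read_core_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("structure_id", "chain", "ranges", "label")
  if (!all(needed %in% names(tab))) {
    stop("core table must have columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicate labels in core table: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  defs <- lapply(seq_len(nrow(tab)), function(i) {
    core_definition(tab$structure_id[i], tab$chain[i], tab$ranges[i], tab$label[i])
  })
  names(defs) <- tab$label
  attr(defs, "table") <- tibble::as_tibble(tab)
  defs
}

#' Construct a CA core trace
#'
#' The unit of structural comparison: an ordered set of CA positions with
#' parallel residue tags.
#'
#' @param label Taxon label.
#' @param xyz n x 3 numeric matrix of CA coordinates (Angstrom).
#' @param tags Optional tibble with columns `chain`, `resno`, `ins`, `aa`
#'   parallel to the rows of `xyz`; synthesised if missing.
#' @return A `core_trace` object.
#' @export
core_trace <- function(label, xyz, tags = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3 || nrow(xyz) < 3) {
    stop("a core trace needs an n x 3 coordinate matrix with n >= 3")
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trace '", label, "'")
  if (is.null(tags)) {
    tags <- tibble::tibble(chain = "A", resno = seq_len(nrow(xyz)),
                           ins = "", aa = "ALA")
  }
  if (nrow(tags) != nrow(xyz)) stop("tags and coordinates differ in length")
  dimnames(xyz) <- NULL
  structure(list(label = label, xyz = xyz, tags = tibble::as_tibble(tags)),
            class = "core_trace")
}

#' @export
print.core_trace <- function(x, ...) {
  cat("<core_trace>", x$label, "-", nrow(x$xyz), "CA positions\n")
  invisible(x)
}

#' Extract the fold-core CA trace selected by a core definition
#'
#' Returns the CA positions of exactly those residues of the named chain
#' whose author residue number falls in the union of the definition's
#' inclusive ranges, in range order. Residues absent from the model (not
#' modeled, or lacking a CA) are simply skipped; if more than 20% of the
#' selected span is missing a warning reports the count.
#'
#' @param model A `structure_model`.
#' @param core A `core_definition`.
#' @return A `core_trace`.
#' @export
extract_core <- function(model, core) {
  stopifnot(inherits(model, "structure_model"), inherits(core, "core_definition"))
  res <- model$residues[model$residues$chain == core$chain_id, , drop = FALSE]
  if (nrow(res) == 0) {
    stop("chain '", core$chain_id, "' not present in ", model$structure_id)
  }
  keep <- lapply(core$ranges, function(r) {
    which(res$resno >= r[1] & res$resno <= r[2])
  })
  idx <- unlist(keep)
  if (length(idx) == 0) stop("core selects no residues")
  span <- sum(vapply(core$ranges, function(r) r[2] - r[1] + 1L, integer(1)))
  missing <- span - length(idx)
  if (missing > 0.2 * span) {
    warning(missing, " of ", span, " selected residues missing from ",
            model$structure_id, " chain ", core$chain_id)
  }
  core_trace(core$label, as.matrix(res[idx, c("x", "y", "z")]),
             res[idx, c("chain", "resno", "ins", "aa")])
}

#' Use the full modeled chain as a core
#'
#' Convenience for full-length comparison mode: every CA residue of the
#' chain becomes the trace.
#'
#' @inheritParams count_modeled_residues
#' @param label Taxon label.
#' @return A `core_trace`.
#' @export
full_chain_trace <- function(model, chain_id, label = model$structure_id) {
  n <- count_modeled_residues(model, chain_id)
  if (n < 3) stop("chain '", chain_id, "' has fewer than 3 CA residues")
  res <- model$residues[model$residues$chain == chain_id, , drop = FALSE]
  core_trace(label, as.matrix(res[, c("x", "y", "z")]),
             res[, c("chain", "resno", "ins", "aa")])
}

#' Write a CA-only PDB file
#'
#' Serialises a `core_trace` (or `structure_model`) as minimal ATOM records,
#' one CA per residue, suitable for visual inspection.
#'
#' @param x A `core_trace` or `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(x, path) {
  if (inherits(x, "structure_model")) {
    tags <- x$residues[, c("chain", "resno", "ins", "aa")]
    xyz <- as.matrix(x$residues[, c("x", "y", "z")])
  } else if (inherits(x, "core_trace")) {
    tags <- x$tags
    xyz <- x$xyz
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  n <- nrow(xyz)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, substr(tags$aa, 1, 3), substr(tags$chain, 1, 1),
    tags$resno %% 10000L, ifelse(tags$ins == "", " ", substr(tags$ins, 1, 1)),
    xyz[, 1], xyz[, 2], xyz[, 3]
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
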