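#' Validate a pipeline configuration
#'
#' A configuration describes one end-to-end run: which coordinate files and
#' chains to compare, how cores are chosen (`mode = "core"` uses the
#' residue ranges of the core table; `mode = "full_length"` uses each
#' structure's entire modeled chain), which named clades to test for
#' monophyly, and where to write artifacts.
#'
#' @param structures Data frame (or list of lists) with columns/fields
#'   `path`, `chain`, `label`.
#' @param core_table Path to a core-definition table (see
#'   [read_core_table()]); required for `mode = "core"`.
#' @param mode `"core"` or `"full_length"`.
#' @param clades Named list of character vectors (clade label sets).
#' @param output_dir Artifact directory.
#' @param align_params An [align_params()] list.
#' @param seed Integer recorded for provenance (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(structures, core_table = NULL,
                            mode = c("core", "full_length"),
                            clades = list(), output_dir = "foldphylo_run",
                            align_params = foldphylo::align_params(),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.list(structures) && !is.data.frame(structures)) {
    structures <- do.call(rbind, lapply(structures, function(s) {
      data.frame(path = s$path, chain = s$chain, label = s$label)
    }))
  }
  structures <- tibble::as_tibble(structures)
  needed <- c("path", "chain", "label")
  if (!all(needed %in% names(structures))) {
    stop("structures needs columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(structures) < 3) stop("need at least 3 structures")
  if (anyDuplicated(structures$label)) {
    stop("duplicate structure labels: ",
         paste(unique(structures$label[duplicated(structures$label)]),
               collapse = ", "))
  }
  if (mode == "core" && is.null(core_table)) {
    stop("mode 'core' requires a core_table")
  }
  for (nm in names(clades)) {
    missing <- setdiff(clades[[nm]], structures$label)
    if (length(missing) > 0) {
      stop("clade '", nm, "' references unknown label(s): ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(structures = structures, core_table = core_table,
                 mode = mode, clades = clades, output_dir = output_dir,
                 align_params = align_params, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys `structures` (list of `path`, `chain`,
#'   `label`), `core_table`, `mode`, `clades`, `output_dir`, `seed`, and an
#'   optional `align` block of [align_params()] keys.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ap <- do.call(align_params,
                if (is.null(y$align)) list() else as.list(y$align))
  pipeline_config(
    structures = y$structures,
    core_table = y$core_table,
    mode = if (is.null(y$mode)) "core" else y$mode,
    clades = if (is.null(y$clades)) list() else lapply(y$clades, unlist),
    output_dir = if (is.null(y$output_dir)) "foldphylo_run" else y$output_dir,
    align_params = ap,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

#' Align traces, build the RMSD matrix, and infer the NJ tree
#'
#' The in-memory heart of [run_pipeline()]: multiple superposition onto the
#' common core, all-vs-all common-core RMSDs, neighbor joining, and the
#' clade report. Useful directly when the traces already exist (e.g. from
#' [evolve_along_tree()]).
#'
#' @param traces List of >= 3 `core_trace`.
#' @param clades Named list of label sets to test for monophyly.
#' @param params [align_params()].
#' @return List with `alignment`, `matrix` (a `distance_matrix`), `tree`
#'   (`ape::phylo`) and `clades` (tibble report).
#' @export
analyze_traces <- function(traces, clades = list(), params = align_params()) {
  alignment <- multiple_superpose(traces, params)
  d <- build_distance_matrix(alignment)
  tree <- neighbor_joining(d)
  report <- clade_report(tree, clades)
  list(alignment = alignment, matrix = d, tree = tree, clades = report)
}

#' Monophyly report for named clades
#'
#' @param tree `ape::phylo`.
#' @param clades Named list of character vectors of leaf labels.
#' @return Tibble with columns `clade`, `n_taxa`, `monophyletic`.
#' @export
clade_report <- function(tree, clades) {
  if (length(clades) == 0) {
    return(tibble::tibble(clade = character(), n_taxa = integer(),
                          monophyletic = logical()))
  }
  tibble::tibble(
    clade = names(clades),
    n_taxa = unname(vapply(clades, length, integer(1))),
    monophyletic = unname(vapply(clades, function(tx) {
      as.logical(is_monophyletic(tree, tx))
    }, logical(1)))
  )
}

#' Run the full structure-phylogeny pipeline
#'
#' Loads every structure, extracts cores (per the core table, or the full
#' modeled chain in full-length mode), superposes them onto the common
#' core, builds the all-vs-all RMSD matrix, infers the neighbor-joining
#' tree, tests the configured clades, and writes all artifacts into
#' `output_dir`: `matrix.phy`, `matrix.csv`, `tree.nwk`, `clades.txt`,
#' `config.yaml` and `run.log`. Reruns with identical config and inputs
#' produce byte-identical matrix and tree files.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the [analyze_traces()] result list plus `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character()
  stamp <- function(stage) {
    log_lines <<- c(log_lines, sprintf(
      "%-12s %.2fs", stage, as.numeric(Sys.time() - t0, units = "secs")))
  }

  defs <- NULL
  if (config$mode == "core") {
    defs <- tryCatch(read_core_table(config$core_table),
                     error = function(e) stop("stage core_table: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  }
  stamp("config")

  traces <- lapply(seq_len(nrow(config$structures)), function(i) {
    row <- config$structures[i, ]
    model <- tryCatch(load_structure(row$path),
                      error = function(e) stop("stage load [", row$label,
                                               "]: ", conditionMessage(e),
                                               call. = FALSE))
    tryCatch({
      if (config$mode == "full_length") {
        full_chain_trace(model, row$chain, label = row$label)
      } else {
        def <- defs[[row$label]]
        if (is.null(def)) {
          stop("no core definition for label '", row$label, "'")
        }
        def$chain_id <- row$chain
        extract_core(model, def)
      }
    }, error = function(e) stop("stage extract [", row$label, "]: ",
                                conditionMessage(e), call. = FALSE))
  })
  stamp("extract")

  alignment <- tryCatch(multiple_superpose(traces, config$align_params),
                        error = function(e) stop("stage superpose: ",
                                                 conditionMessage(e),
                                                 call. = FALSE))
  stamp("superpose")
  d <- build_distance_matrix(alignment)
  stamp("distmat")
  tree <- neighbor_joining(d)
  stamp("tree")
  report <- clade_report(tree, config$clades)
  stamp("clades")

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix_phylip = file.path(config$output_dir, "matrix.phy"),
    matrix_csv = file.path(config$output_dir, "matrix.csv"),
    tree = file.path(config$output_dir, "tree.nwk"),
    clades = file.path(config$output_dir, "clades.txt"),
    config = file.path(config$output_dir, "config.yaml"),
    log = file.path(config$output_dir, "run.log")
  )
  write_phylip(d, paths$matrix_phylip)
  write_distance_csv(d, paths$matrix_csv)
  write_newick(tree, paths$tree)
  clade_lines <- if (nrow(report) == 0) {
    "no clades configured"
  } else {
    sprintf("%-30s n=%-3d monophyletic=%s", report$clade, report$n_taxa,
            report$monophyletic)
  }
  writeLines(clade_lines, paths$clades)
  yaml::write_yaml(list(
    structures = lapply(seq_len(nrow(config$structures)), function(i) {
      as.list(config$structures[i, ])
    }),
    core_table = config$core_table, mode = config$mode,
    clades = config$clades, output_dir = config$output_dir,
    seed = config$seed,
    align = unclass(config$align_params)
  ), paths$config)
  stamp("write")
  writeLines(c(
    paste("foldphylo", as.character(utils::packageVersion("foldphylo"))),
    paste("mode", config$mode),
    paste("structures", nrow(config$structures)),
    paste("common core", length(alignment$common_columns), "positions"),
    log_lines
  ), paths$log)

  invisible(list(alignment = alignment, matrix = d, tree = tree,
                 clades = report, paths = paths))
}

#' Download coordinate files from the PDB (explicit opt-in)
#'
#' Fetches `<id>.pdb` files from RCSB into a directory. Never called by any
#' other function in the package: network access is always explicit.
#'
#' @param ids Character vector of 4-character PDB ids.
#' @param dir Destination directory.
#' @return Tibble with columns `id` and `path`.
#' @export
fetch_pdb <- function(ids, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(ids, function(id) {
    dest <- file.path(dir, paste0(tolower(id), ".pdb"))
    if (!file.exists(dest)) {
      utils::download.file(
        paste0("https://files.rcsb.org/download/", toupper(id), ".pdb"),
        dest, quiet = TRUE
      )
    }
    dest
  }, character(1))
  tibble::tibble(id = ids, path = unname(paths))
}
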