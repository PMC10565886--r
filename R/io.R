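#' Write a scenario to disk as plain-text tables
#'
#' Writes the CSV schemas the pipeline reads (species traits, gravid
#' studies, hatching records, tip states), the trees as one-per-line Newick,
#' and the ground truth as JSON alongside.
#'
#' @param scenario a `"gravitherm_scenario"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scenario$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(scenario$gravid_studies,
                   file.path(dir, "gravid_studies.csv"), row.names = FALSE)
  utils::write.csv(scenario$hatching, file.path(dir, "hatching.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(species = names(scenario$tip_states),
                              state = unname(scenario$tip_states)),
                   file.path(dir, "tip_states.csv"), row.names = FALSE)
  write_newick(scenario$tree, file.path(dir, "tree.nwk"))
  writeLines(vapply(scenario$trees, ape::write.tree, character(1L)),
             file.path(dir, "trees.nwk"))
  truth <- scenario$truth
  truth$node_values <- as.data.frame(truth$node_values)
  jsonlite::write_json(c(truth, list(config = scenario$config)),
                       file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}

#' Read a scenario written by [write_scenario()]
#'
#' @param dir directory holding the CSV/Newick files.
#' @return a list with the elements [run_full_analysis()] needs (`tree`,
#'   `trees`, `traits`, `gravid_studies`, `hatching`, `tip_states`).
#' @export
read_scenario <- function(dir) {
  need <- c("traits.csv", "gravid_studies.csv", "hatching.csv",
            "tip_states.csv", "tree.nwk", "trees.nwk")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("scenario directory is missing: ", paste(missing, collapse = ", "))
  ts <- utils::read.csv(file.path(dir, "tip_states.csv"))
  tip_states <- stats::setNames(as.integer(ts$state), ts$species)
  structure(list(
    tree = read_newick(readLines(file.path(dir, "tree.nwk"))[1L]),
    trees = read_newick_trees(file.path(dir, "trees.nwk")),
    traits = utils::read.csv(file.path(dir, "traits.csv"),
                             stringsAsFactors = FALSE),
    gravid_studies = utils::read.csv(file.path(dir, "gravid_studies.csv"),
                                     stringsAsFactors = FALSE),
    hatching = utils::read.csv(file.path(dir, "hatching.csv"),
                               stringsAsFactors = FALSE),
    tip_states = tip_states), class = "gravitherm_scenario")
}

#' Write imputed datasets as suffixed CSV files plus a manifest
#'
#' @param imp a `"pmm_imputation"`.
#' @param dir output directory.
#' @param stem file stem; copies become `<stem>_1.csv`, ...
#' @return `dir`, invisibly.
#' @export
write_imputations <- function(imp, dir, stem = "imputed") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(imp$imputations))
    utils::write.csv(imp$imputations[[j]],
                     file.path(dir, sprintf("%s_%d.csv", stem, j)),
                     row.names = FALSE)
  jsonlite::write_json(list(m = imp$m, k = imp$k, seed = imp$seed,
                            cells = imp$cells),
                       file.path(dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Recognised fields are the arguments of [analysis_config()]; unknown fields
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `"gravitherm_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  ints <- c("seed", "nitt", "burnin", "thin", "m_imputations", "events",
            "iters_per_event", "n_trees", "hmm_rmax", "hmm_restarts",
            "n_chains")
  vals[names(vals) %in% ints] <-
    lapply(vals[names(vals) %in% ints], as.integer)
  do.call(analysis_config, vals)
}
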