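#' Write allocation reports as a CSV sheet-set
#'
#' Emits the run's deliverable as diff-able delimited text: per-unit
#' assignments, a per-node summary (loads joined with catchment
#' statistics), the scenario table, the move log, and a machine-readable
#' JSON metadata record (configuration echo, package version, timestamp)
#' sufficient to reproduce the run. All data files are deterministic for
#' identical inputs; the timestamp lives only in the metadata record.
#'
#' @param result An `hs_allocation` (the final configuration to report).
#' @param territory The matching `hs_territory`.
#' @param dir Output directory (created if needed).
#' @param scenarios Optional scenario table from [run_scenarios()].
#' @param extra Optional named list merged into the metadata record.
#' @return Invisibly, the vector of written file paths.
#' @export
write_allocation_report <- function(result, territory, dir,
                                    scenarios = NULL, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  p <- file.path(dir, "assignments.csv")
  readr::write_csv(result$records, p, progress = FALSE, na = "")
  paths <- c(paths, p)

  summary <- per_node_summary(result, territory)
  loads <- result$loads
  node_sheet <- dplyr::left_join(loads, summary[, c("node", "mean_minutes",
                                                    "mean_km", "area",
                                                    "density")],
                                 by = "node")
  p <- file.path(dir, "node_summary.csv")
  readr::write_csv(node_sheet, p, progress = FALSE, na = "")
  paths <- c(paths, p)

  if (!is.null(scenarios)) {
    p <- file.path(dir, "scenarios.csv")
    readr::write_csv(scenarios, p, progress = FALSE, na = "")
    paths <- c(paths, p)
  }

  p <- file.path(dir, "move_log.csv")
  readr::write_csv(result$moves, p, progress = FALSE, na = "")
  paths <- c(paths, p)

  meta <- c(list(
    package = "hubspoke",
    version = as.character(utils::packageVersion("hubspoke")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(result$config),
    n_units = nrow(territory$units),
    n_nodes = nrow(territory$nodes),
    total_population = sum(territory$units$population),
    violations = nrow(result$violations),
    moves = nrow(result$moves)
  ), extra)
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)

  invisible(paths)
}
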