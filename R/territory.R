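#' Normalize a municipal code
#'
#' Purely numeric codes are zero-padded to six digits, the ISTAT municipal
#' code convention, so that codes survive round trips through software that
#' strips leading zeros. Non-numeric codes are returned trimmed but otherwise
#' unchanged. The operation is idempotent.
#'
#' @param x Character (or coercible) vector of codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_code(c("66049", "066049", "ZZ9"))
#' @export
normalize_code <- function(x) {
  x <- trimws(as.character(x))
  numeric_like <- grepl("^[0-9]+$", x) & nchar(x) <= 6L
  x[numeric_like] <- sprintf("%06d", as.integer(x[numeric_like]))
  x
}

# Sniff the field delimiter from the first line of a delimited file.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return(",")
  n_semi <- lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))
  n_comma <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_semi >= n_comma && n_semi > 0L) ";" else ","
}

# Sniff the decimal mark: with a semicolon delimiter ISTAT distributions
# typically use a decimal comma; confirm by looking for "d,d" tokens in a
# sample of data lines.
sniff_decimal <- function(path, delim) {
  if (delim != ";") return(".")
  lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("[0-9],[0-9]", lines))) "," else "."
}

resolve_dialect <- function(path, delim = "auto", decimal = "auto") {
  if (identical(delim, "auto")) delim <- sniff_delim(path)
  if (identical(decimal, "auto")) decimal <- sniff_decimal(path, delim)
  if (delim == decimal) {
    stop("hubspoke: delimiter and decimal mark cannot both be '", delim, "'",
         call. = FALSE)
  }
  list(delim = delim, decimal = decimal)
}

read_delim_dialect <- function(path, delim, decimal) {
  readr::read_delim(
    path,
    delim = delim,
    locale = readr::locale(decimal_mark = decimal,
                           grouping_mark = if (decimal == ".") "," else "."),
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE,
    progress = FALSE,
    show_col_types = FALSE
  )
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("hubspoke: ", what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# Parse numerics under the file's decimal convention; returns NA for
# unparseable entries (callers count and reject those rows).
parse_num <- function(x, decimal) {
  if (decimal == ",") x <- gsub(",", ".", gsub("\\.", "", x))
  suppressWarnings(as.numeric(x))
}

#' Parse an origin-destination travel matrix
#'
#' Reads a delimited text file in the ISTAT national OD dialect: one row per
#' directed pair with origin code, destination code, travel time in minutes
#' and (optionally) road distance in km. Travel times may be
#' direction-dependent; asymmetric entries are stored as given. Codes are
#' normalized with [normalize_code()]. Rows whose minutes (or km) fail to
#' parse as numbers are dropped with a message reporting the count.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter: `","`, `";"` or `"auto"` (sniffed).
#' @param decimal Decimal mark: `"."`, `","` or `"auto"` (sniffed).
#' @param col_origin,col_dest,col_minutes,col_km Column names in the file.
#'   `col_km` may be absent from the file, in which case km is NA.
#' @return A tibble of class `hs_od` with columns `origin`, `dest`,
#'   `minutes`, `km`.
#' @export
parse_od_matrix <- function(path,
                            delim = "auto", decimal = "auto",
                            col_origin = "origin_code",
                            col_dest = "dest_code",
                            col_minutes = "minutes",
                            col_km = "km") {
  if (!file.exists(path)) {
    stop("hubspoke: OD matrix file not found: ", path, call. = FALSE)
  }
  dia <- resolve_dialect(path, delim, decimal)
  raw <- read_delim_dialect(path, dia$delim, dia$decimal)
  require_columns(raw, c(col_origin, col_dest, col_minutes), "OD matrix")

  od <- tibble::tibble(
    origin = normalize_code(raw[[col_origin]]),
    dest = normalize_code(raw[[col_dest]]),
    minutes = parse_num(raw[[col_minutes]], dia$decimal),
    km = if (col_km %in% names(raw)) {
      parse_num(raw[[col_km]], dia$decimal)
    } else {
      NA_real_
    }
  )

  bad <- is.na(od$minutes) | (col_km %in% names(raw) & is.na(od$km))
  if (any(bad)) {
    message("hubspoke: rejected ", sum(bad),
            " OD row(s) with unparseable numeric values")
    od <- od[!bad, , drop = FALSE]
  }
  if (any(od$minutes < 0, na.rm = TRUE) || any(od$km < 0, na.rm = TRUE)) {
    stop("hubspoke: OD matrix contains negative travel times or distances",
         call. = FALSE)
  }

  key <- paste(od$origin, od$dest, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    conflicting <- vapply(dup, function(k) {
      rows <- od[key == k, ]
      length(unique(rows$minutes)) > 1L ||
        length(unique(rows$km[!is.na(rows$km)])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      pair <- sub("\r", " -> ", dup[conflicting][1])
      stop("hubspoke: duplicate directed pair(s) with conflicting values, ",
           "e.g. ", pair, call. = FALSE)
    }
    od <- od[!duplicated(key), , drop = FALSE]
  }
  class(od) <- c("hs_od", class(od))
  od
}

#' Parse a municipal demographics table
#'
#' One demand unit per row: code, name, resident population and land area
#' in km2. Codes are normalized; duplicates are an error, as is a negative
#' population or a non-positive area.
#'
#' @inheritParams parse_od_matrix
#' @param col_code,col_name,col_population,col_area Column names in the file.
#' @return A tibble with columns `code`, `name`, `population`, `area`.
#' @export
parse_demographics <- function(path,
                               delim = "auto", decimal = "auto",
                               col_code = "code",
                               col_name = "name",
                               col_population = "population",
                               col_area = "area_km2") {
  if (!file.exists(path)) {
    stop("hubspoke: demographics file not found: ", path, call. = FALSE)
  }
  dia <- resolve_dialect(path, delim, decimal)
  raw <- read_delim_dialect(path, dia$delim, dia$decimal)
  require_columns(raw, c(col_code, col_name, col_population, col_area),
                  "demographics table")

  units <- tibble::tibble(
    code = normalize_code(raw[[col_code]]),
    name = trimws(raw[[col_name]]),
    population = parse_num(raw[[col_population]], dia$decimal),
    area = parse_num(raw[[col_area]], dia$decimal)
  )
  if (anyDuplicated(units$code)) {
    stop("hubspoke: duplicate demand-unit code(s): ",
         paste(unique(units$code[duplicated(units$code)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(units$population)) || any(units$population < 0)) {
    stop("hubspoke: population must be a non-negative number for every unit",
         call. = FALSE)
  }
  if (any(is.na(units$area)) || any(units$area <= 0)) {
    stop("hubspoke: land area must be a positive number for every unit",
         call. = FALSE)
  }
  units$population <- as.integer(round(units$population))
  units
}

#' Parse a hub/spoke node roster
#'
#' Columns: `code` (must match a demand-unit code), `role` (`hub` or
#' `spoke`) and an optional per-node `cap` override. When `cap` is absent
#' or empty the role default applies at allocation time (50,000 residents
#' for hubs, 40,000 for spokes).
#'
#' @inheritParams parse_od_matrix
#' @return A tibble with columns `code`, `role`, `cap` (NA = role default).
#' @export
parse_nodes <- function(path, delim = "auto", decimal = "auto") {
  if (!file.exists(path)) {
    stop("hubspoke: node roster file not found: ", path, call. = FALSE)
  }
  dia <- resolve_dialect(path, delim, decimal)
  raw <- read_delim_dialect(path, dia$delim, dia$decimal)
  require_columns(raw, c("code", "role"), "node roster")

  nodes <- tibble::tibble(
    code = normalize_code(raw$code),
    role = tolower(trimws(raw$role)),
    cap = if ("cap" %in% names(raw)) {
      parse_num(raw$cap, dia$decimal)
    } else {
      NA_real_
    }
  )
  if (anyDuplicated(nodes$code)) {
    stop("hubspoke: duplicate node code(s) in roster", call. = FALSE)
  }
  if (!all(nodes$role %in% c("hub", "spoke"))) {
    stop("hubspoke: node role must be 'hub' or 'spoke'", call. = FALSE)
  }
  if (any(!is.na(nodes$cap) & nodes$cap <= 0)) {
    stop("hubspoke: node cap override must be positive", call. = FALSE)
  }
  nodes
}

#' Assemble and validate a territory
#'
#' Merges demand units, the node roster and the OD matrix into a single
#' validated territory. Validation resolves node codes against unit codes,
#' requires a travel-time entry for every (unit, node) pair in the
#' unit-to-node direction (the direction used throughout: patients travel
#' to facilities), and defaults missing self-pairs to 0 minutes / 0 km.
#' Any other missing pair is an error, never an imputation.
#'
#' @param units Tibble from [parse_demographics()].
#' @param nodes Tibble from [parse_nodes()].
#' @param od Tibble from [parse_od_matrix()].
#' @return An object of class `hs_territory`: a list with `units`, `nodes`,
#'   `od`, and dense lookup matrices `minutes` and `km` (rows = unit codes,
#'   columns = node codes).
#' @export
build_territory <- function(units, nodes, od) {
  stopifnot(is.data.frame(units), is.data.frame(nodes), is.data.frame(od))
  if (nrow(nodes) == 0L || !any(nodes$role == "hub")) {
    stop("hubspoke: a territory requires at least one hub node", call. = FALSE)
  }
  unknown <- setdiff(nodes$code, units$code)
  if (length(unknown) > 0L) {
    stop("hubspoke: node code(s) not found among demand units: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  units <- units[order(units$code), , drop = FALSE]
  nodes <- nodes[order(nodes$code), , drop = FALSE]

  minutes <- matrix(NA_real_, nrow = nrow(units), ncol = nrow(nodes),
                    dimnames = list(units$code, nodes$code))
  km <- minutes
  sel <- od$dest %in% nodes$code & od$origin %in% units$code
  idx <- cbind(match(od$origin[sel], units$code),
               match(od$dest[sel], nodes$code))
  minutes[idx] <- od$minutes[sel]
  km[idx] <- od$km[sel]

  # self-pairs default to zero travel
  self <- intersect(units$code, nodes$code)
  for (s in self) {
    if (is.na(minutes[s, s])) {
      minutes[s, s] <- 0
      km[s, s] <- 0
    }
  }
  if (anyNA(minutes)) {
    miss <- which(is.na(minutes), arr.ind = TRUE)
    labels <- paste0(rownames(minutes)[miss[, 1]], " -> ",
                     colnames(minutes)[miss[, 2]])
    stop("hubspoke: OD matrix has no travel time for ", length(labels),
         " (unit, node) pair(s): ",
         paste(utils::head(labels, 5L), collapse = "; "),
         if (length(labels) > 5L) " ..." else "", call. = FALSE)
  }

  structure(
    list(units = tibble::as_tibble(units),
         nodes = tibble::as_tibble(nodes),
         od = tibble::as_tibble(od),
         minutes = minutes,
         km = km),
    class = "hs_territory"
  )
}

#' Read a territory from its three input files
#'
#' Convenience wrapper: parse the OD matrix, demographics and node roster
#' and assemble them with [build_territory()].
#'
#' @param od_path,demo_path,nodes_path Paths to the three delimited files.
#' @param ... Dialect options forwarded to the parsers.
#' @return An `hs_territory`.
#' @export
read_territory <- function(od_path, demo_path, nodes_path, ...) {
  build_territory(
    units = parse_demographics(demo_path, ...),
    nodes = parse_nodes(nodes_path, ...),
    od = parse_od_matrix(od_path, ...)
  )
}

#' Write a territory to delimited text files
#'
#' Emits the same three-file format the parsers read (`demographics.csv`,
#' `nodes.csv`, `od_matrix.csv`), so generated territories round-trip.
#'
#' @param territory An `hs_territory`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_territory <- function(territory, dir) {
  stopifnot(inherits(territory, "hs_territory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    demographics = file.path(dir, "demographics.csv"),
    nodes = file.path(dir, "nodes.csv"),
    od = file.path(dir, "od_matrix.csv")
  )
  demo <- territory$units
  names(demo) <- c("code", "name", "population", "area_km2")
  readr::write_csv(demo, paths[["demographics"]], progress = FALSE)
  readr::write_csv(territory$nodes, paths[["nodes"]], progress = FALSE)
  od <- territory$od
  names(od)[1:2] <- c("origin_code", "dest_code")
  readr::write_csv(od, paths[["od"]], progress = FALSE)
  invisible(paths)
}

#' @export
print.hs_territory <- function(x, ...) {
  cat("<hs_territory> ", nrow(x$units), " demand units, ",
      sum(x$nodes$role == "hub"), " hub(s) + ",
      sum(x$nodes$role == "spoke"), " spoke(s), total population ",
      format(sum(x$units$population), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# minutes from every unit to every node (dense lookup; total by construction)
unit_node_minutes <- function(territory) territory$minutes

# population named by unit code
unit_populations <- function(territory) {
  stats::setNames(territory$units$population, territory$units$code)
}
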