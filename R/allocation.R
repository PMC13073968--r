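#' Feasible nodes for one demand unit
#'
#' Nodes whose travel time from the unit is within the cut-off, sorted by
#' ascending travel time with ties broken by node code. An empty result
#' means the unit is infeasible at this cut-off (not an error).
#'
#' @param unit A unit code present in the territory.
#' @param territory An `hs_territory`.
#' @param cutoff Travel-time threshold in minutes.
#' @return Character vector of node codes (possibly empty).
#' @export
feasible_nodes <- function(unit, territory, cutoff) {
  m <- territory$minutes
  t_row <- stats::setNames(m[unit, ], colnames(m))
  keep <- which(t_row <= cutoff)
  nd <- names(t_row)[keep]
  nd[order(t_row[keep], nd)]
}

#' Near-optimal candidate set
#'
#' The subset of a unit's feasible nodes whose travel time is within
#' `(1 + margin)` of the unit's minimum feasible travel time. Order is
#' inherited from the feasible list (ascending time, ties by code), so the
#' first element is the preferred node.
#'
#' @param unit Unit code.
#' @param feasible Non-empty character vector from [feasible_nodes()].
#' @param territory An `hs_territory`.
#' @param margin Fractional band width (default 0.05).
#' @return Character vector of node codes; never empty.
#' @export
candidate_set <- function(unit, feasible, territory, margin = 0.05) {
  if (length(feasible) == 0L) {
    stop("hubspoke: candidate_set requires a non-empty feasible set; ",
         "handle exclusion first", call. = FALSE)
  }
  t_f <- territory$minutes[unit, feasible]
  feasible[t_f <= (1 + margin) * min(t_f)]
}

#' Allocation priority order
#'
#' Orders feasible units for processing: (i) fewer candidate nodes first,
#' (ii) smaller minimum travel time first, (iii) larger population first,
#' and finally unit code ascending as a fixed deterministic tie-break.
#'
#' @param units Character vector of unit codes to order.
#' @param candidate_sets Named list (by unit code) of candidate-set
#'   vectors, as produced by [candidate_set()]; counts used for criterion
#'   (i) under the default `priority_count = "candidates"`.
#' @param territory An `hs_territory`.
#' @return `units` reordered.
#' @export
priority_order <- function(units, candidate_sets, territory) {
  n_cand <- lengths(candidate_sets[units])
  min_t <- vapply(units, function(u) {
    cs <- candidate_sets[[u]]
    if (length(cs) == 0L) Inf else territory$minutes[u, cs[1]]
  }, numeric(1))
  pop <- unit_populations(territory)[units]
  units[order(n_cand, min_t, -pop, units)]
}

empty_moves <- function() {
  tibble::tibble(unit = character(), from = character(), to = character(),
                 delta_minutes = numeric())
}

# Build the loads table (one row per node) from an assignment record set.
build_loads <- function(records, territory, config) {
  caps <- effective_caps(territory, config)
  pops <- unit_populations(territory)
  alloc <- records[records$status == "allocated", , drop = FALSE]
  served <- stats::setNames(numeric(length(caps)), names(caps))
  if (nrow(alloc) > 0L) {
    agg <- rowsum(pops[alloc$code], group = alloc$node)
    served[rownames(agg)] <- agg[, 1]
  }
  ncodes <- territory$nodes$code
  served_n <- as.integer(served[ncodes])
  cap_n <- as.integer(caps[ncodes])
  tibble::tibble(
    node = ncodes,
    role = territory$nodes$role,
    cap = cap_n,
    served = served_n,
    excess = pmax(0L, served_n - cap_n)
  )
}

violations_from_loads <- function(loads) {
  v <- loads[loads$excess > 0, c("node", "served", "cap", "excess")]
  v[order(-v$excess, v$node), , drop = FALSE]
}

new_allocation <- function(config, records, territory,
                           moves = empty_moves(), priority = character()) {
  loads <- build_loads(records, territory, config)
  structure(
    list(config = config,
         records = records,
         loads = loads,
         violations = violations_from_loads(loads),
         moves = moves,
         priority = priority),
    class = "hs_allocation"
  )
}

#' Proximity-first baseline allocation
#'
#' Assigns every feasible unit to the preferred (minimum travel time)
#' member of its near-optimal candidate set. Capacity overloads are
#' recorded in the result's violations, never prevented: the baseline
#' reveals where overloads would occur. Units with no node within the
#' cut-off are excluded under strict exclusion, or force-assigned to the
#' globally nearest node (and flagged) otherwise. Host units are pinned to
#' their own node when `pin_hosts` is set.
#'
#' @param territory An `hs_territory`.
#' @param config An `hs_config`.
#' @return An `hs_allocation`: per-unit records, per-node loads,
#'   violations, and an (empty) move log.
#' @export
assign_proximity_first <- function(territory, config) {
  stopifnot(inherits(territory, "hs_territory"), inherits(config, "hs_config"))
  ucodes <- territory$units$code
  ncodes <- territory$nodes$code
  mins <- territory$minutes
  n <- length(ucodes)

  status <- rep("allocated", n)
  node <- rep(NA_character_, n)
  pinned <- rep(FALSE, n)
  forced <- rep(FALSE, n)
  cand_sets <- stats::setNames(vector("list", n), ucodes)
  feas_sets <- stats::setNames(vector("list", n), ucodes)

  for (i in seq_len(n)) {
    u <- ucodes[i]
    feas <- feasible_nodes(u, territory, config$cutoff)
    feas_sets[[u]] <- feas
    if (u %in% ncodes && config$pin_hosts) {
      node[i] <- u
      pinned[i] <- TRUE
      cand_sets[[u]] <- u
      next
    }
    if (length(feas) == 0L) {
      cand_sets[[u]] <- character(0)
      if (config$strict_exclusion) {
        status[i] <- "excluded"
      } else {
        ord <- order(mins[u, ], ncodes)
        node[i] <- ncodes[ord[1]]
        forced[i] <- TRUE
      }
      next
    }
    cs <- candidate_set(u, feas, territory, config$margin)
    cand_sets[[u]] <- cs
    node[i] <- cs[1]
  }

  idx <- cbind(seq_len(n), match(node, ncodes))
  minutes <- ifelse(is.na(node), NA_real_, territory$minutes[idx])
  km <- ifelse(is.na(node), NA_real_, territory$km[idx])

  records <- tibble::tibble(
    code = ucodes,
    name = territory$units$name,
    status = status,
    node = node,
    minutes = minutes,
    km = km,
    pinned = pinned,
    forced = forced,
    moved = FALSE,
    over_cutoff = !is.na(minutes) & minutes > config$cutoff
  )

  feas_units <- ucodes[status == "allocated"]
  counting <- if (config$priority_count == "candidates") cand_sets else feas_sets
  prio <- priority_order(feas_units, counting, territory)

  new_allocation(config, records, territory, priority = prio)
}

#' Iterative cap-compliant reallocation
#'
#' Resolves capacity overloads left by the baseline allocation through
#' single-unit moves. While any node exceeds its cap and an improving move
#' exists, the most overloaded node (ties by code) donates the unit whose
#' move to a node with sufficient spare capacity adds the least travel
#' time; ties go to the smaller population, then the unit code. Every
#' accepted move strictly reduces total excess, which bounds the number of
#' moves and guarantees termination. The cut-off is not re-imposed on
#' moved units: a move may push a unit beyond the cut-off, in which case
#' the record is flagged `over_cutoff`. When no single move can reduce the
#' total excess the procedure stops and the residual violations are
#' reported (an outcome, not an error).
#'
#' @param result An `hs_allocation` from [assign_proximity_first()].
#' @param territory The same `hs_territory`.
#' @param config Scenario configuration; defaults to the result's own.
#' @return An `hs_allocation` with updated records, loads, violations and
#'   an ordered move log (`unit`, `from`, `to`, `delta_minutes`).
#' @export
resolve_overloads <- function(result, territory, config = result$config) {
  stopifnot(inherits(result, "hs_allocation"))
  rec <- result$records
  ncodes <- territory$nodes$code
  caps <- effective_caps(territory, config)
  pops <- unit_populations(territory)
  mins <- territory$minutes
  kms <- territory$km
  moves <- list()

  repeat {
    alloc <- rec$status == "allocated"
    served <- stats::setNames(numeric(length(ncodes)), ncodes)
    if (any(alloc)) {
      agg <- rowsum(pops[rec$code[alloc]], group = rec$node[alloc])
      served[rownames(agg)] <- agg[, 1]
    }
    excess <- pmax(0, served - caps)
    if (sum(excess) == 0) break

    over <- ncodes[excess > 0]
    over <- over[order(-excess[over], over)]
    best <- NULL

    for (nd in over) {
      donors <- which(alloc & rec$node == nd & !rec$pinned &
                        pops[rec$code] > 0)
      if (length(donors) == 0L) next
      for (i in donors) {
        u <- rec$code[i]
        alts <- ncodes[ncodes != nd & (caps - served) >= pops[u]]
        if (length(alts) == 0L) next
        delta <- mins[u, alts] - mins[u, nd]
        cand <- data.frame(row = i, unit = u, alt = alts,
                           delta = delta, pop = pops[u],
                           t_alt = mins[u, alts],
                           stringsAsFactors = FALSE)
        best <- rbind(best, cand)
      }
      if (!is.null(best)) break  # largest-excess node with any move donates
    }

    if (is.null(best)) break  # irreducible overload: report residual
    pick <- best[order(best$delta, best$pop, best$unit,
                       best$t_alt, best$alt), ][1, ]
    i <- pick$row
    from <- rec$node[i]
    rec$node[i] <- pick$alt
    rec$minutes[i] <- mins[pick$unit, pick$alt]
    rec$km[i] <- kms[pick$unit, pick$alt]
    rec$moved[i] <- TRUE
    rec$over_cutoff[i] <- rec$minutes[i] > config$cutoff
    moves[[length(moves) + 1L]] <- tibble::tibble(
      unit = pick$unit, from = from, to = pick$alt,
      delta_minutes = pick$delta
    )
  }

  move_log <- if (length(moves) > 0L) {
    dplyr::bind_rows(result$moves, moves)
  } else {
    result$moves
  }
  new_allocation(config, rec, territory,
                 moves = move_log, priority = result$priority)
}

#' Run one scenario: baseline and cap-compliant allocations
#'
#' Produces the two policy outputs of a scenario: (a) the proximity-first
#' baseline, which shows where capacity overloads would occur, and (b) the
#' cap-compliant allocation obtained by iterative reallocation. Both share
#' the same exclusion set: feasibility at the cut-off is decided before
#' capacity.
#'
#' @param territory An `hs_territory`.
#' @param config An `hs_config` (its `mode` field is overridden per output).
#' @return A list with elements `baseline` and `cap_compliant`, both
#'   `hs_allocation` objects.
#' @export
allocate_scenario <- function(territory, config) {
  base_cfg <- config
  base_cfg$mode <- "baseline"
  baseline <- assign_proximity_first(territory, base_cfg)
  cap_cfg <- config
  cap_cfg$mode <- "cap_compliant"
  cap <- resolve_overloads(baseline, territory, cap_cfg)
  list(baseline = baseline, cap_compliant = cap)
}

#' Exact small-instance allocation by exhaustive enumeration
#'
#' A validation oracle: enumerates every assignment of feasible units to
#' their feasible nodes, keeping only cap-respecting assignments, and
#' returns one minimizing total travel minutes (ties resolved to the
#' lexicographically smallest assignment vector over units in code order).
#' Pinned host units are fixed to their own node and consume capacity
#' before enumeration. Intended for tiny instances only; refuses instances
#' above the size limit.
#'
#' @param territory An `hs_territory`.
#' @param config An `hs_config`.
#' @param max_units,max_nodes Enumeration size limits (default 12 free
#'   units, 4 nodes).
#' @return An `hs_allocation` with an extra `feasible` field; when no
#'   cap-respecting assignment exists, `feasible` is `FALSE` and the
#'   records mark every free unit `excluded`.
#' @export
exact_small_allocation <- function(territory, config,
                                   max_units = 12L, max_nodes = 4L) {
  ucodes <- territory$units$code
  ncodes <- territory$nodes$code
  if (length(ncodes) > max_nodes) {
    stop("hubspoke: instance exceeds exact-enumeration node limit (",
         length(ncodes), " > ", max_nodes, ")", call. = FALSE)
  }
  caps <- effective_caps(territory, config)
  pops <- unit_populations(territory)
  mins <- territory$minutes

  fixed_node <- stats::setNames(rep(NA_character_, length(ucodes)), ucodes)
  free <- character(0)
  excluded <- character(0)
  for (u in ucodes) {
    if (u %in% ncodes && config$pin_hosts) {
      fixed_node[u] <- u
    } else {
      feas <- feasible_nodes(u, territory, config$cutoff)
      if (length(feas) == 0L) excluded <- c(excluded, u) else free <- c(free, u)
    }
  }
  if (length(free) > max_units) {
    stop("hubspoke: instance exceeds exact-enumeration unit limit (",
         length(free), " > ", max_units, ")", call. = FALSE)
  }

  base_load <- stats::setNames(numeric(length(ncodes)), ncodes)
  hosts <- names(fixed_node)[!is.na(fixed_node)]
  for (h in hosts) base_load[fixed_node[h]] <- base_load[fixed_node[h]] + pops[h]
  if (any(base_load > caps)) {
    # pinned hosts alone overload a node: no cap-respecting assignment
    return(exact_result(territory, config, fixed_node, free, excluded,
                        assignment = NULL))
  }

  feas_list <- lapply(free, function(u) {
    f <- feasible_nodes(u, territory, config$cutoff)
    f[order(f)]  # explore in code order for lexicographic tie-break
  })
  names(feas_list) <- free

  best <- new.env(parent = emptyenv())
  best$cost <- Inf
  best$assign <- NULL
  load <- base_load
  assign_vec <- stats::setNames(rep(NA_character_, length(free)), free)

  recurse <- function(k, cost) {
    if (cost >= best$cost) return(invisible(NULL))
    if (k > length(free)) {
      best$cost <- cost
      best$assign <- assign_vec
      return(invisible(NULL))
    }
    u <- free[k]
    for (nd in feas_list[[u]]) {
      if (load[nd] + pops[u] > caps[nd]) next
      load[nd] <<- load[nd] + pops[u]
      assign_vec[u] <<- nd
      recurse(k + 1L, cost + mins[u, nd])
      load[nd] <<- load[nd] - pops[u]
      assign_vec[u] <<- NA_character_
    }
    invisible(NULL)
  }
  if (length(free) == 0L) {
    best$assign <- assign_vec
    best$cost <- 0
  } else {
    recurse(1L, 0)
  }

  exact_result(territory, config, fixed_node, free, excluded,
               assignment = if (is.finite(best$cost)) best$assign else NULL)
}

exact_result <- function(territory, config, fixed_node, free, excluded,
                         assignment) {
  ucodes <- territory$units$code
  ncodes <- territory$nodes$code
  feasible <- !is.null(assignment)
  node <- fixed_node
  if (feasible && length(free) > 0L) node[free] <- assignment[free]
  status <- ifelse(ucodes %in% excluded | is.na(node[ucodes]),
                   "excluded", "allocated")
  node_out <- unname(ifelse(status == "allocated", node[ucodes],
                            NA_character_))
  idx <- cbind(seq_along(ucodes), match(node_out, ncodes))
  minutes <- ifelse(is.na(node_out), NA_real_, territory$minutes[idx])
  km <- ifelse(is.na(node_out), NA_real_, territory$km[idx])
  records <- tibble::tibble(
    code = ucodes,
    name = territory$units$name,
    status = status,
    node = node_out,
    minutes = minutes,
    km = km,
    pinned = ucodes %in% ncodes & config$pin_hosts,
    forced = FALSE,
    moved = FALSE,
    over_cutoff = !is.na(minutes) & minutes > config$cutoff
  )
  out <- new_allocation(config, records, territory)
  out$feasible <- feasible
  out
}

#' Total realized travel minutes of an allocation
#'
#' @param result An `hs_allocation`.
#' @return Sum of realized minutes over allocated units.
#' @export
total_minutes <- function(result) {
  sum(result$records$minutes[result$records$status == "allocated"])
}

#' @export
print.hs_allocation <- function(x, ...) {
  n_alloc <- sum(x$records$status == "allocated")
  n_excl <- sum(x$records$status == "excluded")
  cat("<hs_allocation> mode ", x$config$mode, ", cutoff ", x$config$cutoff,
      " min: ", n_alloc, " allocated, ", n_excl, " excluded, ",
      nrow(x$violations), " cap violation(s), ", nrow(x$moves),
      " move(s)\n", sep = "")
  invisible(x)
}

#' Serialize an allocation deterministically
#'
#' Canonical text form (records, loads, move log as CSV blocks) used for
#' byte-identity checks and golden files. Identical territory and
#' configuration always produce identical serializations: the pipeline has
#' no hidden randomness.
#'
#' @param result An `hs_allocation`.
#' @return A single character scalar.
#' @export
serialize_allocation <- function(result) {
  paste(
    "# records", readr::format_csv(result$records),
    "# loads", readr::format_csv(result$loads),
    "# moves", readr::format_csv(result$moves),
    sep = "\n"
  )
}
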