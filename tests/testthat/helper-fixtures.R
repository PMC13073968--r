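# Build a small territory in code from a named population vector and a
# unit-by-node travel-time matrix (rownames = unit codes, colnames = node
# codes). Node roles default to hub for the first node, spoke for the rest.
make_territory <- function(pop, minutes, roles = NULL, area = NULL,
                           km = NULL) {
  ucodes <- names(pop)
  ncodes <- colnames(minutes)
  stopifnot(identical(rownames(minutes), ucodes))
  if (is.null(roles)) {
    roles <- stats::setNames(
      c("hub", rep("spoke", length(ncodes) - 1L)), ncodes
    )
  }
  if (is.null(area)) area <- stats::setNames(rep(100, length(pop)), ucodes)
  if (is.null(km)) km <- minutes * 0.8

  units <- tibble::tibble(code = ucodes,
                          name = paste0("U_", ucodes),
                          population = as.integer(pop),
                          area = as.numeric(area[ucodes]))
  nodes <- tibble::tibble(code = ncodes,
                          role = as.character(roles[ncodes]),
                          cap = NA_real_)
  od <- tibble::tibble(
    origin = rep(ucodes, times = length(ncodes)),
    dest = rep(ncodes, each = length(ucodes)),
    minutes = as.vector(minutes),
    km = as.vector(km)
  )
  build_territory(units, nodes, od)
}

# Independent exhaustive oracle: enumerate every assignment of feasible
# units to their feasible nodes with expand.grid, filter cap-respecting
# assignments, and return the minimum total minutes (NA if none exists).
# Pinned hosts are fixed first, mirroring the allocator contract.
oracle_exact_minutes <- function(territory, config) {
  ucodes <- territory$units$code
  ncodes <- territory$nodes$code
  caps <- ifelse(territory$nodes$role == "hub", config$hub_cap,
                 config$spoke_cap)
  caps <- ifelse(is.na(territory$nodes$cap), caps, territory$nodes$cap)
  names(caps) <- ncodes
  pops <- stats::setNames(territory$units$population, ucodes)

  fixed <- intersect(ucodes, ncodes)
  free <- setdiff(ucodes, if (config$pin_hosts) fixed else character(0))
  feas <- lapply(free, function(u) {
    t_u <- territory$minutes[u, ]
    names(t_u)[t_u <= config$cutoff]
  })
  names(feas) <- free
  free <- free[lengths(feas) > 0L]  # infeasible units are excluded
  feas <- feas[free]

  base_load <- stats::setNames(numeric(length(ncodes)), ncodes)
  base_cost <- 0
  if (config$pin_hosts) {
    for (h in fixed) {
      base_load[h] <- base_load[h] + pops[h]
      base_cost <- base_cost + territory$minutes[h, h]
    }
  }
  if (length(free) == 0L) {
    return(if (all(base_load <= caps)) base_cost else NA_real_)
  }
  grid <- expand.grid(feas, stringsAsFactors = FALSE)
  best <- NA_real_
  for (r in seq_len(nrow(grid))) {
    asg <- unlist(grid[r, , drop = FALSE], use.names = FALSE)
    load <- base_load
    for (i in seq_along(free)) {
      load[asg[i]] <- load[asg[i]] + pops[free[i]]
    }
    if (any(load > caps)) next
    cost <- base_cost +
      sum(territory$minutes[cbind(free, asg)])
    if (is.na(best) || cost < best) best <- cost
  }
  best
}

# Independent scan of all single-unit moves from an allocation: returns
# the move (unit, to, delta) with minimal added minutes among moves that
# take a unit off an overloaded node onto a node with enough spare
# capacity, or NULL when no such move exists.
oracle_best_single_move <- function(result, territory, config) {
  rec <- result$records
  loads <- result$loads
  caps <- stats::setNames(loads$cap, loads$node)
  served <- stats::setNames(loads$served, loads$node)
  pops <- stats::setNames(territory$units$population, territory$units$code)
  over <- loads$node[loads$excess > 0]
  over <- over[order(-loads$excess[match(over, loads$node)], over)]
  if (length(over) == 0L) return(NULL)
  nd <- over[1]
  cand <- NULL
  rows <- which(rec$status == "allocated" & rec$node == nd & !rec$pinned &
                  pops[rec$code] > 0)
  for (i in rows) {
    u <- rec$code[i]
    for (alt in setdiff(loads$node, nd)) {
      if (served[alt] + pops[u] > caps[alt]) next
      cand <- rbind(cand, data.frame(
        unit = u, to = alt,
        delta = territory$minutes[u, alt] - territory$minutes[u, nd],
        pop = pops[u], t_alt = territory$minutes[u, alt]
      ))
    }
  }
  if (is.null(cand)) return(NULL)
  cand[order(cand$delta, cand$pop, cand$unit, cand$t_alt, cand$to), ][1, ]
}

# TRUE if any unit on any overloaded node could move to a node with
# enough spare capacity (i.e. an excess-reducing single move exists).
oracle_any_improving_move <- function(result, territory) {
  rec <- result$records
  loads <- result$loads
  pops <- stats::setNames(territory$units$population, territory$units$code)
  for (nd in loads$node[loads$excess > 0]) {
    rows <- which(rec$status == "allocated" & rec$node == nd & !rec$pinned &
                    pops[rec$code] > 0)
    for (i in rows) {
      spare <- loads$cap - loads$served
      if (any(loads$node != nd & spare >= pops[rec$code[i]])) return(TRUE)
    }
  }
  FALSE
}
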