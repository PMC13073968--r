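three_node_unit <- function(times) {
  m <- matrix(99, nrow = 4, ncol = 3,
              dimnames = list(c("U", "A", "B", "C"), c("A", "B", "C")))
  m["U", ] <- times
  m["A", "A"] <- 0; m["B", "B"] <- 0; m["C", "C"] <- 0
  make_territory(
    pop = c(U = 1000L, A = 5000L, B = 5000L, C = 5000L),
    minutes = m,
    roles = c(A = "hub", B = "spoke", C = "spoke")
  )
}

test_that("feasible_nodes filters by cutoff and sorts by time then code", {
  terr <- three_node_unit(c(25, 31, 19))
  expect_equal(feasible_nodes("U", terr, 30), c("C", "A"))
  expect_equal(feasible_nodes("U", terr, 10), character(0))

  terr_tie <- three_node_unit(c(20, 20, 40))
  expect_equal(feasible_nodes("U", terr_tie, 30), c("A", "B"))
})

test_that("candidate_set applies the near-optimal margin band", {
  terr <- three_node_unit(c(20, 20.9, 25))
  feas <- feasible_nodes("U", terr, 30)
  expect_equal(candidate_set("U", feas, terr, margin = 0.05), c("A", "B"))
  expect_equal(candidate_set("U", feas, terr, margin = 0), "A")

  terr2 <- three_node_unit(c(10, 10.5, 10.5))
  feas2 <- feasible_nodes("U", terr2, 30)
  expect_equal(candidate_set("U", feas2, terr2, margin = 0.05),
               c("A", "B", "C"))
  expect_error(candidate_set("U", character(0), terr2), "non-empty")
})

test_that("priority order: fewer candidates, shorter time, larger population, code", {
  pop <- c(u1 = 500L, u2 = 500L, u3 = 500L, u4 = 900L, N = 1000L, M = 1000L)
  m <- matrix(99, nrow = 6, ncol = 2,
              dimnames = list(names(pop), c("M", "N")))
  m["u1", ] <- c(12, 12.2)  # two candidates, min 12
  m["u2", ] <- c(9, 30)     # one candidate, min 9
  m["u3", ] <- c(12, 30)    # one candidate, min 12
  m["u4", ] <- c(12, 30)    # one candidate, min 12, bigger population
  m["M", ] <- c(0, 50); m["N", ] <- c(50, 0)
  terr <- make_territory(pop, m, roles = c(M = "hub", N = "hub"))
  units <- c("u1", "u2", "u3", "u4")
  cs <- lapply(units, function(u) {
    candidate_set(u, feasible_nodes(u, terr, 30), terr, 0.05)
  })
  names(cs) <- units
  # u2 first (9 min), then u4 before u3 (population), u1 last (2 candidates)
  expect_equal(priority_order(units, cs, terr), c("u2", "u4", "u3", "u1"))

  # all criteria tied: unit code is the final deterministic tie-break
  tied <- c("066003", "066001")
  cs_t <- list("066003" = "M", "066001" = "M")
  pop2 <- c("066001" = 10L, "066003" = 10L, M = 1L, N = 1L)
  m2 <- matrix(c(5, 40, 5, 40, 0, 50, 50, 0), nrow = 4, byrow = TRUE,
               dimnames = list(names(pop2), c("M", "N")))
  terr2 <- make_territory(pop2, m2, roles = c(M = "hub", N = "hub"))
  expect_equal(priority_order(tied, cs_t, terr2), c("066001", "066003"))
})

test_that("baseline assigns each unit to its nearest feasible node", {
  terr <- generate_planar_territory(generator_params(seed = 21))
  cfg <- scenario_config(cutoff = 30)
  res <- assign_proximity_first(terr, cfg)

  rec <- res$records
  expect_equal(sort(rec$code), sort(terr$units$code))  # partition
  for (i in which(rec$status == "allocated" & !rec$pinned)) {
    t_u <- terr$minutes[rec$code[i], ]
    feas <- t_u[t_u <= cfg$cutoff]
    expect_equal(rec$minutes[i], min(feas))  # one-line argmin oracle
  }
  # hosts pinned to their own node at zero travel
  hosts <- rec[rec$pinned, ]
  expect_equal(hosts$node, hosts$code)
  expect_equal(hosts$minutes, rep(0, nrow(hosts)))
})

test_that("baseline records overloads without preventing them", {
  terr <- generate_overload_instance(7)
  cfg <- scenario_config(cutoff = attr(terr, "cutoff"))
  res <- assign_proximity_first(terr, cfg)
  expect_gte(nrow(res$violations), 1L)

  # violation magnitude equals the independent argmin population sum
  pops <- stats::setNames(terr$units$population, terr$units$code)
  for (r in seq_len(nrow(res$violations))) {
    nd <- res$violations$node[r]
    assigned <- res$records$code[res$records$status == "allocated" &
                                   res$records$node == nd]
    expect_equal(res$violations$served[r], sum(pops[assigned]))
    expect_equal(res$violations$excess[r],
                 sum(pops[assigned]) - res$violations$cap[r])
  }
})

test_that("strict exclusion and force-assignment treat infeasible units correctly", {
  terr <- generate_infeasible_fringe(9, k = 5, cutoff = 20)
  cfg <- scenario_config(cutoff = 20)
  res <- assign_proximity_first(terr, cfg)
  expect_equal(sum(res$records$status == "excluded"), 5L)
  expect_true(all(is.na(res$records$node[res$records$status == "excluded"])))

  cfg_force <- scenario_config(cutoff = 20, strict_exclusion = FALSE)
  forced <- assign_proximity_first(terr, cfg_force)
  expect_equal(sum(forced$records$status == "excluded"), 0L)
  frows <- forced$records[forced$records$forced, ]
  expect_equal(nrow(frows), 5L)
  expect_true(all(frows$over_cutoff))
  for (i in seq_len(nrow(frows))) {  # forced target is the global nearest
    expect_equal(frows$minutes[i], min(terr$minutes[frows$code[i], ]))
  }
})

test_that("reallocation is a no-op without violations", {
  terr <- generate_planar_territory(generator_params(seed = 2, hub_boost = 1))
  cfg <- scenario_config(cutoff = 40)
  base <- assign_proximity_first(terr, cfg)
  expect_equal(nrow(base$violations), 0L)
  fixed <- resolve_overloads(base, terr)
  expect_equal(fixed$records, base$records)
  expect_equal(nrow(fixed$moves), 0L)
})

test_that("reallocation picks the minimum added-time move, as brute force does", {
  # A holds its host (30k) plus u1 and u2 and exceeds cap 50k by 5k;
  # either donor fits under B's spare capacity
  pop <- c(A = 30000L, B = 5000L, u1 = 15000L, u2 = 10000L)
  m <- matrix(c(0, 60, 60, 0, 10, 15, 12, 14), nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "u1", "u2"), c("A", "B")))
  terr <- make_territory(pop, m, roles = c(A = "hub", B = "hub"))
  cfg <- scenario_config(cutoff = 30, hub_cap = 50000L)
  base <- assign_proximity_first(terr, cfg)
  expect_equal(base$violations$excess, 5000L)

  expected <- oracle_best_single_move(base, terr, cfg)
  fixed <- resolve_overloads(base, terr)
  expect_equal(nrow(fixed$violations), 0L)
  expect_equal(nrow(fixed$moves), 1L)
  expect_equal(fixed$moves$unit, expected$unit)
  expect_equal(fixed$moves$to, expected$to)
  expect_equal(fixed$moves$delta_minutes, expected$delta)
})

test_that("irreducible overloads are reported, not forced", {
  # single node, load above cap, nowhere to move
  pop <- c(A = 60000L, u1 = 1000L)
  m <- matrix(c(0, 10), nrow = 2, dimnames = list(c("A", "u1"), "A"))
  terr <- make_territory(pop, m, roles = c(A = "hub"))
  base <- assign_proximity_first(terr, scenario_config(cutoff = 30))
  fixed <- resolve_overloads(base, terr)
  expect_gte(nrow(fixed$violations), 1L)
  expect_equal(nrow(fixed$moves), 0L)
  expect_false(oracle_any_improving_move(fixed, terr))
})

test_that("moved units may exceed the cutoff and are flagged", {
  pop <- c(A = 48000L, B = 1000L, u1 = 5000L)
  m <- matrix(c(0, 90, 90, 0, 20, 45), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "u1"), c("A", "B")))
  terr <- make_territory(pop, m, roles = c(A = "hub", B = "spoke"))
  pair <- allocate_scenario(terr, scenario_config(cutoff = 30))
  expect_equal(pair$baseline$violations$node, "A")
  rec <- pair$cap_compliant$records
  expect_equal(rec$node[rec$code == "u1"], "B")
  expect_equal(rec$minutes[rec$code == "u1"], 45)
  expect_true(rec$over_cutoff[rec$code == "u1"])
  expect_equal(nrow(pair$cap_compliant$violations), 0L)
})

test_that("scenario pair shares exclusions; ample caps leave baseline unchanged", {
  terr <- generate_infeasible_fringe(13, k = 4, cutoff = 20)
  total <- sum(terr$units$population)
  cfg <- scenario_config(cutoff = 20, hub_cap = total, spoke_cap = total)
  pair <- allocate_scenario(terr, cfg)
  expect_equal(pair$baseline$records$status, pair$cap_compliant$records$status)
  expect_equal(pair$baseline$records, pair$cap_compliant$records)
  expect_equal(nrow(pair$baseline$violations), 0L)
})

test_that("allocated sets nest as the cutoff grows", {
  for (s in c(3, 17, 31)) {
    terr <- generate_planar_territory(generator_params(seed = s))
    prev <- character(0)
    for (co in c(10, 20, 30, 40)) {
      res <- assign_proximity_first(terr, scenario_config(cutoff = co))
      cur <- res$records$code[res$records$status == "allocated"]
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("identical inputs give byte-identical allocations", {
  terr <- generate_overload_instance(3)
  cfg <- scenario_config(cutoff = attr(terr, "cutoff"))
  s1 <- serialize_allocation(allocate_scenario(terr, cfg)$cap_compliant)
  s2 <- serialize_allocation(allocate_scenario(terr, cfg)$cap_compliant)
  expect_identical(s1, s2)
})

test_that("exact allocator solves trivial instances and detects infeasibility", {
  # 1 free unit, 2 nodes, times (5, 9): picks the 5-minute node
  pop <- c(A = 1000L, B = 1000L, u = 500L)
  m <- matrix(c(0, 70, 70, 0, 5, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "u"), c("A", "B")))
  terr <- make_territory(pop, m, roles = c(A = "hub", B = "hub"))
  res <- exact_small_allocation(terr, scenario_config(cutoff = 30))
  expect_true(res$feasible)
  expect_equal(res$records$node[res$records$code == "u"], "A")
  expect_equal(total_minutes(res), 5)

  # two 30k units, one 50k-cap node: pigeonhole infeasibility
  pop2 <- c(A = 0L, u1 = 30000L, u2 = 30000L)
  m2 <- matrix(c(0, 10, 12), nrow = 3, dimnames = list(names(pop2), "A"))
  terr2 <- make_territory(pop2, m2, roles = c(A = "hub"))
  res2 <- exact_small_allocation(terr2, scenario_config(cutoff = 30))
  expect_false(res2$feasible)

  expect_error(
    exact_small_allocation(generate_planar_territory(generator_params(1)),
                           scenario_config(cutoff = 30)),
    "limit"
  )
})

test_that("exact allocator matches an independent exhaustive enumeration", {
  for (s in 1:10) {
    terr <- generate_planar_territory(
      generator_params(seed = 100 + s, n_units = 6L, n_hubs = 2L,
                       n_spokes = 1L, n_clusters = 2L)
    )
    total <- sum(terr$units$population)
    cfg <- scenario_config(cutoff = 60, hub_cap = ceiling(total * 0.6),
                           spoke_cap = ceiling(total * 0.4))
    res <- exact_small_allocation(terr, cfg)
    oracle <- oracle_exact_minutes(terr, cfg)
    if (res$feasible) {
      expect_equal(total_minutes(res), oracle)
    } else {
      expect_true(is.na(oracle))
    }
  }
})

test_that("heuristic never beats the exact optimum when cap-compliant", {
  checked <- 0L
  for (s in 1:30) {
    terr <- generate_planar_territory(
      generator_params(seed = 200 + s, n_units = 8L, n_hubs = 2L,
                       n_spokes = 1L, n_clusters = 3L)
    )
    total <- sum(terr$units$population)
    cfg <- scenario_config(cutoff = 45, hub_cap = ceiling(total * 0.5),
                           spoke_cap = ceiling(total * 0.4))
    pair <- allocate_scenario(terr, cfg)
    heur <- pair$cap_compliant
    if (nrow(heur$violations) == 0L &&
        !any(heur$records$over_cutoff) &&
        all(heur$records$status == "allocated")) {
      oracle <- oracle_exact_minutes(terr, cfg)
      expect_false(is.na(oracle))  # heuristic feasibility implies oracle's
      expect_gte(total_minutes(heur), oracle - 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)  # the comparison must actually exercise cases
})
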