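# Run code under a fixed RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic-territory generator parameters
#'
#' Defaults emulate a sparse mountainous province: ~65 small municipalities
#' in a handful of valley clusters over a ~70 x 70 km extent, heavy-tailed
#' (lognormal) populations with three dominant hub towns holding roughly
#' half of the residents, low population densities, and road travel times
#' derived from planar positions via a detour factor and mild
#' direction-dependent noise.
#'
#' @param seed Integer RNG seed; every generated quantity is a
#'   deterministic function of it.
#' @param n_units Number of demand units (default 65).
#' @param n_hubs,n_spokes Number of hub and spoke nodes (default 3 and 8);
#'   `n_units >= n_hubs + n_spokes`.
#' @param pop_meanlog,pop_sdlog Lognormal population model for ordinary
#'   municipalities (defaults give a median near 1,100 residents with a
#'   heavy upper tail).
#' @param hub_boost Multiplier applied to the population of hub host
#'   towns (default 6, concentrating roughly 50-55 percent of residents
#'   in the three hub towns).
#' @param speed Average road speed in km per minute (default 0.7, i.e.
#'   42 km/h on mountain roads).
#' @param detour Road-network detour multiplier on straight-line distance
#'   (>= 1; default 1.3).
#' @param asymmetry Per-direction multiplicative noise fraction on travel
#'   times, in `[0, 1)` (default 0.10); 0 yields a symmetric matrix.
#' @param n_clusters Number of settlement clusters (default 6).
#' @param cluster_spread Within-cluster positional standard deviation in
#'   km (default 7).
#' @param extent Side of the square study area in km (default 70,
#'   matching a province of roughly 5,000 km2).
#' @param area_meanlog,area_sdlog Lognormal model for municipal land
#'   areas in km2 (defaults give a median near 60 km2).
#' @return A validated list of class `hs_genparams`.
#' @export
generator_params <- function(seed,
                             n_units = 65L,
                             n_hubs = 3L,
                             n_spokes = 8L,
                             pop_meanlog = 7.0,
                             pop_sdlog = 1.0,
                             hub_boost = 6,
                             speed = 0.7,
                             detour = 1.3,
                             asymmetry = 0.10,
                             n_clusters = 6L,
                             cluster_spread = 7,
                             extent = 70,
                             area_meanlog = log(60),
                             area_sdlog = 0.5) {
  p <- list(seed = as.integer(seed), n_units = as.integer(n_units),
            n_hubs = as.integer(n_hubs), n_spokes = as.integer(n_spokes),
            pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
            hub_boost = hub_boost, speed = speed, detour = detour,
            asymmetry = asymmetry, n_clusters = as.integer(n_clusters),
            cluster_spread = cluster_spread, extent = extent,
            area_meanlog = area_meanlog, area_sdlog = area_sdlog)
  if (p$n_hubs < 1L) {
    stop("hubspoke: at least one hub is required", call. = FALSE)
  }
  if (p$n_units < p$n_hubs + p$n_spokes) {
    stop("hubspoke: n_units must be at least n_hubs + n_spokes",
         call. = FALSE)
  }
  if (p$detour < 1) stop("hubspoke: detour factor must be >= 1", call. = FALSE)
  if (p$asymmetry < 0 || p$asymmetry >= 1) {
    stop("hubspoke: asymmetry must be in [0, 1)", call. = FALSE)
  }
  if (p$speed <= 0 || p$extent <= 0 || p$cluster_spread < 0 ||
      p$n_clusters < 1L || p$hub_boost < 1) {
    stop("hubspoke: invalid generator parameters", call. = FALSE)
  }
  structure(p, class = "hs_genparams")
}

#' Generate a synthetic planar territory
#'
#' Places demand units in settlement clusters on a plane, draws
#' heavy-tailed populations and land areas, selects hub hosts as the
#' largest-population towns of the most populous clusters (spoke hosts as
#' the leading towns of the remaining clusters, then the next-largest
#' towns overall), and derives a directed travel matrix: road km =
#' straight-line distance times the detour factor; minutes = km divided
#' by speed, perturbed per direction by the asymmetry fraction. Fully
#' reproducible from the seed.
#'
#' @param params An `hs_genparams` from [generator_params()].
#' @return An `hs_territory` (with the generating parameters attached as
#'   attribute `"params"`).
#' @export
generate_planar_territory <- function(params) {
  stopifnot(inherits(params, "hs_genparams"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_units
    codes <- sprintf("%06d", 900000L + seq_len(n))
    centers <- cbind(stats::runif(p$n_clusters, 0.15, 0.85) * p$extent,
                     stats::runif(p$n_clusters, 0.15, 0.85) * p$extent)
    cluster <- sample.int(p$n_clusters, n, replace = TRUE)
    pos <- centers[cluster, , drop = FALSE] +
      matrix(stats::rnorm(2L * n, sd = p$cluster_spread), ncol = 2L)

    pop <- pmax(1, round(stats::rlnorm(n, p$pop_meanlog, p$pop_sdlog)))
    area <- stats::rlnorm(n, p$area_meanlog, p$area_sdlog)

    # hub hosts: largest town of each of the most populous clusters
    cl_pop <- rowsum(pop, cluster)
    cl_rank <- as.integer(rownames(cl_pop))[order(-cl_pop[, 1])]
    pick_largest <- function(cl, taken) {
      in_cl <- setdiff(which(cluster == cl), taken)
      if (length(in_cl) == 0L) return(integer(0))
      in_cl[order(-pop[in_cl], codes[in_cl])][1]
    }
    hosts <- integer(0)
    for (cl in cl_rank[seq_len(min(p$n_hubs, length(cl_rank)))]) {
      hosts <- c(hosts, pick_largest(cl, hosts))
    }
    hubs <- hosts
    rest_clusters <- cl_rank[-seq_len(min(p$n_hubs, length(cl_rank)))]
    for (cl in rest_clusters) {
      if (length(hosts) >= p$n_hubs + p$n_spokes) break
      hosts <- c(hosts, pick_largest(cl, hosts))
    }
    while (length(hosts) < p$n_hubs + p$n_spokes) {
      remaining <- setdiff(seq_len(n), hosts)
      nxt <- remaining[order(-pop[remaining], codes[remaining])][1]
      hosts <- c(hosts, nxt)
    }
    spokes <- setdiff(hosts, hubs)
    pop[hubs] <- round(pop[hubs] * p$hub_boost)

    d <- as.matrix(stats::dist(pos))
    km <- d * p$detour
    base_min <- km / p$speed
    eps <- matrix(stats::runif(n * n, -p$asymmetry, p$asymmetry), n, n)
    minutes <- base_min * (1 + eps)
    diag(minutes) <- 0
    diag(km) <- 0

    units <- tibble::tibble(
      code = codes,
      name = paste0("Town_", sprintf("%03d", seq_len(n))),
      population = as.integer(pop),
      area = round(area, 3)
    )
    nodes <- tibble::tibble(
      code = codes[c(hubs, spokes)],
      role = c(rep("hub", length(hubs)), rep("spoke", length(spokes))),
      cap = NA_real_
    )
    od <- tibble::tibble(
      origin = rep(codes, each = n),
      dest = rep(codes, times = n),
      minutes = round(as.vector(t(minutes)), 4),
      km = round(as.vector(t(km)), 4)
    )
    terr <- build_territory(units, nodes, od)
    attr(terr, "params") <- p
    terr
  })
}

#' Generate a territory with a resolvable hub overload
#'
#' Searches seeded variations of the planar generator for a territory
#' where, at the stated cut-off, the proximity-first baseline overloads at
#' least one node while total network capacity still suffices, so that
#' iterative reallocation can reach full cap compliance. Hub host towns
#' are clamped just below the hub cap (a hub town larger than its own cap
#' would make the overload irreducible, since the host is pinned); the
#' surrounding catchment then supplies the excess. Both conditions are
#' asserted by running the allocator before the territory is returned; an
#' instance failing the self-check is never handed out.
#'
#' @param seed Integer seed.
#' @param cutoff Cut-off (minutes) at which the overload must occur
#'   (default 30); attached to the result as attribute `"cutoff"`.
#' @param max_attempts Bounded retry budget over derived seeds.
#' @return An `hs_territory` passing the self-check.
#' @export
generate_overload_instance <- function(seed, cutoff = 30, max_attempts = 40L) {
  cfg <- scenario_config(cutoff = cutoff)
  for (a in seq_len(max_attempts) - 1L) {
    sub_seed <- (seed + 7919L * a) %% 2147483647L
    terr <- generate_planar_territory(
      generator_params(seed = sub_seed, hub_boost = 8)
    )
    units <- terr$units
    hubs <- terr$nodes$code[terr$nodes$role == "hub"]
    hit <- units$code %in% hubs
    units$population[hit] <- pmin(units$population[hit],
                                  as.integer(0.9 * cfg$hub_cap))
    terr <- build_territory(units, terr$nodes, terr$od)
    pair <- allocate_scenario(terr, cfg)
    if (nrow(pair$baseline$violations) >= 1L &&
        nrow(pair$cap_compliant$violations) == 0L) {
      attr(terr, "cutoff") <- cutoff
      return(terr)
    }
  }
  stop("hubspoke: could not generate a resolvable overload instance in ",
       max_attempts, " attempts", call. = FALSE)
}

#' Generate a territory with an infeasible fringe
#'
#' Produces a territory in which exactly `k` demand units lie beyond the
#' cut-off from every node (an infeasible mountainous fringe) while all
#' remaining units are feasible. Built by rescaling a planar territory's
#' travel times so every unit is comfortably within the cut-off, then
#' pushing the `k` most remote non-host units beyond it. The count is
#' verified before the territory is returned.
#'
#' @param seed Integer seed.
#' @param k Number of infeasible units (`0 <= k <= n_units - n_nodes`).
#' @param cutoff Cut-off in minutes the fringe must violate (default 20);
#'   attached as attribute `"cutoff"`.
#' @param params Optional `hs_genparams` overriding the generator
#'   defaults (its seed is replaced by `seed`).
#' @return An `hs_territory` with exactly `k` infeasible units.
#' @export
generate_infeasible_fringe <- function(seed, k, cutoff = 20, params = NULL) {
  if (is.null(params)) params <- generator_params(seed = seed)
  params$seed <- as.integer(seed)
  terr <- generate_planar_territory(params)
  ncodes <- terr$nodes$code
  nonhost <- setdiff(terr$units$code, ncodes)
  if (k > length(nonhost)) {
    stop("hubspoke: k exceeds the number of non-host units", call. = FALSE)
  }

  min_t <- apply(terr$minutes, 1, min)
  scale <- if (length(nonhost) == 0L) 1 else 0.9 * cutoff / max(min_t[nonhost])
  od <- terr$od
  od$minutes <- od$minutes * scale
  od$km <- od$km * scale

  if (k > 0L) {
    remote <- nonhost[order(-min_t[nonhost], nonhost)][seq_len(k)]
    push <- od$origin %in% remote & od$dest %in% ncodes
    od$minutes[push] <- od$minutes[push] + 1.5 * cutoff
    od$km[push] <- od$km[push] * 2
  }

  out <- build_territory(terr$units, terr$nodes, od)
  infeasible <- sum(apply(out$minutes, 1, min) > cutoff)
  if (infeasible != k) {
    stop("hubspoke: fringe self-check failed (", infeasible,
         " infeasible units, expected ", k, ")", call. = FALSE)
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "params") <- params
  out
}
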