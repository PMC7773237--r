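# Simulation module: agent synthesis and placement, the monthly decision
# loop (fast C++ engine plus an R reference step used by the hand-traced
# oracle tests), and the trajectory table.
#
# Randomness is split between two named seeds: placementSeed fixes the
# start positions (identical across runs regardless of behavior), and
# behaviorSeed drives counter-based per-(agent, tick) streams for scouting
# radii and land-sharing deal outcomes.

.EVENT_LEVELS <- c("STAYED", "MOVED", "DEAL_OK", "DROPPED_OUT",
                   "FORCED_RELOCATE")

#' Create a SimulationConfig
#'
#' @param placementSeed,behaviorSeed integer seeds (positions / behavior).
#' @param sampleFraction fraction of base population synthesized (0, 1].
#' @param pDeal land-sharing deal success probability (default 0.5).
#' @param scoutMinKm,scoutMaxKm scouting radius bounds, km (15 / 30).
#' @param nTicks monthly ticks (default 132 = 11 years).
#' @param maxDealFailures per-season failed deals triggering drop-out (3).
#' @param weights numeric(6) signed favorability coefficients.
#' @param startMonth,startYear calendar anchor of tick 1.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(placementSeed = 1L, behaviorSeed = 2L,
                             sampleFraction = 0.1, pDeal = 0.5,
                             scoutMinKm = 15, scoutMaxKm = 30,
                             nTicks = 132L, maxDealFailures = 3L,
                             weights = c(1, 1, 1, -0.25, -1, -0.25),
                             startMonth = 1L, startYear = 2008L) {
  new("SimulationConfig", placementSeed = as.integer(placementSeed),
      behaviorSeed = as.integer(behaviorSeed),
      sampleFraction = sampleFraction, pDeal = pDeal,
      scoutMinKm = scoutMinKm, scoutMaxKm = scoutMaxKm,
      nTicks = as.integer(nTicks),
      maxDealFailures = as.integer(maxDealFailures),
      weights = weights, startMonth = as.integer(startMonth),
      startYear = as.integer(startYear))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d ticks from %d-%02d, sample %.0f%%,",
                     " p(deal) = %.2f\n"),
              object@nTicks, object@startYear, object@startMonth,
              100 * object@sampleFraction, object@pDeal))
  cat(sprintf("  scouting %.0f-%.0f km; drop-out after %d failed deals;",
              object@scoutMinKm, object@scoutMaxKm, object@maxDealFailures))
  cat(sprintf(" seeds: placement %d, behavior %d\n",
              object@placementSeed, object@behaviorSeed))
  invisible(object)
})

#' Synthesize per-district agent counts
#'
#' Per-district count = round-half-up(fraction * base population).
#'
#' @param baseCounts named numeric vector of base populations (>= 0).
#' @param fraction sampling fraction in (0, 1].
#' @return named integer vector of agent counts.
#' @examples
#' synthesizePopulation(c(Awdal = 28510), 0.10)  # 2851
#' @export
synthesizePopulation <- function(baseCounts, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (any(baseCounts < 0)) stop("base populations must be non-negative")
  counts <- as.integer(floor(fraction * baseCounts + 0.5))
  names(counts) <- names(baseCounts)
  counts
}

# evaluate an expression under a temporary, seeded R RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Rasterize district polygons onto a template grid
#'
#' Assigns each cell (by its center) to the first district polygon that
#' contains it; 0 marks cells outside every district.
#'
#' @param template a [RasterGrid-class].
#' @param districts named list of polygon vertex matrices.
#' @return integer matrix of district indices (0 = outside) with the
#'   district names attached as the `"districts"` attribute.
#' @export
districtRaster <- function(template, districts) {
  nr <- nRows(template); nc <- nCols(template)
  cc <- cellCenters(template)
  X <- as.vector(matrix(cc$x, nr, nc, byrow = TRUE))
  Y <- as.vector(matrix(cc$y, nr, nc))
  out <- integer(nr * nc)
  for (i in rev(seq_along(districts))) {
    inside <- pointInPolygon(X, Y, districts[[i]])
    out[inside] <- i  # earlier districts overwrite later: first-wins
  }
  m <- matrix(out, nr, nc)
  attr(m, "districts") <- names(districts)
  m
}

#' Place agents on eligible cells of their home districts
#'
#' Start cells are drawn uniformly at random (with replacement — cells may
#' host several agents) from each district's eligible cells: inside the
#' district polygon, suitable, and on public land. Placement depends only on
#' `placementSeed`; identical seeds give identical start positions no
#' matter what the behavior seed is.
#'
#' @param counts named integer vector of per-district agent counts.
#' @param districts named list of district polygons (or an integer district
#'   raster from [districtRaster()]).
#' @param privateMask,suitabilityMask binary [RasterGrid-class] masks.
#' @param placementSeed integer seed.
#' @param ethnicityMatrix optional character/integer matrix labeling each
#'   cell's ethnic territory; copied onto the agents.
#' @return data.frame with columns `id`, `row`, `col`, `homeDistrict`,
#'   `ethnicity`, `clan`, `state`, `failedDeals`.
#' @export
placeAgents <- function(counts, districts, privateMask, suitabilityMask,
                        placementSeed, ethnicityMatrix = NULL) {
  if (is.matrix(districts)) {
    dmat <- districts
    dnames <- attr(districts, "districts")
    if (is.null(dnames)) dnames <- paste0("D", seq_len(max(dmat, 1)))
  } else {
    dmat <- districtRaster(privateMask, districts)
    dnames <- names(districts)
  }
  eligible <- dmat * (privateMask@values == 0) *
    (suitabilityMask@values == 1)
  rows <- integer(0); cols <- integer(0); home <- character(0)
  .withSeed(placementSeed, {
    for (d in seq_along(dnames)) {
      nm <- dnames[d]
      k <- if (nm %in% names(counts)) counts[[nm]] else 0L
      if (k == 0) next
      cells <- which(eligible == d)
      if (length(cells) == 0)
        stop(sprintf("district '%s' has no eligible cell for %d agent(s)",
                     nm, k))
      pick <- cells[sample.int(length(cells), k, replace = TRUE)]
      rows <- c(rows, (pick - 1L) %% nrow(dmat) + 1L)
      cols <- c(cols, (pick - 1L) %/% nrow(dmat) + 1L)
      home <- c(home, rep(nm, k))
    }
  })
  n <- length(rows)
  if (n == 0)
    return(data.frame(id = integer(0), row = integer(0), col = integer(0),
                      homeDistrict = character(0),
                      ethnicity = character(0), clan = character(0),
                      state = character(0), failedDeals = integer(0),
                      stringsAsFactors = FALSE))
  eth <- if (is.null(ethnicityMatrix)) rep(NA_character_, n) else
    as.character(ethnicityMatrix[cbind(rows, cols)])
  data.frame(id = seq_len(n), row = rows, col = cols, homeDistrict = home,
             ethnicity = eth,
             clan = ifelse(is.na(eth), home, paste(eth, home, sep = ":")),
             state = "PASTORALIST", failedDeals = 0L,
             stringsAsFactors = FALSE)
}

#' Per-(agent, tick) random stream
#'
#' A lazy uniform(0,1) supply backed by the engine's counter-based
#' splitmix64 stream, keyed by (behaviorSeed, agent id, tick). Both the C++
#' engine and the R reference step consume draws from this stream in the
#' same order (first the scouting radius, then one draw per private-cell
#' deal attempt), so their trajectories agree bit for bit.
#'
#' @param behaviorSeed,id,tick stream key.
#' @return an environment with a `$uniform()` function.
#' @export
agentStream <- function(behaviorSeed, id, tick) {
  env <- new.env(parent = emptyenv())
  env$n <- 32L
  env$buf <- cpp_stream_uniforms(behaviorSeed, id, tick, env$n)
  env$pos <- 0L
  env$uniform <- function() {
    env$pos <- env$pos + 1L
    if (env$pos > env$n) {
      env$n <- env$n * 2L
      env$buf <- cpp_stream_uniforms(behaviorSeed, id, tick, env$n)
    }
    env$buf[[env$pos]]
  }
  env
}

#' Scripted random stream for tests and worked examples
#'
#' @param values uniforms returned in order by `$uniform()`.
#' @return an environment with a `$uniform()` function.
#' @export
scriptedStream <- function(values) {
  env <- new.env(parent = emptyenv())
  env$buf <- values; env$pos <- 0L
  env$uniform <- function() {
    env$pos <- env$pos + 1L
    if (env$pos > length(env$buf)) stop("scripted stream exhausted")
    env$buf[[env$pos]]
  }
  env
}

#' Draw a scouting radius
#'
#' Uniform on [scoutMinKm, scoutMaxKm] (default 15-30 km, the consensus
#' monthly mobility range of a pastoralist household).
#'
#' @param stream a stream from [agentStream()] or [scriptedStream()].
#' @param scoutMinKm,scoutMaxKm radius bounds in km.
#' @return radius in km.
#' @export
drawScoutingRadius <- function(stream, scoutMinKm = 15, scoutMaxKm = 30) {
  scoutMinKm + stream$uniform() * (scoutMaxKm - scoutMinKm)
}

#' Attempt a land-sharing deal
#'
#' @param stream a stream from [agentStream()] or [scriptedStream()].
#' @param pDeal success probability in [0, 1].
#' @return logical: did the negotiation succeed?
#' @export
attemptDeal <- function(stream, pDeal) {
  if (pDeal < 0 || pDeal > 1) stop("pDeal must lie in [0, 1]")
  stream$uniform() < pDeal
}

#' Ordered candidate cells within a scouting radius
#'
#' All suitable cells whose centers lie within `radiusKm` of the agent's
#' position (current cell included unless excluded), sorted by favorability
#' score descending with deterministic tie-breaks: nearer cells first, then
#' smaller row-major index.
#'
#' @param score [RasterGrid-class] (or matrix) of favorability scores.
#' @param pos integer(2) (row, col) agent position.
#' @param radiusKm scouting radius, km.
#' @param suitable optional logical/binary matrix; by default every cell
#'   with a finite score is a candidate.
#' @param cellSizeM cell edge in meters (taken from `score` when it is a
#'   [RasterGrid-class]).
#' @param excludeCurrent drop the current cell (the forced-relocation rule
#'   on the first tick of a season).
#' @return data.frame with `row`, `col`, `score`, `distKm` in walk order.
#' @export
candidateCells <- function(score, pos, radiusKm, suitable = NULL,
                           cellSizeM = NULL, excludeCurrent = FALSE) {
  if (is(score, "RasterGrid")) {
    cellSizeM <- score@cellSize
    score <- score@values
  }
  if (is.null(cellSizeM)) stop("cellSizeM required for matrix input")
  if (is.null(suitable)) suitable <- matrix(TRUE, nrow(score), ncol(score))
  res <- cpp_candidate_cells(score, suitable == 1, as.integer(pos[1]),
                             as.integer(pos[2]), radiusKm,
                             cellSizeM / 1000, excludeCurrent)
  as.data.frame(res)
}

#' One monthly decision step for a single agent (reference implementation)
#'
#' Walks the ordered candidate list: the current cell means stay; a public
#' cell is occupied immediately; a private cell requires a successful
#' land-sharing deal; each failed deal increments the per-season failure
#' counter, and reaching `maxDealFailures` converts the agent to IDP
#' (DROPPED_OUT). On the first tick of a new season the current cell is
#' excluded from the candidates (forced relocation). This mirrors the C++
#' engine draw-for-draw and exists for oracle tests and worked examples.
#'
#' @param agent list/one-row data.frame with `id`, `row`, `col`,
#'   `failedDeals`.
#' @param score favorability [RasterGrid-class] or matrix.
#' @param suitable binary matrix (1 = suitable).
#' @param privateLand binary matrix (1 = private).
#' @param tick tick number (keys the random stream).
#' @param config a [SimulationConfig-class].
#' @param newSeason is this the first tick of a new season?
#' @param stream optional stream (default the agent's
#'   [agentStream()]); pass a [scriptedStream()] to script outcomes.
#' @param cellSizeM cell edge in meters when `score` is a plain matrix.
#' @return list with `agent` (updated) and `record` (one trajectory row).
#' @export
stepAgent <- function(agent, score, suitable, privateLand, tick, config,
                      newSeason = FALSE, stream = NULL, cellSizeM = NULL) {
  if (is(score, "RasterGrid")) {
    cellSizeM <- score@cellSize
    score <- score@values
  }
  if (is.null(stream))
    stream <- agentStream(config@behaviorSeed, agent$id, tick)
  radius <- drawScoutingRadius(stream, config@scoutMinKm, config@scoutMaxKm)
  cands <- candidateCells(score, c(agent$row, agent$col), radius,
                          suitable, cellSizeM, excludeCurrent = newSeason)
  if (newSeason) agent$failedDeals <- 0L
  event <- "STAYED"; dealFailsTick <- 0L
  if (nrow(cands) == 0)
    warning(sprintf("agent %d: empty candidate set at tick %d; staying put",
                    agent$id, tick))
  for (k in seq_len(nrow(cands))) {
    cd <- cands[k, ]
    if (cd$row == agent$row && cd$col == agent$col) {
      event <- "STAYED"; break
    }
    if (privateLand[cd$row, cd$col] == 0) {
      agent$row <- cd$row; agent$col <- cd$col
      event <- if (newSeason) "FORCED_RELOCATE" else "MOVED"
      break
    }
    if (attemptDeal(stream, config@pDeal)) {
      agent$row <- cd$row; agent$col <- cd$col
      event <- "DEAL_OK"
      break
    }
    dealFailsTick <- dealFailsTick + 1L
    agent$failedDeals <- agent$failedDeals + 1L
    if (agent$failedDeals >= config@maxDealFailures) {
      event <- "DROPPED_OUT"
      break
    }
  }
  state <- if (event == "DROPPED_OUT") "IDP" else "PASTORALIST"
  list(agent = agent,
       record = data.frame(tick = tick, id = agent$id, row = agent$row,
                           col = agent$col,
                           favorability = score[agent$row, agent$col],
                           radiusKm = radius, state = state, event = event,
                           dealFails = dealFailsTick,
                           stringsAsFactors = FALSE))
}

#' SimulationResult: trajectory table plus per-tick summary
#'
#' @slot trajectory data.frame of per-agent per-tick records (`tick`, `id`,
#'   `row`, `col`, `favorability`, `radiusKm`, `state`, `event`,
#'   `dealFails`).
#' @slot tickSummary data.frame with per-tick `activeCount` and
#'   `droppedCount`.
#' @slot agentsStart,agentsFinal agent tables before and after the run.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SimulationResult",
  representation(trajectory = "data.frame", tickSummary = "data.frame",
                 agentsStart = "data.frame", agentsFinal = "data.frame",
                 config = "SimulationConfig"))

#' @rdname SimulationResult-class
#' @param x,object a `SimulationResult`.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname SimulationResult-class
#' @export
setMethod("trajectory", "SimulationResult", function(x) x@trajectory)

#' @rdname SimulationResult-class
#' @export
setGeneric("tickSummary", function(x) standardGeneric("tickSummary"))

#' @rdname SimulationResult-class
#' @export
setMethod("tickSummary", "SimulationResult", function(x) x@tickSummary)

setMethod("show", "SimulationResult", function(object) {
  ts <- object@tickSummary
  cat(sprintf("SimulationResult: %d agents, %d ticks\n",
              nrow(object@agentsStart), nrow(ts)))
  cat(sprintf("  active at end: %d; cumulative drop-outs: %d\n",
              ts$activeCount[nrow(ts)], sum(ts$droppedCount)))
  cat(sprintf("  trajectory rows: %d\n", nrow(object@trajectory)))
  invisible(object)
})

#' Run the monthly decision loop
#'
#' Iterates ticks 1..nTicks over one favorability surface per season,
#' stepping every active agent in id order (agents do not interact, and
#' each draws from its own counter-based random stream, so results are
#' independent of update order). Failed-deal counters reset at season
#' boundaries; the first tick of each new season forces relocation.
#'
#' @param stacks list of [EnvironmentStack-class], one per season of the
#'   run in time order (see [seasonSequence()]), or a list of precomputed
#'   score [RasterGrid-class] objects via `scores`.
#' @param agents agent table from [placeAgents()].
#' @param config a [SimulationConfig-class].
#' @param recordTicks integer ticks to record in the trajectory (default
#'   all; drop-out rows are always recorded).
#' @param scores optional list of precomputed favorability
#'   [RasterGrid-class] per season (bypasses `stacks`).
#' @param suitable,privateLand binary matrices, required with `scores`.
#' @param cellSizeM cell edge, required with `scores` given as matrices.
#' @return a [SimulationResult-class].
#' @export
runSimulation <- function(stacks = NULL, agents, config,
                          recordTicks = NULL, scores = NULL,
                          suitable = NULL, privateLand = NULL,
                          cellSizeM = NULL) {
  seq <- seasonSequence(config@nTicks, config@startMonth, config@startYear)
  nSeasons <- length(seq$seasons)
  if (is.null(scores)) {
    if (length(stacks) < nSeasons)
      stop(sprintf("missing seasonal stack: need %d stacks, got %d",
                   nSeasons, length(stacks)))
    for (i in seq_len(nSeasons)) {
      if (seasonIndex(stacks[[i]]@season) !=
          seasonIndex(seq$seasons[[i]]))
        stop(sprintf("stack %d is %s %d but the run needs %s %d", i,
                     stacks[[i]]@season@name, stacks[[i]]@season@year,
                     seq$seasons[[i]]@name, seq$seasons[[i]]@year))
    }
    scores <- lapply(stacks[seq_len(nSeasons)], favorabilitySurface,
                     weights = config@weights)
    suitable <- stacks[[1]]@suitabilityMask@values
    privateLand <- stacks[[1]]@privateMask@values
    cellSizeM <- stacks[[1]]@v1@cellSize
  }
  scoreMats <- lapply(scores, function(s)
    if (is(s, "RasterGrid")) s@values else s)
  if (is.null(cellSizeM))
    cellSizeM <- if (is(scores[[1]], "RasterGrid"))
      scores[[1]]@cellSize else stop("cellSizeM required")
  tickSeason <- seq$tickSeason
  newSeason <- c(FALSE, diff(tickSeason) != 0)
  rec <- rep(TRUE, config@nTicks)
  if (!is.null(recordTicks)) {
    rec <- rep(FALSE, config@nTicks)
    rec[recordTicks] <- TRUE
  }
  res <- cpp_run_simulation(scoreMats, as.integer(tickSeason), newSeason,
                            suitable == 1, privateLand == 1,
                            as.integer(agents$id), as.integer(agents$row),
                            as.integer(agents$col), cellSizeM / 1000,
                            config@scoutMinKm, config@scoutMaxKm,
                            config@pDeal, config@maxDealFailures,
                            config@behaviorSeed, rec)
  if (res$emptyCandidateEvents > 0)
    warning(sprintf("%d agent-tick(s) had an empty candidate set (stayed)",
                    res$emptyCandidateEvents))
  traj <- data.frame(tick = res$tick, id = res$id, row = res$row,
                     col = res$col, favorability = res$favorability,
                     radiusKm = res$radiusKm,
                     state = ifelse(res$state == 1, "IDP", "PASTORALIST"),
                     event = .EVENT_LEVELS[res$event + 1L],
                     dealFails = res$dealFails, stringsAsFactors = FALSE)
  final <- agents
  final$row <- res$finalRow; final$col <- res$finalCol
  final$state <- ifelse(res$finalActive == 1, "PASTORALIST", "IDP")
  new("SimulationResult", trajectory = traj,
      tickSummary = data.frame(tick = seq_len(config@nTicks),
                               activeCount = res$activeCount,
                               droppedCount = res$droppedCount),
      agentsStart = agents, agentsFinal = final, config = config)
}

#' Write / read a trajectory table as CSV
#'
#' @param result a [SimulationResult-class] (or its trajectory data.frame).
#' @param path file path.
#' @return `writeTrajectory` invisibly returns `path`; `readTrajectory`
#'   returns the trajectory data.frame.
#' @export
writeTrajectory <- function(result, path) {
  df <- if (is(result, "SimulationResult")) result@trajectory else result
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
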