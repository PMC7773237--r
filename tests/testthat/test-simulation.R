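# Agent synthesis, placement, the decision step, and run-level invariants.

test_that("population synthesis rounds half-up per district", {
  expect_equal(unname(synthesizePopulation(c(A = 1000), 0.25)), 250L)
  expect_equal(unname(synthesizePopulation(c(Awdal = 28510), 0.10)), 2851L)
  expect_equal(unname(synthesizePopulation(c(A = 15), 0.1)), 2L)  # 1.5 up
  ref <- read.csv(refPath("reference_base_populations.csv"))
  counts <- synthesizePopulation(setNames(ref$basePopulation,
                                          ref$district), 0.10)
  expect_equal(unname(counts), ref$agents10pct)
  expect_equal(sum(counts), 22575L)
  expect_equal(unname(synthesizePopulation(c(A = 0), 0.5)), 0L)
  expect_error(synthesizePopulation(c(A = 10), 0), "fraction")
})

test_that("placement is uniform over eligible cells and seed-reproducible", {
  template <- rasterGrid(matrix(0, 2, 2), 1000, c(0, 2000))
  dmat <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  attr(dmat, "districts") <- c("A", "B")
  pub <- rasterGrid(matrix(0, 2, 2), 1000, c(0, 2000))
  suit <- rasterGrid(matrix(1, 2, 2), 1000, c(0, 2000))
  ag <- placeAgents(c(A = 10000L), dmat, pub, suit, placementSeed = 5)
  expect_equal(nrow(ag), 10000)
  tab <- table(ag$row)  # district A = column 1, rows 1 and 2
  expect_equal(sort(unique(ag$col)), 1L)
  p <- chisq.test(tab, p = c(0.5, 0.5))$p.value
  expect_gt(p, 0.001)
  # identical seed, identical placement
  ag2 <- placeAgents(c(A = 10000L), dmat, pub, suit, placementSeed = 5)
  expect_identical(ag, ag2)
  ag3 <- placeAgents(c(A = 10000L), dmat, pub, suit, placementSeed = 6)
  expect_false(identical(ag$row, ag3$row))
})

test_that("placement fails loudly when a district has no eligible cell", {
  dmat <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  attr(dmat, "districts") <- c("A", "B")
  allPrivate <- rasterGrid(matrix(c(1, 1, 0, 0), 2, 2), 1000, c(0, 2000))
  suit <- rasterGrid(matrix(1, 2, 2), 1000, c(0, 2000))
  expect_error(placeAgents(c(A = 3L), dmat, allPrivate, suit, 1), "'A'")
  # zero counts everywhere -> empty agent table
  none <- placeAgents(c(A = 0L, B = 0L), dmat, allPrivate, suit, 1)
  expect_equal(nrow(none), 0)
})

test_that("agent streams are deterministic and match the C++ engine draws", {
  s1 <- agentStream(42, 7, 3)
  s2 <- agentStream(42, 7, 3)
  draws1 <- replicate(50, s1$uniform())
  draws2 <- replicate(50, s2$uniform())
  expect_identical(draws1, draws2)
  expect_equal(draws1,
               as.numeric(pastoralsim:::cpp_stream_uniforms(42, 7, 3, 50)))
  s3 <- agentStream(42, 7, 4)  # different tick, different stream
  expect_false(isTRUE(all.equal(draws1[1], s3$uniform())))
  expect_true(all(draws1 >= 0 & draws1 < 1))
})

test_that("scouting radii are uniform on [15, 30] km", {
  draws <- vapply(1:20000, function(i)
    drawScoutingRadius(agentStream(1, i, 1)), numeric(1))
  expect_true(all(draws >= 15 & draws <= 30))
  expect_equal(mean(draws), 22.5, tolerance = 0.01)
  expect_equal(var(draws), 15^2 / 12, tolerance = 0.05)
})

test_that("deal attempts follow the Bernoulli probability", {
  expect_true(attemptDeal(scriptedStream(0.999), 1))
  expect_false(attemptDeal(scriptedStream(0.001), 0))
  hits <- vapply(1:20000, function(i)
    attemptDeal(agentStream(2, i, 1), 0.3), logical(1))
  expect_equal(mean(hits), 0.3, tolerance = 0.02)
  expect_error(attemptDeal(scriptedStream(0.5), 1.2), "pDeal")
})

test_that("candidate cells are ordered by score, then distance, then index", {
  score <- matrix(0.1, 5, 5)
  score[2, 3] <- 0.9; score[4, 3] <- 0.5; score[3, 2] <- 0.5
  cands <- candidateCells(score, c(3, 3), radiusKm = 1.5,
                          cellSizeM = 1000)
  expect_equal(nrow(cands), 9)  # 3x3 block within 1.5 km
  expect_equal(unlist(cands[1, c("row", "col")]), c(row = 2, col = 3))
  # equal scores 0.5 at distance 1: row-major index breaks the tie
  expect_equal(cands$score[2:3], c(0.5, 0.5))
  expect_equal(cands$row[2:3], c(3, 4))  # (3,2) index 12 < (4,3) index 18
  # nearer-first tie-break among the 0.1 cells
  rest <- cands[4:9, ]
  expect_true(all(diff(rest$distKm) >= 0))
  # radius below cell size: only the current cell
  self <- candidateCells(score, c(3, 3), 0.5, cellSizeM = 1000)
  expect_equal(nrow(self), 1)
  expect_equal(self$row, 3)
  none <- candidateCells(score, c(3, 3), 0.5, cellSizeM = 1000,
                         excludeCurrent = TRUE)
  expect_equal(nrow(none), 0)
  # unsuitable cells never appear
  suit <- matrix(1, 5, 5); suit[2, 3] <- 0
  cands2 <- candidateCells(score, c(3, 3), 1.5, suitable = suit,
                           cellSizeM = 1000)
  expect_false(any(cands2$row == 2 & cands2$col == 3))
})

test_that("a hand-traced decision path is reproduced exactly", {
  # 5 x 5 grid, 1 km cells. Agent starts at (3,3). Private cells: (2,3) and
  # (2,2). Scores: (2,3)=0.9, (2,2)=0.8, (3,4)=0.7, (3,3)=0.5, rest 0.1.
  # Radius fixed at 1.5 km (scoutMin = scoutMax), so candidates are the
  # 3 x 3 block around the agent. pDeal = 0.5; deal draw u < 0.5 succeeds.
  score <- matrix(0.1, 5, 5)
  score[2, 3] <- 0.9; score[2, 2] <- 0.8; score[3, 4] <- 0.7
  score[3, 3] <- 0.5
  priv <- matrix(0, 5, 5); priv[2, 3] <- 1; priv[2, 2] <- 1
  suit <- matrix(1, 5, 5)
  cfg <- simulationConfig(pDeal = 0.5, scoutMinKm = 1.5, scoutMaxKm = 1.5,
                          maxDealFailures = 3L)
  agent <- list(id = 1L, row = 3L, col = 3L, failedDeals = 0L)
  step <- function(agent, tick, newSeason, draws) {
    stepAgent(agent, score, suit, priv, tick, cfg, newSeason = newSeason,
              stream = scriptedStream(draws), cellSizeM = 1000)
  }
  # tick 1: walk (2,3) fail, (2,2) fail, (3,4) public -> MOVED, 2 failures
  r1 <- step(agent, 1, FALSE, c(0.5, 0.9, 0.9))
  expect_equal(r1$record$event, "MOVED")
  expect_equal(c(r1$agent$row, r1$agent$col), c(3, 4))
  expect_equal(r1$agent$failedDeals, 2)
  expect_equal(r1$record$dealFails, 2)
  expect_equal(r1$record$favorability, 0.7)
  # tick 2 (new season): counter resets, current cell excluded;
  # (2,3) deal succeeds -> DEAL_OK
  r2 <- step(r1$agent, 2, TRUE, c(0.5, 0.1))
  expect_equal(r2$record$event, "DEAL_OK")
  expect_equal(c(r2$agent$row, r2$agent$col), c(2, 3))
  expect_equal(r2$agent$failedDeals, 0)
  # tick 3: own cell (2,3) is the top candidate -> STAYED, no deal needed
  r3 <- step(r2$agent, 3, FALSE, c(0.5))
  expect_equal(r3$record$event, "STAYED")
  expect_equal(c(r3$agent$row, r3$agent$col), c(2, 3))
  # tick 4 (new season): (2,2) fails, then (3,4) public -> FORCED_RELOCATE
  r4 <- step(r3$agent, 4, TRUE, c(0.5, 0.9))
  expect_equal(r4$record$event, "FORCED_RELOCATE")
  expect_equal(c(r4$agent$row, r4$agent$col), c(3, 4))
  expect_equal(r4$agent$failedDeals, 1)
  # tick 5: (2,3) fails (2 failures now); (2,2) is out of range from (3,4);
  # next candidate is the current cell -> STAYED
  r5 <- step(r4$agent, 5, FALSE, c(0.5, 0.9))
  expect_equal(r5$record$event, "STAYED")
  expect_equal(r5$agent$failedDeals, 2)
  # tick 6: (2,3) fails again -> third failure this season -> DROPPED_OUT
  r6 <- step(r5$agent, 6, FALSE, c(0.5, 0.9))
  expect_equal(r6$record$event, "DROPPED_OUT")
  expect_equal(r6$record$state, "IDP")
  expect_equal(c(r6$agent$row, r6$agent$col), c(3, 4))  # exits in place
})

test_that("the R reference step and the C++ engine agree draw for draw", {
  set.seed(33)
  nr <- 12; nc <- 12; nTicks <- 8; nAgents <- 12
  suit <- matrix(1, nr, nc); suit[sample(nr * nc, 10)] <- 0
  priv <- matrix(rbinom(nr * nc, 1, 0.3), nr, nc)
  sq <- seasonSequence(nTicks)
  scores <- lapply(seq_along(sq$seasons), function(i)
    matrix(runif(nr * nc), nr, nc))
  cfg <- simulationConfig(behaviorSeed = 77L, pDeal = 0.4,
                          scoutMinKm = 2, scoutMaxKm = 5, nTicks = nTicks)
  ok <- which(suit == 1)
  start <- sample(ok, nAgents, replace = TRUE)
  agents <- data.frame(id = seq_len(nAgents),
                       row = (start - 1) %% nr + 1,
                       col = (start - 1) %/% nr + 1,
                       homeDistrict = "A", ethnicity = NA, clan = "A",
                       state = "PASTORALIST", failedDeals = 0L)
  sim <- runSimulation(agents = agents, config = cfg,
                       scores = lapply(sq$tickSeason[!duplicated(sq$tickSeason)],
                                       function(i) scores[[i]]),
                       suitable = suit, privateLand = priv,
                       cellSizeM = 1000)
  traj <- trajectory(sim)
  # replay with the R reference step
  state <- agents
  newSeason <- c(FALSE, diff(sq$tickSeason) != 0)
  rows <- list()
  for (t in seq_len(nTicks)) {
    sc <- scores[[sq$tickSeason[t]]]
    if (newSeason[t]) state$failedDeals <- 0L
    for (a in seq_len(nrow(state))) {
      if (state$state[a] != "PASTORALIST") next
      res <- stepAgent(as.list(state[a, ]), sc, suit, priv, t, cfg,
                       newSeason = newSeason[t], cellSizeM = 1000)
      state$row[a] <- res$agent$row; state$col[a] <- res$agent$col
      state$failedDeals[a] <- res$agent$failedDeals
      if (res$record$event == "DROPPED_OUT") state$state[a] <- "IDP"
      rows[[length(rows) + 1L]] <- res$record
    }
  }
  ref <- do.call(rbind, rows)
  expect_equal(nrow(traj), nrow(ref))
  for (colName in names(ref))
    expect_equal(traj[[colName]], ref[[colName]], info = colName)
})

test_that("run-level invariants hold on a small stochastic run", {
  stacks <- flatStackSeries(14, nr = 10, nc = 10)
  # make some structure: private band, one unsuitable cell
  for (i in seq_along(stacks)) {
    stacks[[i]]@privateMask@values[, 5:6] <- 1
    stacks[[i]]@suitabilityMask@values[1, 1] <- 0
    stacks[[i]]@v1@values[] <- matrix(seq(0, 1, length.out = 100), 10, 10)
  }
  agents <- data.frame(id = 1:40, row = rep(2:9, 5), col = rep(2:9, 5),
                       homeDistrict = "A", ethnicity = NA, clan = "A",
                       state = "PASTORALIST", failedDeals = 0L)
  cfg <- simulationConfig(behaviorSeed = 9L, pDeal = 0.3,
                          scoutMinKm = 2, scoutMaxKm = 4, nTicks = 14L)
  sim <- runSimulation(stacks, agents, cfg)
  ts <- tickSummary(sim)
  # conservation and monotone decline
  expect_equal(ts$activeCount + cumsum(ts$droppedCount), rep(40, 14))
  expect_true(all(diff(ts$activeCount) <= 0))
  traj <- trajectory(sim)
  # one row per active agent per tick; dropped ids never reappear
  expect_equal(nrow(traj), sum(ts$activeCount) + sum(ts$droppedCount))
  for (id in unique(traj$id[traj$event == "DROPPED_OUT"])) {
    tDrop <- traj$tick[traj$id == id & traj$event == "DROPPED_OUT"]
    expect_equal(max(traj$tick[traj$id == id]), tDrop)
  }
  # bit-identical reruns
  sim2 <- runSimulation(stacks, agents, cfg)
  expect_identical(trajectory(sim2), traj)
  # different behavior seed: same starts, different paths
  cfg3 <- simulationConfig(behaviorSeed = 10L, pDeal = 0.3,
                           scoutMinKm = 2, scoutMaxKm = 4, nTicks = 14L)
  sim3 <- runSimulation(stacks, agents, cfg3)
  expect_identical(sim3@agentsStart, sim@agentsStart)
  expect_false(identical(trajectory(sim3), traj))
  # deal probability 1: nobody ever drops out
  cfg4 <- simulationConfig(behaviorSeed = 9L, pDeal = 1,
                           scoutMinKm = 2, scoutMaxKm = 4, nTicks = 14L)
  sim4 <- runSimulation(stacks, agents, cfg4)
  expect_equal(tickSummary(sim4)$activeCount, rep(40, 14))
  expect_false(any(trajectory(sim4)$event == "DROPPED_OUT"))
})

test_that("on a uniform all-public landscape agents move only at season turns", {
  stacks <- flatStackSeries(9, nr = 8, nc = 8)
  agents <- data.frame(id = 1:5, row = c(3, 4, 5, 6, 4),
                       col = c(3, 4, 5, 3, 6), homeDistrict = "A",
                       ethnicity = NA, clan = "A", state = "PASTORALIST",
                       failedDeals = 0L)
  cfg <- simulationConfig(behaviorSeed = 3L, nTicks = 9L,
                          scoutMinKm = 2, scoutMaxKm = 4)
  traj <- trajectory(runSimulation(stacks, agents, cfg))
  boundaries <- c(4, 7)  # Gu starts in April, Hagaa in July
  expect_true(all(traj$event[traj$tick %in% boundaries] ==
                    "FORCED_RELOCATE"))
  expect_true(all(traj$event[!traj$tick %in% boundaries] == "STAYED"))
  # per-tick displacement bounded by the scouting radius
  for (id in agents$id) {
    tr <- traj[traj$id == id, ]
    d <- sqrt(diff(tr$row)^2 + diff(tr$col)^2)  # cells of 1 km
    expect_true(all(d <= 4 + sqrt(2) + 1e-9))
  }
})
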