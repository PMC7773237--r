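test_that("computeSavi matches hand-evaluated values", {
  g <- function(x) smallGrid(matrix(x, 1, 1))
  expect_equal(gridValues(computeSavi(g(0.3), g(0.3))), matrix(0, 1, 1))
  expect_equal(gridValues(computeSavi(g(0.4), g(0.2))),
               matrix(1.5 * 0.2 / 1.1, 1, 1))
  expect_equal(gridValues(computeSavi(g(1), g(0))), matrix(1, 1, 1))
  # zero denominator becomes nodata
  expect_true(is.na(gridValues(computeSavi(g(0), g(0), L = 0))))
  expect_error(computeSavi(g(1), smallGrid(matrix(0, 2, 2))), "aligned")
  expect_error(computeSavi(g(1), g(1), L = -1), "non-negative")
})

test_that("seasonal median composites ignore nodata per cell", {
  s1 <- smallGrid(matrix(c(0.1, 0.2, NA, NA), 2, 2))
  s2 <- smallGrid(matrix(c(0.5, NA, 0.6, NA), 2, 2))
  s3 <- smallGrid(matrix(c(0.9, 0.2, 0.8, NA), 2, 2))
  s4 <- smallGrid(matrix(c(0.5, 0.2, 0.2, NA), 2, 2))
  med <- gridValues(seasonalMedianComposite(list(s1, s2, s3, s4)))
  expect_equal(med[1, 1], 0.5)    # odd after removing none: {.1,.5,.9,.5}->.5
  expect_equal(med[2, 1], 0.2)    # median of the 3 present values
  expect_equal(med[1, 2], 0.6)    # {NA,.6,.8,.2} -> 0.6
  expect_true(is.na(med[2, 2]))   # nodata everywhere
  one <- seasonalMedianComposite(list(s1))
  expect_equal(gridValues(one), gridValues(s1))
  expect_error(seasonalMedianComposite(list()), "empty")
})

test_that("conflict surfaces score current and lagged events correctly", {
  template <- smallGrid(matrix(0, 4, 4))
  gu <- seasonId("Gu", 2008)
  ev <- function(month, year) data.frame(x = 2500, y = 1500,
                                         year = year, month = month)
  none <- conflictSurface(data.frame(x = numeric(0), y = numeric(0),
                                     year = integer(0), month = integer(0)),
                          gu, template, globalMax = 2)
  expect_equal(gridValues(none), matrix(0, 4, 4))
  # one event this season, global max 2 -> 0.5 at that cell
  cur <- conflictSurface(ev(5, 2008), gu, template, globalMax = 2)
  expect_equal(gridValues(cur)[3, 3], 0.5)
  expect_equal(sum(gridValues(cur)), 0.5)
  # one event only in the preceding season -> half effect: 0.25
  lag <- conflictSurface(ev(2, 2008), gu, template, globalMax = 2)
  expect_equal(gridValues(lag)[3, 3], 0.25)
  # lagWeight 0 kills the carry-over entirely
  lag0 <- conflictSurface(ev(2, 2008), gu, template, lagWeight = 0,
                          globalMax = 2)
  expect_equal(gridValues(lag0), matrix(0, 4, 4))
  expect_error(conflictSurface(ev(5, 2008), gu, template, lagWeight = -0.1,
                               globalMax = 2), "lagWeight")
  expect_message(conflictSurface(data.frame(x = 1e6, y = 1e6, year = 2008,
                                            month = 5),
                                 gu, template, globalMax = 2), "dropped")
})

test_that("with no current events the surface is lagWeight times last season's", {
  template <- smallGrid(matrix(0, 5, 5))
  set.seed(7)
  prevEv <- data.frame(x = runif(12, 0, 5000), y = runif(12, 0, 5000),
                       year = 2008, month = sample(1:3, 12, TRUE))
  gu <- seasonId("Gu", 2008); jilaal <- seasonId("Jilaal", 2008)
  G <- 10  # large enough that nothing clips
  lagged <- conflictSurface(prevEv, gu, template, lagWeight = 0.5,
                            globalMax = G)
  base <- conflictSurface(prevEv, jilaal, template, lagWeight = 0.5,
                          globalMax = G)
  expect_equal(gridValues(lagged), 0.5 * gridValues(base))
})

test_that("conflictGlobalMax is the max lag-weighted cell score over the window", {
  template <- smallGrid(matrix(0, 4, 4))
  # 3 events in one cell in Jilaal, 1 event same cell in Gu: Gu raw = 1+0.5*3
  ev <- data.frame(x = rep(500, 4), y = rep(500, 4), year = 2008,
                   month = c(1, 2, 3, 5))
  seasons <- list(seasonId("Jilaal", 2008), seasonId("Gu", 2008))
  expect_equal(conflictGlobalMax(ev, seasons, template), 3)
  expect_equal(conflictGlobalMax(ev[ev$month == 5, , drop = FALSE],
                                 seasons, template), 1)  # floor of 1
})

test_that("ethnic border rings score 1 / 0.5 / 0.25 / 0 by distance", {
  template <- rasterGrid(matrix(0, 3, 50), 1000, c(0, 3000))
  border <- matrix(c(25000, -1e5, 25000, 1e5), 1)  # vertical line x = 25 km
  out <- gridValues(ethnicBorderSurface(border, template))
  row <- out[2, ]
  centers <- (1:50 - 0.5) * 1000
  dist <- abs(centers - 25000)
  expect_equal(row[26], 1.0)              # crossed cell
  expect_equal(row[20], 0.5)              # 5.5 km: first ring
  expect_equal(row[10], 0.25)             # 15.5 km: second ring
  expect_equal(row[48], 0)                # 22.5 km: outside
  # non-increasing in distance to the border
  ord <- order(dist)
  expect_true(all(diff(row[ord]) <= 1e-12))
  expect_warning(zero <- ethnicBorderSurface(matrix(numeric(0), 0, 4),
                                             template), "empty")
  expect_equal(gridValues(zero), matrix(0, 3, 50))
})

test_that("water layers honor the dry-season shutdown and count points", {
  mask <- smallGrid(matrix(c(1, 0, 1, 0), 2, 2))
  pts <- data.frame(x = c(500, 1500, 1500), y = c(1500, 500, 500))
  dry <- waterLayers(mask, pts, seasonId("Jilaal", 2008))
  expect_equal(gridValues(dry$v2), matrix(0, 2, 2))
  wet <- waterLayers(mask, pts, seasonId("Gu", 2008))
  expect_equal(gridValues(wet$v2), gridValues(mask))
  # counts {1, 0, 0, 2} normalize to {0.5, 0, 0, 1}
  expect_equal(gridValues(wet$v3)[1, 1], 0.5)
  expect_equal(gridValues(wet$v3)[2, 2], 1.0)
  expect_equal(gridValues(wet$v3)[1, 2], 0)
})

test_that("slope from a tilted plane matches the analytic gradient", {
  nr <- 6; nc <- 8
  z <- matrix(rep(100 * (1:nc), each = nr), nr, nc)  # +100 m per 1 km cell
  elev <- smallGrid(z)
  deg <- gridValues(slopeSurface(elev, normalize = FALSE))
  expect_equal(deg[2:(nr - 1), 2:(nc - 1)],
               matrix(atan(0.1) * 180 / pi, nr - 2, nc - 2))
  flat <- slopeSurface(smallGrid(matrix(7, 5, 5)), normalize = FALSE)
  expect_equal(gridValues(flat), matrix(0, 5, 5))
  norm <- gridValues(slopeSurface(elev))
  expect_equal(max(norm), 1)
  expect_error(slopeSurface(smallGrid(matrix(0, 2, 2))), "3 x 3")
})

test_that("tenure mask applies the 14 km city / 4 km town radii", {
  template <- rasterGrid(matrix(0, 1, 30), 1000, c(0, 1000))
  city <- data.frame(x = 500, y = 500, sizeClass = "city")
  town <- data.frame(x = 500, y = 500, sizeClass = "town")
  mc <- gridValues(tenureMask(city, template))
  mt <- gridValues(tenureMask(town, template))
  expect_equal(mc[1, 11], 1)  # 10 km from the city: private
  expect_equal(mc[1, 16], 0)  # 15 km: public
  expect_equal(mt[1, 11], 0)  # 10 km from a town only: public
  expect_equal(mt[1, 4], 1)   # 3 km: private
  none <- tenureMask(data.frame(x = numeric(0), y = numeric(0),
                                sizeClass = character(0)), template)
  expect_equal(gridValues(none), matrix(0, 1, 30))
})

test_that("favorability is the signed additive score with a suitability sentinel", {
  mk <- function(v1, v2, v3, v4, v5, v6, suit = 1) {
    z <- function(x) smallGrid(matrix(x, 2, 2))
    environmentStack(z(v1), z(v2), z(v3), z(v4), z(v5), z(v6),
                     z(0), z(suit), seasonId("Gu", 2008))
  }
  expect_equal(gridValues(favorabilitySurface(mk(0, 0, 0, 0, 0, 0))),
               matrix(0, 2, 2))
  expect_equal(gridValues(favorabilitySurface(mk(1, 1, 1, 0, 0, 0))),
               matrix(3, 2, 2))
  expect_equal(gridValues(favorabilitySurface(mk(0, 0, 0, 1, 1, 1))),
               matrix(-1.5, 2, 2))
  expect_equal(gridValues(favorabilitySurface(mk(1, 0, 0, 0, 0, 0,
                                                 suit = 0))),
               matrix(UNSUITABLE_SCORE, 2, 2))
})

test_that("favorability is monotone in each component layer", {
  set.seed(11)
  z <- function(x) smallGrid(matrix(x, 3, 3))
  vals <- lapply(1:6, function(i) matrix(runif(9, 0.2, 0.8), 3, 3))
  mkStack <- function(vals) environmentStack(
    smallGrid(vals[[1]]), smallGrid(vals[[2]]), smallGrid(vals[[3]]),
    smallGrid(vals[[4]]), smallGrid(vals[[5]]), smallGrid(vals[[6]]),
    z(0), z(1), seasonId("Gu", 2008))
  base <- gridValues(favorabilitySurface(mkStack(vals)))
  for (i in 1:6) {
    v2 <- vals
    v2[[i]] <- pmin(v2[[i]] + 0.1, 1)
    pert <- gridValues(favorabilitySurface(mkStack(v2)))
    if (i <= 3) expect_true(all(pert >= base - 1e-12))
    else expect_true(all(pert <= base + 1e-12))
  }
})
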