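refCounts <- read.csv(refPath("reference_district_counts.csv"),
                      stringsAsFactors = FALSE, check.names = FALSE)
refSde <- read.csv(refPath("reference_sde.csv"), stringsAsFactors = FALSE)

test_that("district counts assign containment and exclude outside points", {
  d <- twoSquareDistricts(1000)
  pts <- data.frame(x = c(200, 500, 900, 1200, 1800, 5000),
                    y = c(200, 500, 900, 500, 800, 5000))
  res <- districtCounts(pts, d)
  expect_equal(res$counts, c(A = 3L, B = 2L))
  expect_equal(res$outside, 1L)
  expect_equal(sum(res$counts) + res$outside, nrow(pts))
  # a point on the shared border goes to the first district in order
  border <- districtCounts(data.frame(x = 1000, y = 500), d)
  expect_equal(border$counts, c(A = 1L, B = 0L))
})

test_that("count change reproduces the published per-district differences", {
  jan08 <- setNames(refCounts$jan2008, refCounts$district)
  oct18 <- setNames(refCounts$oct2018, refCounts$district)
  change <- countChange(jan08, oct18)
  expect_equal(unname(change["Woqooyi Galbeed"]), -3445)
  expect_equal(unname(change["Sanaag"]), -2871)
  expect_equal(unname(change["Nugaal"]), -114)
  expect_equal(unname(change), refCounts$totalDifference)
  expect_equal(countChange(jan08, jan08), setNames(rep(0, 7),
                                                   names(jan08)))
  expect_error(countChange(jan08, oct18[-1]), "mismatch")
})

test_that("range span finds the published most/least populated districts", {
  jan08 <- setNames(refCounts$jan2008, refCounts$district)
  rs <- rangeSpan(jan08)
  expect_equal(rs$maxDistrict, "Sanaag")
  expect_equal(rs$minDistrict, "Bari")
  expect_equal(rs$span, 2285)
  oct18 <- setNames(refCounts$oct2018, refCounts$district)
  rs2 <- rangeSpan(oct18)
  expect_equal(rs2$maxDistrict, "Togdheer")
  expect_equal(rs2$minDistrict, "Woqooyi Galbeed")
  expect_equal(rs2$span, 2479)
  expect_equal(rangeSpan(c(only = 5))$span, 0)
})

test_that("Jenks breaks split the classic well-separated example", {
  expect_equal(jenksBreaks(c(1, 2, 3, 10, 11, 12), 2), 3)
  expect_equal(jenksBreaks(c(11, 3, 1, 12, 2, 10), 2), 3)  # order-invariant
  expect_length(jenksBreaks(1:5, 1), 0)
  expect_error(jenksBreaks(c(1, 1, 2), 3), "distinct")
  cls <- jenksClassify(c(1, 2, 3, 10, 11, 12), 3)
  expect_equal(cls, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("Jenks dynamic program equals exhaustive-search optimum", {
  bruteCost <- function(x, k) {
    x <- sort(x); n <- length(x)
    ssd <- function(v) sum((v - mean(v))^2)
    best <- Inf
    for (splits in asplit(combn(n - 1, k - 1), 2)) {
      bounds <- c(0, splits, n)
      cost <- sum(vapply(seq_len(k), function(i)
        ssd(x[(bounds[i] + 1):bounds[i + 1]]), numeric(1)))
      best <- min(best, cost)
    }
    best
  }
  dpCost <- function(x, k) {
    b <- jenksBreaks(x, k)
    cls <- jenksClassify(sort(x), b)
    sum(vapply(unique(cls), function(i) {
      v <- sort(x)[cls == i]; sum((v - mean(v))^2)
    }, numeric(1)))
  }
  set.seed(9)
  for (rep in 1:6) {
    n <- sample(6:12, 1); k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k) next
    expect_equal(dpCost(x, k), bruteCost(x, k), tolerance = 1e-9)
  }
})

test_that("kernel density matches the quadratic kernel pointwise", {
  # single unit point: value at the point is 3/(pi r^2) per m^2
  tpl <- rasterGrid(matrix(0, 3, 3), 1000, c(-1500, 1500))
  d <- kernelDensity(data.frame(x = 0, y = 0), 1000, template = tpl)
  expect_equal(gridValues(d)[2, 2], 3 / pi, tolerance = 1e-12)  # per km^2
  # zero at the support edge and beyond
  tpl2 <- rasterGrid(matrix(0, 1, 3), 1000, c(-500, 500))
  d2 <- kernelDensity(data.frame(x = -500, y = 0), 1000, template = tpl2)
  expect_equal(gridValues(d2)[1, 2], 0)   # center exactly at radius
  expect_equal(gridValues(d2)[1, 3], 0)
})

test_that("kernel density conserves mass and is linear in weights", {
  pts <- data.frame(x = c(0, 2000, -1500), y = c(0, 500, -2500),
                    pop = c(1, 2, 3))
  d <- kernelDensity(pts, 3000, cellSize = 100)
  cellAreaKm2 <- (100 / 1000)^2
  mass <- sum(gridValues(d)) * cellAreaKm2
  expect_equal(mass, sum(pts$pop), tolerance = 0.005)
  pts2 <- pts; pts2$pop <- 2 * pts$pop
  d2 <- kernelDensity(pts2, 3000, cellSize = 100)
  expect_equal(gridValues(d2), 2 * gridValues(d))
})

test_that("kd stats use the population-sd convention", {
  expect_equal(unname(kdStats(smallGrid(matrix(0, 2, 2)))), c(0, 0, 0, 0))
  expect_equal(unname(kdStats(smallGrid(matrix(3, 2, 2)))), c(3, 3, 3, 0))
  st <- kdStats(smallGrid(matrix(c(0, 0, 1, 1), 2, 2)))
  expect_equal(unname(st), c(0, 1, 0.5, 0.5))
})

test_that("the deviational ellipse matches the symmetric-cross closed form", {
  d <- 4000
  pts <- data.frame(x = c(d, -d, 0, 0), y = c(0, 0, d, -d))
  sde <- standardDeviationalEllipse(pts, nSd = 2)
  sigma <- d / sqrt(2)
  expect_equal(sde@centroid, c(0, 0))
  expect_equal(sde@semiAxes, rep(2 * sigma, 2))
  expect_equal(sde@area, pi * (2 * sigma)^2 / 1e6)
})

test_that("collinear east-west points give rotation 90 and a degenerate ellipse", {
  pts <- data.frame(x = c(-3, -1, 2, 5) * 1000, y = rep(0, 4))
  expect_warning(sde <- standardDeviationalEllipse(pts), "collinear")
  expect_equal(sde@rotationDeg, 90)
  expect_equal(sde@semiAxes[2], 0)
  expect_equal(sde@area, 0)
  expect_error(standardDeviationalEllipse(data.frame(x = 1, y = 1)),
               "at least 2")
})

test_that("the ellipse is equivariant under translation and rotation", {
  set.seed(21)
  pts <- data.frame(x = rnorm(300, sd = 2000) + rnorm(300, sd = 500),
                    y = rnorm(300, sd = 800))
  base <- standardDeviationalEllipse(pts)
  shifted <- standardDeviationalEllipse(
    data.frame(x = pts$x + 5e5, y = pts$y - 2e5))
  expect_equal(shifted@centroid, base@centroid + c(5e5, -2e5))
  expect_equal(shifted@area, base@area)
  expect_equal(shifted@rotationDeg, base@rotationDeg)
  theta <- 30 * pi / 180  # counterclockwise rotation of the points
  rot <- data.frame(x = pts$x * cos(theta) - pts$y * sin(theta),
                    y = pts$x * sin(theta) + pts$y * cos(theta))
  rsde <- standardDeviationalEllipse(rot)
  expect_equal(rsde@area, base@area, tolerance = 1e-9)
  expect_equal((base@rotationDeg - 30) %% 180, rsde@rotationDeg,
               tolerance = 1e-6)
})

test_that("the 2-SD ellipse contains most of an isotropic normal sample", {
  set.seed(5)
  pts <- data.frame(x = rnorm(4000, sd = 1000), y = rnorm(4000, sd = 1000))
  sde <- standardDeviationalEllipse(pts, nSd = 2)
  e <- eigen(matrix(c(var(pts$x), cov(pts$x, pts$y),
                      cov(pts$x, pts$y), var(pts$y)), 2), symmetric = TRUE)
  xt <- pts$x - sde@centroid[1]; yt <- pts$y - sde@centroid[2]
  u <- (xt * e$vectors[1, 1] + yt * e$vectors[2, 1]) / sde@semiAxes[1]
  v <- (xt * e$vectors[1, 2] + yt * e$vectors[2, 2]) / sde@semiAxes[2]
  frac <- mean(u^2 + v^2 <= 1)
  expect_gte(frac, 0.85)   # Rayleigh: 1 - exp(-2) ~ 0.865
  expect_lte(frac, 0.98)
})

test_that("SDE summaries reproduce the published areal statistics", {
  a2008 <- refSde$areaKm2[refSde$year == 2008]
  a2018 <- refSde$areaKm2[refSde$year == 2018]
  s2008 <- sdeSummary(a2008)
  s2018 <- sdeSummary(a2018)
  expect_equal(s2008$meanArea, 594767)
  expect_equal(s2008$areaSpan, 21859)
  expect_equal(s2018$meanArea, 501781)
  expect_equal(s2018$areaSpan, 4109)
  expect_equal(s2008$meanArea - s2018$meanArea, 92986)
  expect_equal(sdeSummary(c(5, 5, 5))$areaSpan, 0)
})
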