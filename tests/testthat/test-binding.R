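test_that("quadratic-root complex concentration matches a bisection oracle", {
  # mass balance: Kd x = (F_T/n - x)(L_T - x); bisection on 10,000 draws
  set.seed(101)
  n_draws <- 10000
  ft <- runif(n_draws, 0, 1000)
  lt <- runif(n_draws, 1, 500)
  kd <- runif(n_draws, 0.01, 300)
  nn <- sample(1:5, n_draws, replace = TRUE)
  x <- mapply(function(f, l, k, n)
    boundFraction(f, l, k, 1, n)$complex, ft, lt, kd, nn)
  lo <- rep(0, n_draws)
  hi <- pmin(ft / nn, lt)
  g <- function(v) kd * v - (ft / nn - v) * (lt - v)
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
  }
  expect_lt(max(abs(x - (lo + hi) / 2)), 1e-9)
})

test_that("stoichiometric limit and division guard behave as specified", {
  # kd -> 0 with excess sites: all ligand bound, f_obs = f_max
  out <- boundFraction(600, 100, kd = 1e-12, fMax = 0.7, n = 3)
  expect_equal(out$complex, 100, tolerance = 1e-6)
  expect_equal(out$fObs, 0.7, tolerance = 1e-8)
  expect_error(boundFraction(100, 0, 10, 0.5, 3), "division guard")
  expect_error(boundFraction(-1, 10, 10, 0.5, 3), "input error")
})

test_that("f_obs is monotone in fiber concentration and saturates at f_max", {
  f <- boundFraction(seq(0, 5000, by = 25), 100, kd = 24, fMax = 0.82,
                     n = 3)$fObs
  expect_true(all(diff(f) >= -1e-12))
  f_inf <- boundFraction(1e9 * 24 * 3, 100, kd = 24, fMax = 0.82, n = 3)$fObs
  expect_equal(f_inf, 0.82, tolerance = 1e-6)
})

test_that("noiseless titrations from published-scale parameters refit exactly", {
  # 10-point designs; (kd, fmax) pairs at the three reference scales
  cases <- list(
    list(kd = 43, fmax = 0.46, lt = 50, hi = 950),
    list(kd = 12, fmax = 0.47, lt = 100, hi = 500),
    list(kd = 24, fmax = 0.82, lt = 100, hi = 500))
  for (cs in cases) {
    s <- simulateTitration(cs$kd, cs$fmax, 3, cs$lt,
                           seq(0, cs$hi, length.out = 10))
    fit <- fitKd(s, n = 3)
    expect_equal(kdValue(fit), cs$kd, tolerance = 1e-4)
    expect_equal(fMaxValue(fit), cs$fmax, tolerance = 1e-4)
  }
})

test_that("titration simulation is exact when noiseless and calibrated when noisy", {
  grid <- seq(0, 500, length.out = 10)
  s0 <- simulateTitration(24, 0.82, 3, 100, grid)
  expect_equal(s0@fractionalDecreases,
               boundFraction(grid, 100, 24, 0.82, 3)$fObs, tolerance = 1e-12)
  # Monte Carlo moment check on the injected noise
  resid <- unlist(lapply(1:200, function(sd) {
    s <- simulateTitration(24, 0.4, 3, 100, grid[-1], noiseSd = 0.02,
                           seed = sd)
    s@fractionalDecreases - boundFraction(grid[-1], 100, 24, 0.4, 3)$fObs
  }))
  expect_equal(sd(resid), 0.02, tolerance = 0.1)
  # determinism by seed
  s1 <- simulateTitration(24, 0.4, 3, 100, grid, noiseSd = 0.02, seed = 7)
  s2 <- simulateTitration(24, 0.4, 3, 100, grid, noiseSd = 0.02, seed = 7)
  expect_identical(s1@fractionalDecreases, s2@fractionalDecreases)
})

test_that("non-identifiable or degenerate series raise fit failures", {
  flat <- new("TitrationSeries", ligandTotal = 100,
              fiberTotals = c(10, 20, 30, 40),
              fractionalDecreases = rep(0.5, 4))
  expect_error(fitKd(flat), "fit failure")
  short <- new("TitrationSeries", ligandTotal = 100,
               fiberTotals = c(10, 20), fractionalDecreases = c(0.1, 0.2))
  expect_error(fitKd(short), ">= 3")
})

test_that("rescue percentage anchors, table-derived values and affine invariance", {
  expect_equal(rescuePercentage(0.40, 0.40), 0)       # floor anchor
  expect_equal(rescuePercentage(1.0, 0.40), 100)      # ceiling anchor
  # viability summary shipped with the package: HeLa fiber-alone 0.40
  tab <- read.csv(system.file("extdata", "mtt_viability_example.csv",
                              package = "fibscreen"))
  hela <- tab[tab$cell_line == "HeLa", ]
  base <- hela$mean_viability[hela$condition == "fiber_alone"]
  r <- function(cond) round(rescuePercentage(
    hela$mean_viability[hela$condition == cond], base))
  expect_equal(r("BAF4"), 88)
  expect_equal(r("BAF11"), 48)
  expect_equal(r("BAF30"), 18)
  pc <- tab[tab$cell_line == "PC12", ]
  expect_equal(round(rescuePercentage(
    pc$mean_viability[pc$condition == "BAF31"],
    pc$mean_viability[pc$condition == "fiber_alone"])), 92)
  # affine invariance under a common positive rescaling
  expect_equal(rescuePercentage(0.66 * 3, 0.40 * 3, 1.0 * 3),
               rescuePercentage(0.66, 0.40, 1.0))
  expect_error(rescuePercentage(0.5, 0.9, 0.8), "input error")
})

test_that("summary-statistic t test matches an oracle built from raw data", {
  # identical groups: t = 0, p = 1
  null_case <- groupTTest(0.5, 0.1, 4, 0.5, 0.1, 4)
  expect_equal(null_case$t, 0)
  expect_equal(null_case$p, 1)
  # construct raw samples with exactly the requested mean and sd, then
  # compare against stats::t.test
  mk <- function(m, s, n) {
    x <- rnorm(n)
    m + s * (x - mean(x)) / sd(x)
  }
  set.seed(5)
  x1 <- mk(0.66, 0.04, 4)
  x2 <- mk(0.40, 0.05, 4)
  pooled <- groupTTest(0.66, 0.04, 4, 0.40, 0.05, 4, variant = "pooled")
  ref_p <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref_p$statistic), tolerance = 1e-9)
  expect_equal(pooled$p, ref_p$p.value, tolerance = 1e-9)
  expect_equal(pooled$t, 8.12, tolerance = 0.01)  # the worked example scale
  welch <- groupTTest(0.66, 0.04, 4, 0.40, 0.05, 4, variant = "welch")
  ref_w <- t.test(x1, x2)
  expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-9)
  expect_equal(welch$p, ref_w$p.value, tolerance = 1e-9)
  expect_error(groupTTest(1, 0.1, 1, 1, 0.1, 4), "input error")
})

test_that("titration CSV reader handles fractional and raw-area input", {
  tf <- tempfile(fileext = ".csv")
  grid <- seq(0, 500, length.out = 10)
  s <- simulateTitration(24, 0.82, 3, 100, grid)
  write.csv(data.frame(fiber_uM = grid, ligand_uM = 100,
                       fractional_decrease = s@fractionalDecreases),
            tf, row.names = FALSE)
  s2 <- readTitrationCsv(tf)
  expect_equal(s2@fractionalDecreases, s@fractionalDecreases)
  expect_equal(s2@ligandTotal, 100)
  # raw areas: A = A_L (1 - f)
  tf2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(fiber_uM = grid, ligand_uM = 100,
                       peak_area = 1000 * (1 - s@fractionalDecreases)),
            tf2, row.names = FALSE)
  s3 <- readTitrationCsv(tf2)
  expect_equal(s3@fractionalDecreases, s@fractionalDecreases[-1],
               tolerance = 1e-12)
})
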