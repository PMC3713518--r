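toy_results <- function() {
  # constructed component values with known per-component rankings
  set.seed(42)
  n <- 10
  data.frame(
    id = sprintf("cmp%02d", 1:n),
    lj_attractive = c(-9, -8, -7.5, -7, -6.5, -10, -11, -7.2, -5, -12),
    lj_repulsive = c(0.5, 1, 0.2, 0.8, 0.3, 2, 0.1, 0.6, 0.4, 0.9),
    hbond = c(-1, -0.5, -0.1, -2, -0.3, -1.5, -0.05, -0.8, -3, -0.25),
    electrostatics = c(-0.2, 0.1, -0.5, -1, 0.2, -0.8, 0, -0.4, -0.6, -1.2),
    solvation = c(-0.1, -0.2, 0, -0.5, -0.3, -0.4, -0.15, -0.25, -0.05, -0.6),
    stringsAsFactors = FALSE)
}

test_that("hard filters remove poses above either energy bound", {
  r <- toy_results()
  r$total <- rowSums(r[, 2:6])
  out <- applyHardFilters(r, filterConfig())
  # lj_attractive = -6.5 removed, hbond = -0.1 removed (bounds -7.0 / -0.2)
  expect_false("cmp05" %in% out$id)  # lj -6.5
  expect_false("cmp03" %in% out$id)  # hbond -0.1
  expect_false("cmp07" %in% out$id)  # hbond -0.05
  # hand tally of survivors
  expect_setequal(out$id, c("cmp01", "cmp02", "cmp04", "cmp06", "cmp08",
                            "cmp10"))
  # idempotent and a subset
  expect_identical(applyHardFilters(out, filterConfig()), out)
  expect_true(all(out$id %in% r$id))
  # empty input -> empty output
  expect_equal(nrow(applyHardFilters(r[0, ], filterConfig())), 0)
})

test_that("component top-fraction selection matches a manual rank intersection", {
  r <- toy_results()
  r$total <- rowSums(r[, 2:6])
  out <- componentTopfraction(r, filterConfig())
  # manual oracle: intersect per-component top-4 (ceiling(0.4 * 10)) sets
  k <- ceiling(0.4 * nrow(r))
  manual <- Reduce(intersect, list(
    r$id[order(r$total, r$id)][1:k],
    r$id[order(r$lj_attractive + r$lj_repulsive, r$id)][1:k],
    r$id[order(r$solvation, r$id)][1:k],
    r$id[order(r$hbond, r$id)][1:k],
    r$id[order(r$electrostatics, r$id)][1:k]))
  expect_setequal(out$id, manual)
  # single result is trivially in the top fraction
  one <- componentTopfraction(r[1, ], filterConfig())
  expect_equal(nrow(one), 1)
  # survivor count bounded by ceil(0.4 n) for any single component
  expect_lte(nrow(out), k)
})

test_that("final ranking orders by binding energy, then Sc, then id", {
  r <- data.frame(
    id = c("e", "d", "c", "b", "a"),
    binding_energy = c(-5, -8, -8, -2, -2),
    sc = c(0.5, 0.3, 0.7, 0.4, 0.4),
    stringsAsFactors = FALSE)
  out <- finalRank(r)
  # hand-sorted: c (-8, .7), d (-8, .3), e (-5), a (-2, .4), b (-2, .4)
  expect_equal(out$id, c("c", "d", "e", "a", "b"))
  expect_equal(out$rank, 1:5)
  # permuting input does not change ranks
  out2 <- finalRank(r[sample(5), ])
  expect_equal(out2$id, out$id)
})

test_that("shape complementarity is high for parallel flat surfaces at contact", {
  # two parallel, densely sampled slabs of carbon atoms facing each other
  grid <- expand.grid(y = seq(-4.5, 4.5, by = 0.75),
                      z = seq(-4.5, 4.5, by = 0.75))
  slab <- function(x) data.frame(
    elety = "C", elesy = "C", resid = "SLB", resno = 1L, strand = 0L,
    x = x, y = grid$y, z = grid$z, charge = 0, donor = FALSE,
    acceptor = FALSE, aromatic = FALSE, apolar = TRUE,
    stringsAsFactors = FALSE)
  lig_atoms <- data.frame(
    name = sprintf("C%d", seq_len(nrow(grid))), elesy = "C",
    x = 3.8, y = grid$y, z = grid$z, charge = 0, donor = FALSE,
    acceptor = FALSE, aromatic = FALSE, apolar = TRUE,
    stringsAsFactors = FALSE)
  lig <- new("Ligand", id = "slab", atoms = lig_atoms,
             bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                order = numeric(0), rotatable = logical(0)),
             rings = list())
  sc <- shapeComplementarity(slab(0), lig)
  expect_gt(sc, 0.8)
  # brute-force oracle: recompute the buried-interface median directly from
  # the definition (all sample pairs, burial cut at 2 A)
  sf <- fibscreen:::.surfacePoints(slab(0), 2)
  sl <- fibscreen:::.surfacePoints(ligandAtoms(lig), 2)
  d2x <- outer(rowSums(sf$points^2), rowSums(sl$points^2), "+") -
    2 * sf$points %*% t(sl$points)
  d2x[d2x < 0] <- 0
  dl <- sqrt(apply(d2x, 2, min))
  df <- sqrt(apply(d2x, 1, min))
  burial <- max(2, min(dl) + 0.5)
  s1 <- fibscreen:::.scSamples(sl$points[dl <= burial, , drop = FALSE],
                               sl$normals[dl <= burial, , drop = FALSE],
                               sf$points, sf$normals)
  s2 <- fibscreen:::.scSamples(sf$points[df <= burial, , drop = FALSE],
                               sf$normals[df <= burial, , drop = FALSE],
                               sl$points, sl$normals)
  expect_equal(sc, median(c(s1, s2)), tolerance = 1e-12)
})

test_that("anti-aligned surface normals give negative scores", {
  # constructed samples: coincident points whose normals point the same way
  # (anti-aligned facing): alignment = dot(n_a, -n_b) = -1
  pa <- matrix(c(0, 0, 0), 1, 3)
  na <- matrix(c(1, 0, 0), 1, 3)
  pb <- matrix(c(0.5, 0, 0), 1, 3)
  nb <- matrix(c(-1, 0, 0), 1, 3)  # facing -> +1
  expect_gt(fibscreen:::.scSamples(pa, na, pb, nb), 0.8)
  nb_anti <- matrix(c(1, 0, 0), 1, 3)
  expect_lt(fibscreen:::.scSamples(pa, na, pb, nb_anti), -0.8)
})

test_that("a distant ligand raises a no-interface error, not a zero score", {
  fib <- fix_fiber()
  pr <- fix_probe()
  far <- transformLigand(pr, diag(3), c(50, 0, 0))
  err <- tryCatch(shapeComplementarity(fib, far), error = identity)
  expect_s3_class(err, "noInterfaceError")
})
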