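test_that("hydrogen-bond window boundaries are inclusive at all six edges", {
  n_contacts <- function(d1, t1, t2) {
    s <- hb_setup(d1, t1, t2)
    nrow(hbondContacts(s$ligand, s$fiber))
  }
  # d1 edges (2.8, 3.5) inclusive; outside the window excluded
  expect_equal(n_contacts(2.8, 125, 160), 1)
  expect_equal(n_contacts(3.5, 125, 160), 1)
  expect_equal(n_contacts(2.79, 125, 160), 0)
  expect_equal(n_contacts(3.51, 125, 160), 0)
  # theta1 edges (100, 150)
  expect_equal(n_contacts(3.1, 100, 160), 1)
  expect_equal(n_contacts(3.1, 150, 160), 1)
  expect_equal(n_contacts(3.1, 99.4, 160), 0)
  expect_equal(n_contacts(3.1, 150.6, 160), 0)
  # theta2 edges (130, 180)
  expect_equal(n_contacts(3.1, 125, 130), 1)
  expect_equal(n_contacts(3.1, 125, 180), 1)
  expect_equal(n_contacts(3.1, 125, 129.4), 0)
})

test_that("spec example geometry counts as a contact and acceptor-free ligands give none", {
  s <- hb_setup(3.1, 125, 170)
  hb <- hbondContacts(s$ligand, s$fiber)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d1, 3.1, tolerance = 1e-9)
  expect_equal(hb$theta1, 125, tolerance = 1e-6)
  expect_equal(hb$theta2, 170, tolerance = 1e-6)
  # ligand with no acceptors -> empty
  ring <- micro_ring_ligand(c(3, 0, 0), c(1, 0, 0))
  expect_equal(nrow(hbondContacts(ring, s$fiber)), 0)
})

test_that("probe bridging two rail lysines yields exactly two contacts, matching a brute-force scan", {
  fib <- fix_fiber_ap()
  pr <- fix_probe()
  pose <- fix_pose()
  lig <- applyPose(pr, pose)
  hb <- hbondContacts(lig, fib)
  expect_equal(nrow(hb), 2)
  expect_setequal(hb$strand, c(0L, 2L))
  # brute-force oracle: enumerate every acceptor-NZ pair and apply the
  # windows directly
  fa <- fiberAtoms(fib)
  la <- ligandAtoms(lig)
  w <- geometryWindows()
  count <- 0
  for (i in which(la$acceptor)) {
    nb <- lig@bonds
    ante_i <- c(nb$a2[nb$a1 == i], nb$a1[nb$a2 == i])[1]
    nzs <- which(fa$elety == "NZ")
    for (k in nzs) {
      p_acc <- c(la$x[i], la$y[i], la$z[i])
      p_nz <- c(fa$x[k], fa$y[k], fa$z[k])
      d1 <- sqrt(sum((p_acc - p_nz)^2))
      ce <- fa[fa$strand == fa$strand[k] & fa$resno == fa$resno[k] &
               fa$elety == "CE", ]
      t1 <- fibscreen:::.angle3(c(la$x[ante_i], la$y[ante_i], la$z[ante_i]),
                                p_acc, p_nz)
      t2 <- fibscreen:::.angle3(c(ce$x, ce$y, ce$z), p_nz, p_acc)
      if (d1 >= w@d1[1] && d1 <= w@d1[2] && t1 >= w@theta1[1] &&
          t1 <= w@theta1[2] && t2 >= w@theta2[1] && t2 <= w@theta2[2]) {
        count <- count + 1
      }
    }
  }
  expect_equal(nrow(hb), count)
})

# a one-residue PHE fiber with its ring centered at `ctr`, ring normal +x
micro_phe_fiber <- function(ctr) {
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ang <- seq(0, 300, by = 60) * pi / 180
  rows <- list()
  pos <- list(N = c(-50, 0, 0), CA = c(-49, 0, 0), C = c(-48, 1, 0),
              O = c(-47, 1, 0), CB = c(-49, 1.5, 0))
  for (i in seq_along(ring_names)) {
    pos[[ring_names[i]]] <- ctr + 1.39 * c(0, cos(ang[i]), sin(ang[i]))
  }
  for (nm in names(pos)) {
    ann <- fibscreen:::.atomAnnotation("PHE", nm)
    rows[[length(rows) + 1]] <- data.frame(
      elety = nm, elesy = ann$elesy, resid = "PHE", resno = 1L, strand = 0L,
      x = pos[[nm]][1], y = pos[[nm]][2], z = pos[[nm]][3],
      charge = ann$charge, donor = ann$donor, acceptor = ann$acceptor,
      aromatic = ann$aromatic, apolar = ann$apolar, stringsAsFactors = FALSE)
  }
  new("FiberModel", atoms = do.call(rbind, rows), sequence = "F",
      registration = "in_register_parallel", rise = 4.8, shear = 0,
      axis = c(0, 0, 1))
}

test_that("stacking window boundaries are inclusive at the d2 and phi edges", {
  ctr <- c(2, 0, 0)
  fib <- micro_phe_fiber(ctr)
  frame <- new("SurfaceFrame", origin = ctr, normal = c(1, 0, 0),
               inPlane = cbind(c(0, 0, 1), c(0, 1, 0)))
  n_stack <- function(d2, phi) {
    nrm <- c(cos(phi * pi / 180), sin(phi * pi / 180), 0)
    ring <- micro_ring_ligand(ctr + c(d2, 0, 0), nrm)
    nrow(stackingContacts(ring, fib, frame = frame))
  }
  expect_equal(n_stack(4.0, 10), 1)
  expect_equal(n_stack(5.0, 10), 1)
  expect_equal(n_stack(3.99, 10), 0)
  expect_equal(n_stack(5.01, 10), 0)
  expect_equal(n_stack(4.5, 0), 1)
  expect_equal(n_stack(4.5, 40), 1)
  expect_equal(n_stack(4.5, 40.6), 0)
  # 10 A away -> empty; phi equals the hand-computed normal-normal angle
  expect_equal(n_stack(10, 10), 0)
  st <- stackingContacts(micro_ring_ligand(ctr + c(4.5, 0, 0),
                                           c(cos(0.3), sin(0.3), 0)),
                         fib, frame = frame)
  expect_equal(st$phi, 0.3 * 180 / pi, tolerance = 1e-6)
})

test_that("full pharmacophore check passes for the constructed probe pose and reports reasons on failure", {
  fib <- fix_fiber_ap()
  pr <- fix_probe()
  pose <- fix_pose()
  lig <- applyPose(pr, pose)
  rep <- checkPharmacophore(lig, fib)
  expect_true(rep@passes)
  expect_equal(rep@strandsSpanned, 3L)
  expect_gte(nrow(rep@stackContacts), 1)
  # displaced pose: single or no H-bond -> fails with min_lys_contacts
  lig_far <- transformLigand(lig, diag(3), c(6, 0, 0))
  rep2 <- checkPharmacophore(lig_far, fib)
  expect_false(rep2@passes)
  expect_true("min_lys_contacts" %in% rep2@failureReasons)
})

test_that("shrinking any window never converts a fail into a pass", {
  fib <- fix_fiber_ap()
  pr <- fix_probe()
  pose <- fix_pose()
  base <- applyPose(pr, pose)
  w1 <- geometryWindows()
  set.seed(99)
  for (i in 1:12) {
    lig <- transformLigand(base, fibscreen:::.rotAxis(rnorm(3), rnorm(1, 0, 6)),
                           rnorm(3, 0, 0.6))
    shrink <- function(iv, lo, hi) c(iv[1] + lo, iv[2] - hi)
    w2 <- geometryWindows(
      d1 = shrink(w1@d1, runif(1, 0, 0.2), runif(1, 0, 0.2)),
      theta1 = shrink(w1@theta1, runif(1, 0, 10), runif(1, 0, 10)),
      theta2 = shrink(w1@theta2, runif(1, 0, 10), runif(1, 0, 10)),
      d2 = shrink(w1@d2, runif(1, 0, 0.2), runif(1, 0, 0.2)),
      phi = c(w1@phi[1], w1@phi[2] - runif(1, 0, 10)),
      minLysContacts = w1@minLysContacts,
      strandSpan = w1@strandSpan)
    p1 <- checkPharmacophore(lig, fib, w1)@passes
    p2 <- checkPharmacophore(lig, fib, w2)@passes
    expect_false(p2 && !p1)
  }
})

test_that("register compatibility separates in-register from sheared rails", {
  fib_in <- fix_fiber()
  expect_equal(registerCompatibility(fib_in, 9.6, 0.5), "compatible")
  # shear chosen so the rail spacing is 12.0 A: sqrt(9.6^2 + (2s)^2) = 12
  s <- sqrt(12^2 - 9.6^2) / 2
  fib_out <- buildFiber("KLVFFA", 6, "out_of_register", shear = s)
  rail <- lysineRail(fib_out)
  d02 <- sqrt(sum((unlist(rail[rail$strand == 2, 3:5]) -
                   unlist(rail[rail$strand == 0, 3:5]))^2))
  expect_equal(d02, 12.0, tolerance = 1e-9)
  expect_equal(registerCompatibility(fib_out, 9.6, 0.5), "incompatible")
  # degenerate tolerance accepts anything
  expect_equal(registerCompatibility(fib_out, 9.6, Inf), "compatible")
  # too few rail entries
  expect_error(registerCompatibility(buildFiber("LVFFA", 6), 9.6, 0.5),
               "rail")
})

test_that("consensus pharmacophore averages features with the expected spread", {
  fib <- fix_fiber_ap()
  pr <- fix_probe()
  lig <- applyPose(pr, fix_pose())
  # singleton: consensus equals the pose's own features, spread 0
  c1 <- consensusPharmacophore(list(lig))
  a <- ligandAtoms(lig)
  expect_equal(c1$acceptor$centroid,
               colMeans(atom_xyz(a[a$acceptor, ])), tolerance = 1e-12)
  expect_equal(c1$acceptor$spread, 0)
  # two poses offset by a known vector: centroid at midpoint, spread = half
  off <- c(1.2, 0, 0)
  lig2 <- transformLigand(lig, diag(3), off)
  c2 <- consensusPharmacophore(list(lig, lig2))
  expect_equal(c2$acceptor$centroid,
               colMeans(atom_xyz(a[a$acceptor, ])) + off / 2,
               tolerance = 1e-12)
  expect_equal(c2$acceptor$spread, sqrt(sum((off / 2)^2)), tolerance = 1e-12)
  expect_equal(c2$ring$spread, sqrt(sum((off / 2)^2)), tolerance = 1e-12)
  # mixed frames error
  expect_error(consensusPharmacophore(list(lig, lig2),
                                      frames = c("seg", "full")), "mixed")
})
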