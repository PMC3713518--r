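# Shared fixtures, built in code at test time.

fix_fiber <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildFiber("KLVFFA", 6)
    cache
  }
})

fix_fiber_ap <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- buildFiber("KLVFFA", 6, "antiparallel")
    cache
  }
})

fix_probe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeProbeLigand(9.6, 10)
    cache
  }
})

# random proper rotation matrix
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d), 2*(b*d+a*c),
           2*(b*c+a*d), a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c), 2*(c*d+a*b), a^2-b^2-c^2+d^2),
         nrow = 3, byrow = TRUE)
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

# minimal hand-built FiberModel: one LYS per strand at controlled positions.
# nz_list / ce_list: per-strand NZ and CE coordinates.
micro_lys_fiber <- function(nz_list, ce_list, rise = 4.8) {
  rows <- list()
  for (s in seq_along(nz_list) - 1L) {
    nz <- nz_list[[s + 1]]
    ce <- ce_list[[s + 1]]
    far <- c(-50, -50, -50 + 4.8 * s)
    tmpl <- list(
      N = far + c(0, 0, 0), CA = far + c(1.5, 0, 0), C = far + c(2.5, 1, 0),
      O = far + c(3.5, 1, 0), CB = far + c(1.5, 1.5, 0),
      CG = far + c(2, 2.5, 0), CD = far + c(2, 3.5, 0),
      CE = ce, NZ = nz)
    for (nm in names(tmpl)) {
      ann <- fibscreen:::.atomAnnotation("LYS", nm)
      rows[[length(rows) + 1]] <- data.frame(
        elety = nm, elesy = ann$elesy, resid = "LYS", resno = 1L,
        strand = s, x = tmpl[[nm]][1], y = tmpl[[nm]][2], z = tmpl[[nm]][3],
        charge = ann$charge, donor = ann$donor, acceptor = ann$acceptor,
        aromatic = ann$aromatic, apolar = ann$apolar,
        stringsAsFactors = FALSE)
    }
  }
  new("FiberModel", atoms = do.call(rbind, rows), sequence = "K",
      registration = "in_register_parallel", rise = rise, shear = 0,
      axis = c(0, 0, 1))
}

# single-acceptor ligand: acceptor O at `acc`, antecedent C at `ante`.
micro_acceptor_ligand <- function(acc, ante) {
  atoms <- data.frame(
    name = c("C1", "O1"), elesy = c("C", "O"),
    x = c(ante[1], acc[1]), y = c(ante[2], acc[2]), z = c(ante[3], acc[3]),
    charge = c(0, -0.5), donor = FALSE, acceptor = c(FALSE, TRUE),
    aromatic = FALSE, apolar = c(TRUE, FALSE), stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = 1L, a2 = 2L, order = 1, rotatable = FALSE)
  new("Ligand", id = "micro", atoms = atoms, bonds = bonds, rings = list())
}

# flat hexagonal ring ligand centered at ctr with plane normal `normal`
micro_ring_ligand <- function(ctr, normal, radius = 1.4) {
  n <- fibscreen:::.unit(normal)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- fibscreen:::.unit(fibscreen:::.cross(n, ref))
  v <- fibscreen:::.cross(n, u)
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- t(vapply(ang, function(a) ctr + radius * (cos(a) * u + sin(a) * v),
                  numeric(3)))
  atoms <- data.frame(
    name = paste0("C", 1:6), elesy = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = 0, donor = FALSE, acceptor = FALSE, aromatic = TRUE,
    apolar = FALSE, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1.5,
                      rotatable = FALSE)
  new("Ligand", id = "ring", atoms = atoms, bonds = bonds, rings = list(1:6))
}

# cached window-satisfying probe pose on the antiparallel fiber (expensive)
fix_pose <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- idealProbePose(fix_fiber_ap(), fix_probe())
    cache
  }
})

# geometry constructor: single-lysine fiber at the origin with CE along -x;
# acceptor/antecedent placed to realize exact (d1, theta1, theta2)
hb_setup <- function(d1, theta1, theta2) {
  nz <- c(0, 0, 0)
  ce <- c(-1.5, 0, 0)
  b <- (180 - theta2) * pi / 180
  acc <- d1 * c(cos(b), sin(b), 0)
  w <- -c(cos(b), sin(b), 0)               # unit(NZ - acc)
  wp <- c(-w[2], w[1], 0)
  th <- theta1 * pi / 180
  ante <- acc + 1.4 * (cos(th) * w + sin(th) * wp)
  list(fiber = micro_lys_fiber(list(nz), list(ce)),
       ligand = micro_acceptor_ligand(acc, ante))
}

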