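# Charge assignment, the built-in solvers, interpolation, units, and the
# external-backend adapter contracts.

test_that("internal charge table yields integer residue charges", {
  p <- generate_peptide("AA", id = "diala")
  ch <- assign_charges_radii(p)
  rc <- residue_charges(ch)
  expect_true(all(abs(rc$charge - round(rc$charge)) < 1e-3))
  expect_equal(rc$charge, c(0, 0), tolerance = 1e-9)

  rc2 <- residue_charges(assign_charges_radii(generate_peptide("ADEKR")))
  expect_equal(rc2$charge, c(0, -1, -1, 1, 1), tolerance = 1e-9)
  expect_true(all(assign_charges_radii(p)$atoms$radius > 0))
})

test_that("unknown atoms in internal-table mode are reported by name", {
  p <- generate_peptide("AD")
  p$atoms$atom[p$atoms$atom == "CB"][1] <- "XQ1"
  err <- expect_error(assign_charges_radii(p),
                      class = "escapist_unmapped_atom")
  expect_match(conditionMessage(err), "XQ1")
})

test_that("PQR round trip preserves charges and radii", {
  ch <- assign_charges_radii(generate_peptide("ADFKS", id = "pqr"))
  path <- tempfile(fileext = ".pqr")
  write_pqr(ch, path)
  back <- parse_structure(path)
  expect_s3_class(back, "charged_structure")
  expect_equal(back$atoms$charge, ch$atoms$charge, tolerance = 1e-9)
  expect_equal(back$atoms$radius, ch$atoms$radius, tolerance = 1e-9)
})

test_that("zero charges give an identically zero field", {
  sys <- synthetic_charge_system("point", q = 0)
  f <- solve_potential(sys, solver_params(), mode = "uniform")
  expect_lt(max(abs(f$values)), 1e-12)
})

test_that("uniform-dielectric FD solution matches the Coulomb closed form", {
  sys <- synthetic_charge_system("point", q = 1, radius = 1)
  f <- solve_potential(sys, solver_params(), mode = "uniform")
  r <- 5
  want <- coulomb_constant(298) / (78 * r)
  for (pos in list(c(r, 0, 0), c(0, -r, 0), c(0, 0, r))) {
    expect_equal(potential_at(f, pos), want, tolerance = 0.05)
  }
})

test_that("two-dielectric FD solution matches the Born closed form", {
  pr <- solver_params()
  sys <- synthetic_charge_system("born", q = 1, radius = 2)
  f <- solve_potential(sys, pr, mode = "two_dielectric")
  C <- coulomb_constant(298)
  Rb <- 2 + pr$probe_radius          # dielectric boundary radius
  r_out <- Rb + 1
  expect_equal(potential_at(f, c(r_out, 0, 0)), C / (78 * r_out),
               tolerance = 0.10)
  # interior: Coulomb in eps_in plus the Born reaction-field constant
  r_in <- 1
  want_in <- C / (2 * r_in) + C * (1 / 78 - 1 / 2) / Rb
  expect_equal(potential_at(f, c(r_in, 0, 0)), want_in, tolerance = 0.10)
})

test_that("halving the grid spacing moves the Born surface potential < 5%", {
  sys <- synthetic_charge_system("born", q = 1, radius = 2)
  pos <- c(2 + 1.4 + 1, 0, 0)
  v1 <- potential_at(solve_potential(sys, solver_params(grid_spacing = 1.0)),
                     pos)
  v2 <- potential_at(solve_potential(sys, solver_params(grid_spacing = 0.5)),
                     pos)
  expect_lt(abs(v2 - v1) / abs(v2), 0.05)
})

test_that("solver failure to converge is a classed error", {
  sys <- synthetic_charge_system("point", q = 1)
  expect_error(
    solve_potential(sys, solver_params(max_iter = 1L, tol = 1e-12),
                    mode = "uniform"),
    class = "escapist_convergence_error"
  )
})

test_that("trilinear interpolation: node identity, edge midpoint, exact on linear fields", {
  f <- structure(
    list(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(2L, 2L, 2L),
         values = array(c(2, 4, 0, 0, 0, 0, 0, 0), dim = c(2, 2, 2)),
         units = "kT/e", temperature = 298),
    class = "potential_field"
  )
  expect_equal(potential_at(f, c(0, 0, 0)), 2)
  expect_equal(potential_at(f, c(1, 0, 0)), 4)
  expect_equal(potential_at(f, c(0.5, 0, 0)), 3)
  expect_error(potential_at(f, c(5, 0, 0)), class = "escapist_out_of_bounds")

  # phi(x, y, z) = a x + b y + c z + d is reproduced exactly
  dims <- c(9L, 7L, 8L)
  gx <- seq(0, by = 0.5, length.out = dims[1]) - 2
  gy <- seq(0, by = 0.5, length.out = dims[2]) - 1
  gz <- seq(0, by = 0.5, length.out = dims[3])
  vals <- outer(outer(1.3 * gx, -0.7 * gy, `+`), 0.2 * gz + 4, `+`)
  fl <- structure(
    list(origin = c(-2, -1, 0), spacing = c(0.5, 0.5, 0.5), dims = dims,
         values = vals, units = "kT/e", temperature = 298),
    class = "potential_field"
  )
  set.seed(2)
  pts <- cbind(runif(25, -2, 2), runif(25, -1, 2), runif(25, 0, 3.5))
  want <- 1.3 * pts[, 1] - 0.7 * pts[, 2] + 0.2 * pts[, 3] + 4
  expect_equal(potential_at(fl, pts), want, tolerance = 1e-12)
})

test_that("direct Coulomb potentials are rotation-invariant and linear in charge", {
  p <- generate_peptide("ADFKST", jitter = 0.2, seed = 9)
  ch <- assign_charges_radii(p)
  base <- atom_potentials(ch)

  # rigid rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- ch
  xyz <- as.matrix(ch$atoms[, c("x", "y", "z")]) %*% R
  rot$atoms$x <- xyz[, 1] + 11; rot$atoms$y <- xyz[, 2] - 3
  rot$atoms$z <- xyz[, 3] + 2
  expect_equal(atom_potentials(rot)$phi, base$phi, tolerance = 1e-6)

  # doubling all charges doubles all potentials
  dbl <- ch
  dbl$atoms$charge <- 2 * dbl$atoms$charge
  expect_equal(atom_potentials(dbl)$phi, 2 * base$phi, tolerance = 1e-9)
})

test_that("superposition holds for the uniform grid solver", {
  pr <- solver_params()
  mk <- function(charges) {
    sys <- synthetic_charge_system("dipole", q = 1, separation = 4)
    sys$atoms$charge <- charges
    sys
  }
  fA <- solve_potential(mk(c(1, 0)), pr, mode = "uniform")
  fB <- solve_potential(mk(c(0, -1)), pr, mode = "uniform")
  fAB <- solve_potential(mk(c(1, -1)), pr, mode = "uniform")
  pos <- c(3.5, 1, 0)
  expect_equal(potential_at(fA, pos) + potential_at(fB, pos),
               potential_at(fAB, pos), tolerance = 1e-3)
})

test_that("atom potentials cover requested atoms; glycine has no CB entry", {
  p <- generate_peptide("ADGFA", id = "glyin")
  pots <- atom_potentials(assign_charges_radii(p))
  cb <- pots[pots$atom == "CB", ]
  expect_identical(sort(cb$resno), c(1L, 2L, 4L, 5L))
  expect_equal(sum(pots$atom == "CA"), 5L)
  expect_true(all(is.finite(pots$phi)))
})

test_that("kT/e <-> millivolt conversion is self-inverse", {
  x <- c(-420, -1.5, 0, 93.7)
  expect_equal(mv_to_kte(kte_to_mv(x)), x, tolerance = 1e-12)
  expect_equal(kte_to_mv(1), 25.68, tolerance = 1e-3)
})

test_that("APBS input file carries the reference parameters", {
  path <- tempfile(fileext = ".in")
  write_apbs_input("mol.pqr", solver_params(), "pot",
                   dims = c(65L, 65L, 65L), origin = c(-16, -16, -16),
                   path = path)
  txt <- readLines(path)
  expect_true(any(grepl("pdie 2.0", txt, fixed = TRUE)))
  expect_true(any(grepl("sdie 78.0", txt, fixed = TRUE)))
  expect_true(any(grepl("temp 298.0", txt, fixed = TRUE)))
  expect_true(any(grepl("srad 1.4", txt, fixed = TRUE)))
  expect_true(any(grepl("lpbe", txt, fixed = TRUE)))
})

test_that("missing external executables raise classed errors naming the config key", {
  old <- options(escapist.apbs = file.path(tempdir(), "no-such-apbs"),
                 escapist.pdb2pqr = file.path(tempdir(), "no-such-pdb2pqr"))
  on.exit(options(old))
  ch <- assign_charges_radii(generate_peptide("ADFK"))
  err <- expect_error(
    atom_potentials(ch, backend = "external"),
    class = "escapist_missing_executable"
  )
  expect_match(conditionMessage(err), "escapist.apbs")
  err2 <- expect_error(
    assign_charges_radii(generate_peptide("ADFK"), forcefield = "pdb2pqr"),
    class = "escapist_missing_executable"
  )
  expect_match(conditionMessage(err2), "pdb2pqr")
})

test_that("OpenDX scalar grids are read back in the right orientation", {
  # 2 x 3 x 4 grid with value = 100 i + 10 j + k (1-based indices)
  vals <- numeric(0)
  for (i in 1:2) for (j in 1:3) for (k in 1:4) {
    vals <- c(vals, 100 * i + 10 * j + k)   # DX order: z fastest
  }
  lines <- c(
    "# test grid",
    "object 1 class gridpositions counts 2 3 4",
    "origin 0.0 0.0 0.0",
    "delta 0.5 0.0 0.0",
    "delta 0.0 0.5 0.0",
    "delta 0.0 0.0 0.5",
    "object 2 class gridconnections counts 2 3 4",
    "object 3 class array type double rank 0 items 24 data follows",
    vapply(split(vals, ceiling(seq_along(vals) / 3)),
           function(v) paste(sprintf("%.6e", v), collapse = " "),
           character(1)),
    'attribute "dep" string "positions"'
  )
  path <- tempfile(fileext = ".dx")
  writeLines(lines, path)
  f <- read_dx(path)
  expect_identical(f$dims, c(2L, 3L, 4L))
  expect_equal(f$values[1, 1, 1], 111)
  expect_equal(f$values[2, 3, 4], 234)
  expect_equal(potential_at(f, c(0.5, 1.0, 1.5)), 234)
})
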