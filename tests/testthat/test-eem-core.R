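test_that("assembled system matches the equalization equations", {
  # one atom: [[B, -1], [1, 0]] with rhs (-A, Q)
  one <- eem_molecule("one", data.frame(element = "O", name = "O1",
                                        x = 0, y = 0, z = 0),
                      total_charge = -1)
  sys <- assemble_system(one, water_params())
  expect_equal(sys$matrix, matrix(c(8, 1, -1, 0), 2, 2))
  expect_equal(sys$rhs, c(-3.4, -1))

  # two identical atoms at distance R: off-diagonals k / R, symmetric block
  two <- eem_molecule("two", data.frame(element = c("O", "O"),
                                        name = c("O1", "O2"),
                                        x = c(0, 2.5), y = 0, z = 0))
  sys2 <- assemble_system(two, water_params(), Q = 0)
  expect_equal(sys2$matrix[1, 2], 0.5 / 2.5)
  expect_equal(sys2$matrix[2, 1], sys2$matrix[1, 2])
  expect_equal(diag(sys2$matrix)[1:2], c(8, 8))
  expect_equal(sys2$matrix[3, ], c(1, 1, 0))
  expect_equal(sys2$matrix[1:2, 3], c(-1, -1))

  # entries depend on distances only: invariant under rigid motion
  mol <- random_molecule(5, seed = 42)
  sys_a <- assemble_system(mol, toy_params_E())
  sys_b <- assemble_system(transform_molecule(mol, random_rotation(7),
                                              c(3, 3, -9)),
                           toy_params_E())
  expect_equal(sys_b$matrix, sys_a$matrix, tolerance = 1e-12)

  # a missing atom type is reported by name
  expect_error(assemble_system(random_molecule(4, seed = 1, elements = "S"),
                               water_params()),
               "atom type.*S")
})

test_that("solve_charges handles closed-form cases", {
  p <- water_params()
  one <- eem_molecule("one", data.frame(element = "O", name = "O1",
                                        x = 0, y = 0, z = 0))
  cs <- solve_charges(one, p, Q = 1)
  expect_equal(cs$charges, 1)
  expect_equal(cs$chi_bar, 3.4 + 8.0) # A + B

  # homonuclear diatomic at Q = 0: symmetry forces q = 0, chi_bar = A
  hom <- eem_molecule("hom", data.frame(element = c("O", "O"),
                                        name = c("O1", "O2"),
                                        x = c(0, 1.2), y = 0, z = 0))
  cs2 <- solve_charges(hom, p, Q = 0)
  expect_equal(cs2$charges, c(0, 0), tolerance = 1e-12)
  expect_equal(cs2$chi_bar, 3.4)
})

test_that("solver agrees with an independent dense-solve oracle", {
  # heteronuclear diatomic: A1=2, B1=6, A2=4, B2=8, k=0.5, R=1.5, Q=0
  p <- eem_params("E", k = 0.5,
                  table = data.frame(type = c("H", "O"),
                                     A = c(2, 4), B = c(6, 8)))
  mol <- eem_molecule("het", data.frame(element = c("H", "O"),
                                        name = c("H1", "O1"),
                                        x = c(0, 1.5), y = 0, z = 0))
  # oracle: write the explicit 3x3 system from the formalism and solve it
  # with a generic dense solve, independently of assemble_system
  oracle_m <- rbind(c(6, 0.5 / 1.5, -1),
                    c(0.5 / 1.5, 8, -1),
                    c(1, 1, 0))
  oracle <- solve(oracle_m, c(-2, -4, 0))
  cs <- solve_charges(mol, p, Q = 0)
  expect_equal(cs$charges, oracle[1:2], tolerance = 1e-12)
  expect_equal(cs$chi_bar, oracle[3], tolerance = 1e-12)

  # and across random molecules: generic solve of the assembled system
  for (seed in 1:10) {
    m <- random_molecule(sample(2:6, 1), seed = seed)
    sys <- assemble_system(m, toy_params_E(), Q = m$total_charge)
    ref <- qr.solve(sys$matrix, sys$rhs)
    got <- solve_charges(m, toy_params_E())
    expect_equal(got$charges, ref[seq_len(n_atoms(m))], tolerance = 1e-10)
    expect_equal(got$chi_bar, ref[n_atoms(m) + 1], tolerance = 1e-10)
  }
})

test_that("charges conserve Q and equalize electronegativity", {
  for (seed in c(3, 14, 15)) {
    mol <- random_molecule(12, seed = seed)
    cs <- solve_charges(mol, toy_params_E())
    expect_lt(abs(sum(cs$charges) - mol$total_charge), 1e-8)
    chi <- effective_electronegativity(mol, toy_params_E(), cs$charges)
    expect_lt(max(chi) - min(chi), 1e-8)
    expect_equal(mean(chi), cs$chi_bar, tolerance = 1e-8)
  }
})

test_that("effective electronegativity detects non-equalized charges", {
  mol <- random_molecule(6, seed = 8)
  cs <- solve_charges(mol, toy_params_E())
  q <- cs$charges
  q[1] <- q[1] + 0.1
  q[2] <- q[2] - 0.1
  chi <- effective_electronegativity(mol, toy_params_E(), q)
  expect_gt(max(chi) - min(chi), 1e-4)

  # far-separated atoms with zero charge sit at their A values
  iso <- eem_molecule("iso", data.frame(
    element = c("H", "O"), name = c("H1", "O1"),
    x = c(0, 1e6), y = 0, z = 0))
  chi0 <- effective_electronegativity(iso, water_params(), c(0, 0))
  expect_equal(chi0, c(2.2, 3.4), tolerance = 1e-5)
})

test_that("charges are frame-invariant and permutation-equivariant", {
  mol <- random_molecule(10, seed = 21)
  cs <- solve_charges(mol, toy_params_E())
  moved <- transform_molecule(mol, random_rotation(4), c(-7, 2, 11))
  expect_equal(solve_charges(moved, toy_params_E())$charges, cs$charges,
               tolerance = 1e-10)
  set.seed(9)
  perm <- sample(n_atoms(mol))
  pm <- permute_molecule(mol, perm)
  expect_equal(solve_charges(pm, toy_params_E())$charges, cs$charges[perm],
               tolerance = 1e-10)
})

test_that("harmonic molecular electronegativity matches closed forms", {
  same <- eem_molecule("same", data.frame(
    element = c("O", "O", "O"), name = c("O1", "O2", "O3"),
    x = c(0, 2, 4), y = 0, z = 0))
  expect_equal(harmonic_electronegativity(same,
                                          c(O = 3.5)), 3.5)
  duo <- eem_molecule("duo", data.frame(
    element = c("C", "O"), name = c("C1", "O1"),
    x = c(0, 2), y = 0, z = 0))
  expect_equal(harmonic_electronegativity(duo, c(C = 2, O = 4)), 8 / 3)
  # water with the packaged Pauling table: 3 / (2/2.20 + 1/3.44)
  w <- read_pdb(water_pdb())
  expect_equal(harmonic_electronegativity(w), 2.50044, tolerance = 1e-5)
  expect_error(harmonic_electronegativity(duo, c(C = 2)), "O")
})

test_that("parameter files round-trip at nine decimals", {
  p <- eem_params("EX", k = 0.123456789,
                  table = data.frame(type = c("O1", "O2", "H1"),
                                     A = c(4.123456789, 4.4, 2.123456788),
                                     B = c(8.987654321, 8.2, 9.000000001)))
  path <- tempfile(fileext = ".eem")
  write_eem_params(p, path)
  back <- read_eem_params(path)
  expect_equal(back$scheme, "EX")
  expect_equal(back$k, p$k, tolerance = 1e-9)
  expect_equal(back$table, p$table, tolerance = 1e-9)
  expect_error(eem_params("E", k = 0.4,
                          table = data.frame(type = "O", A = 4, B = -1)),
               "B must be positive")
  expect_error(eem_params("E", k = -1,
                          table = data.frame(type = "O", A = 4, B = 1)),
               "k must be")
})
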