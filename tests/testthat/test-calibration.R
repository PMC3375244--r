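test_that("regression rows rearrange the equalization equation", {
  # isolated single atom: empty pair sum, y = chi_bar_ref, x = ref charge
  one <- eem_molecule("one", data.frame(element = "O", name = "O1",
                                        x = 0, y = 0, z = 0))
  rec1 <- reference_record(one, ref_charges = -0.4, chi_bar_ref = 3.1)
  rows1 <- build_regression_rows(list(rec1), "E", k = 0.7)
  expect_equal(rows1$O$x, -0.4)
  expect_equal(rows1$O$y, 3.1)

  # two atoms: y1 = chi - k q2 / R, verified by direct evaluation
  duo <- eem_molecule("duo", data.frame(element = c("C", "O"),
                                        name = c("C1", "O1"),
                                        x = c(0, 1.6), y = 0, z = 0))
  rec2 <- reference_record(duo, ref_charges = c(0.25, -0.25),
                           chi_bar_ref = 2.8)
  rows2 <- build_regression_rows(list(rec2), "E", k = 0.5)
  expect_equal(rows2$C$y, 2.8 - 0.5 * (-0.25) / 1.6)
  expect_equal(rows2$O$y, 2.8 - 0.5 * 0.25 / 1.6)

  # k = 0 wipes the electrostatic term: y = chi_bar_ref everywhere
  rows0 <- build_regression_rows(list(rec2), "E", k = 0)
  expect_equal(c(rows0$C$y, rows0$O$y), rep(2.8, 2))
})

test_that("per-type least squares recovers exact and noisy lines", {
  # line through two points: (0, 2) and (1, 8) -> A = 2, B = 6
  rows <- list(O = data.frame(x = c(0, 1), y = c(2, 8), mol_id = "m"))
  fit <- fit_parameters(rows)
  expect_equal(fit$A, 2)
  expect_equal(fit$B, 6)

  # noiseless rows on y = A + Bx recover exactly
  set.seed(4)
  x <- rnorm(50)
  rows <- list(C = data.frame(x = x, y = 3.25 + 5.5 * x, mol_id = "m"))
  fit <- fit_parameters(rows)
  expect_equal(fit$A, 3.25, tolerance = 1e-10)
  expect_equal(fit$B, 5.5, tolerance = 1e-10)

  # gaussian noise: estimates match an independent normal-equations solve
  # and fall within 4 theoretical standard errors of the truth
  set.seed(7)
  x <- rnorm(200)
  y <- 3.25 + 5.5 * x + rnorm(200, 0, 0.01)
  fit <- fit_parameters(list(C = data.frame(x = x, y = y, mol_id = "m")))
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(fit$A, fit$B), as.numeric(beta), tolerance = 1e-10)
  sigma2 <- sum((y - X %*% beta)^2) / (200 - 2)
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_lt(abs(fit$A - 3.25), 4 * se[1])
  expect_lt(abs(fit$B - 5.5), 4 * se[2])

  expect_error(fit_parameters(list(S = data.frame(x = 1, y = 2,
                                                  mol_id = "m"))),
               "'S' has fewer than 2")
  expect_error(fit_parameters(list(S = data.frame(x = c(1, 1), y = c(2, 3),
                                                  mol_id = "m"))),
               "'S' has zero variance")
})

test_that("noiseless forward data is recovered exactly at the true k", {
  spec <- fixture_spec(n_molecules = 8, atoms_per_molecule = c(8, 14),
                       seed = 31)
  mols <- make_molecules(spec)
  recs <- forward_reference(mols, spec$true_params, noise_sigma = 0,
                            seed = 31)
  fit <- suppressWarnings(
    eem_calibrate(recs, "E", k_grid = seq(0.1, 0.8, by = 0.1)))
  expect_equal(fit$params$k, 0.4)
  truth <- spec$true_params$table
  got <- fit$params$table[match(truth$type, fit$params$table$type), ]
  expect_equal(got$A, truth$A, tolerance = 1e-8)
  expect_equal(got$B, truth$B, tolerance = 1e-8)
  expect_gt(fit$internal$R_avg, 0.9999)
  # score curve covers the full grid and peaks at the selected k
  expect_equal(length(fit$k_scores), 8L)
  expect_equal(unname(which.max(fit$k_scores)), 4L)
})

test_that("degenerate grids and ties follow the contract", {
  spec <- fixture_spec(n_molecules = 4, atoms_per_molecule = c(6, 8),
                       seed = 13)
  recs <- forward_reference(make_molecules(spec), spec$true_params,
                            noise_sigma = 0, seed = 13)
  one_k <- suppressWarnings(eem_calibrate(recs, "E", k_grid = 0.25))
  expect_equal(one_k$params$k, 0.25)
  expect_equal(length(one_k$k_scores), 1L)

  # single-atom molecules have no electrostatic term, so every k scores
  # identically: the tie must resolve to the smallest k
  singles <- lapply(c(-1, 1), function(Q) {
    mol <- eem_molecule(paste0("ion", Q),
                        data.frame(element = "Ca", name = "CA1",
                                   x = 0, y = 0, z = 0),
                        total_charge = Q)
    reference_record(mol, ref_charges = Q, chi_bar_ref = 1)
  })
  fit <- suppressWarnings(eem_calibrate(singles, "E",
                                        k_grid = c(0.3, 0.7)))
  expect_equal(fit$params$k, 0.3)
})

test_that("validation statistics expose agreement and its blind spots", {
  set.seed(2)
  q <- rnorm(20, 0, 0.3)
  expect_equal(unname(charge_agreement(q, q)), c(1, 0, 0))
  shifted <- charge_agreement(q + 0.05, q)
  expect_equal(unname(shifted), c(1, 0.05, 0.05))
  # squared Pearson cannot see a sign flip; the deviations can
  neg <- charge_agreement(-q, q)
  expect_equal(neg[["r2"]], 1)
  expect_equal(neg[["rmsd"]], 2 * sqrt(mean(q^2)))

  # invariants of a full validation: D <= RMSD per molecule, averages are
  # means, solve uses Q = sum(reference charges)
  spec <- fixture_spec(n_molecules = 5, atoms_per_molecule = c(6, 10),
                       seed = 17)
  recs <- forward_reference(make_molecules(spec), spec$true_params,
                            noise_sigma = 0.02, seed = 17)
  val <- eem_validate(spec$true_params, recs)
  expect_true(all(val$per_molecule$d <= val$per_molecule$rmsd + 1e-12))
  expect_equal(val$R_avg, mean(val$per_molecule$r2))
  expect_equal(val$RMSD_avg, mean(val$per_molecule$rmsd))
  expect_equal(val$D_avg, mean(val$per_molecule$d))

  # ordering of records does not change the statistics
  val_rev <- eem_validate(spec$true_params, rev(recs))
  expect_equal(val_rev$R_avg, val$R_avg)
  expect_equal(val_rev$RMSD_avg, val$RMSD_avg)
})

test_that("noisy references still calibrate well", {
  spec <- fixture_spec(n_molecules = 8, atoms_per_molecule = c(8, 14),
                       seed = 31, noise_sigma = 0.01)
  mols <- make_molecules(spec)
  recs <- forward_reference(mols, spec$true_params,
                            noise_sigma = spec$noise_sigma, seed = 31)
  fit <- suppressWarnings(
    eem_calibrate(recs, "E", k_grid = seq(0.2, 0.6, by = 0.1)))
  expect_gt(fit$internal$R_avg, 0.95)
})

test_that("the fit object behaves like a model object", {
  spec <- fixture_spec(n_molecules = 5, atoms_per_molecule = c(6, 10),
                       seed = 23)
  mols <- make_molecules(spec)
  recs <- forward_reference(mols, spec$true_params, noise_sigma = 0,
                            seed = 23)
  fit <- suppressWarnings(eem_calibrate(recs, "E", k_grid = c(0.3, 0.4)))
  cf <- coef(fit)
  expect_true(all(c("A", "B") %in% colnames(cf)))
  pred <- predict(fit, mols[[1]], Q = 0)
  expect_s3_class(pred, "eem_charges")
  expect_lt(abs(sum(pred$charges)), 1e-8)
  expect_output(print(summary(fit)), "Internal validation")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
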