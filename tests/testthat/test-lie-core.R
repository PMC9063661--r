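test_that("delta_energies subtracts free from bound, componentwise", {
  same <- complex_energies("a", -10, -10, -5, -5)
  expect_equal(delta_energies(same), c(d_vdw = 0, d_elec = 0))

  ce <- complex_energies("b", -50, -10, -5, -20)
  expect_equal(delta_energies(ce), c(d_vdw = -40, d_elec = 15))

  set.seed(21)
  for (i in 1:20) {
    e <- rnorm(4, -20, 10)
    ce <- complex_energies("x", e[1], e[2], e[3], e[4])
    expect_equal(delta_energies(ce),
                 c(d_vdw = e[1] - e[2], d_elec = e[3] - e[4]))
  }
})

test_that("lie_predict applies the three-parameter linear form", {
  eq2 <- abeta_lie_parameters()
  expect_equal(lie_predict(complex_energies("a", -5, -5, -3, -3), eq2),
               -5.880)
  # d_vdw = -10, d_elec = +5: 0.288*(-10) - 0.049*5 - 5.880
  expect_equal(lie_predict(complex_energies("a", -20, -10, -5, -10), eq2),
               -9.005)
  std <- standard_lie_parameters()
  expect_equal(lie_predict(complex_energies("a", -15, -5, -4, -2), std),
               -2.8)

  # affine in each energy difference separately
  p <- lie_parameters(0.3, -0.05, -6)
  base <- lie_predict(complex_energies("a", -10, 0, 4, 0), p) - p$gamma
  scaled <- lie_predict(complex_energies("a", -30, 0, 12, 0), p) - p$gamma
  expect_equal(scaled, 3 * base)

  # vectorised over a table
  tab <- gen_lie_dataset(n_ligands = 8, seed = 5)
  pred <- lie_predict(tab, eq2)
  expect_equal(pred, vapply(seq_len(8), function(i)
    lie_predict(complex_energies(tab$ligand_id[i], tab$vdw_bound[i],
                                 tab$vdw_free[i], tab$elec_bound[i],
                                 tab$elec_free[i]), eq2), numeric(1)))
})

test_that("fit_lie recovers exact linear structure and rejects bad designs", {
  gt <- lie_parameters(0.31, -0.07, -4.2)
  tab <- gen_lie_dataset(gt, n_ligands = 12, residual_sd = 0, seed = 8)
  fit <- fit_lie(tab)
  expect_equal(fit$params$alpha, gt$alpha, tolerance = 1e-8)
  expect_equal(fit$params$beta, gt$beta, tolerance = 1e-8)
  expect_equal(fit$params$gamma, gt$gamma, tolerance = 1e-8)
  expect_equal(fit$r, 1, tolerance = 1e-8)
  expect_equal(fit$se, 0, tolerance = 1e-7)

  # n = 4 general-position points with exact structure interpolate exactly
  tab4 <- gen_lie_dataset(gt, n_ligands = 4, residual_sd = 0, seed = 9)
  fit4 <- fit_lie(tab4)
  expect_equal(max(abs(fit4$residuals)), 0, tolerance = 1e-9)
  expect_equal(fit4$r, 1, tolerance = 1e-9)

  expect_error(fit_lie(tab[1:3, ]), ">= 4")

  coll <- tab
  coll$elec_bound <- coll$elec_free + 2 * (coll$vdw_bound - coll$vdw_free)
  expect_error(fit_lie(coll), "collinear")
})

test_that("fit_lie matches a direct Nelder-Mead least-squares oracle", {
  set.seed(33)
  for (n in c(6, 8, 10)) {
    tab <- gen_lie_dataset(lie_parameters(0.25, -0.06, -5), n_ligands = n,
                           residual_sd = 1.2, seed = n)
    fit <- fit_lie(tab)
    oracle <- brute_force_lie_fit(tab$vdw_bound - tab$vdw_free,
                                  tab$elec_bound - tab$elec_free,
                                  tab$dg_exp)
    expect_equal(fit$params$alpha, oracle$alpha, tolerance = 1e-4)
    expect_equal(fit$params$beta, oracle$beta, tolerance = 1e-4)
    expect_equal(fit$params$gamma, oracle$gamma, tolerance = 1e-4)
    expect_equal(sum(fit$residuals^2), oracle$sse, tolerance = 1e-6)
  }
})

test_that("least-squares fit beats any perturbed parameter set on its own data", {
  tab <- gen_lie_dataset(n_ligands = 20, seed = 14)
  fit <- fit_lie(tab, se_definition = "rmse")
  set.seed(15)
  for (i in 1:25) {
    perturbed <- lie_parameters(fit$params$alpha + rnorm(1, 0, 0.05),
                                fit$params$beta + rnorm(1, 0, 0.05),
                                fit$params$gamma + rnorm(1, 0, 0.5))
    expect_lte(fit$se, evaluate_lie(tab, perturbed, "rmse")$se)
  }
})

test_that("pearson_r matches hand-computed values and its invariances", {
  expect_equal(pearson_r(1:3, 2 * (1:3) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)

  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")

  set.seed(6)
  x <- rnorm(20); y <- rnorm(20)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.2 * y - 4), r, tolerance = 1e-12)
  expect_equal(pearson_r(-x, y), -r, tolerance = 1e-12)
})

test_that("standard_error implements both conventions", {
  expect_equal(standard_error(rep(0, 5), 3, "dof_corrected"), 0)
  expect_equal(standard_error(rep(0, 5), 0, "rmse"), 0)
  expect_equal(standard_error(c(1, -1, 1, -1), definition = "rmse"), 1)
  expect_equal(standard_error(c(3, 4), 0, "rmse"), sqrt(12.5))
  expect_equal(standard_error(c(3, 4), 1, "dof_corrected"), 5)
  expect_error(standard_error(c(1, 2), 2, "dof_corrected"), "more than")
  expect_error(standard_error(numeric(0)), "no residuals")
})

test_that("ki_to_dg applies RT ln(Ki) at 1 M standard state", {
  expect_equal(ki_to_dg(1, 275), 0)
  expect_equal(ki_to_dg(1, 350), 0)
  expect_equal(ki_to_dg(1e-6, 300), -8.2355, tolerance = 1e-4)
  # halving Ki lowers dG by RT ln 2
  d <- ki_to_dg(5e-7, 300) - ki_to_dg(1e-6, 300)
  expect_equal(d, -lie_constants[["gas_constant"]] * 300 * log(2))
  expect_error(ki_to_dg(0, 300), "> 0")
  expect_error(ki_to_dg(1e-6, -1), "> 0")
})

test_that("evaluate_lie applies frozen parameters consistently", {
  tab <- gen_lie_dataset(n_ligands = 20, seed = 18)
  fit <- fit_lie(tab, se_definition = "rmse")
  ev <- evaluate_lie(tab, fit$params, se_definition = "rmse")
  expect_equal(ev$r, fit$r, tolerance = 1e-12)
  expect_equal(ev$se, fit$se, tolerance = 1e-12)  # rmse charges no dof
  expect_equal(ev$residuals, fit$residuals, tolerance = 1e-12)
  expect_error(evaluate_lie(tab[1:2, ], fit$params), ">= 3")
})

test_that("Ki-only tables are converted before fitting", {
  tab <- gen_lie_dataset(n_ligands = 10, seed = 31)
  tab_ki <- tab
  tab_ki$ki_molar <- exp(tab$dg_exp / (lie_constants[["gas_constant"]] * 300))
  tab_ki$dg_exp <- NULL
  fit_dg <- fit_lie(tab)
  fit_ki <- fit_lie(tab_ki, temperature = 300)
  expect_equal(fit_ki$params$alpha, fit_dg$params$alpha, tolerance = 1e-9)
  expect_equal(fit_ki$params$gamma, fit_dg$params$gamma, tolerance = 1e-9)
})

test_that("compare_methods correlates columns and ranks by r", {
  tab <- gen_lie_dataset(n_ligands = 30, seed = 25)
  fit <- fit_lie(tab)
  set.seed(26)
  m <- data.frame(ligand_id = tab$ligand_id, dg_exp = tab$dg_exp,
                  dg_exact = tab$dg_exp,
                  dg_lie = fit$predicted,
                  dg_noisy = tab$dg_exp + rnorm(30, 0, 4))
  cmp <- compare_methods(m)
  expect_equal(cmp$method[1], "exact")
  expect_equal(cmp$r[cmp$method == "exact"], 1)
  expect_equal(cmp$se[cmp$method == "exact"], 0)
  expect_true(all(diff(cmp$r) <= 0))
  expect_gt(cmp$r[cmp$method == "lie"], cmp$r[cmp$method == "noisy"])

  expect_error(compare_methods(m[, c("ligand_id", "dg_exp")]),
               "no method columns")
})

test_that("permutation null of compare correlations is centred near zero", {
  tab <- gen_lie_dataset(n_ligands = 30, seed = 27)
  set.seed(28)
  rs <- replicate(1000, pearson_r(sample(tab$dg_exp), tab$dg_exp))
  # exact permutation mean is -1/(n-1)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("random_split is a deterministic exhaustive partition", {
  tab <- gen_lie_dataset(n_ligands = 30, seed = 2)
  sp <- random_split(tab, 20, seed = 123)
  expect_equal(nrow(sp$train), 20)
  expect_equal(nrow(sp$test), 10)
  expect_setequal(c(sp$train$ligand_id, sp$test$ligand_id), tab$ligand_id)
  expect_length(intersect(sp$train$ligand_id, sp$test$ligand_id), 0)

  sp2 <- random_split(tab, 20, seed = 123)
  expect_identical(sp$train$ligand_id, sp2$train$ligand_id)
  sp3 <- random_split(tab, 20, seed = 124)
  expect_false(identical(sp$train$ligand_id, sp3$train$ligand_id))

  expect_error(random_split(tab, 0, 1), "n_train")
  expect_error(random_split(tab, 30, 1), "n_train")
})

test_that("fit reports round-trip through JSON", {
  tab <- gen_lie_dataset(n_ligands = 12, seed = 41)
  fit <- fit_lie(tab)
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, f)
  p <- read_fit_params(f)
  expect_equal(p$alpha, fit$params$alpha, tolerance = 1e-12)
  expect_equal(p$beta, fit$params$beta, tolerance = 1e-12)
  expect_equal(p$gamma, fit$params$gamma, tolerance = 1e-12)
})
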