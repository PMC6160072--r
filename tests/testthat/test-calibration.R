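test_that("auxiliary statistics match hand arithmetic on a toy panel", {
  s <- aux_stats(toy_panel())
  expect_equal(s$stat, rumidyn:::aux_stat_order())
  expect_equal(s$value[s$stat == "girl_mean_R1"], 12)
  expect_equal(s$value[s$stat == "girl_sd_R1"], sd(c(10, 14)))  # sample SD
  expect_equal(s$value[s$stat == "boy_mean_D3"], 4)
  expect_true(all(is.finite(s$value)))
  expect_true(all(abs(s$value[grepl("^cor_", s$stat)]) <= 1))
})

test_that("a duplicated construct correlates perfectly and degeneracy warns", {
  panel <- toy_panel()
  panel$rumination[panel$wave == 2] <- panel$rumination[panel$wave == 1]
  s <- aux_stats(panel)
  expect_equal(s$value[s$stat == "cor_R1_R2"], 1)

  flat <- toy_panel()
  flat$rumination[flat$wave == 2] <- 9
  warns <- testthat::capture_warnings(s2 <- aux_stats(flat))
  expect_true(any(grepl("degenerate variance", warns)))
  expect_equal(s2$value[s2$stat == "cor_R1_R2"], 0)
  expect_equal(s2$value[s2$stat == "cor_R2_R3"], 0)
})

test_that("auxiliary statistics are invariant to relabelling individuals", {
  spec <- small_spec(20, 20)
  panel <- generate_panel(sample_profiles(spec, 8), model_params(), spec, 8)
  perm <- panel
  new_ids <- setNames(sample(unique(panel$id)), unique(panel$id))
  perm$id <- as.integer(new_ids[as.character(perm$id)])
  perm <- perm[order(perm$id, perm$wave), ]
  expect_equal(aux_stats(panel)$value, aux_stats(perm)$value)
})

test_that("the objective vanishes under common random numbers at the truth", {
  p <- model_params()
  spec <- small_spec(15, 15)
  seed_a <- child_seed(77, 0)
  prof0 <- panel_profiles(generate_panel(sample_profiles(spec, 1), p, spec, 2))
  panel <- generate_panel(prof0, p, spec, seed = seed_a)
  emp <- suppressWarnings(aux_stats(panel))
  obj0 <- calib_objective(c(theta9 = p$theta9), emp, panel, p,
                          n_sim = 1, seed_set = seed_a, spec = spec)
  expect_identical(obj0, 0)

  # zero weights null the objective for any theta
  w0 <- tibble::tibble(stat = rumidyn:::aux_stat_order(), weight = 0)
  expect_equal(calib_objective(c(theta9 = 3), emp, panel, p, weights = w0,
                               n_sim = 1, seed_set = seed_a, spec = spec), 0)

  # structural bound violations return a penalty, not an error
  pen <- calib_objective(c(theta8 = 1.5), emp, panel, p,
                         n_sim = 1, seed_set = seed_a, spec = spec)
  expect_gte(pen, 1e8)
})

test_that("the objective rises under a 50% distortion of the rumination effect", {
  p <- model_params()
  spec <- cohort_spec(n_girls = 353, n_boys = 308)
  wins <- vapply(1:20, function(r) {
    prof <- sample_profiles(spec, seed = child_seed(60, r))
    panel <- generate_panel(prof, p, spec, seed = child_seed(61, r))
    emp <- suppressWarnings(aux_stats(panel))
    ss <- child_seed(62, r + 0:1)
    f_true <- calib_objective(c(theta7 = p$theta7), emp, panel, p,
                              n_sim = 2, seed_set = ss, spec = spec)
    f_off <- calib_objective(c(theta7 = p$theta7 * 1.5), emp, panel, p,
                             n_sim = 2, seed_set = ss, spec = spec)
    f_off > f_true
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("calibration from the truth stays at the truth on a noise-free panel", {
  p0 <- model_params(theta10 = 0, theta11 = 0)
  spec <- small_spec(60, 60)
  panel <- generate_panel(sample_profiles(spec, 10), p0, spec, seed = 10)
  fit <- calibrate_model(panel, init = c(theta9 = 1.4741), params = p0,
                         options = list(n_starts = 1, maxit = 60, n_sim = 1,
                                        weights_B = 40, seed = 3, spec = spec))
  expect_true(fit$converged)
  expect_lte(fit$objective, fit$init_objective)
  expect_equal(unname(fit$estimate), 1.4741, tolerance = 0.05)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(is.na(tidy(fit)$std.error[1]))
  expect_equal(glance(fit)$converged, TRUE)

  expect_error(
    calibrate_model(panel, init = c(theta8 = 1.5)),
    class = "rumidyn_invalid_config"
  )
  expect_error(
    calibrate_model(panel, init = c(foo = 1)),
    class = "rumidyn_invalid_config"
  )
})

test_that("bootstrap standard errors behave at the degenerate and stochastic ends", {
  p <- model_params()
  spec <- small_spec(25, 25)
  panel <- generate_panel(sample_profiles(spec, 21), p, spec, seed = 21)
  fit <- calibrate_model(panel, init = c(theta9 = 1.4741), params = p,
                         options = list(n_starts = 1, maxit = 25, n_sim = 1,
                                        weights_B = 40, seed = 4, spec = spec))

  same <- bootstrap_se(panel, fit, B = 2,
                       options = list(replicate_seeds = c(123L, 123L),
                                      maxit = 25))
  expect_equal(unname(same$std_error), 0)

  se <- bootstrap_se(panel, fit, B = 4,
                     options = list(maxit = 25), seed = 9)
  expect_gt(unname(se$std_error["theta9"]), 0)
  expect_equal(nrow(se$bootstrap), 4)
  expect_false(is.na(tidy(se)$std.error[1]))
  expect_error(bootstrap_se(panel, fit, B = 1),
               class = "rumidyn_invalid_config")
})
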