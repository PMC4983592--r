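test_that("generated tables are deterministic under a fixed seed", {
  cfg <- sim_config(rng_seed = 77)
  tr <- gen_traits(cfg, "random", n_species = 6)
  expect_identical(tr, gen_traits(cfg, "random", n_species = 6))
  expect_identical(gen_cafeteria(cfg), gen_cafeteria(cfg))
  expect_identical(gen_field(cfg), gen_field(cfg))
  expect_identical(gen_feces(cfg), gen_feces(cfg))
  # a different seed changes the draws
  cfg2 <- sim_config(rng_seed = 78)
  expect_false(identical(gen_field(cfg), gen_field(cfg2)))
})

test_that("every generated table passes its schema validation", {
  cfg <- sim_config(rng_seed = 79, n_individuals = c(M_arvalis = 3L,
                                                     M_glareolus = 4L))
  expect_silent(validate_table(gen_traits(cfg)[, 1:4], "traits"))
  expect_silent(validate_table(gen_cafeteria(cfg), "cafeteria"))
  expect_silent(validate_table(gen_field(cfg), "depots"))
  fz <- gen_feces(cfg)
  expect_silent(validate_table(fz$feces, "feces"))
  expect_silent(validate_table(fz$germination, "germination"))
})

test_that("the fixture trait table matches the published classification", {
  tr <- gen_traits()
  expect_equal(nrow(tr), 15)
  expect_equal(sum(classify_weight(tr$seed_weight_mg) == "heavy"), 3)
  expect_equal(sum(tr$nutrient_flag), 5)
  expect_equal(sum(tr$status == "endangered"), 3)
  expect_equal(sum(tr$field_offered), 8)
  singleton <- gen_traits(sim_config(rng_seed = 5), "random", n_species = 1)
  expect_silent(validate_table(singleton[, 1:4], "traits"))
})

test_that("consumption saturates and vanishes at the hazard extremes", {
  tr <- tiny_traits()
  off <- sim_config(rng_seed = 80, baseline_log_hazard = -Inf,
                    n_individuals = c(M_glareolus = 2L))
  expect_true(all(gen_cafeteria(off, tr)$cumulative_consumed == 0))
  sat <- sim_config(rng_seed = 80, baseline_log_hazard = Inf,
                    n_individuals = c(M_glareolus = 2L))
  caf <- gen_cafeteria(sat, tr)
  done <- caf[caf$time_min > 0, ]
  expect_true(all(done$cumulative_consumed == done$seeds_offered))
  # all seeds eaten within the first 15-min interval: the curve ramps from
  # (0, 0) to (15, 10) and stays flat, giving 75 + 10 * 345 seed-minutes
  sc <- preference_scores(caf)
  expect_true(all(sc$a_i == 3525))
})

test_that("trait effects push preference in the configured direction", {
  cfg <- sim_config(rng_seed = 81, beta_nutrient = 1, beta_light = 0,
                    beta_common = 0, n_individuals = c(M_glareolus = 60L))
  tr <- gen_traits(cfg)
  sc <- preference_scores(gen_cafeteria(cfg, tr)) |>
    dplyr::left_join(derive_traits(tr[, 1:4]), by = "species_name")
  m <- tapply(sc$r_i, sc$nutrient_flag, mean)
  expect_gt(m[["1"]], m[["0"]])
})

test_that("field removal reproduces its analytic expectation without
           background noise", {
  # no invertebrates, flat rodent removal probability 0.35 in both sowing
  # treatments: the paired estimator's grand mean is 35% at large n
  p_rod <- 0.35
  cfg <- sim_config(rng_seed = 82, invertebrate_hazard = 0,
                    rodent_hazard = -log(1 - p_rod), beta_sowing_normal = 0,
                    n_replications = 25, plots_per_replication = 8)
  rem <- removal_rates(gen_field(cfg))
  expect_true(all(rem$status == "computed" | rem$r_aa == 10))
  n <- sum(!is.na(rem$sr_r))
  mc_se <- stats::sd(rem$sr_r, na.rm = TRUE) / sqrt(n)
  expect_lt(abs(mean(rem$sr_r, na.rm = TRUE) - 35), 3 * mc_se)
})

test_that("gut passage recovery scales with the intact-passage probability", {
  tr <- gen_traits()
  none <- sim_config(rng_seed = 83, p_intact_passage = 0)
  expect_equal(sum(gen_feces(none, tr)$feces$n_recovered), 0)
  all_through <- sim_config(rng_seed = 83, p_intact_passage = 1)
  rr <- recovery_rate(gen_feces(all_through, tr)$feces)
  expect_equal(rr$mean_per_individual, 150) # 15 species x 10 seeds
  # default calibration: 26 voles x 150 seeds at p = 5/3900, expected total 5
  totals <- vapply(1:40, function(s) {
    sum(gen_feces(sim_config(rng_seed = s), tr)$feces$n_recovered)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 5), 3 * sqrt(5 / 40))
})
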