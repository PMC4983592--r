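test_that("trapezoidal AUC reproduces hand-computed areas", {
  expect_equal(trapezoid_auc(c(0, 15, 30), c(0, 2, 4)), 60) # 15*1 + 15*3
  expect_equal(trapezoid_auc(c(0, 360), c(10, 10)), 3600)   # rectangle
  expect_equal(trapezoid_auc(c(0, 15, 360), c(0, 0, 0)), 0)
  expect_error(trapezoid_auc(c(0, 15), c(2, 1)), "non-decreasing")
  expect_error(trapezoid_auc(c(0, 15, 15), c(0, 1, 2)), "strictly increasing")
  expect_error(trapezoid_auc(c(5, 15), c(0, 1)), "start at 0")
  expect_error(trapezoid_auc(c(0, 15, 30), c(0, 1)), "aligned")
})

test_that("trapezoidal AUC matches a fine-grid Riemann integral", {
  sched <- cafeteria_schedule()
  sched <- sched[sched <= 360]
  set.seed(401)
  for (i in 1:20) {
    cum <- cumsum(c(0, stats::rbinom(length(sched) - 1, 3, 0.3)))
    cum <- pmin(cum, 10)
    a <- trapezoid_auc(sched, cum)
    b <- riemann_auc(sched, cum)
    if (b > 0) expect_lt(abs(a - b) / b, 1e-6)
  }
})

test_that("pointwise-larger consumption curves never shrink the area", {
  sched <- c(0, 15, 30, 60, 120, 360)
  set.seed(402)
  for (i in 1:25) {
    lo <- cumsum(c(0, stats::rbinom(5, 2, 0.4)))
    hi <- pmin(lo + cumsum(c(0, stats::rbinom(5, 1, 0.5))), max(lo) + 5)
    expect_gte(trapezoid_auc(sched, hi), trapezoid_auc(sched, lo))
  }
})

test_that("Rodgers' index standardizes areas to [0, 1] with max exactly 1", {
  sc <- tibble::tibble(individual = "MG_01", vole_species = "M_glareolus",
                       species_name = paste("Sp", 1:3),
                       a_i = c(3600, 1800, 0))
  expect_equal(rodgers_index(sc)$r_i, c(1, 0.5, 0))
  expect_equal(rodgers_index(sc[1, ])$r_i, 1) # singleton is its own max

  # per-vole-species scope: one score of exactly 1 in each scope
  two <- tibble::tibble(
    individual = c("MA_01", "MG_01"),
    vole_species = c("M_arvalis", "M_glareolus"),
    species_name = "Sp 1", a_i = c(100, 4000)
  )
  per <- rodgers_index(two, "per_vole_species")
  expect_equal(per$r_i, c(1, 1))
  glob <- rodgers_index(two, "global")
  expect_equal(glob$r_i, c(0.025, 1))

  # scale invariance: multiplying all areas in a scope leaves R_i unchanged
  sc2 <- sc
  sc2$a_i <- sc2$a_i * 7.3
  expect_equal(rodgers_index(sc2)$r_i, rodgers_index(sc)$r_i)

  sc$a_i <- 0
  expect_error(rodgers_index(sc), "undefined")
})

test_that("predation rates evaluate the recorded step function", {
  expect_equal(predation_rate_at(c(0, 360), c(0, 9), 10, 360), 90)
  expect_equal(predation_rate_at(c(0, 360), c(0, 0), 10, 360), 0)
  # cut-off between observations uses the latest count at or before it
  expect_equal(predation_rate_at(c(0, 15, 30), c(0, 2, 4), 10, 20), 20)
  expect_error(predation_rate_at(c(0, 15), c(0, 2), 10, -1),
               "before the first observation")
})

test_that("preference scores combine AUC, index and rates coherently", {
  caf <- dplyr::bind_rows(
    caf_series(c(0, 180, 360, 1440), c(0, 5, 5, 10), species = "Alpha seedum"),
    caf_series(c(0, 180, 360, 1440), c(0, 0, 2, 6), species = "Beta seedum"),
    caf_series(c(0, 180, 360, 1440), c(0, 2, 4, 8), individual = "MA_01",
               vole = "M_arvalis", species = "Alpha seedum")
  )
  sc <- preference_scores(caf, window_min = 360)
  # the 24 h check enters the rates, never the area
  a_alpha <- trapezoid_auc(c(0, 180, 360), c(0, 5, 5))
  expect_equal(sc$a_i[sc$individual == "MG_01" &
                        sc$species_name == "Alpha seedum"], a_alpha)
  expect_true(all(sc$sp_r_24h >= sc$sp_r_6h))
  # SP_R at the final observation equals final cumulative / offered * 100
  expect_equal(sc$sp_r_24h[sc$species_name == "Beta seedum"], 60)
  # per-vole-species standardization: a max of 1 in each vole species
  expect_equal(as.vector(tapply(sc$r_i, sc$vole_species, max)), c(1, 1))
})

test_that("preference summaries group by trait with study-sized classes", {
  cfg <- sim_config(rng_seed = 31, n_individuals = c(M_arvalis = 2L,
                                                     M_glareolus = 2L))
  tr <- gen_traits(cfg)
  sc <- preference_scores(gen_cafeteria(cfg, tr))
  by_wc <- summarize_preference(sc, tr[, 1:4], "weight_class",
                                vole_species = "M_glareolus")
  # 15 species split 12 light / 3 heavy, times 2 individuals
  expect_equal(sort(by_wc$n), c(6L, 24L))
  two <- summarize_preference(
    tibble::tibble(individual = c("a", "b"), vole_species = "M_glareolus",
                   species_name = "Alpha seedum", a_i = 1,
                   r_i = c(0.4, 0.6), sp_r_6h = c(40, 60), sp_r_24h = 100),
    tiny_traits(), "species")
  expect_equal(two$mean_ri, 0.5)
  expect_equal(two$se_ri, 0.1)
  expect_error(summarize_preference(sc, tr[, 1:4], "species",
                                    vole_species = "M_musculus"),
               "unknown vole species")
})
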