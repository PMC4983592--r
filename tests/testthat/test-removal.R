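test_that("the zero/exclusion correction reproduces the worked cases", {
  out <- seed_removal_rate(c(10, 8, 4, 5), c(5, 8, 8, 6))
  expect_equal(out$status, c("computed", "zeroed", "excluded", "zeroed"))
  expect_equal(out$sr_r, c(50, 0, NA, 0))
  # degenerate pairs: both empty is zeroed, control-only-empty is excluded
  expect_equal(seed_removal_rate(0, 0)$status, "zeroed")
  expect_equal(seed_removal_rate(0, 3)$status, "excluded")
  expect_error(seed_removal_rate(-1, 2), ">= 0")
})

test_that("seed_removal_rate equals the brute-force rule table on {0..10}^2", {
  grid <- expand.grid(r_nra = 0:10, r_aa = 0:10)
  got <- seed_removal_rate(grid$r_nra, grid$r_aa)
  want <- mapply(function(a, b) fox_oracle(a, b), grid$r_nra, grid$r_aa,
                 SIMPLIFY = FALSE)
  expect_equal(got$status, vapply(want, `[[`, "", "status"))
  expect_equal(got$sr_r, vapply(want, `[[`, 1, "sr_r"))
  # non-excluded rates always lie in [0, 100]
  kept <- got$sr_r[got$status != "excluded"]
  expect_true(all(kept >= 0 & kept <= 100))
})

test_that("depot pairing keys on plot, round and species", {
  expect_equal(nrow(pair_depots(depot_pair(10, 5))), 1)
  one <- depot_pair(10, 5)[1, ]
  expect_warning(p <- pair_depots(one), "unpaired")
  expect_equal(nrow(p), 0)
  eight <- dplyr::bind_rows(lapply(paste("Sp", 1:8), function(s) {
    depot_pair(8, 4, species = s)
  }))
  expect_equal(nrow(pair_depots(eight)), 8)
  # unequal offerings within a pair are an error, not a silent ratio change
  uneq <- depot_pair(10, 5)
  uneq$seeds_offered <- c(10L, 20L)
  expect_error(pair_depots(uneq), "seeds_offered differs")
})

test_that("round averaging drops excluded records, not their partners", {
  rem <- dplyr::bind_rows(
    removal_rates(depot_pair(10, 5, round = 1)),           # 50%
    removal_rates(depot_pair(10, 7, round = 2)),           # 30%
    removal_rates(depot_pair(4, 8, round = 1, plot = "R1P2")),  # excluded
    removal_rates(depot_pair(10, 8, round = 2, plot = "R1P2")), # 20%
    removal_rates(depot_pair(8, 8, round = 1, plot = "R1P3")),  # zeroed
    removal_rates(depot_pair(9, 9, round = 2, plot = "R1P3")),  # zeroed
    removal_rates(depot_pair(4, 8, round = 1, plot = "R1P4")),  # excluded
    removal_rates(depot_pair(3, 9, round = 2, plot = "R1P4"))   # excluded
  )
  av <- average_rounds(rem)
  expect_equal(av$sr_r[av$plot == "R1P1"], 40)
  expect_equal(av$n_rounds[av$plot == "R1P1"], 2L)
  expect_equal(av$sr_r[av$plot == "R1P2"], 20) # single retained round
  expect_equal(av$sr_r[av$plot == "R1P3"], 0)
  expect_false("R1P4" %in% av$plot) # both rounds excluded: key absent
})

test_that("removal summaries give mean, SE and n per group", {
  tr <- tiny_traits()
  av <- tibble::tibble(
    replication = 1L, plot = paste0("R1P", 1:4), sowing_rate = "normal",
    species_name = c("Alpha seedum", "Alpha seedum", "Delta seedum",
                     "Gamma seedum"),
    sr_r = c(40, 60, 25, 30), n_rounds = 2L
  )
  by_sp <- summarize_removal(av, tr, "species")
  alpha <- by_sp[by_sp$species_name == "Alpha seedum", ]
  expect_equal(alpha$mean_srr, 50)
  expect_equal(alpha$se_srr, 10) # sd 14.142 / sqrt(2)
  delta <- by_sp[by_sp$species_name == "Delta seedum", ]
  expect_equal(delta$n, 1L)
  expect_equal(delta$se_srr, 0) # singleton SE convention, flagged by n = 1
  by_wc <- summarize_removal(av, tr, "weight_class")
  expect_equal(sum(by_wc$n), 4L)
  expect_setequal(by_wc$weight_class, c("light", "heavy"))
  # summaries are invariant to input row order
  shuffled <- av[c(3, 1, 4, 2), ]
  expect_equal(as.data.frame(dplyr::arrange(by_sp, species_name)),
               as.data.frame(dplyr::arrange(
                 summarize_removal(shuffled, tr, "species"), species_name)))
  expect_error(summarize_removal(av, tr[1:2, ], "species"), "Gamma seedum")
})

test_that("a zero shared hazard yields exactly zero removal, and a noisy
           null matches the enumeration bias of the corrected estimator", {
  # no removal pressure at all: every pair retains all seeds, all zeroed
  cfg0 <- sim_config(rng_seed = 21, invertebrate_hazard = 0, rodent_hazard = 0)
  av0 <- average_rounds(removal_rates(gen_field(cfg0)))
  expect_true(all(av0$sr_r == 0))

  # equal nonzero hazards in both treatments: the correction keeps positive
  # differences but zeroes/excludes inversions, so the grand mean sits at
  # the positive value given by exact enumeration over Bin(10, 1-p) pairs
  cfg <- sim_config(rng_seed = 22, rodent_hazard = 0, n_replications = 25,
                    plots_per_replication = 8)
  p_inv <- 1 - exp(-cfg$invertebrate_hazard)
  pr <- stats::dbinom(0:10, 10, 1 - p_inv)
  vals <- c(); wts <- c()
  for (rn in 0:10) for (ra in 0:10) {
    o <- fox_oracle(rn, ra)
    if (o$status != "excluded") {
      vals <- c(vals, o$sr_r); wts <- c(wts, pr[rn + 1] * pr[ra + 1])
    }
  }
  exp_mean <- sum(vals * wts) / sum(wts)
  exp_sd <- sqrt(sum(vals^2 * wts) / sum(wts) - exp_mean^2)
  rem <- removal_rates(gen_field(cfg))
  kept <- rem$sr_r[rem$status != "excluded"]
  expect_gt(exp_mean, 0) # the estimator is positively biased under this null
  expect_lt(abs(mean(kept) - exp_mean), 3 * exp_sd / sqrt(length(kept)))
})
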