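# small in-code fixtures shared across test files

tiny_traits <- function() {
  tibble::tibble(
    species_name = c("Alpha seedum", "Beta seedum", "Gamma seedum",
                     "Delta seedum"),
    seed_weight_mg = c(0.5, 1.2, 4.0, 7.2),
    nutrient_flag = c(1L, 0L, 1L, 0L),
    status = c("common", "endangered", "common", "common")
  )
}

# one paired depot record set: both treatments for a single key
depot_pair <- function(r_nra, r_aa, plot = "R1P1", round = 1L,
                       species = "Alpha seedum", sowing = "normal",
                       replication = 1L, offered = 10L) {
  tibble::tibble(
    replication = replication, plot = plot, sowing_rate = sowing,
    treatment = c("no_rodent_access", "all_access"), round = round,
    species_name = species, seeds_offered = offered,
    seeds_remaining = c(r_nra, r_aa)
  )
}

# cafeteria series rows for one individual x species curve
caf_series <- function(times, cum, individual = "MG_01",
                       vole = "M_glareolus", species = "Alpha seedum",
                       offered = 10L) {
  tibble::tibble(
    individual = individual, vole_species = vole, sex = "F",
    body_weight_g = 21, species_name = species, time_min = times,
    cumulative_consumed = as.integer(cum), seeds_offered = offered
  )
}

# independent rule-table oracle for the zero/exclusion correction
fox_oracle <- function(r_nra, r_aa, ratio = 5 / 4) {
  if (r_nra > r_aa) {
    return(list(status = "computed", sr_r = (r_nra - r_aa) / r_nra * 100))
  }
  if (r_nra == 0 && r_aa == 0) return(list(status = "zeroed", sr_r = 0))
  if (r_nra == 0) return(list(status = "excluded", sr_r = NA_real_))
  if (r_aa / r_nra > ratio) return(list(status = "excluded", sr_r = NA_real_))
  list(status = "zeroed", sr_r = 0)
}

# brute-force integral of the piecewise-linear curve through (t, c):
# midpoint Riemann sum on a fine grid (independent of the trapezoid path)
riemann_auc <- function(t, c, n_grid = 2e5) {
  lo <- min(t); hi <- max(t)
  mids <- seq(lo, hi, length.out = n_grid + 1)
  mids <- (mids[-1] + mids[-length(mids)]) / 2
  sum(stats::approx(t, c, xout = mids)$y) * (hi - lo) / n_grid
}
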