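#' Area under a cumulative consumption curve (trapezoidal rule)
#'
#' Integrates the cumulative number of seeds consumed against observation
#' time with the trapezoidal rule, i.e. the curve is taken as linear between
#' observations. Units are seed-minutes. The area is 0 exactly when no seed
#' was consumed within the window.
#'
#' @param schedule_min Strictly increasing observation times in minutes,
#'   starting at 0.
#' @param cumulative_consumed Non-decreasing, non-negative counts aligned to
#'   `schedule_min`, with `cumulative_consumed[1] == 0`.
#' @return Scalar area in seed-minutes.
#' @examples
#' trapezoid_auc(c(0, 15, 30), c(0, 2, 4)) # 60 seed-minutes
#' @export
trapezoid_auc <- function(schedule_min, cumulative_consumed) {
  sf_check_series(schedule_min, cumulative_consumed)
  pracma::trapz(schedule_min, cumulative_consumed)
}

sf_check_series <- function(t, c) {
  sf_check_number(t, "schedule_min", 0)
  sf_check_number(c, "cumulative_consumed", 0)
  if (length(t) != length(c)) {
    sf_stop("schedule_min and cumulative_consumed must be aligned")
  }
  if (length(t) < 1 || t[1] != 0) sf_stop("observation schedule must start at 0")
  if (any(diff(t) <= 0)) sf_stop("schedule_min must be strictly increasing")
  if (any(diff(c) < 0)) sf_stop("cumulative consumption must be non-decreasing")
  invisible(TRUE)
}

#' Seed predation rate at a time cut-off
#'
#' `SP_R` is the percentage of the offered seeds consumed by `cutoff_min`,
#' evaluated as a right-continuous step function: the count at the latest
#' observation at or before the cut-off (the counts actually recorded), not
#' an interpolation.
#'
#' @inheritParams trapezoid_auc
#' @param seeds_offered Positive integer, seeds offered at time 0.
#' @param cutoff_min Cut-off time within the schedule bounds (at or after the
#'   first observation).
#' @return Percent in `[0, 100]`.
#' @examples
#' predation_rate_at(c(0, 15, 30), c(0, 2, 4), 10, 20) # 20%
#' @export
predation_rate_at <- function(schedule_min, cumulative_consumed,
                              seeds_offered, cutoff_min) {
  sf_check_series(schedule_min, cumulative_consumed)
  sf_check_number(seeds_offered, "seeds_offered", 1)
  if (cutoff_min < schedule_min[1]) {
    sf_stop("cutoff_min lies before the first observation")
  }
  at <- max(which(schedule_min <= cutoff_min))
  cumulative_consumed[at] / seeds_offered * 100
}

#' Rodgers' preference index from consumption areas
#'
#' Standardizes each individual-by-species area `A_i` by the maximum area in
#' its standardization scope: `R_i = A_i / max(A_i)`. Scores range from 0 to
#' 1, with 1 the most preferred seed species; at least one score per scope is
#' exactly 1. The default scope standardizes within each vole species (every
#' individual and seed species of that vole pooled); `"global"` pools both
#' vole species.
#'
#' @param scores Tibble with columns `individual`, `vole_species`,
#'   `species_name` and `a_i` (e.g. from [preference_scores()]).
#' @param scope `"per_vole_species"` (default) or `"global"`.
#' @return `scores` with an added `r_i` column.
#' @export
rodgers_index <- function(scores, scope = c("per_vole_species", "global")) {
  scope <- match.arg(scope)
  sf_check_number(scores$a_i, "a_i", 0)
  key <- if (scope == "per_vole_species") {
    as.character(scores$vole_species)
  } else {
    rep("all", nrow(scores))
  }
  mx <- tapply(scores$a_i, key, max)
  if (any(mx <= 0)) {
    sf_stop("rodgers_index: all areas are zero within standardization scope '",
            names(mx)[which(mx <= 0)[1]], "'; the index is undefined")
  }
  scores$r_i <- scores$a_i / as.vector(mx[key])
  scores
}

#' Default cafeteria observation schedule, in minutes
#'
#' Every 15 min for the first 2 h, every 30 min for the following 4 h, and a
#' final inspection at 24 h.
#'
#' @return Numeric vector of observation times.
#' @export
cafeteria_schedule <- function() {
  c(seq(0, 120, by = 15), seq(150, 360, by = 30), 1440)
}

#' Preference scores from cafeteria observation series
#'
#' For every individual-by-seed-species series computes the consumption area
#' `A_i` (trapezoidal rule over the directly observed window, default
#' 0-360 min -- the 24 h final check enters the predation rates only),
#' Rodgers' index `R_i` within the chosen standardization scope, and the
#' predation rates after 6 h and after the final inspection.
#'
#' @param cafeteria Long-format cafeteria records (schema `"cafeteria"`).
#' @param scope Standardization scope for [rodgers_index()].
#' @param window_min Integration window for `A_i` in minutes (default 360);
#'   observations after the window do not contribute to the area.
#' @return Tibble with one row per individual and species: `individual`,
#'   `vole_species`, `species_name`, `a_i`, `r_i`, `sp_r_6h`, `sp_r_24h`.
#' @export
preference_scores <- function(cafeteria, scope = c("per_vole_species", "global"),
                              window_min = 360) {
  scope <- match.arg(scope)
  cafeteria <- validate_table(cafeteria, "cafeteria")
  scores <- cafeteria |>
    group_by(.data$individual, .data$vole_species, .data$species_name) |>
    arrange(.data$time_min, .by_group = TRUE) |>
    summarise(
      a_i = {
        keep <- .data$time_min <= window_min
        trapezoid_auc(.data$time_min[keep], .data$cumulative_consumed[keep])
      },
      sp_r_6h = predation_rate_at(.data$time_min, .data$cumulative_consumed,
                                  .data$seeds_offered[1],
                                  min(360, max(.data$time_min))),
      sp_r_24h = predation_rate_at(.data$time_min, .data$cumulative_consumed,
                                   .data$seeds_offered[1], max(.data$time_min)),
      .groups = "drop"
    )
  rodgers_index(scores, scope)
}

#' Summarize preference scores by species or seed trait
#'
#' Mean and standard error of the 6 h predation rate and of Rodgers' index,
#' separately for each vole species.
#'
#' @param scores Output of [preference_scores()].
#' @param traits Trait table covering every species present.
#' @param group_by One of `"species"`, `"weight_class"`, `"nutrient_flag"`,
#'   `"status"`.
#' @param vole_species Optional: restrict to `"M_arvalis"` or
#'   `"M_glareolus"`; an unknown label is an error.
#' @param threshold_mg Weight-class threshold forwarded to [derive_traits()].
#' @return Tibble with `vole_species`, the grouping column, `n`, and
#'   mean/SE columns for `sp_r_6h` and `r_i`. Empty groups are absent.
#' @export
summarize_preference <- function(scores, traits, group_by = "species",
                                 vole_species = NULL, threshold_mg = 3.62) {
  group_by <- match.arg(group_by, c("species", "weight_class",
                                    "nutrient_flag", "status"))
  traits <- derive_traits(traits, threshold_mg)
  scores$species_name <- match_species(scores$species_name, traits)
  if (!is.null(vole_species)) {
    if (!vole_species %in% sf_enum$vole_species) {
      sf_stop("unknown vole species label: ", vole_species)
    }
    scores <- filter(scores, .data$vole_species == !!vole_species)
  }
  joined <- left_join(scores, traits, by = "species_name")
  joined |>
    group_by(.data$vole_species,
             across(all_of(sf_group_cols[[group_by]]))) |>
    reframe(
      n = n(),
      mean_spr_6h = mean(.data$sp_r_6h),
      se_spr_6h = if (n() > 1) sd(.data$sp_r_6h) / sqrt(n()) else 0,
      mean_ri = mean(.data$r_i),
      se_ri = if (n() > 1) sd(.data$r_i) / sqrt(n()) else 0
    )
}
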