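#' Shannon diversity and Pielou evenness of feeding activity
#'
#' `H = -sum(p_i * log(p_i))` (natural log) over the species with positive
#' counts, with `p_i` the count share; zero-count species contribute nothing.
#' Evenness is `J = H / log(S_offered)`, where `S_offered` is the number of
#' seed species *offered*, not the number actually consumed: with 8 species
#' on offer, a published diversity of H = 1.83 corresponds to
#' J = 1.83 / log(8) = 0.88, which pins down this denominator convention.
#'
#' Because H is invariant to rescaling all counts by a constant, `counts`
#' may be raw feeding-event counts or percentage feeding rates.
#'
#' @param counts Non-negative numeric vector (optionally named by species) of
#'   feeding events or rates; at least one must be positive.
#' @param s_offered Number of seed species offered; must be at least the
#'   number of species with positive counts and greater than 1 (evenness is
#'   undefined for a single category).
#' @return List with elements `H` (nats) and `J` (in `[0, 1]`).
#' @examples
#' shannon_evenness(rep(5, 8), 8) # H = log(8), J = 1
#' @export
shannon_evenness <- function(counts, s_offered) {
  sf_check_number(counts, "counts", 0)
  sf_check_number(s_offered, "s_offered", 1)
  if (all(counts == 0)) sf_stop("all counts are zero; diversity is undefined")
  if (s_offered == 1) sf_stop("evenness is undefined for a single offered species")
  if (sum(counts > 0) > s_offered) {
    sf_stop("more species with positive counts (", sum(counts > 0),
            ") than species offered (", s_offered, ")")
  }
  H <- as.numeric(vegan::diversity(counts, index = "shannon"))
  list(H = H, J = pielou_evenness(H, s_offered))
}

#' Pielou evenness from a Shannon diversity value
#'
#' `J = H / log(S)` with `S` the number of *offered* seed species. Using the
#' offered richness (rather than the richness actually consumed) is the
#' convention adopted throughout this package; it is the only reading under
#' which a diversity of H = 1.83 over 8 offered species gives J = 0.88.
#'
#' @param H Shannon diversity in nats.
#' @param s_offered Number of offered categories (> 1).
#' @return Evenness in `[0, 1]` (up to rounding of `H`).
#' @examples
#' round(pielou_evenness(1.83, 8), 2) # 0.88
#' @export
pielou_evenness <- function(H, s_offered) {
  sf_check_number(H, "H", 0)
  sf_check_number(s_offered, "s_offered", 1)
  if (any(s_offered == 1)) {
    sf_stop("evenness is undefined for a single offered species")
  }
  H / log(s_offered)
}

#' Rodent density from a trapping summary
#'
#' Minimum number alive (captured individuals excluding recaptures) divided
#' by the field area in hectares. Reports conventionally round to 2 decimals.
#'
#' @param n_individuals Non-negative count of distinct individuals.
#' @param field_length_m,field_width_m Field dimensions in metres.
#' @return Individuals per hectare (unrounded).
#' @examples
#' round(rodent_density(10, 198, 53), 2) # 9.53 on a 1.0494 ha field
#' @export
rodent_density <- function(n_individuals, field_length_m, field_width_m) {
  sf_check_number(n_individuals, "n_individuals", 0)
  sf_check_number(field_length_m, "field_length_m", 0, strict = TRUE)
  sf_check_number(field_width_m, "field_width_m", 0, strict = TRUE)
  n_individuals / (field_length_m * field_width_m / 1e4)
}

#' Summaries of video-observed depot visitation
#'
#' @param events Feeding-event log (schema `"events"`); may be empty.
#' @param total_hours Total footage duration in hours.
#' @param depots_observed Number of depots under observation; must be at
#'   least the number of distinct depots with logged events.
#' @return List with `percent_time` (visit seconds as a percentage of the
#'   observation period), `percent_depots_visited`, and `per_guild`, a tibble
#'   of event counts and total durations per guild.
#' @examples
#' ev <- tibble::tibble(guild = "vole", species_name = "Buglossoides arvensis",
#'                      duration_s = rep(2275 / 12, 12), depot = paste0("d", 1:12))
#' video_summary(ev, total_hours = 720, depots_observed = 30)
#' @export
video_summary <- function(events, total_hours, depots_observed) {
  events <- validate_table(events, "events")
  sf_check_number(total_hours, "total_hours", 0, strict = TRUE)
  sf_check_number(depots_observed, "depots_observed", 1)
  visited <- dplyr::n_distinct(events$depot)
  if (visited > depots_observed) {
    sf_stop("distinct visited depots (", visited, ") exceed depots_observed (",
            depots_observed, ")")
  }
  per_guild <- events |>
    group_by(.data$guild) |>
    summarise(n_events = n(), total_duration_s = sum(.data$duration_s),
              .groups = "drop")
  list(
    percent_time = sum(events$duration_s) / (total_hours * 3600) * 100,
    percent_depots_visited = visited / depots_observed * 100,
    per_guild = per_guild
  )
}

#' Per-guild feeding profile: event counts, diversity and evenness
#'
#' Tallies feeding events per seed species within each guild (voles vs mice)
#' and computes Shannon diversity and Pielou evenness against the number of
#' species offered.
#'
#' @param events Feeding-event log (schema `"events"`).
#' @param s_offered Number of seed species offered (default 8, the field
#'   design).
#' @return Tibble with one row per guild present: `guild`, `n_events`,
#'   `n_species_fed`, `total_duration_s`, `H`, `J`.
#' @export
guild_feeding_profile <- function(events, s_offered = 8) {
  events <- validate_table(events, "events")
  if (nrow(events) == 0) sf_stop("no feeding events")
  events |>
    group_by(.data$guild) |>
    summarise(
      n_events = n(),
      n_species_fed = dplyr::n_distinct(.data$species_name),
      total_duration_s = sum(.data$duration_s),
      H = shannon_evenness(as.numeric(table(.data$species_name)), s_offered)$H,
      .groups = "drop"
    ) |>
    mutate(J = pielou_evenness(.data$H, s_offered))
}
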