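#' Rodent-attributable seed removal rate for one depot pair
#'
#' Computes `SR_R = (R_NRA - R_AA) / R_NRA * 100` for a paired exclosure
#' design, where `R_NRA` is the count of seeds remaining on the depot caged
#' against rodents and `R_AA` the count remaining on the open depot of the
#' same plot. Invertebrate removal is assumed equal in both treatments, so a
#' positive difference is attributed to rodents.
#'
#' Inverted pairs (`R_NRA <= R_AA`), which would give a rate of zero or less,
#' are handled by the zero/exclusion correction: the pair is *excluded* when
#' the larger count exceeds the smaller by more than `exclusion_ratio`
#' (default 5:4), and *zeroed* (`SR_R = 0`) otherwise. Two degenerate cases:
#' both depots empty is zeroed; an empty control depot (`R_NRA = 0`) with
#' seeds left on the open depot is excluded (the ratio is undefined and the
#' control is fully depleted).
#'
#' Note that because every positive difference is retained while inversions
#' are zeroed or discarded, the corrected estimator is positively biased
#' whenever both treatments experience stochastic background removal; see the
#' methods vignette.
#'
#' @param r_nra,r_aa Non-negative integer vectors: seeds remaining on the
#'   no-rodent-access and all-access depots.
#' @param exclusion_ratio Positive scalar; pairs whose larger/smaller count
#'   ratio exceeds it are excluded (default `5/4`).
#' @return Tibble with columns `r_nra`, `r_aa`, `status`
#'   (`computed`/`zeroed`/`excluded`) and `sr_r` (percent; `NA` for excluded
#'   pairs).
#' @examples
#' seed_removal_rate(10, 5)          # computed, 50%
#' seed_removal_rate(c(8, 4, 5), c(8, 8, 6))
#' @export
seed_removal_rate <- function(r_nra, r_aa, exclusion_ratio = 5 / 4) {
  sf_check_number(r_nra, "r_nra", 0)
  sf_check_number(r_aa, "r_aa", 0)
  sf_check_number(exclusion_ratio, "exclusion_ratio", 0, strict = TRUE)
  n <- max(length(r_nra), length(r_aa))
  r_nra <- rep_len(r_nra, n)
  r_aa <- rep_len(r_aa, n)

  status <- character(n)
  sr_r <- rep(NA_real_, n)

  computed <- r_nra > r_aa
  status[computed] <- "computed"
  sr_r[computed] <- (r_nra[computed] - r_aa[computed]) / r_nra[computed] * 100

  inv <- !computed
  # ratio of the larger to the smaller count; R_NRA = 0 with R_AA > 0 gives Inf
  ratio <- ifelse(r_nra == 0, ifelse(r_aa == 0, 1, Inf), r_aa / r_nra)
  zeroed <- inv & ratio <= exclusion_ratio
  status[zeroed] <- "zeroed"
  sr_r[zeroed] <- 0
  status[inv & !zeroed] <- "excluded"

  tibble(r_nra = r_nra, r_aa = r_aa, status = status, sr_r = sr_r)
}

#' Pair all-access and no-rodent-access depots by plot, round and species
#'
#' @param depots Depot records (schema `"depots"`); each
#'   (plot, round, species) key may hold at most one record per treatment.
#'   Keys present in only one treatment are reported with a warning and
#'   omitted. Pairs whose two depots offered different seed numbers are an
#'   error (the removal rate compares raw counts).
#' @return Tibble with one row per complete pair: `replication`, `plot`,
#'   `sowing_rate`, `round`, `species_name`, `seeds_offered`, `r_nra`, `r_aa`.
#' @export
pair_depots <- function(depots) {
  depots <- validate_table(depots, "depots")
  wide <- depots |>
    mutate(treatment = ifelse(.data$treatment == "all_access", "r_aa", "r_nra")) |>
    pivot_wider(
      id_cols = c("replication", "plot", "sowing_rate", "round", "species_name"),
      names_from = "treatment",
      values_from = c("seeds_remaining", "seeds_offered")
    )
  for (col in c("seeds_remaining_r_nra", "seeds_remaining_r_aa",
                "seeds_offered_r_nra", "seeds_offered_r_aa")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  unpaired <- is.na(wide$seeds_remaining_r_nra) | is.na(wide$seeds_remaining_r_aa)
  if (any(unpaired)) {
    warning(sum(unpaired), " unpaired depot key(s) omitted (single treatment ",
            "present)", call. = FALSE)
    wide <- wide[!unpaired, ]
  }
  mismatch <- wide$seeds_offered_r_nra != wide$seeds_offered_r_aa
  if (any(mismatch)) {
    sf_stop("pair_depots: seeds_offered differs within ", sum(mismatch),
            " depot pair(s); removal rates compare raw counts and require ",
            "equal offerings")
  }
  wide |>
    transmute(.data$replication, .data$plot, .data$sowing_rate, .data$round,
              .data$species_name, seeds_offered = .data$seeds_offered_r_nra,
              r_nra = .data$seeds_remaining_r_nra,
              r_aa = .data$seeds_remaining_r_aa)
}

#' Per-pair removal rates with the zero/exclusion correction
#'
#' Convenience wrapper: [pair_depots()] followed by [seed_removal_rate()].
#'
#' @inheritParams pair_depots
#' @inheritParams seed_removal_rate
#' @return Tibble of removal records: pairing keys plus `status` and `sr_r`.
#' @export
removal_rates <- function(depots, exclusion_ratio = 5 / 4) {
  pairs <- pair_depots(depots)
  rate <- seed_removal_rate(pairs$r_nra, pairs$r_aa, exclusion_ratio)
  pairs$status <- rate$status
  pairs$sr_r <- rate$sr_r
  pairs
}

#' Average removal rates over sampling rounds
#'
#' Excluded records are removed before averaging; a (plot, species) key whose
#' records are excluded in every round is absent from the result; keys
#' observed in a single round carry that round's value.
#'
#' @param removal Output of [removal_rates()] (or a compatible tibble with
#'   `status` and `sr_r`).
#' @return Tibble keyed by (replication, plot, sowing_rate, species_name)
#'   with `sr_r` (mean over retained rounds) and `n_rounds` used.
#' @export
average_rounds <- function(removal) {
  removal |>
    filter(.data$status != "excluded") |>
    group_by(.data$replication, .data$plot, .data$sowing_rate,
             .data$species_name) |>
    summarise(sr_r = mean(.data$sr_r), n_rounds = n(), .groups = "drop")
}

sf_group_cols <- list(
  species = "species_name",
  sowing_rate = "sowing_rate",
  weight_class = "weight_class",
  nutrient_flag = "nutrient_flag",
  status = "status",
  species_x_sowing_rate = c("species_name", "sowing_rate")
)

# mean/SE summary used by both removal and preference tables; SE of a
# singleton group is reported as 0 (the n column flags n = 1 groups)
sf_mean_se <- function(x) {
  n <- sum(!is.na(x))
  tibble(n = n, mean = mean(x, na.rm = TRUE),
         se = if (n > 1) sd(x, na.rm = TRUE) / sqrt(n) else 0)
}

#' Summarize removal rates by species, sowing rate or seed trait
#'
#' @param removal_avg Round-averaged removal records from [average_rounds()].
#' @param traits Trait table covering every species present (error otherwise).
#' @param group_by One of `"species"`, `"sowing_rate"`, `"weight_class"`,
#'   `"nutrient_flag"`, `"status"`, `"species_x_sowing_rate"`. `"status"`
#'   refers to the plants' Red-List status (common/endangered).
#' @param threshold_mg Weight-class threshold forwarded to [derive_traits()].
#' @return Tibble with the grouping column(s), `n`, `mean_srr` and `se_srr`
#'   (sample SD / sqrt(n); 0 for singleton groups, flagged by `n = 1`).
#'   Groups with no records are absent.
#' @export
summarize_removal <- function(removal_avg, traits,
                              group_by = "species", threshold_mg = 3.62) {
  group_by <- match.arg(group_by, names(sf_group_cols))
  traits <- derive_traits(traits, threshold_mg)
  removal_avg$species_name <- match_species(removal_avg$species_name, traits)
  joined <- removal_avg |>
    select(-any_of("status")) |>
    left_join(traits, by = "species_name")
  joined |>
    group_by(across(all_of(sf_group_cols[[group_by]]))) |>
    reframe(sf_mean_se(.data$sr_r)) |>
    rename(mean_srr = "mean", se_srr = "se")
}
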