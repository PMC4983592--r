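#' Seed recovery after gut passage
#'
#' Summarizes intact seeds retrieved from feces samples: per-individual
#' totals (mean and standard error over individuals, zeros included),
#' per-species tallies, and germination of the recovered seeds.
#'
#' @param feces Feces records (schema `"feces"`): one row per individual and
#'   recovered species; individuals with no recovered seeds carry a single
#'   placeholder row with `species_name = NA` and `n_recovered = 0`.
#' @return Object of class `recovery_report`: a list with `n_individuals`,
#'   `total_recovered`, `per_species_recovered` (named integer vector),
#'   `mean_per_individual`, `se_per_individual`, `per_species_germinated`,
#'   and `germination_digested_pct` (pooled over species; `NA` when nothing
#'   was recovered).
#' @export
recovery_rate <- function(feces) {
  feces <- validate_table(feces, "feces")
  if (nrow(feces) == 0) sf_stop("recovery_rate: empty feces collection")
  per_ind <- feces |>
    group_by(.data$individual) |>
    summarise(total = sum(.data$n_recovered), .groups = "drop")
  per_sp <- feces |>
    filter(!is.na(.data$species_name), .data$n_recovered > 0) |>
    group_by(.data$species_name) |>
    summarise(recovered = sum(.data$n_recovered),
              germinated = sum(.data$n_germinated), .groups = "drop")
  total <- sum(per_ind$total)
  n <- nrow(per_ind)
  structure(list(
    n_individuals = n,
    total_recovered = total,
    per_species_recovered = stats::setNames(per_sp$recovered, per_sp$species_name),
    mean_per_individual = total / n,
    se_per_individual = if (n > 1) sd(per_ind$total) / sqrt(n) else 0,
    per_species_germinated = stats::setNames(per_sp$germinated, per_sp$species_name),
    germination_digested_pct =
      if (total > 0) sum(per_sp$germinated) / total * 100 else NA_real_
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Seed recovery from %d feces samples\n", x$n_individuals))
  cat(sprintf("  %d intact seed(s) recovered: %.1f +/- %.1f seeds per individual\n",
              x$total_recovered, x$mean_per_individual, x$se_per_individual))
  if (x$total_recovered > 0) {
    for (s in names(x$per_species_recovered)) {
      cat(sprintf("  %s: %d recovered, %d germinated\n", s,
                  x$per_species_recovered[[s]], x$per_species_germinated[[s]]))
    }
    cat(sprintf("  germination of digested seeds (pooled): %.1f%%\n",
                x$germination_digested_pct))
  }
  invisible(x)
}

#' Germination rate in percent
#'
#' @param n_germinated Non-negative count(s) of germinated seeds.
#' @param n_tested Positive count(s) of seeds tested.
#' @return Percentage(s) of germinated seeds.
#' @examples
#' germination_rate(30, 40) # 75%
#' @export
germination_rate <- function(n_germinated, n_tested) {
  sf_check_number(n_germinated, "n_germinated", 0)
  sf_check_number(n_tested, "n_tested", 1)
  if (any(n_germinated > n_tested)) {
    sf_stop("n_germinated exceeds n_tested")
  }
  n_germinated / n_tested * 100
}

#' Compare germination of digested versus undigested seeds
#'
#' Difference in germination percentage (digested minus undigested) together
#' with the exact conditional two-sided p-value of the 2x2 count table
#' (Fisher's exact test). Counts in germination assays after gut passage are
#' tiny, so an exact test on the contingency table is the natural choice.
#'
#' @param digested,undigested One-row germination assays (schema
#'   `"germination"`) for the same species, with conditions `"digested"` and
#'   `"undigested"` respectively.
#' @return List with `species_name`, `difference_pct` (percentage points) and
#'   `p_value`.
#' @examples
#' d <- tibble::tibble(species_name = "Capsella bursa-pastoris",
#'                     condition = "digested", n_tested = 5, n_germinated = 1)
#' u <- tibble::tibble(species_name = "Capsella bursa-pastoris",
#'                     condition = "undigested", n_tested = 40, n_germinated = 30)
#' compare_germination(d, u)
#' @export
compare_germination <- function(digested, undigested) {
  digested <- validate_table(digested, "germination")
  undigested <- validate_table(undigested, "germination")
  if (nrow(digested) != 1 || nrow(undigested) != 1) {
    sf_stop("compare_germination expects one assay per condition")
  }
  if (sf_species_key(digested$species_name) !=
      sf_species_key(undigested$species_name)) {
    sf_stop("assays are for different species: ", digested$species_name,
            " vs ", undigested$species_name)
  }
  if (digested$condition != "digested" || undigested$condition != "undigested") {
    sf_stop("assay conditions must be 'digested' and 'undigested'")
  }
  tab <- matrix(c(digested$n_germinated,
                  digested$n_tested - digested$n_germinated,
                  undigested$n_germinated,
                  undigested$n_tested - undigested$n_germinated),
                nrow = 2)
  list(
    species_name = digested$species_name,
    difference_pct = germination_rate(digested$n_germinated, digested$n_tested) -
      germination_rate(undigested$n_germinated, undigested$n_tested),
    p_value = fisher.test(tab)$p.value
  )
}
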