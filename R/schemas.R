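#' Classify seed weight into light/heavy classes
#'
#' Seed weight is dichotomized at a threshold (default 3.62 mg, the break used
#' for the 15-species set analysed by this package). A weight exactly equal to
#' the threshold is classed `"light"`: the threshold acts as the upper break of
#' the light interval, mirroring interval-cut semantics. This boundary
#' convention is a package choice; published classifications never place a
#' species exactly on the break.
#'
#' @param seed_weight_mg Numeric vector of per-seed weights in milligrams;
#'   all values must be positive.
#' @param threshold_mg Positive scalar threshold in milligrams (default 3.62).
#' @return Character vector of `"light"` / `"heavy"`, same length as input.
#' @examples
#' classify_weight(c(0.5, 3.62, 7.2))
#' @export
classify_weight <- function(seed_weight_mg, threshold_mg = 3.62) {
  sf_check_number(seed_weight_mg, "seed_weight_mg", 0, strict = TRUE)
  sf_check_number(threshold_mg, "threshold_mg", 0, strict = TRUE)
  if (length(threshold_mg) != 1) sf_stop("threshold_mg must be a single value")
  ifelse(seed_weight_mg <= threshold_mg, "light", "heavy")
}

#' Derive the full trait table (adds the weight class)
#'
#' @param traits Trait table with columns `species_name`, `seed_weight_mg`,
#'   `nutrient_flag`, `status` (see [load_table()], schema `"traits"`).
#' @param threshold_mg Weight-class threshold in mg passed to
#'   [classify_weight()].
#' @return The trait tibble with an added `weight_class` column.
#' @export
derive_traits <- function(traits, threshold_mg = 3.62) {
  traits <- validate_table(traits, "traits")
  traits$weight_class <- classify_weight(traits$seed_weight_mg, threshold_mg)
  traits
}

# canonical key for case-insensitive, whitespace-normalized species matching
sf_species_key <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Match species names in a data table against a trait table
#'
#' Names are compared case-insensitively after whitespace normalization.
#' Species present in the data but absent from the trait table are an error
#' (never a silent drop).
#'
#' @param species Character vector of species names appearing in a data table.
#' @param traits Validated trait table.
#' @return Character vector of canonical names as spelled in `traits`.
#' @export
match_species <- function(species, traits) {
  key <- sf_species_key(species)
  tkey <- sf_species_key(traits$species_name)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    missing <- unique(species[is.na(idx)])
    sf_stop("species not present in the trait table: ",
            paste(missing, collapse = ", "))
  }
  traits$species_name[idx]
}

## ---- schema registry -------------------------------------------------------

sf_enum <- list(
  sowing_rate  = c("normal", "reduced"),
  treatment    = c("all_access", "no_rodent_access"),
  vole_species = c("M_arvalis", "M_glareolus"),
  sex          = c("F", "M"),
  status       = c("common", "endangered"),
  guild        = c("vole", "mouse"),
  condition    = c("digested", "undigested")
)

# column type spec per schema; "c" character, "d" double, "i" integer
sf_schema_cols <- list(
  traits = c(species_name = "c", seed_weight_mg = "d", nutrient_flag = "i",
             status = "c"),
  depots = c(replication = "i", plot = "c", sowing_rate = "c", treatment = "c",
             round = "i", species_name = "c", seeds_offered = "i",
             seeds_remaining = "i"),
  cafeteria = c(individual = "c", vole_species = "c", sex = "c",
                body_weight_g = "d", species_name = "c", time_min = "d",
                cumulative_consumed = "i", seeds_offered = "i"),
  events = c(guild = "c", species_name = "c", duration_s = "d", depot = "c"),
  trapping = c(n_individuals = "i", field_length_m = "d", field_width_m = "d"),
  feces = c(individual = "c", seeds_fed_total = "i", species_name = "c",
            n_recovered = "i", n_germinated = "i"),
  germination = c(species_name = "c", condition = "c", n_tested = "i",
                  n_germinated = "i")
)

#' Names of the tabular schemas understood by the package
#' @return Character vector of schema names.
#' @export
schema_names <- function() names(sf_schema_cols)

sf_rows <- function(i) paste0("row ", paste(head(which(i), 5), collapse = ", "))

sf_check_enum <- function(df, col, schema) {
  levels <- sf_enum[[col]]
  bad <- !is.na(df[[col]]) & !(df[[col]] %in% levels)
  if (any(bad)) {
    sf_stop(schema, ": ", sf_rows(bad), ": field '", col, "' must be one of ",
            paste(levels, collapse = "/"), " (got '",
            df[[col]][which(bad)[1]], "')")
  }
}

sf_check_range <- function(df, col, schema, lower = 0, upper_col = NULL,
                           strict = FALSE, allow_na = FALSE) {
  x <- df[[col]]
  bad <- if (strict) x <= lower else x < lower
  if (!is.null(upper_col)) bad <- bad | x > df[[upper_col]]
  bad[is.na(x)] <- !allow_na
  if (any(bad)) {
    sf_stop(schema, ": ", sf_rows(bad), ": field '", col, "' out of range",
            if (!is.null(upper_col)) paste0(" (must be within [", lower, ", ",
                                            upper_col, "])"))
  }
}

## ---- per-schema validators -------------------------------------------------

sf_validate_traits <- function(df) {
  sf_check_range(df, "seed_weight_mg", "traits", 0, strict = TRUE)
  sf_check_range(df, "nutrient_flag", "traits", 0, upper_col = NULL)
  bad <- !(df$nutrient_flag %in% c(0L, 1L))
  if (any(bad)) sf_stop("traits: ", sf_rows(bad), ": nutrient_flag must be 0 or 1")
  sf_check_enum(df, "status", "traits")
  dup <- duplicated(sf_species_key(df$species_name))
  if (any(dup)) sf_stop("traits: ", sf_rows(dup), ": duplicated species_name")
  df
}

sf_validate_depots <- function(df) {
  sf_check_enum(df, "sowing_rate", "depots")
  sf_check_enum(df, "treatment", "depots")
  bad <- !(df$round %in% c(1L, 2L))
  if (any(bad)) sf_stop("depots: ", sf_rows(bad), ": round must be 1 or 2")
  sf_check_range(df, "seeds_offered", "depots", 0, strict = TRUE)
  sf_check_range(df, "seeds_remaining", "depots", 0, upper_col = "seeds_offered")
  key <- paste(df$plot, df$round, sf_species_key(df$species_name), df$treatment)
  dup <- duplicated(key)
  if (any(dup)) {
    sf_stop("depots: ", sf_rows(dup),
            ": duplicate (plot, round, species, treatment) record")
  }
  df
}

sf_validate_cafeteria <- function(df) {
  sf_check_enum(df, "vole_species", "cafeteria")
  sf_check_enum(df, "sex", "cafeteria")
  sf_check_range(df, "body_weight_g", "cafeteria", 0, strict = TRUE)
  sf_check_range(df, "seeds_offered", "cafeteria", 1)
  sf_check_range(df, "time_min", "cafeteria", 0)
  sf_check_range(df, "cumulative_consumed", "cafeteria", 0,
                 upper_col = "seeds_offered")
  # per-series structural invariants
  chk <- df |>
    group_by(.data$individual, .data$species_name) |>
    arrange(.data$time_min, .by_group = TRUE) |>
    summarise(
      starts_zero = .data$time_min[1] == 0 & .data$cumulative_consumed[1] == 0,
      increasing = all(diff(.data$time_min) > 0),
      monotone = all(diff(.data$cumulative_consumed) >= 0),
      .groups = "drop"
    )
  if (!all(chk$starts_zero)) {
    b <- chk[!chk$starts_zero, ][1, ]
    sf_stop("cafeteria: series (", b$individual, ", ", b$species_name,
            ") must start at time 0 with 0 seeds consumed")
  }
  if (!all(chk$increasing)) {
    b <- chk[!chk$increasing, ][1, ]
    sf_stop("cafeteria: series (", b$individual, ", ", b$species_name,
            ") has non-increasing observation times")
  }
  if (!all(chk$monotone)) {
    b <- chk[!chk$monotone, ][1, ]
    sf_stop("cafeteria: series (", b$individual, ", ", b$species_name,
            ") has decreasing cumulative consumption")
  }
  df
}

sf_validate_events <- function(df) {
  sf_check_enum(df, "guild", "events")
  sf_check_range(df, "duration_s", "events", 0)
  df
}

sf_validate_trapping <- function(df) {
  sf_check_range(df, "n_individuals", "trapping", 0)
  sf_check_range(df, "field_length_m", "trapping", 0, strict = TRUE)
  sf_check_range(df, "field_width_m", "trapping", 0, strict = TRUE)
  df
}

sf_validate_feces <- function(df) {
  sf_check_range(df, "seeds_fed_total", "feces", 1)
  sf_check_range(df, "n_recovered", "feces", 0)
  sf_check_range(df, "n_germinated", "feces", 0, upper_col = "n_recovered")
  # a species may be NA only on a zero-recovery placeholder row
  bad <- is.na(df$species_name) & df$n_recovered > 0
  if (any(bad)) {
    sf_stop("feces: ", sf_rows(bad), ": species_name missing on a row with ",
            "recovered seeds")
  }
  df
}

sf_validate_germination <- function(df) {
  sf_check_enum(df, "condition", "germination")
  sf_check_range(df, "n_tested", "germination", 1)
  sf_check_range(df, "n_germinated", "germination", 0, upper_col = "n_tested")
  df
}

sf_validators <- list(
  traits = sf_validate_traits, depots = sf_validate_depots,
  cafeteria = sf_validate_cafeteria, events = sf_validate_events,
  trapping = sf_validate_trapping, feces = sf_validate_feces,
  germination = sf_validate_germination
)

#' Validate a tabular record collection against a named schema
#'
#' Checks required columns, coerces integer-like columns, enforces enumerated
#' values and row-level invariants (e.g. `seeds_remaining <= seeds_offered`,
#' non-decreasing cumulative consumption). Violations raise an error naming
#' the schema, the offending row numbers and the field.
#'
#' @param df A data frame.
#' @param schema_name One of [schema_names()].
#' @return The validated tibble (invisibly usable in pipelines).
#' @export
validate_table <- function(df, schema_name) {
  schema_name <- match.arg(schema_name, schema_names())
  spec <- sf_schema_cols[[schema_name]]
  missing <- setdiff(names(spec), names(df))
  if (length(missing)) {
    sf_stop(schema_name, ": missing required column(s): ",
            paste(missing, collapse = ", "))
  }
  df <- as_tibble(df)[, names(spec)]
  for (col in names(spec)) {
    x <- df[[col]]
    if (nrow(df) == 0) { # empty collections carry typed empty columns
      df[[col]] <- switch(spec[[col]], c = character(), i = integer(),
                          d = double())
      next
    }
    if (spec[[col]] == "c") {
      df[[col]] <- as.character(x)
    } else if (spec[[col]] == "i") {
      if (!is.numeric(x)) sf_stop(schema_name, ": column '", col, "' must be numeric")
      if (any(!is.na(x) & x != round(x))) {
        sf_stop(schema_name, ": column '", col, "' must be whole numbers")
      }
      df[[col]] <- as.integer(round(x))
    } else {
      if (!is.numeric(x)) sf_stop(schema_name, ": column '", col, "' must be numeric")
      df[[col]] <- as.double(x)
    }
  }
  na_ok <- if (schema_name == "feces") "species_name" else character()
  for (col in setdiff(names(spec), na_ok)) {
    if (anyNA(df[[col]])) {
      sf_stop(schema_name, ": ", sf_rows(is.na(df[[col]])),
              ": field '", col, "' is missing")
    }
  }
  sf_validators[[schema_name]](df)
}

#' Read and validate a CSV table
#'
#' CSV dialect: UTF-8, comma-separated, `.` decimal mark, header row
#' mandatory. An empty file (header only) yields an empty collection with a
#' warning.
#'
#' @param path Path to a CSV file.
#' @param schema_name One of [schema_names()].
#' @return Validated tibble.
#' @export
load_table <- function(path, schema_name) {
  schema_name <- match.arg(schema_name, schema_names())
  if (!file.exists(path)) sf_stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) warning("empty table (header only): ", path, call. = FALSE)
  validate_table(df, schema_name)
}

#' Validate and write a table to CSV
#'
#' Writing then re-reading with [load_table()] is lossless field by field.
#'
#' @param df Table conforming to `schema_name`.
#' @param path Output CSV path.
#' @param schema_name One of [schema_names()].
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema_name) {
  df <- validate_table(df, schema_name)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
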