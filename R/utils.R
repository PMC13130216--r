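# Shared helpers: string normalisation, FAERS date handling, rounding.

#' Normalise free-text terms for matching
#'
#' Case-folds, trims, and collapses internal whitespace.  All drug-name and
#' preferred-term matching in the package goes through this normalisation;
#' no fuzzy matching is attempted.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
fold_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(as.character(x)))
}

# Round half away from zero (the convention used when rendering percentages,
# so 0.25 -> 0.3 rather than banker's 0.2).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parse FAERS-style dates
#'
#' FAERS date fields are numeric strings: `YYYYMMDD` (full precision),
#' `YYYYMM`, or `YYYY` (partial).  Partial dates are padded with `01`
#' components so that every parseable date yields a calendar date usable
#' for ordering (deduplication needs a total order), while the `full`
#' flag records whether the day was actually present -- onset arithmetic
#' requires day precision and treats partial dates as missing.
#'
#' @param x Character (or numeric) vector of raw date fields.
#' @return A tibble with columns `date` (Date, `NA` if unparseable) and
#'   `full` (logical, `TRUE` only for valid 8-digit dates).
#' @export
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[!stringr::str_detect(x, "^[0-9]{4}([0-9]{2}([0-9]{2})?)?$") | is.na(x)] <- NA_character_
  padded <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 4L ~ paste0(x, "0101"),
    nchar(x) == 6L ~ paste0(x, "01"),
    TRUE ~ x
  )
  date <- as.Date(padded, format = "%Y%m%d")
  tibble::tibble(date = date, full = !is.na(date) & !is.na(x) & nchar(x) == 8L)
}

format_faers_date <- function(date) {
  ifelse(is.na(date), NA_character_, format(date, "%Y%m%d"))
}

# Deterministic per-module substream seed derived from the run seed, kept
# inside 32-bit integer range.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Age unit conversion.  Codes follow the FDA ASCII dialect; missing code
# with a present value is taken to be years.
convert_age_years <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(stringr::str_trim(ifelse(is.na(age_cod), "YR", age_cod)))
  cod[cod == ""] <- "YR"
  mult <- dplyr::case_when(
    cod == "DEC" ~ 10,
    cod == "YR" ~ 1,
    cod == "MON" ~ 1 / 12,
    cod == "WK" ~ 1 / 52.1775,
    cod == "DY" ~ 1 / 365.25,
    cod == "HR" ~ 1 / 8766,
    TRUE ~ NA_real_
  )
  out <- age * mult
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

convert_weight_kg <- function(wt, wt_cod) {
  wt <- suppressWarnings(as.numeric(wt))
  cod <- toupper(stringr::str_trim(ifelse(is.na(wt_cod), "KG", wt_cod)))
  cod[cod == ""] <- "KG"
  mult <- dplyr::case_when(
    cod == "KG" ~ 1,
    cod == "LBS" ~ 0.45359237,
    cod == "GMS" ~ 1 / 1000,
    TRUE ~ NA_real_
  )
  out <- wt * mult
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

map_reporter_code <- function(occp_cod) {
  cod <- toupper(stringr::str_trim(as.character(occp_cod)))
  dplyr::case_when(
    cod %in% "MD" ~ "physician",
    cod %in% "PH" ~ "pharmacist",
    cod %in% c("OT", "HP") ~ "other_health",
    cod %in% "CN" ~ "consumer",
    TRUE ~ NA_character_
  )
}

# Covariate bins used throughout the descriptive and regression layers.
age_bin_levels <- c("<18", "18-65", ">=65")
weight_bin_levels <- c("<50", "50-80", ">=80")

bin_age <- function(age_years) {
  factor(
    dplyr::case_when(
      is.na(age_years) ~ NA_character_,
      age_years < 18 ~ "<18",
      age_years < 65 ~ "18-65",
      TRUE ~ ">=65"
    ),
    levels = age_bin_levels
  )
}

bin_weight <- function(weight_kg) {
  factor(
    dplyr::case_when(
      is.na(weight_kg) ~ NA_character_,
      weight_kg < 50 ~ "<50",
      weight_kg < 80 ~ "50-80",
      TRUE ~ ">=80"
    ),
    levels = weight_bin_levels
  )
}

outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

# Display grouping of FAERS outcome codes.  DE/LT/HO/DS map to their usual
# labels; congenital anomaly, required intervention and "other" are pooled
# as "Other outcomes".  Severity order breaks ties when one report carries
# several codes.
outcome_group_levels <- c("Died", "Life threatening", "Hospitalized",
                          "Disabled", "Other outcomes")

outcome_group <- function(codes) {
  if (length(codes) == 0 || all(is.na(codes))) {
    return(NA_character_)
  }
  codes <- intersect(toupper(codes), outcome_codes)
  if (length(codes) == 0) {
    return(NA_character_)
  }
  if ("DE" %in% codes) "Died"
  else if ("LT" %in% codes) "Life threatening"
  else if ("HO" %in% codes) "Hospitalized"
  else if ("DS" %in% codes) "Disabled"
  else "Other outcomes"
}
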