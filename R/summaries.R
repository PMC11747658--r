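#' @name summaries
#' @title Clinical characteristics and annual-trend summaries
#' @description
#' Descriptive tables over a flagged cohort: gender, age band, reporter
#' occupation, serious-outcome and fatality strata per drug and pooled, and
#' the calendar-year reporting trend. Ages arrive with mixed unit codes
#' (decades, years, months, weeks, days, hours) and are converted to years
#' before binning.
NULL

OCCP_LABELS <- c(MD = "Physician", PH = "Pharmacist",
                 OT = "Other health professionals", CN = "Consumer",
                 RN = "Registered nurse", HP = "Health Professionals",
                 LW = "Lawyer")

OUTC_LABELS <- c(DE = "Death", DS = "Disability",
                 HO = "Hospitalization-initial or prolonged",
                 LT = "Life-threatening",
                 OT = "Other important medical events",
                 CA = "Congenital anomaly", RI = "Required intervention")

AGE_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                 DY = 1 / 365.25, HR = 1 / 8766)

AGE_BANDS <- c("<18", "18-64.9", "65-85", ">85", "Unknown")

#' Convert reported age to years
#'
#' FAERS ages carry a unit code: DEC (decades, x10), YR (x1), MON (/12),
#' WK (/52), DY (/365.25), HR (/8766). A value without a recognised unit
#' code, or a negative age, converts to missing with a warning.
#'
#' @param age numeric vector of reported ages.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years (`NA` where unresolvable).
#' @export
#' @examples
#' age_in_years(c(6, 7, 730.5), c("MON", "DEC", "DY"))
age_in_years <- function(age, age_cod) {
  fac <- AGE_FACTORS[toupper(age_cod)]
  out <- age * fac
  bad_unit <- !is.na(age) & is.na(fac)
  if (any(bad_unit)) {
    warning(sum(bad_unit), " age value(s) without a recognised unit code set to missing",
            call. = FALSE)
    out[bad_unit] <- NA_real_
  }
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    warning(sum(neg), " negative age(s) set to missing", call. = FALSE)
    out[neg] <- NA_real_
  }
  unname(out)
}

#' Assign ages in years to the reporting age bands
#'
#' Bands are `[0, 18)`, `[18, 65)` (labelled "18-64.9"), `[65, 85]`,
#' `(85, Inf)`; missing ages map to "Unknown". The 65.0 and 85.0 boundaries
#' belong to the "65-85" band, matching the "18-64.9" label convention.
#'
#' @param years numeric vector of ages in years.
#' @return character vector of band labels.
#' @export
bin_age <- function(years) {
  dplyr::case_when(
    is.na(years) ~ "Unknown",
    years < 18 ~ "<18",
    years < 65 ~ "18-64.9",
    years <= 85 ~ "65-85",
    TRUE ~ ">85"
  )
}

# per-case covariates used by the characteristics table
case_covariates <- function(fd) {
  demo <- fd$demo |>
    dplyr::mutate(
      age_years = age_in_years(.data$age, .data$age_cod),
      age_band = bin_age(.data$age_years),
      gender = dplyr::case_when(.data$sex == "F" ~ "Female",
                                .data$sex == "M" ~ "Male",
                                TRUE ~ "Unknown"),
      reporter = dplyr::coalesce(unname(OCCP_LABELS[.data$occp_cod]), "Unknown")
    )
  fatal_ids <- unique(fd$outc$primaryid[fd$outc$outc_cod == "DE"])
  demo$fatal <- demo$primaryid %in% fatal_ids
  demo
}

#' Clinical characteristics strata per drug and pooled
#'
#' Builds the gender / age-band / reporter / serious-outcome / fatality
#' strata of a flagged cohort, per annotated drug and pooled over distinct
#' cases (a case with two primary-suspect statins appears under each drug but
#' once in the pooled column). Within the gender, age and reporter families
#' the counts (including Unknown) sum to the column total; serious outcomes
#' are counted once per (case, outcome code), so that family can exceed the
#' case count. Fatal means at least one Death (DE) outcome. Percentages are
#' over the column case total, rounded half-up to one decimal.
#'
#' @param fd a `faers_data` cohort (deduplicated, event-flagged cases).
#' @param annotations tibble `primaryid`, `drug` (see
#'   [filter_primary_suspect()]).
#' @param pooled_label label for the pooled column (default `"all"`).
#' @return tibble with columns `family`, `level`, `drug`, `n`, `pct`.
#' @export
characteristics_table <- function(fd, annotations, pooled_label = "all") {
  cov <- case_covariates(fd)
  pooled <- dplyr::mutate(cov, drug = pooled_label)
  per_drug <- dplyr::inner_join(annotations, cov, by = "primaryid")
  all_cov <- dplyr::bind_rows(per_drug, pooled)

  outc <- fd$outc |>
    dplyr::distinct(.data$primaryid, .data$outc_cod) |>
    dplyr::mutate(level = unname(OUTC_LABELS[.data$outc_cod]))
  outc_drug <- dplyr::bind_rows(
    dplyr::inner_join(annotations, outc, by = "primaryid"),
    dplyr::mutate(outc, drug = pooled_label)
  )

  totals <- all_cov |> dplyr::count(.data$drug, name = "n_cases")

  one_family <- function(df, var, family) {
    df |>
      dplyr::count(.data$drug, level = .data[[var]]) |>
      dplyr::mutate(family = family)
  }
  gender <- one_family(all_cov, "gender", "gender")
  ageb <- one_family(all_cov, "age_band", "age")
  rep_ <- one_family(all_cov, "reporter", "reporter")

  no_outc <- all_cov |>
    dplyr::anti_join(dplyr::distinct(outc, .data$primaryid), by = "primaryid") |>
    dplyr::count(.data$drug) |>
    dplyr::mutate(level = "Unknown", family = "serious_outcome")
  serious <- outc_drug |>
    dplyr::count(.data$drug, .data$level) |>
    dplyr::mutate(family = "serious_outcome") |>
    dplyr::bind_rows(no_outc)

  fatality <- all_cov |>
    dplyr::mutate(level = dplyr::if_else(.data$fatal, "Fatal outcome",
                                         "Non-fatal outcome")) |>
    dplyr::count(.data$drug, .data$level) |>
    dplyr::mutate(family = "fatality")

  dplyr::bind_rows(gender, ageb, rep_, serious, fatality) |>
    dplyr::left_join(totals, by = "drug") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / .data$n_cases, 1)) |>
    dplyr::select("family", "level", "drug", "n", "pct") |>
    dplyr::arrange(.data$family, .data$drug, .data$level)
}

#' Annual reporting trend
#'
#' Counts per calendar year (from the FDA receipt date of the kept case
#' version) by annotated drug, plus yearly totals over distinct cases and
#' each year's share of the grand total (percent, one decimal, half-up).
#'
#' @param fd a `faers_data` cohort.
#' @param annotations tibble `primaryid`, `drug`.
#' @return list with `by_drug` (tibble `year`, `drug`, `n`) and `totals`
#'   (tibble `year`, `n`, `share_pct`).
#' @export
annual_trend <- function(fd, annotations) {
  demo <- dplyr::mutate(fd$demo, year = as.integer(substr(.data$fda_dt, 1, 4)))
  by_drug <- dplyr::inner_join(annotations, demo, by = "primaryid") |>
    dplyr::count(.data$year, .data$drug)
  totals <- demo |>
    dplyr::count(.data$year) |>
    dplyr::mutate(share_pct = round_half_up(100 * .data$n / sum(.data$n), 1))
  list(by_drug = by_drug, totals = totals)
}
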