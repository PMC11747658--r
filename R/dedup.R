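#' Deduplicate versioned case reports
#'
#' FAERS cases are re-submitted as new versions; analyses keep exactly one
#' record per `caseid`. The rule follows FDA guidance: retain the version with
#' the latest FDA receipt date (`fda_dt`), breaking ties by the numerically
#' largest `primaryid`. Records without a `caseid` are quarantined and
#' counted, never silently dropped. The output is sorted by `caseid`, so the
#' result does not depend on input order.
#'
#' @param fd a `faers_data` object (see [assemble_cases()]).
#' @return a `faers_data` object with one DEMO row per `caseid` and the
#'   satellite tables restricted to the kept `primaryid`s. Carries a `dedup`
#'   attribute: `n_input`, `n_kept`, `n_removed`, `n_quarantined`
#'   (conservation: `n_input = n_kept + n_removed + n_quarantined`).
#' @export
deduplicate_cases <- function(fd) {
  stopifnot(inherits(fd, "faers_data"))
  demo <- fd$demo
  n_input <- nrow(demo)
  quarantine <- is.na(demo$caseid) | trimws(demo$caseid) == ""
  n_quarantined <- sum(quarantine)
  demo <- demo[!quarantine, , drop = FALSE]

  kept <- demo |>
    dplyr::mutate(.fda = as.numeric(.data$fda_dt),
                  .pid = as.numeric(.data$primaryid)) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$.fda), dplyr::desc(.data$.pid)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-".fda", -".pid")

  out <- subset_faers(fd, kept$primaryid)
  out$demo <- kept
  attr(out, "dedup") <- list(n_input = n_input,
                             n_kept = nrow(kept),
                             n_removed = n_input - n_quarantined - nrow(kept),
                             n_quarantined = n_quarantined)
  out
}
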