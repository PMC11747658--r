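#' Build a 2x2 contingency table for a drug/event pair
#'
#' Counts are case-level: a case with three matching reactions still
#' contributes one report. With the full reporting universe as comparator,
#' * `a` = target-drug cases with the event,
#' * `b` = target-drug cases without it,
#' * `c` = all other cases with the event,
#' * `d` = all other cases without it.
#'
#' @param universe character vector of all case ids in the analysis universe
#'   (deduplicated).
#' @param target case ids with the target drug as primary suspect.
#' @param event case ids with at least one event-set reaction.
#' @param level table level label (`"class"`, `"drug"` or `"drug_pt"`).
#' @param drug,event_name optional labels carried through to results.
#' @return a `contingency_table`: list with `a`, `b`, `c`, `d`, `n`, `level`,
#'   `drug`, `event_name`.
#' @export
build_2x2 <- function(universe, target, event,
                      level = c("drug", "class", "drug_pt"),
                      drug = NA_character_, event_name = NA_character_) {
  level <- match.arg(level)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty analysis universe", call. = FALSE)
  target <- intersect(unique(target), universe)
  event <- intersect(unique(event), universe)
  a <- length(intersect(target, event))
  b <- length(target) - a
  c_ <- length(event) - a
  d <- length(universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d, n = length(universe),
                 level = level, drug = drug, event_name = event_name),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> level=", x$level,
      if (!is.na(x$drug)) paste0(" drug=", x$drug) else "",
      "\n  a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d, " (n=", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Observed and expected counts for every drug x preferred-term cell
#'
#' The unit is the case: a duplicated preferred term within one case never
#' inflates `N`. Expected counts assume row/column independence,
#' `E = (row margin x column margin) / grand total`, computed over the
#' complete drug x PT grid so that `sum(E) == sum(N)` exactly. No
#' stratification is applied by default (pass `strata`, a tibble
#' `primaryid,stratum`, to sum E over strata instead).
#'
#' @param assignments tibble `primaryid`, `drug`: the primary-suspect drug of
#'   each case (one row per case-drug pair).
#' @param reactions tibble `primaryid`, `pt`.
#' @param strata optional tibble `primaryid`, `stratum`; expected counts are
#'   computed within stratum and summed.
#' @return a `cell_counts` tibble with columns `drug`, `pt`, `N`, `E` and
#'   attributes `row_margin`, `col_margin`, `total`.
#' @export
build_cell_counts <- function(assignments, reactions, strata = NULL) {
  pairs <- dplyr::inner_join(assignments, reactions, by = "primaryid") |>
    dplyr::distinct(.data$primaryid, .data$drug, .data$pt)
  if (dplyr::n_distinct(pairs$drug) < 2 || dplyr::n_distinct(pairs$pt) < 2) {
    stop("cell counts need at least 2 drugs and 2 preferred terms", call. = FALSE)
  }

  expected_grid <- function(p) {
    nn <- dplyr::count(p, .data$drug, .data$pt, name = "N")
    grid <- tidyr::expand_grid(drug = sort(unique(p$drug)),
                               pt = sort(unique(p$pt))) |>
      dplyr::left_join(nn, by = c("drug", "pt")) |>
      dplyr::mutate(N = dplyr::coalesce(.data$N, 0L))
    rowm <- grid |> dplyr::group_by(.data$drug) |>
      dplyr::summarise(n_row = sum(.data$N), .groups = "drop")
    colm <- grid |> dplyr::group_by(.data$pt) |>
      dplyr::summarise(n_col = sum(.data$N), .groups = "drop")
    total <- sum(grid$N)
    grid <- grid |>
      dplyr::left_join(rowm, by = "drug") |>
      dplyr::left_join(colm, by = "pt") |>
      dplyr::mutate(E = .data$n_row * .data$n_col / total)
    list(grid = grid, rowm = rowm, colm = colm, total = total)
  }

  if (is.null(strata)) {
    res <- expected_grid(pairs)
    out <- res$grid
  } else {
    pairs_s <- dplyr::inner_join(pairs, strata, by = "primaryid")
    parts <- lapply(split(pairs_s, pairs_s$stratum), expected_grid)
    out <- dplyr::bind_rows(lapply(parts, `[[`, "grid")) |>
      dplyr::group_by(.data$drug, .data$pt) |>
      dplyr::summarise(N = sum(.data$N), E = sum(.data$E), .groups = "drop")
    res <- expected_grid(pairs)   # margins reported unstratified
  }
  out <- dplyr::select(out, "drug", "pt", "N", "E")
  attr(out, "row_margin") <- res$rowm
  attr(out, "col_margin") <- res$colm
  attr(out, "total") <- res$total
  class(out) <- c("cell_counts", class(out))
  out
}
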