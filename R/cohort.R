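#' @name cohort
#' @title Primary-suspect cohort selection and event-set flagging
#' @description
#' Cohort construction has two halves: mapping verbatim drug names to the
#' seven canonical statins through a synonym lexicon (exact match after
#' trimming and case-folding; no substring matching), and flagging cases whose
#' reactions intersect an SMQ-style preferred-term set for drug-related
#' hepatic disorders. MedDRA itself is licensed, so the packaged event set is
#' a synthetic stand-in list; a real SMQ export drops in as the same
#' two-column CSV (`pt,scope`).
NULL

#' The seven statins studied
#' @export
STATINS <- c("atorvastatin", "fluvastatin", "lovastatin", "pitavastatin",
             "pravastatin", "rosuvastatin", "simvastatin")

#' Read a drug synonym lexicon
#'
#' Two-column CSV `canonical,synonym`. Synonyms are upper-cased and trimmed at
#' load. Synonym sets must be pairwise disjoint across canonical drugs;
#' a violation aborts.
#'
#' @param path CSV path; default is the packaged statin lexicon.
#' @return tibble with columns `canonical`, `synonym` (class `drug_lexicon`).
#' @export
read_drug_lexicon <- function(path = NULL) {
  path <- path %||% pv_extdata("statin_lexicon.csv")
  lex <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("canonical", "synonym") %in% names(lex))) {
    stop("lexicon must have columns 'canonical' and 'synonym'", call. = FALSE)
  }
  lex$canonical <- tolower(trimws(lex$canonical))
  lex$synonym <- toupper(trimws(lex$synonym))
  lex <- dplyr::distinct(lex)
  dup <- lex |>
    dplyr::distinct(.data$canonical, .data$synonym) |>
    dplyr::count(.data$synonym) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("lexicon synonym(s) mapped to multiple canonical drugs: ",
         paste(dup$synonym, collapse = ", "), call. = FALSE)
  }
  class(lex) <- c("drug_lexicon", class(lex))
  lex
}

#' Normalize verbatim drug names against a lexicon
#'
#' Exact synonym lookup after trimming and upper-casing. No substring or
#' fuzzy matching: an unmatched verbatim returns `NA`.
#'
#' @param raw_name character vector of verbatim drug names.
#' @param lexicon a `drug_lexicon` (see [read_drug_lexicon()]).
#' @return character vector of canonical names, `NA` where unmatched.
#' @export
#' @examples
#' lex <- read_drug_lexicon()
#' normalize_drug(c("LIPITOR", "atorvastatin calcium ", "CERIVASTATIN"), lex)
normalize_drug <- function(raw_name, lexicon) {
  key <- toupper(trimws(raw_name))
  lexicon$canonical[match(key, lexicon$synonym)]
}

#' Select cases with a lexicon drug as Primary Suspect
#'
#' Keeps cases having at least one drug row with `role_cod == "PS"` whose
#' name normalizes to a canonical drug, and annotates each kept case with that
#' drug. A case with two distinct primary-suspect statins yields one
#' annotation row per statin (per-drug tables count it under each; class-level
#' tables count the case once).
#'
#' @param fd a deduplicated `faers_data` object.
#' @param lexicon a `drug_lexicon`.
#' @return list of class `pv_cohort`: `data` (the kept cases as
#'   `faers_data`), `annotations` (tibble `primaryid`, `drug`), and
#'   `n_cases` (distinct kept cases).
#' @export
filter_primary_suspect <- function(fd, lexicon) {
  stopifnot(inherits(fd, "faers_data"))
  ann <- fd$drug |>
    dplyr::filter(.data$role_cod == "PS") |>
    dplyr::mutate(drug = normalize_drug(.data$drugname, lexicon)) |>
    dplyr::filter(!is.na(.data$drug)) |>
    dplyr::distinct(.data$primaryid, .data$drug) |>
    dplyr::arrange(.data$primaryid, .data$drug)
  ids <- unique(ann$primaryid)
  structure(list(data = subset_faers(fd, ids),
                 annotations = ann,
                 n_cases = length(ids)),
            class = "pv_cohort")
}

#' @export
print.pv_cohort <- function(x, ...) {
  cat("<pv_cohort> ", x$n_cases, " primary-suspect cases across ",
      dplyr::n_distinct(x$annotations$drug), " drugs\n", sep = "")
  invisible(x)
}

#' Read an SMQ-style event-set CSV
#'
#' Two-column CSV `pt,scope` with scope `narrow` or `broad`. Preferred terms
#' are upper-cased and trimmed.
#'
#' @param path CSV path; default is the packaged synthetic hepatic-disorder
#'   stand-in list.
#' @return tibble with columns `pt`, `scope`.
#' @export
read_event_set <- function(path = NULL) {
  path <- path %||% pv_extdata("hepatic_smq_synthetic.csv")
  es <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("pt", "scope") %in% names(es))) {
    stop("event-set file must have columns 'pt' and 'scope'", call. = FALSE)
  }
  es$pt <- toupper(trimws(es$pt))
  es$scope <- tolower(trimws(es$scope))
  if (!all(es$scope %in% c("narrow", "broad"))) {
    stop("event-set scope must be 'narrow' or 'broad'", call. = FALSE)
  }
  dplyr::distinct(dplyr::filter(es, .data$pt != ""))
}

#' Combine narrow and broad preferred-term lists into one event set
#'
#' Returns the deduplicated union of the two scopes and reports the narrow,
#' broad, intersection and union sizes (SMQ comprehensive searches combine
#' both scopes; the union can never be smaller than either list).
#'
#' @param narrow,broad character vectors of preferred terms, or a tibble as
#'   returned by [read_event_set()] passed as `narrow` (scopes are split out).
#' @return sorted character vector of unique upper-cased terms (class
#'   `pt_set`), with a `sizes` attribute.
#' @export
build_event_set <- function(narrow, broad = NULL) {
  if (is.data.frame(narrow)) {
    es <- narrow
    broad <- es$pt[es$scope == "broad"]
    narrow <- es$pt[es$scope == "narrow"]
  }
  narrow <- unique(toupper(trimws(narrow)))
  broad <- unique(toupper(trimws(broad)))
  terms <- sort(union(narrow, broad))
  terms <- terms[terms != ""]
  if (length(terms) == 0) {
    stop("event set is empty: configuration error", call. = FALSE)
  }
  sizes <- c(narrow = length(narrow), broad = length(broad),
             intersection = length(intersect(narrow, broad)),
             union = length(terms))
  message("event set: ", sizes[["narrow"]], " narrow, ", sizes[["broad"]],
          " broad, ", sizes[["intersection"]], " shared, union ",
          sizes[["union"]], " preferred terms")
  structure(terms, sizes = sizes, class = c("pt_set", "character"))
}

#' Flag cases whose reactions intersect an event set
#'
#' @param fd a `faers_data` object.
#' @param event_set character vector of preferred terms (see
#'   [build_event_set()]).
#' @return tibble with one row per case version: `primaryid`, `flagged`
#'   (logical, `TRUE` iff at least one reaction PT is in the set), and
#'   `matched` (list column of the matched PTs, for PT-level analyses).
#' @export
flag_events <- function(fd, event_set) {
  stopifnot(inherits(fd, "faers_data"))
  hits <- fd$reac |>
    dplyr::filter(.data$pt %in% event_set) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(matched = list(sort(unique(.data$pt))), .groups = "drop")
  out <- tibble::tibble(primaryid = fd$demo$primaryid) |>
    dplyr::left_join(hits, by = "primaryid") |>
    dplyr::mutate(flagged = !vapply(.data$matched, is.null, logical(1)))
  out$matched <- lapply(out$matched, function(x) if (is.null(x)) character(0) else x)
  out[, c("primaryid", "flagged", "matched")]
}
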