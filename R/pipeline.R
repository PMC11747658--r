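#' @name report_pipeline
#' @title End-to-end signal-mining pipeline
#' @description
#' Orchestrates ingest -> deduplication -> primary-suspect cohort -> event
#' flagging -> contingency counting -> ROR/EBGM -> classification ->
#' summaries, recording stage counts in a run manifest for auditability. All
#' thresholds live in the configuration and default to the conventional
#' positivity rules (co-report count >= 3, 95% CI, EBGM05 > 2).
NULL

#' Pipeline configuration
#'
#' @param lexicon a `drug_lexicon`; default is the packaged statin lexicon.
#' @param event_set a `pt_set` or character vector of preferred terms;
#'   default is the packaged hepatic stand-in set (union of scopes).
#' @param min_count minimum co-report count for ROR positivity.
#' @param strict_count require strictly more than `min_count` co-reports.
#' @param ci_level confidence level for the Woolf interval.
#' @param ebgm05_threshold EBGM05 positivity cutoff.
#' @param prior_starts optimizer starts for [fit_mgps_prior()].
#' @param squash squash identical cells before prior fitting.
#' @param methods signal statistics to compute: subset of
#'   `c("ror", "ebgm")`. Dropping `"ebgm"` skips the cell grid and prior fit
#'   (EBGM columns become `NA`).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(lexicon = NULL, event_set = NULL,
                            min_count = 3, strict_count = FALSE,
                            ci_level = 0.95, ebgm05_threshold = 2,
                            prior_starts = 5, squash = FALSE,
                            methods = c("ror", "ebgm"),
                            out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  lexicon <- lexicon %||% statin_lexicon()
  event_set <- event_set %||% hepatic_event_set()
  if (length(event_set) == 0) {
    stop("configuration error: event set is empty", call. = FALSE)
  }
  if (ci_level <= 0 || ci_level >= 1) {
    stop("configuration error: ci_level must be in (0, 1)", call. = FALSE)
  }
  structure(list(lexicon = lexicon, event_set = event_set,
                 min_count = min_count, strict_count = strict_count,
                 ci_level = ci_level, ebgm05_threshold = ebgm05_threshold,
                 prior_starts = prior_starts, squash = squash,
                 methods = methods, out_dir = out_dir),
            class = "pipeline_config")
}

# primary-suspect drug label for every case in the universe: canonical
# lexicon name where it matches, otherwise the trimmed upper-case verbatim
ps_assignments <- function(fd, lexicon) {
  fd$drug |>
    dplyr::filter(.data$role_cod == "PS") |>
    dplyr::mutate(drug = dplyr::coalesce(normalize_drug(.data$drugname, lexicon),
                                         toupper(trimws(.data$drugname)))) |>
    dplyr::distinct(.data$primaryid, .data$drug)
}

#' Compute class-, drug- and drug x PT-level signal statistics
#'
#' Builds the 2x2 tables (full-database comparator) and the drug x PT cell
#' counts over the whole deduplicated universe, fits the MGPS prior on all
#' cells, and returns one row per signal with ROR, Woolf CI, EBGM, EBGM05,
#' EBGM95 and the dual positivity flags.
#'
#' @param fd the deduplicated `faers_data` universe.
#' @param annotations cohort annotations (tibble `primaryid`, `drug`) from
#'   [filter_primary_suspect()].
#' @param config a [pipeline_config()].
#' @return list: `signals` (tibble with `level`, `drug`, `pt`, `a`, `ror`,
#'   `ci_low`, `ci_high`, `N`, `E`, `ebgm`, `ebgm05`, `ebgm95`,
#'   `ror_positive`, `ebgm_positive`), `tables_2x2`, `cells` (the
#'   `cell_counts` grid), `prior`.
#' @export
compute_signals <- function(fd, annotations, config = pipeline_config()) {
  universe <- fd$demo$primaryid
  n <- length(universe)
  event_ids <- unique(fd$reac$primaryid[fd$reac$pt %in% config$event_set])
  drugs <- sort(unique(annotations$drug))

  # class- and drug-level 2x2 tables
  tabs <- c(
    list(build_2x2(universe, unique(annotations$primaryid), event_ids,
                   level = "class", drug = "all",
                   event_name = "event_set")),
    lapply(drugs, function(dd) {
      ids <- annotations$primaryid[annotations$drug == dd]
      build_2x2(universe, ids, event_ids, level = "drug", drug = dd,
                event_name = "event_set")
    })
  )
  tab_df <- dplyr::bind_rows(lapply(tabs, function(t) {
    tibble::tibble(level = t$level, drug = t$drug, a = t$a, b = t$b,
                   c = t$c, d = t$d)
  }))

  use_ebgm <- "ebgm" %in% config$methods

  # cell counts + prior over the full drug x PT universe
  cells <- NULL
  prior <- NULL
  if (use_ebgm) {
    assign_all <- ps_assignments(fd, config$lexicon)
    cells <- build_cell_counts(assign_all, fd$reac)
    prior <- fit_mgps_prior(cells, starts = config$prior_starts,
                            squash = config$squash)
  }

  na_ebgm <- function(k) {
    tibble::tibble(N = rep(NA_integer_, k), E = NA_real_, Q = NA_real_,
                   ebgm = NA_real_, ebgm05 = NA_real_, ebgm95 = NA_real_)
  }

  # class/drug level: N = a, E from the table margins
  lvl_ror <- ror(tab_df$a, tab_df$b, tab_df$c, tab_df$d,
                 conf_level = config$ci_level)
  lvl_E <- (tab_df$a + tab_df$b) * (tab_df$a + tab_df$c) / n
  lvl_eb <- if (use_ebgm) {
    ebgm_cell(tab_df$a, pmax(lvl_E, 1e-12), prior)
  } else {
    na_ebgm(nrow(tab_df))
  }
  lvl_cls <- classify_signals(tab_df$a, lvl_ror,
                              if (use_ebgm) lvl_eb else NULL,
                              min_count = config$min_count,
                              strict = config$strict_count,
                              ebgm05_threshold = config$ebgm05_threshold)
  lvl_sig <- dplyr::bind_cols(
    tab_df[, c("level", "drug")],
    tibble::tibble(pt = NA_character_, a = tab_df$a),
    lvl_ror[, c("ror", "ci_low", "ci_high")],
    tibble::tibble(N = tab_df$a, E = lvl_E),
    lvl_eb[, c("ebgm", "ebgm05", "ebgm95")],
    lvl_cls
  )

  # drug x PT level, cohort drugs x event-set PTs with at least one report
  pt_cases <- fd$reac |>
    dplyr::filter(.data$pt %in% config$event_set) |>
    dplyr::distinct(.data$primaryid, .data$pt)
  n_pt <- dplyr::count(pt_cases, .data$pt, name = "n_pt")
  n_drug <- annotations |>
    dplyr::count(.data$drug, name = "n_drug")
  pt_sig <- dplyr::inner_join(annotations, pt_cases, by = "primaryid",
                              relationship = "many-to-many") |>
    dplyr::count(.data$drug, .data$pt, name = "a") |>
    dplyr::left_join(n_drug, by = "drug") |>
    dplyr::left_join(n_pt, by = "pt") |>
    dplyr::mutate(b = .data$n_drug - .data$a,
                  c = .data$n_pt - .data$a,
                  d = n - .data$n_drug - .data$c)
  if (nrow(pt_sig) > 0) {
    pt_ror <- ror(pt_sig$a, pt_sig$b, pt_sig$c, pt_sig$d,
                  conf_level = config$ci_level)
    pt_eb <- if (use_ebgm) {
      pt_cells <- dplyr::left_join(pt_sig, cells, by = c("drug", "pt"))
      ebgm_cell(pt_cells$N, pt_cells$E, prior)
    } else {
      na_ebgm(nrow(pt_sig))
    }
    pt_cls <- classify_signals(pt_sig$a, pt_ror,
                               if (use_ebgm) pt_eb else NULL,
                               min_count = config$min_count,
                               strict = config$strict_count,
                               ebgm05_threshold = config$ebgm05_threshold)
    pt_rows <- dplyr::bind_cols(
      tibble::tibble(level = "drug_pt", drug = pt_sig$drug, pt = pt_sig$pt,
                     a = pt_sig$a),
      pt_ror[, c("ror", "ci_low", "ci_high")],
      pt_eb[, c("N", "E", "ebgm", "ebgm05", "ebgm95")],
      pt_cls
    )
  } else {
    pt_rows <- lvl_sig[0, ]
  }

  signals <- dplyr::bind_rows(lvl_sig, pt_rows) |>
    dplyr::arrange(.data$level, .data$drug, .data$pt)
  list(signals = signals, tables_2x2 = tab_df, cells = cells, prior = prior)
}

#' Run the full pipeline
#'
#' Either pass in-memory data (`data =` a `faers_data` object, e.g. from
#' [simulate_faers()]) or a directory of FAERS quarterly ASCII files
#' (`input_dir`; all `DEMO*.txt` quarters found are ingested). Stages:
#' ingest -> deduplicate -> primary-suspect cohort -> event flagging ->
#' contingency -> ROR/EBGM -> classification -> summaries. The manifest
#' records the case counts entering and leaving every stage; with a fixed
#' input and configuration the run is fully deterministic (the only
#' randomness in the package lives in the generator's seed).
#'
#' @param data a `faers_data` object (all case versions), or `NULL`.
#' @param input_dir directory of quarterly files (used when `data` is NULL).
#' @param config a [pipeline_config()].
#' @return list of class `pv_run`: `manifest`, `signals`, `tables_2x2`,
#'   `cells`, `prior`, `characteristics`, `trend`, `config`.
#' @export
run_pipeline <- function(data = NULL, input_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "ingest"
  res <- tryCatch({
    if (is.null(data)) {
      if (is.null(input_dir)) {
        stop("either data or input_dir must be supplied", call. = FALSE)
      }
      demo_files <- list.files(input_dir, pattern = "^DEMO.*\\.txt$")
      if (length(demo_files) == 0) {
        stop("no DEMO*.txt files found in ", input_dir, call. = FALSE)
      }
      quarters <- sub("^DEMO(.*)\\.txt$", "\\1", demo_files)
      fd <- bind_faers(lapply(quarters, function(q) {
        assemble_cases(read_faers_quarter(input_dir, q))
      }))
    } else {
      fd <- data
    }
    manifest <- list(n_raw_versions = n_case_versions(fd),
                     orphans = fd$orphans)

    stage <- "dedup"
    dd <- deduplicate_cases(fd)
    manifest$dedup <- attr(dd, "dedup")
    manifest$n_unique_cases <- n_case_versions(dd)

    stage <- "cohort"
    if (length(config$event_set) == 0) {
      stop("configuration error: event set is empty", call. = FALSE)
    }
    coh <- filter_primary_suspect(dd, config$lexicon)
    manifest$n_cohort_cases <- coh$n_cases
    flags <- flag_events(coh$data, config$event_set)
    flagged_ids <- flags$primaryid[flags$flagged]
    manifest$n_event_cases <- length(flagged_ids)

    stage <- "signals"
    sig <- compute_signals(dd, coh$annotations, config)

    stage <- "summaries"
    hep_fd <- subset_faers(coh$data, flagged_ids)
    hep_ann <- dplyr::filter(coh$annotations, .data$primaryid %in% flagged_ids)
    chars <- characteristics_table(hep_fd, hep_ann)
    trend <- annual_trend(hep_fd, hep_ann)

    list(manifest = manifest, signals = sig$signals,
         tables_2x2 = sig$tables_2x2, cells = sig$cells, prior = sig$prior,
         characteristics = chars, trend = trend, config = config)
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(res$signals, file.path(config$out_dir, "signals.csv"),
                     progress = FALSE)
    readr::write_csv(res$tables_2x2,
                     file.path(config$out_dir, "tables_2x2.csv"),
                     progress = FALSE)
    if (!is.null(res$cells)) {
      readr::write_csv(tibble::as_tibble(res$cells),
                       file.path(config$out_dir, "cell_counts.csv"),
                       progress = FALSE)
    }
    readr::write_csv(res$characteristics,
                     file.path(config$out_dir, "characteristics.csv"),
                     progress = FALSE)
    readr::write_csv(res$trend$totals,
                     file.path(config$out_dir, "annual_trend.csv"),
                     progress = FALSE)
    manifest_out <- res$manifest
    manifest_out$per_statin_cases <- NULL
    jsonlite::write_json(manifest_out,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(res, class = "pv_run")
}

#' @export
print.pv_run <- function(x, ...) {
  m <- x$manifest
  cat("<pv_run> ", m$n_raw_versions, " raw versions -> ",
      m$n_unique_cases, " unique cases -> ", m$n_cohort_cases,
      " cohort cases -> ", m$n_event_cases, " event cases\n",
      "  signals: ", nrow(x$signals), " rows (",
      sum(x$signals$ror_positive, na.rm = TRUE), " ROR-positive, ",
      sum(x$signals$ebgm_positive, na.rm = TRUE), " EBGM-positive)\n",
      sep = "")
  invisible(x)
}

#' Top-k strongest PT-level signals per drug
#'
#' Ranks the drug x PT rows with at least `min_count` co-reports by ROR
#' descending (ties: larger count first, then PT name) and keeps the top `k`
#' per drug. Set `statistic = "ebgm"` to rank by EBGM instead.
#'
#' @param signals signals tibble from [compute_signals()]/[run_pipeline()].
#' @param k rows per drug.
#' @param min_count minimum co-report count.
#' @param statistic ranking statistic, `"ror"` or `"ebgm"`.
#' @return tibble of the ranked rows.
#' @export
top_signals <- function(signals, k = 5, min_count = 3,
                        statistic = c("ror", "ebgm")) {
  statistic <- match.arg(statistic)
  signals |>
    dplyr::filter(.data$level == "drug_pt", .data$a >= min_count,
                  !is.na(.data[[statistic]])) |>
    dplyr::arrange(.data$drug, dplyr::desc(.data[[statistic]]),
                   dplyr::desc(.data$a), .data$pt) |>
    dplyr::group_by(.data$drug) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup()
}

#' Drug x PT matrix of a signal statistic
#'
#' Cells with fewer than `min_count` co-reports are explicitly `NA`.
#'
#' @param signals signals tibble.
#' @param statistic `"ror"` or `"ebgm"`.
#' @param min_count minimum co-report count for a cell to be shown.
#' @return numeric matrix, drugs as rows, preferred terms as columns.
#' @export
heatmap_matrix <- function(signals, statistic = c("ror", "ebgm"),
                           min_count = 3) {
  statistic <- match.arg(statistic)
  df <- signals |>
    dplyr::filter(.data$level == "drug_pt") |>
    dplyr::mutate(value = dplyr::if_else(.data$a >= min_count,
                                         .data[[statistic]], NA_real_))
  if (nrow(df) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  wide <- df |>
    dplyr::select("drug", "pt", "value") |>
    tidyr::pivot_wider(names_from = "pt", values_from = "value",
                       names_sort = TRUE) |>
    dplyr::arrange(.data$drug)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$drug
  m
}

#' Render a signal heatmap
#'
#' Thin wrapper around \pkg{pheatmap} (suggested dependency) for the matrix
#' from [heatmap_matrix()]; `NA` cells are drawn blank.
#'
#' @param m matrix from [heatmap_matrix()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_signal_heatmap <- function(m, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_signal_heatmap needs the 'pheatmap' package", call. = FALSE)
  }
  p <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                          na_col = "grey90", ...)
  invisible(p)
}
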