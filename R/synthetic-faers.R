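#' @name synthetic_faers
#' @title Synthetic FAERS-style report generator with planted signals
#' @description
#' Generates case reports in the FAERS quarterly data model with known ground
#' truth, so every downstream stage (parsing, deduplication, cohorting,
#' contingency counting, disproportionality) can be validated offline.
#' Each case has one primary-suspect drug (a statin with probability
#' `statin_share`, otherwise a background agent), at least one reaction
#' preferred term, demographics, outcomes, and optionally a later re-submitted
#' version (a duplicate with a strictly larger receipt date, a new
#' `primaryid`, and sometimes a mutated demographic field). Baseline
#' preferred-term probabilities follow a long-tailed Dirichlet draw (many rare
#' terms, mimicking spontaneous-report sparsity); selected terms can be pinned
#' to fixed probabilities via `pt_weights` so planted signal sizes are
#' controlled. For a planted pair `(drug, pt, lambda)`, the term's sampling
#' weight is multiplied by `lambda` in cases whose primary suspect is that
#' drug.
NULL

default_demographics <- function() {
  list(
    sex = c(F = 0.45, M = 0.45, UNK = 0.10),
    age_missing = 0.15,
    age_unit = c(YR = 0.70, MON = 0.15, DEC = 0.10, DY = 0.05),
    occp = c(MD = 0.30, PH = 0.10, OT = 0.15, CN = 0.25, RN = 0.02,
             HP = 0.08, LW = 0.01, UNK = 0.09),
    outcome = c(DE = 0.05, DS = 0.05, HO = 0.33, LT = 0.07, OT = 0.36,
                CA = 0.01, RI = 0.13),
    p_any_outcome = 0.65
  )
}

#' Simulation configuration
#'
#' @param n_cases number of distinct cases (>= 1).
#' @param n_background_drugs number of non-statin background agents.
#' @param n_background_pts number of generic background preferred terms; the
#'   packaged hepatic event set is always included in the PT universe.
#' @param statin_share probability a case's primary suspect is a statin
#'   (uniform over the seven).
#' @param planted_rr data frame `drug`, `pt`, `lambda` of planted relative
#'   reporting-rate multipliers (`lambda >= 0`; 1 = null). `NULL` for none.
#' @param duplicate_rate probability a case receives a second, later version.
#' @param pt_weights optional named numeric: fixed baseline probabilities for
#'   named preferred terms (must sum to < 1); remaining mass is spread over
#'   the other terms by a Dirichlet draw with concentration
#'   `dirichlet_conc`.
#' @param dirichlet_conc Dirichlet concentration for baseline PT
#'   probabilities (small = long tail; default 0.5).
#' @param mean_extra_reactions mean of the Poisson number of reactions beyond
#'   the guaranteed first.
#' @param mean_concomitant mean number of non-primary-suspect drug rows.
#' @param demographics list of category probabilities (see
#'   `pvsignal:::default_demographics()`), partially overridable.
#' @param start_date,end_date receipt-date window (ISO strings).
#' @param seed integer RNG seed; identical `(config, seed)` yields
#'   byte-identical output files.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 5000,
                       n_background_drugs = 40,
                       n_background_pts = 150,
                       statin_share = 0.25,
                       planted_rr = NULL,
                       duplicate_rate = 0.08,
                       pt_weights = NULL,
                       dirichlet_conc = 0.5,
                       mean_extra_reactions = 1.2,
                       mean_concomitant = 0.8,
                       demographics = list(),
                       start_date = "2004-01-01",
                       end_date = "2024-03-31",
                       seed = 1L) {
  demo <- utils::modifyList(default_demographics(), demographics)
  cfg <- list(n_cases = as.integer(n_cases),
              n_background_drugs = as.integer(n_background_drugs),
              n_background_pts = as.integer(n_background_pts),
              statin_share = statin_share,
              planted_rr = planted_rr,
              duplicate_rate = duplicate_rate,
              pt_weights = pt_weights,
              dirichlet_conc = dirichlet_conc,
              mean_extra_reactions = mean_extra_reactions,
              mean_concomitant = mean_concomitant,
              demographics = demo,
              start_date = start_date,
              end_date = end_date,
              seed = as.integer(seed))
  probs <- c(statin_share, duplicate_rate, demo$age_missing,
             demo$p_any_outcome)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_cases < 1) stop("configuration error: n_cases must be >= 1", call. = FALSE)
  if (!is.null(planted_rr)) {
    if (!all(c("drug", "pt", "lambda") %in% names(planted_rr))) {
      stop("configuration error: planted_rr needs columns drug, pt, lambda",
           call. = FALSE)
    }
    if (any(planted_rr$lambda < 0)) {
      stop("configuration error: planted lambda must be >= 0", call. = FALSE)
    }
    cfg$planted_rr <- tibble::as_tibble(planted_rr) |>
      dplyr::mutate(pt = toupper(trimws(.data$pt)))
  }
  if (!is.null(pt_weights)) {
    if (is.null(names(pt_weights)) || any(pt_weights < 0) ||
        sum(pt_weights) >= 1) {
      stop("configuration error: pt_weights must be named, non-negative, sum < 1",
           call. = FALSE)
    }
    names(cfg$pt_weights) <- toupper(trimws(names(pt_weights)))
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic FAERS-style dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return list of class `faers_sim`: `data` (a `faers_data` object holding
#'   all case versions) and `truth` (class `sim_truth`: `pairs`, the realized
#'   case-level (drug, pt) counts with baseline weights and planted lambdas;
#'   `manifest`, stage counts used as oracles downstream; `planted`, the
#'   planted pairs with their expected counts).
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases
  demo_cfg <- config$demographics

  lex <- statin_lexicon()
  syn_by <- split(lex$synonym, lex$canonical)
  hep_pts <- as.character(hepatic_event_set())
  bg_drugs <- sprintf("AGENT%03d", seq_len(config$n_background_drugs))
  pts <- c(hep_pts, sprintf("PT%04d", seq_len(config$n_background_pts)))

  # baseline PT probabilities: pinned weights + Dirichlet long tail
  w <- stats::setNames(numeric(length(pts)), pts)
  fixed <- config$pt_weights %||% numeric(0)
  fixed <- fixed[names(fixed) %in% pts]
  free <- setdiff(pts, names(fixed))
  g <- stats::rgamma(length(free), shape = config$dirichlet_conc)
  w[free] <- (1 - sum(fixed)) * g / sum(g)
  w[names(fixed)] <- fixed

  caseid <- sprintf("%09d", 100000000L + seq_len(n))
  is_statin <- stats::runif(n) < config$statin_share
  ps_drug <- character(n)
  ps_drug[is_statin] <- sample(STATINS, sum(is_statin), replace = TRUE)
  ps_drug[!is_statin] <- sample(bg_drugs, sum(!is_statin), replace = TRUE)
  ps_verbatim <- ps_drug
  for (s in STATINS) {
    ii <- which(ps_drug == s)
    if (length(ii)) ps_verbatim[ii] <- sample(syn_by[[s]], length(ii), replace = TRUE)
  }

  # reactions: per planted-drug group, multiply pinned lambdas into the
  # baseline weights and renormalize; sample with replacement, then distinct
  n_react <- 1L + stats::rpois(n, config$mean_extra_reactions)
  planted <- config$planted_rr
  if (!is.null(planted)) {
    bad <- setdiff(planted$pt, pts)
    if (length(bad)) {
      stop("configuration error: planted PT(s) not in the PT universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(planted$drug, c(STATINS, bg_drugs))
    if (length(bad)) {
      stop("configuration error: planted drug(s) not in the drug universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  planted_drugs <- if (is.null(planted)) character(0) else unique(planted$drug)
  grp <- ifelse(ps_drug %in% planted_drugs, ps_drug, ".base")
  reac_parts <- list()
  for (gname in sort(unique(grp))) {
    idx <- which(grp == gname)
    wg <- w
    if (gname != ".base") {
      rows <- planted[planted$drug == gname, ]
      wg[rows$pt] <- wg[rows$pt] * rows$lambda
    }
    wg <- wg / sum(wg)
    slots <- rep(idx, n_react[idx])
    reac_parts[[gname]] <- tibble::tibble(
      idx = slots,
      pt = sample(pts, length(slots), replace = TRUE, prob = wg)
    )
  }
  reac_case <- dplyr::bind_rows(reac_parts) |>
    dplyr::distinct(.data$idx, .data$pt) |>
    dplyr::arrange(.data$idx, .data$pt)

  # demographics
  sex <- sample(names(demo_cfg$sex), n, replace = TRUE, prob = demo_cfg$sex)
  sex[sex == "UNK"] <- NA_character_
  age_years <- pmin(pmax(stats::rnorm(n, 66, 15), 1), 100)
  unit <- sample(names(demo_cfg$age_unit), n, replace = TRUE,
                 prob = demo_cfg$age_unit)
  age_val <- round(age_years / AGE_FACTORS[unit], 1)
  miss <- stats::runif(n) < demo_cfg$age_missing
  age_val[miss] <- NA_real_
  unit[miss] <- NA_character_
  occp <- sample(names(demo_cfg$occp), n, replace = TRUE, prob = demo_cfg$occp)
  occp[occp == "UNK"] <- NA_character_
  dates <- seq(as.Date(config$start_date), as.Date(config$end_date), by = "day")
  fda <- sample(dates, n, replace = TRUE)

  # outcomes
  n_out <- ifelse(stats::runif(n) < demo_cfg$p_any_outcome,
                  1L + stats::rbinom(n, 2, 0.25), 0L)
  with_out <- which(n_out > 0)
  outc_case <- tibble::tibble(
    idx = rep(with_out, n_out[with_out]),
    outc_cod = unlist(lapply(with_out, function(i) {
      sample(names(demo_cfg$outcome), n_out[i], replace = FALSE,
             prob = demo_cfg$outcome)
    }))
  )

  # concomitant (non-PS) drug rows
  n_con <- stats::rpois(n, config$mean_concomitant)
  with_con <- which(n_con > 0)
  pool <- c(bg_drugs, lex$synonym)
  con_rows <- tibble::tibble(
    idx = rep(with_con, n_con[with_con]),
    drugname = sample(pool, sum(n_con), replace = TRUE),
    role_cod = sample(c("SS", "C", "I"), sum(n_con), replace = TRUE)
  ) |>
    dplyr::group_by(.data$idx) |>
    dplyr::mutate(drug_seq = 1L + dplyr::row_number()) |>
    dplyr::ungroup()

  # versions: everyone gets version 1; duplicates get a strictly later
  # version 2 under a new primaryid, sometimes with a mutated sex field
  dup <- stats::runif(n) < config$duplicate_rate
  pid1 <- paste0(caseid, "1")
  demo1 <- tibble::tibble(primaryid = pid1, caseid = caseid, caseversion = 1L,
                          fda_dt = format(fda, "%Y%m%d"), sex = sex,
                          age = unname(age_val), age_cod = unit, occp_cod = occp)
  di <- which(dup)
  demo2 <- demo1[di, ]
  if (length(di)) {
    demo2$primaryid <- paste0(caseid[di], "2")
    demo2$caseversion <- 2L
    demo2$fda_dt <- format(fda[di] + sample(30:400, length(di), replace = TRUE),
                           "%Y%m%d")
    mut <- stats::runif(length(di)) < 0.3
    demo2$sex[mut] <- sample(c("F", "M"), sum(mut), replace = TRUE)
  }
  demo <- dplyr::bind_rows(demo1, demo2)

  per_case <- function(tab, value_cols) {
    v1 <- dplyr::mutate(tab, primaryid = pid1[.data$idx])
    v2 <- dplyr::filter(tab, .data$idx %in% di) |>
      dplyr::mutate(primaryid = paste0(caseid[.data$idx], "2"))
    dplyr::bind_rows(v1, v2)[, c("primaryid", value_cols)]
  }

  ps_rows <- tibble::tibble(idx = seq_len(n), drug_seq = 1L, role_cod = "PS",
                            drugname = ps_verbatim)
  drug_tab <- dplyr::bind_rows(ps_rows,
                               con_rows[, c("idx", "drug_seq", "role_cod", "drugname")]) |>
    dplyr::arrange(.data$idx, .data$drug_seq) |>
    dplyr::mutate(prod_ai = toupper(.data$drugname))
  drug <- per_case(drug_tab, c("drug_seq", "role_cod", "drugname", "prod_ai"))
  reac <- per_case(reac_case, "pt")
  outc <- per_case(outc_case, "outc_cod")

  fd <- assemble_cases(demo, drug, reac, outc)

  # ground truth
  pair_counts <- reac_case |>
    dplyr::mutate(drug = ps_drug[.data$idx]) |>
    dplyr::count(.data$drug, .data$pt, name = "n_reports")
  lam <- if (is.null(planted)) {
    tibble::tibble(drug = character(0), pt = character(0), lambda = numeric(0))
  } else planted
  pair_counts <- pair_counts |>
    dplyr::left_join(lam, by = c("drug", "pt")) |>
    dplyr::mutate(lambda_true = dplyr::coalesce(.data$lambda, 1),
                  baseline_weight = unname(w[.data$pt])) |>
    dplyr::select("drug", "pt", "lambda_true", "baseline_weight", "n_reports")

  hep_case_ids <- unique(reac_case$idx[reac_case$pt %in% hep_pts])
  planted_truth <- NULL
  if (!is.null(planted)) {
    planted_truth <- planted |>
      dplyr::mutate(
        n_drug_cases = vapply(.data$drug, function(dd) sum(ps_drug == dd),
                              numeric(1)),
        p_hit = 1 - (1 - pmin(unname(w[.data$pt]) * .data$lambda, 1))^
          (1 + config$mean_extra_reactions),
        expected_n = .data$n_drug_cases * .data$p_hit
      )
  }
  manifest <- list(
    n_cases = n,
    n_case_versions = nrow(demo),
    n_duplicates = sum(dup),
    n_reaction_rows = nrow(reac),
    n_ps_statin_cases = sum(is_statin),
    n_hepatic_statin_cases = length(intersect(hep_case_ids, which(is_statin))),
    per_statin_cases = table(ps_drug[is_statin])
  )
  truth <- structure(list(pairs = pair_counts, manifest = manifest,
                          planted = planted_truth),
                     class = "sim_truth")
  structure(list(data = fd, truth = truth, config = config),
            class = "faers_sim")
}

#' @export
print.faers_sim <- function(x, ...) {
  m <- x$truth$manifest
  cat("<faers_sim> ", m$n_cases, " cases (", m$n_case_versions,
      " versions), ", m$n_ps_statin_cases, " statin-PS cases, ",
      m$n_hepatic_statin_cases, " of them with a hepatic PT\n", sep = "")
  invisible(x)
}

#' Write the ground-truth manifest as CSV
#'
#' One row per realized (primary-suspect drug, preferred term) pair:
#' `drug`, `pt`, `lambda_true`, `baseline_weight`, `n_reports`.
#'
#' @param truth a `sim_truth` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  readr::write_csv(truth$pairs, path, progress = FALSE)
  invisible(path)
}
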