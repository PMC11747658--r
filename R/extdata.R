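pv_extdata <- function(file) {
  system.file("extdata", file, package = "pvsignal", mustWork = TRUE)
}

#' Packaged statin synonym lexicon
#'
#' Generic names, common brands and salt forms for the seven statins studied
#' (atorvastatin, fluvastatin, lovastatin, pitavastatin, pravastatin,
#' rosuvastatin, simvastatin). Cerivastatin, withdrawn in 2001, is
#' deliberately absent.
#'
#' @return a `drug_lexicon` tibble.
#' @export
statin_lexicon <- function() read_drug_lexicon(pv_extdata("statin_lexicon.csv"))

#' Packaged hepatic-disorder event set (synthetic stand-in)
#'
#' A synthetic stand-in for the licensed MedDRA SMQ "Drug related hepatic
#' disorders": hand-curated narrow and broad preferred-term lists covering
#' drug-induced liver injury, hepatitis variants, cholestatic syndromes and
#' liver laboratory abnormalities. A real SMQ export in the same two-column
#' CSV (`pt,scope`) drops in via [read_event_set()].
#'
#' @param scope `"union"` (default), `"narrow"` or `"broad"`.
#' @return a `pt_set` character vector.
#' @export
hepatic_event_set <- function(scope = c("union", "narrow", "broad")) {
  scope <- match.arg(scope)
  es <- read_event_set(pv_extdata("hepatic_smq_synthetic.csv"))
  if (scope == "union") {
    suppressMessages(build_event_set(es))
  } else {
    suppressMessages(build_event_set(es$pt[es$scope == scope], character(0)))
  }
}

#' Published reference summary tables
#'
#' Values transcribed from the published tables of a large-scale statin
#' hepatotoxicity disproportionality study of the full FAERS corpus
#' (2004Q1-2024Q1): the annual reporting counts, the clinical-characteristics
#' strata, the drug-level signal table and the per-drug top-5 preferred-term
#' signals. Shipped so that summary arithmetic (percentage shares, fatality
#' proportions, Woolf log-symmetry, dual positivity classification) can be
#' validated against published numbers without the 21M-record corpus.
#'
#' @param which one of `"annual"`, `"characteristics"`, `"drug_signals"`,
#'   `"top_pt_signals"`.
#' @return a tibble.
#' @export
reference_summary <- function(which = c("annual", "characteristics",
                                        "drug_signals", "top_pt_signals")) {
  which <- match.arg(which)
  file <- paste0("reference_", which, ".csv")
  readr::read_csv(pv_extdata(file), show_col_types = FALSE, progress = FALSE)
}
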