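#' @name faers_io
#' @title FAERS quarterly ASCII input/output
#' @description
#' FAERS distributes each quarter as `$`-delimited, unquoted ASCII tables with
#' a header line (post-2012Q4 schema, i.e. with `caseversion`). The package
#' models four of them:
#'
#' * `DEMO` - one row per case version: `primaryid`, `caseid`, `caseversion`,
#'   `fda_dt` (YYYYMMDD receipt date), `sex`, `age`, `age_cod`, `occp_cod`.
#' * `DRUG` - reported drugs: `primaryid`, `drug_seq`, `role_cod`
#'   (PS/SS/C/I), `drugname`, `prod_ai`.
#' * `REAC` - MedDRA preferred terms: `primaryid`, `pt`.
#' * `OUTC` - outcome codes: `primaryid`, `outc_cod` (DE/DS/HO/LT/OT/CA/RI).
#'
#' Malformed rows are never silently dropped: each parsed table carries an
#' `audit` attribute with the rows read and the rows quarantined, and
#' [assemble_cases()] counts orphan rows whose `primaryid` has no DEMO entry.
NULL

FAERS_TABLES <- c("demo", "drug", "reac", "outc")

FAERS_COLUMNS <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "sex", "age",
           "age_cod", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTC_CODES <- c("DE", "DS", "HO", "LT", "OT", "CA", "RI")
SEX_CODES  <- c("F", "M", "UNK")
AGE_CODES  <- c("DEC", "YR", "MON", "WK", "DY", "HR")
OCCP_CODES <- c("MD", "PH", "OT", "CN", "RN", "HP", "LW")

#' Parse one FAERS ASCII table
#'
#' Reads a `$`-delimited, unquoted FAERS table. Mandatory columns missing from
#' the header raise a schema error naming the column. Rows that violate the
#' table's invariants (unparseable `fda_dt`, empty preferred term, outcome
#' code outside the seven FAERS codes) are quarantined and counted in the
#' returned `audit` attribute; field-level problems that do not invalidate the
#' row (an unknown sex or role code) are set to `NA` and counted as malformed.
#'
#' @param path file path.
#' @param kind one of `"demo"`, `"drug"`, `"reac"`, `"outc"`.
#' @return a tibble of typed records with an `audit` attribute
#'   (`n_read`, `n_quarantined`, `n_malformed`).
#' @export
parse_faers_table <- function(path, kind = c("demo", "drug", "reac", "outc")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("FAERS table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "$", quote = "", header = TRUE,
                           colClasses = "character",
                           na.strings = c("", "NA"), check.names = FALSE,
                           fileEncoding = "UTF-8")
  names(raw) <- tolower(trimws(names(raw)))
  req <- FAERS_COLUMNS[[kind]]
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop("FAERS ", toupper(kind), " file is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(raw[req])
  n_read <- nrow(x)
  n_malformed <- 0L
  keep <- rep(TRUE, n_read)

  if (kind == "demo") {
    x$caseversion <- suppressWarnings(as.integer(x$caseversion))
    age_num <- suppressWarnings(as.numeric(x$age))
    n_malformed <- n_malformed + sum(!is.na(x$age) & is.na(age_num))
    x$age <- age_num
    x$sex <- toupper(trimws(x$sex))
    bad_sex <- !is.na(x$sex) & !(x$sex %in% SEX_CODES)
    n_malformed <- n_malformed + sum(bad_sex)
    x$sex[bad_sex] <- NA_character_
    x$age_cod <- toupper(trimws(x$age_cod))
    bad_cod <- !is.na(x$age_cod) & !(x$age_cod %in% AGE_CODES)
    n_malformed <- n_malformed + sum(bad_cod)
    x$age_cod[bad_cod] <- NA_character_
    x$occp_cod <- toupper(trimws(x$occp_cod))
    bad_occ <- !is.na(x$occp_cod) & !(x$occp_cod %in% OCCP_CODES)
    n_malformed <- n_malformed + sum(bad_occ)
    x$occp_cod[bad_occ] <- NA_character_
    keep <- !is.na(x$fda_dt) & grepl("^[0-9]{8}$", x$fda_dt)
  } else if (kind == "drug") {
    x$drug_seq <- suppressWarnings(as.integer(x$drug_seq))
    x$role_cod <- toupper(trimws(x$role_cod))
    bad_role <- !is.na(x$role_cod) & !(x$role_cod %in% ROLE_CODES)
    n_malformed <- n_malformed + sum(bad_role)
    x$role_cod[bad_role] <- NA_character_
    keep <- !is.na(x$drugname) & trimws(x$drugname) != ""
  } else if (kind == "reac") {
    x$pt <- toupper(trimws(x$pt))
    keep <- !is.na(x$pt) & x$pt != ""
  } else if (kind == "outc") {
    x$outc_cod <- toupper(trimws(x$outc_cod))
    keep <- !is.na(x$outc_cod) & x$outc_cod %in% OUTC_CODES
  }
  keep <- keep & !is.na(x$primaryid)
  out <- x[keep, , drop = FALSE]
  attr(out, "audit") <- list(n_read = n_read,
                             n_quarantined = n_read - nrow(out),
                             n_malformed = n_malformed)
  if (n_read == 0L) {
    warning("FAERS ", toupper(kind), " file ", basename(path),
            " contains a header but no records", call. = FALSE)
  }
  out
}

#' Read the four tables of one quarter
#'
#' Expects `DEMO<label>.txt`, `DRUG<label>.txt`, `REAC<label>.txt`,
#' `OUTC<label>.txt` inside `dir`, e.g. `DEMO24Q1.txt`.
#'
#' @param dir directory holding the quarter's files.
#' @param quarter quarter label such as `"24Q1"`.
#' @return named list of parsed tibbles (`demo`, `drug`, `reac`, `outc`).
#' @export
read_faers_quarter <- function(dir, quarter) {
  out <- lapply(FAERS_TABLES, function(k) {
    parse_faers_table(file.path(dir, paste0(toupper(k), quarter, ".txt")), k)
  })
  stats::setNames(out, FAERS_TABLES)
}

#' Assemble parsed tables into a case-level container
#'
#' Joins the DRUG/REAC/OUTC tables onto DEMO by `primaryid`. One case version
#' per DEMO row is retained; rows in the satellite tables whose `primaryid` is
#' absent from DEMO are dropped and counted as orphans (reported, never
#' fatal).
#'
#' @param demo,drug,reac,outc parsed tibbles (see [parse_faers_table()]), or a
#'   list with those names passed as `demo`.
#' @return a `faers_data` object: a list of the four tibbles restricted to
#'   DEMO's primaryids, plus an `orphans` count vector.
#' @export
assemble_cases <- function(demo, drug = NULL, reac = NULL, outc = NULL) {
  if (is.list(demo) && !is.data.frame(demo) && all(FAERS_TABLES %in% names(demo))) {
    q <- demo
    demo <- q$demo; drug <- q$drug; reac <- q$reac; outc <- q$outc
  }
  ids <- demo$primaryid
  orphans <- c(drug = sum(!drug$primaryid %in% ids),
               reac = sum(!reac$primaryid %in% ids),
               outc = sum(!outc$primaryid %in% ids))
  structure(
    list(demo = tibble::as_tibble(demo),
         drug = dplyr::filter(tibble::as_tibble(drug), .data$primaryid %in% ids),
         reac = dplyr::filter(tibble::as_tibble(reac), .data$primaryid %in% ids),
         outc = dplyr::filter(tibble::as_tibble(outc), .data$primaryid %in% ids),
         orphans = orphans),
    class = "faers_data"
  )
}

#' @export
print.faers_data <- function(x, ...) {
  cat("<faers_data> ", nrow(x$demo), " case versions, ",
      nrow(x$drug), " drug rows, ", nrow(x$reac), " reaction rows, ",
      nrow(x$outc), " outcome rows\n", sep = "")
  if (any(x$orphans > 0)) {
    cat("  orphan rows (primaryid not in DEMO):",
        paste(names(x$orphans), x$orphans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of case versions in a `faers_data` object
#' @param fd a `faers_data` object.
#' @return integer count of DEMO rows.
#' @export
n_case_versions <- function(fd) nrow(fd$demo)

# restrict all four tables to a set of primaryids
subset_faers <- function(fd, ids) {
  structure(
    list(demo = dplyr::filter(fd$demo, .data$primaryid %in% ids),
         drug = dplyr::filter(fd$drug, .data$primaryid %in% ids),
         reac = dplyr::filter(fd$reac, .data$primaryid %in% ids),
         outc = dplyr::filter(fd$outc, .data$primaryid %in% ids),
         orphans = fd$orphans),
    class = "faers_data"
  )
}

# stack quarters / splits back together
bind_faers <- function(...) {
  fds <- list(...)
  if (length(fds) == 1 && !inherits(fds[[1]], "faers_data")) fds <- fds[[1]]
  structure(
    list(demo = dplyr::bind_rows(lapply(fds, `[[`, "demo")),
         drug = dplyr::bind_rows(lapply(fds, `[[`, "drug")),
         reac = dplyr::bind_rows(lapply(fds, `[[`, "reac")),
         outc = dplyr::bind_rows(lapply(fds, `[[`, "outc")),
         orphans = Reduce(`+`, lapply(fds, `[[`, "orphans"))),
    class = "faers_data"
  )
}

# write one table in the FAERS dialect ($-delimited, unquoted, header first)
write_faers_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]),
                        NA_character_,
                        format(df[[j]], scientific = FALSE, trim = TRUE))
    }
  }
  utils::write.table(df, path, sep = "$", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a case collection as one FAERS-style quarter
#'
#' Emits `DEMO<label>.txt`, `DRUG<label>.txt`, `REAC<label>.txt`,
#' `OUTC<label>.txt` in the `$`-delimited dialect read by
#' [parse_faers_table()]; the round trip reproduces all modeled fields.
#'
#' @param fd a `faers_data` object.
#' @param dir output directory (created if missing).
#' @param quarter quarter label, e.g. `"24Q1"`.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_faers_quarter <- function(fd, dir, quarter) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(FAERS_TABLES, function(k) {
    file.path(dir, paste0(toupper(k), quarter, ".txt"))
  }, character(1))
  for (k in FAERS_TABLES) {
    write_faers_table(fd[[k]][FAERS_COLUMNS[[k]]], paths[[k]])
  }
  invisible(paths)
}
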