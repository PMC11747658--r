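test_that("header-only files parse to zero records and empty-quarter writes round-trip", {
  dir <- withr::local_tempdir()
  fd0 <- make_mini_faers()
  fd0 <- subset_faers(fd0, character(0))
  paths <- write_faers_quarter(fd0, dir, "24Q1")
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  expect_warning(demo <- parse_faers_table(paths[["demo"]], "demo"),
                 "no records")
  expect_equal(nrow(demo), 0)
})

test_that("a small DRUG table parses with role codes preserved", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "DRUG24Q1.txt")
  writeLines(c("primaryid$drug_seq$role_cod$drugname$prod_ai",
               "1$1$PS$LIPITOR$ATORVASTATIN",
               "2$1$SS$ZOCOR$SIMVASTATIN",
               "3$1$C$ASPIRIN$ASPIRIN"), path)
  drug <- parse_faers_table(path, "drug")
  expect_equal(nrow(drug), 3)
  expect_equal(drug$role_cod, c("PS", "SS", "C"))
  expect_equal(drug$drug_seq, c(1L, 1L, 1L))
})

test_that("missing mandatory columns raise a schema error naming the column", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "REAC24Q1.txt")
  writeLines(c("primaryid$reaction", "1$NAUSEA"), path)
  expect_error(parse_faers_table(path, "reac"), "pt")
})

test_that("malformed rows are quarantined and counted, never silently dropped", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "DEMO24Q1.txt")
  writeLines(c("primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$occp_cod",
               "11$C1$1$20200101$F$60$YR$MD",
               "12$C2$1$NOTADATE$M$50$YR$MD",
               "13$C3$1$20200301$X$40$YR$MD"), path)
  demo <- parse_faers_table(path, "demo")
  audit <- attr(demo, "audit")
  expect_equal(nrow(demo), 2)              # bad fda_dt row quarantined
  expect_equal(audit$n_quarantined, 1)
  expect_gte(audit$n_malformed, 1)         # unknown sex code counted
  expect_true(is.na(demo$sex[demo$primaryid == "13"]))
})

test_that("write then parse is the identity on all modeled fields", {
  dir <- withr::local_tempdir()
  sim <- shared_sim()
  write_faers_quarter(sim$data, dir, "24Q1")
  q <- read_faers_quarter(dir, "24Q1")
  fd2 <- assemble_cases(q)
  for (k in c("demo", "drug", "reac", "outc")) {
    orig <- dplyr::arrange(sim$data[[k]], dplyr::across(dplyr::everything()))
    back <- dplyr::arrange(fd2[[k]], dplyr::across(dplyr::everything()))
    expect_equal(as.data.frame(back), as.data.frame(orig),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("cases split across quarters parse to the same set as a single file", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sim <- shared_sim()
  fd <- sim$data
  ids <- fd$demo$primaryid
  thirds <- split(ids, rep(1:3, length.out = length(ids)))
  labels <- c("23Q1", "23Q2", "23Q3")
  for (i in 1:3) {
    write_faers_quarter(subset_faers(fd, thirds[[i]]), dir1, labels[i])
  }
  write_faers_quarter(fd, dir2, "23Q4")
  multi <- bind_faers(lapply(labels, function(q) {
    assemble_cases(read_faers_quarter(dir1, q))
  }))
  single <- assemble_cases(read_faers_quarter(dir2, "23Q4"))
  for (k in c("demo", "drug", "reac", "outc")) {
    a <- dplyr::arrange(multi[[k]], dplyr::across(dplyr::everything()))
    b <- dplyr::arrange(single[[k]], dplyr::across(dplyr::everything()))
    expect_equal(as.data.frame(a), as.data.frame(b),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("assembly attaches satellites by key and counts orphans", {
  demo <- tibble::tibble(primaryid = "1", caseid = "C1", caseversion = 1L,
                         fda_dt = "20200101", sex = "F", age = 60,
                         age_cod = "YR", occp_cod = "MD")
  reac <- tibble::tibble(primaryid = c("1", "1", "999"),
                         pt = c("NAUSEA", "HEPATITIS", "RASH"))
  drug <- tibble::tibble(primaryid = "1", drug_seq = 1L, role_cod = "PS",
                         drugname = "LIPITOR", prod_ai = "ATORVASTATIN")
  outc <- tibble::tibble(primaryid = character(0), outc_cod = character(0))
  fd <- assemble_cases(demo, drug, reac, outc)
  expect_equal(nrow(fd$reac), 2)              # two PTs attached to the case
  expect_equal(unname(fd$orphans[["reac"]]), 1)
})

test_that("join conservation: attached plus orphan reactions equal parsed rows", {
  sim <- shared_sim()
  fd <- sim$data
  extra <- tibble::tibble(primaryid = c("ZZZ1", "ZZZ2"),
                          pt = c("NAUSEA", "RASH"))
  reac_all <- dplyr::bind_rows(fd$reac, extra)
  fd2 <- assemble_cases(fd$demo, fd$drug, reac_all, fd$outc)
  expect_equal(nrow(fd2$reac) + unname(fd2$orphans[["reac"]]), nrow(reac_all))
})
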