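test_that("2x2 cells are counted case-level from the universe", {
  universe <- c("u1", "u2", "u3", "u4")
  tb <- build_2x2(universe, target = c("u1", "u2"), event = c("u1", "u3"))
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(1, 1, 1, 1))
  expect_equal(tb$n, 4)
})

test_that("a universe without target cases gives a degenerate table flagged by ror", {
  universe <- paste0("u", 1:10)
  tb <- build_2x2(universe, target = character(0), event = c("u1", "u2"))
  expect_equal(c(tb$a, tb$b), c(0, 0))
  rr <- ror(tb)
  expect_false(rr$valid)
  expect_true(is.na(rr$ror))
  expect_error(build_2x2(character(0), "x", "y"), "empty")
})

test_that("repeated matching PTs in one case contribute a single report", {
  universe <- c("u1", "u2", "u3")
  # u1 has three event PTs; event membership is by case, counted once
  reac <- tibble::tibble(primaryid = c("u1", "u1", "u1", "u2"),
                         pt = c("A", "B", "C", "A"))
  evset <- c("A", "B", "C")
  event_ids <- unique(reac$primaryid[reac$pt %in% evset])
  tb <- build_2x2(universe, target = "u1", event = event_ids)
  expect_equal(tb$a, 1)
  # same at the cell level: N counts cases, not reaction rows
  assignments <- tibble::tibble(primaryid = c("u1", "u2", "u3"),
                                drug = c("d1", "d2", "d2"))
  reac2 <- dplyr::bind_rows(reac,
                            tibble::tibble(primaryid = "u3", pt = "B"))
  cells <- build_cell_counts(assignments, reac2)
  expect_equal(cells$N[cells$drug == "d1" & cells$pt == "A"], 1L)
})

test_that("independent margins give E equal to N", {
  # 2 drugs x 2 PTs, perfectly balanced: every cell expects its observation
  assignments <- tibble::tibble(primaryid = as.character(1:40),
                                drug = rep(c("d1", "d2"), each = 20))
  reac <- tibble::tibble(primaryid = as.character(1:40),
                         pt = rep(c("p1", "p2"), times = 20))
  cells <- build_cell_counts(assignments, reac)
  expect_equal(cells$E, as.numeric(cells$N))
})

test_that("expected counts follow the margin product over the grand total", {
  # drug d1 holds all 20 reports of pt p1; margins 20 x 20 over 200 total
  assignments <- tibble::tibble(primaryid = as.character(1:200),
                                drug = c(rep("d1", 20), rep("d2", 180)))
  reac <- tibble::tibble(primaryid = as.character(1:200),
                         pt = c(rep("p1", 20), rep("p2", 180)))
  cells <- build_cell_counts(assignments, reac)
  expect_equal(cells$E[cells$drug == "d1" & cells$pt == "p1"], 2.0)
})

test_that("cell counts conserve margins on simulated data", {
  sim <- shared_sim()
  dd <- deduplicate_cases(sim$data)
  assignments <- dd$drug |>
    dplyr::filter(role_cod == "PS") |>
    dplyr::mutate(drug = toupper(trimws(drugname))) |>
    dplyr::distinct(primaryid, drug)
  cells <- build_cell_counts(assignments, dd$reac)
  expect_lt(abs(sum(cells$E) - sum(cells$N)) / sum(cells$N), 1e-6)
  expect_true(all(cells$E[cells$N > 0] > 0))
})

test_that("degenerate single-drug universes are rejected", {
  assignments <- tibble::tibble(primaryid = c("1", "2"), drug = "d1")
  reac <- tibble::tibble(primaryid = c("1", "2"), pt = c("p1", "p2"))
  expect_error(build_cell_counts(assignments, reac), "at least 2")
})

test_that("pipeline 2x2 equals an independent recount over the emitted files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_cases = 3000, duplicate_rate = 0.1, seed = 11,
                    planted_rr = data.frame(drug = "atorvastatin",
                                            pt = "DRUG-INDUCED LIVER INJURY",
                                            lambda = 5),
                    pt_weights = c("DRUG-INDUCED LIVER INJURY" = 0.01))
  sim <- simulate_faers(cfg)
  write_faers_quarter(sim$data, dir, "24Q1")

  # independent recount with base R over the raw files (latest-version rule
  # applied by hand)
  demo <- read.delim(file.path(dir, "DEMO24Q1.txt"), sep = "$", quote = "",
                     colClasses = "character")
  drug <- read.delim(file.path(dir, "DRUG24Q1.txt"), sep = "$", quote = "",
                     colClasses = "character")
  reac <- read.delim(file.path(dir, "REAC24Q1.txt"), sep = "$", quote = "",
                     colClasses = "character")
  demo <- demo[order(demo$caseid, -as.numeric(demo$fda_dt),
                     -as.numeric(demo$primaryid)), ]
  demo <- demo[!duplicated(demo$caseid), ]
  atorva_syn <- c("ATORVASTATIN", "ATORVASTATIN CALCIUM",
                  "ATORVASTATIN CALCIUM TRIHYDRATE", "LIPITOR")
  ps_ids <- unique(drug$primaryid[drug$role_cod == "PS" &
                                    toupper(trimws(drug$drugname)) %in% atorva_syn])
  ev_ids <- unique(reac$primaryid[toupper(trimws(reac$pt)) ==
                                    "DRUG-INDUCED LIVER INJURY"])
  uni <- demo$primaryid
  a <- length(intersect(intersect(ps_ids, ev_ids), uni))
  b <- length(intersect(ps_ids, uni)) - a
  c_ <- length(intersect(ev_ids, uni)) - a
  d <- length(uni) - a - b - c_

  # pipeline path
  fd <- assemble_cases(read_faers_quarter(dir, "24Q1"))
  dd <- deduplicate_cases(fd)
  coh <- filter_primary_suspect(dd, statin_lexicon())
  tb <- build_2x2(dd$demo$primaryid,
                  coh$annotations$primaryid[coh$annotations$drug == "atorvastatin"],
                  unique(dd$reac$primaryid[dd$reac$pt == "DRUG-INDUCED LIVER INJURY"]))
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(a, b, c_, d))
  expect_gt(tb$a, 0)
})
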