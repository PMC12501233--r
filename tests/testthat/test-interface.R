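test_that("trajectory CSV + sidecar round-trips losslessly", {
  presets <- presets_filled()
  sc <- scenario_from_preset(presets[presets$cell_line == "A4" &
                                       presets$condition == "SS", ])
  tr <- integrate_scenario(sc, settings = solver_settings(t_end = 2,
                                                          n_out = 21))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$states, tr$states)
  expect_equal(back$scenario$cell_line, "A4")
  expect_equal(back$scenario$constants$stress, 3)
  expect_equal(back$settings$t_end, 2)
  # rewriting the reread trajectory reproduces the file byte for byte
  path2 <- tempfile(fileext = ".csv")
  write_trajectory(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("LFQ tables round-trip with the zero-as-missing dialect", {
  synth <- make_lfq_table(generator_spec(seed = 8))
  path <- tempfile(fileext = ".csv")
  write_lfq(synth$lfq, path)
  stored <- utils::read.csv(path)
  expect_false(anyNA(stored[, c("s_1", "s_2", "s_3")]))  # NA stored as 0
  back <- read_lfq(path)
  expect_equal(back$ss_1, synth$lfq$ss_1, tolerance = 1e-12)
  expect_identical(is.na(back$s_1), is.na(synth$lfq$s_1))
  expect_equal(enriched_set(back), enriched_set(synth$lfq))
})

test_that("qPCR and xenograft tables round-trip and validate their schemas", {
  qp <- make_qpcr(generator_spec(seed = 9))
  pq <- tempfile(fileext = ".csv")
  write_qpcr(qp, pq)
  back <- read_qpcr(pq)
  expect_equal(back$ct_nuclear, qp$ct_nuclear, tolerance = 1e-12)

  xg <- make_xenograft_cohort(generator_spec(seed = 9))
  px <- tempfile(fileext = ".csv")
  write_xenografts(xg, px)
  backx <- read_xenografts(px)
  expect_equal(backx$tumor_volume, xg$tumor_volume, tolerance = 1e-12)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,replicate", "S1,1"), bad)
  expect_error(read_qpcr(bad), "missing column")
  writeLines(c("group,pkh_hi,pkh_lo,tumor_volume", "g,150,10,5"), bad)
  expect_error(read_xenografts(bad), "row\\(s\\): 1")
})

test_that("preset tables tolerate a UTF-8 byte-order mark", {
  path <- tempfile(fileext = ".csv")
  con <- file(path, "wb")
  writeBin(as.raw(c(0xef, 0xbb, 0xbf)), con)
  writeLines(readLines(mito_presets_path()), con)
  close(con)
  presets <- load_presets(path)
  expect_equal(nrow(presets), 10)
  expect_equal(names(presets)[1], "cell_line")
})

test_that("the CLI reports usage and failure statuses", {
  expect_output(status <- mito_cli(character(0)), "usage: mitodyn")
  expect_equal(status, 2L)
  expect_output(suppressMessages(status <- mito_cli("frobnicate")),
                "usage: mitodyn")
  expect_equal(status, 2L)
  expect_message(
    suppressWarnings(status <- mito_cli(c("enrich", "--in", tempfile(),
                                          "--out-calls", tempfile(),
                                          "--out-set", tempfile()))),
    "mitodyn enrich")
  expect_equal(status, 1L)
})

test_that("synth then enrich round-trips the planted enrichment truth", {
  dir <- tempfile()
  dir.create(dir)
  prefix <- file.path(dir, "run")
  expect_equal(mito_cli(c("synth", "--what", "lfq", "--seed", "42",
                          "--out", prefix)), 0L)
  calls_path <- file.path(dir, "calls.csv")
  set_path <- file.path(dir, "enriched.txt")
  expect_equal(suppressMessages(
    mito_cli(c("enrich", "--in", paste0(prefix, "_lfq.csv"),
               "--out-calls", calls_path, "--out-set", set_path))), 0L)
  truth <- utils::read.csv(paste0(prefix, "_lfq_truth.csv"))
  expected <- sort(truth$protein_id[truth$category %in%
                                      c("exclusive_SS", "up_SS")])
  expect_equal(readLines(set_path), expected)
})

test_that("the scores subcommand writes both score tables", {
  dir <- tempfile()
  dir.create(dir)
  prefix <- file.path(dir, "synth")
  expect_equal(mito_cli(c("synth", "--seed", "3", "--out", prefix)), 0L)
  expect_equal(mito_cli(c("scores", "--qpcr", paste0(prefix, "_qpcr.csv"),
                          "--xeno", paste0(prefix, "_xeno.csv"),
                          "--out", file.path(dir, "scores"))), 0L)
  qp <- utils::read.csv(file.path(dir, "scores_qpcr.csv"))
  expect_true(all(c("delta_ct", "relative_content") %in% names(qp)))
  xs <- utils::read.csv(file.path(dir, "scores_xeno_scores.csv"))
  expect_true("vehicle" %in% xs$group)
})

test_that("the simulate subcommand writes a trajectory with provenance", {
  dir <- tempfile()
  dir.create(dir)
  out <- file.path(dir, "traj.csv")
  expect_equal(suppressMessages(
    mito_cli(c("simulate", "--cell-line", "OVMZ6", "--condition", "SS",
               "--t-end", "1", "--out", out))), 0L)
  expect_true(file.exists(out))
  prov <- jsonlite::read_json(paste0(out, ".json"), simplifyVector = TRUE)
  expect_equal(prov$scenario$cell_line, "OVMZ6")
  # rerunning from the recorded provenance alone reproduces the output
  tr <- read_trajectory(out)
  rerun <- integrate_scenario(tr$scenario, settings = tr$settings)
  expect_equal(rerun$states, tr$states, tolerance = 1e-12)
})
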