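# Focused-list intersection, the end-to-end pipeline driver, and report
# serialization.

test_that("intersection normalizes homeolog suffixes and reports empty sets", {
  expect_identical(intersect_focused_lists(c("jak2.L", "STAT3"),
                                           c("JAK2", "MSX1")), "JAK2")
  expect_identical(intersect_focused_lists(c("A", "B"), c("C", "D")),
                   character(0))
  expect_identical(intersect_focused_lists(character(0), c("JAK2")),
                   character(0))
})

test_that("the pipeline recovers a planted candidate and nothing else", {
  b <- generate_bundle(small_spec(seed = 101))
  rep <- suppressMessages(run_pipeline(bundle_config(b)))
  expect_identical(rep$candidates, "PLNT1")
  expect_true(all(rep$candidates %in% rep$focused_targets))
  expect_true(all(rep$candidates %in% rep$focused_genes))
  expect_identical(nrow(rep$shared_categories), 3L)
})

test_that("a bundle with no planted overlap yields an empty candidate set", {
  b <- generate_bundle(small_spec(seed = 102, planted_target = "PLNTA",
                                  planted_gene = "PLNTB"))
  rep <- suppressMessages(run_pipeline(bundle_config(b)))
  expect_identical(rep$candidates, character(0))
  expect_true("PLNTA" %in% rep$focused_targets)
  expect_true("PLNTB" %in% rep$focused_genes)
})

test_that("raising either threshold never enlarges the candidate set", {
  b <- generate_bundle(small_spec(seed = 103))
  base <- bundle_config(b)
  prev_by_k <- NULL
  for (k in 1:5) {
    cfg <- base
    cfg$min_chemicals <- k
    r <- suppressMessages(run_pipeline(cfg))
    if (!is.null(prev_by_k)) expect_true(all(r$candidates %in% prev_by_k))
    prev_by_k <- r$candidates
  }
  prev_by_f <- NULL
  for (f in c(0.05, 0.1, 0.2, 0.4)) {
    cfg <- base
    cfg$patient_fraction <- f
    r <- suppressMessages(run_pipeline(cfg))
    if (!is.null(prev_by_f)) expect_true(all(r$candidates %in% prev_by_f))
    prev_by_f <- r$candidates
  }
})

test_that("stage failures abort with the stage name", {
  b <- generate_bundle(small_spec(seed = 104))
  cfg <- bundle_config(b)
  cfg$screen <- tempfile("missing")
  expect_error(suppressMessages(run_pipeline(cfg)), "stage 'read_screen'")
})

test_that("identical config and inputs serialize byte-identically", {
  b <- generate_bundle(small_spec(seed = 105))
  dir <- tempfile("inputs")
  cfg <- write_synthetic_bundle(b, dir)
  out1 <- tempfile("rep1")
  out2 <- tempfile("rep2")
  suppressMessages(run_pipeline(cfg, out_dir = out1))
  suppressMessages(run_pipeline(cfg, out_dir = out2))
  d1 <- dir_digest(out1)
  d2 <- dir_digest(out2)
  expect_identical(names(d1), names(d2))
  expect_identical(unname(d1), unname(d2))
})

test_that("written reports re-parse to the original set-valued fields", {
  b <- generate_bundle(small_spec(seed = 106))
  out <- tempfile("rep")
  rep <- suppressMessages(run_pipeline(bundle_config(b), out_dir = out))
  back <- read_report(out)
  expect_identical(back$candidates, rep$candidates)
  expect_identical(back$focused_targets, rep$focused_targets)
  expect_identical(back$focused_genes, rep$focused_genes)
  expect_identical(back$shared_category_ids, rep$shared_categories$category_id)
  expect_identical(back$n_hits, length(rep$hits))
  # the candidate list appears verbatim in the TSV as well
  cand_tsv <- readr::read_tsv(file.path(out, "candidates.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  expect_identical(as.character(cand_tsv$candidate), rep$candidates)
})

test_that("a YAML configuration file drives the pipeline", {
  b <- generate_bundle(small_spec(seed = 107))
  dir <- tempfile("inputs")
  cfg <- write_synthetic_bundle(b, dir)
  yml <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    screen = "screen.tsv", target_map = "target_map.tsv", cnv = "cnv.tsv",
    annotation = "annotation.tsv", category_map = "categories.tsv",
    min_chemicals = 3, patient_fraction = 0.10, min_genes = 5,
    seed = 107), yml)
  rep <- suppressMessages(run_pipeline(yml))
  expect_identical(rep$candidates, "PLNT1")
})

test_that("curator highlight symbols are echoed when present in either arm", {
  b <- generate_bundle(small_spec(seed = 108))
  cfg <- bundle_config(b)
  cfg$highlight <- c("plnt1", "NOTINANYLIST")
  rep <- suppressMessages(run_pipeline(cfg))
  expect_identical(rep$highlight, "PLNT1")
})
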