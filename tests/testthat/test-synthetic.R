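# Seeded generators: determinism, planted-signal exactness, validator
# compatibility, and spec feasibility errors.

test_that("generators are pure functions of the spec (seed included)", {
  s <- small_spec(seed = 201)
  a <- generate_bundle(s)
  b <- generate_bundle(s)
  expect_identical(tibble::as_tibble(a$screen), tibble::as_tibble(b$screen))
  expect_identical(tibble::as_tibble(a$target_map), tibble::as_tibble(b$target_map))
  expect_identical(a$cohort$deletions, b$cohort$deletions)
  expect_identical(tibble::as_tibble(a$annotation), tibble::as_tibble(b$annotation))
  expect_identical(tibble::as_tibble(a$category_map), tibble::as_tibble(b$category_map))
})

test_that("different seeds give different intervals but identical planted counts", {
  c1 <- generate_cnv_cohort(small_spec(seed = 202))
  c2 <- generate_cnv_cohort(small_spec(seed = 203))
  expect_false(identical(c1$cohort$deletions, c2$cohort$deletions))
  for (cn in list(c1, c2)) {
    gf <- gene_patient_frequency(cn$cohort, cn$annotation)
    expect_identical(gf$n_patients[gf$gene_symbol == "PLNT1"],
                     small_spec()$planted_gene_patients)
  }
})

test_that("the planted target's hit-chemical degree is exact across seeds", {
  for (s in 204:208) {
    spec <- small_spec(seed = s, planted_target_chemicals = 5L)
    chem <- generate_chemical_screen(spec)
    calls <- call_hits(chem$screen)
    expect_identical(sort(hit_chemicals(calls)), sort(chem$hit_ids))
    tf <- target_frequency(chem$hit_ids, chem$target_map)
    expect_identical(tf$n_hit_chemicals[tf$target_symbol == "PLNT1"], 5L)
    # background strictly below the focusing threshold
    bg <- tf[tf$target_symbol != "PLNT1", ]
    expect_true(all(bg$n_hit_chemicals < spec$min_chemicals))
  }
})

test_that("the planted shared-category count is exact, including zero", {
  spec <- small_spec(seed = 209)
  genes_a <- sprintf("TA%02d", 1:20)
  genes_b <- c(sprintf("TB%02d", 1:20), "TA01")
  cm <- generate_functional_map(spec, genes_a, genes_b)
  tA <- suppressMessages(classify_functional(genes_a, cm, spec$min_genes))
  tB <- suppressMessages(classify_functional(genes_b, cm, spec$min_genes))
  expect_identical(nrow(shared_categories(tA, tB)), 3L)

  spec0 <- small_spec(seed = 210, n_shared_categories = 0L)
  cm0 <- generate_functional_map(spec0, genes_a, genes_b)
  tA0 <- suppressMessages(classify_functional(genes_a, cm0, spec0$min_genes))
  tB0 <- suppressMessages(classify_functional(genes_b, cm0, spec0$min_genes))
  expect_identical(nrow(shared_categories(tA0, tB0)), 0L)
})

test_that("generated bundles pass every reader's validation after a disk round-trip", {
  b <- generate_bundle(small_spec(seed = 211))
  dir <- tempfile("bundle")
  cfg <- write_synthetic_bundle(b, dir)
  sc <- read_screen_table(cfg$screen)
  expect_identical(screen_chemicals(sc), screen_chemicals(b$screen))
  tm <- read_target_map(cfg$target_map)
  expect_identical(tibble::as_tibble(tm), tibble::as_tibble(b$target_map))
  co <- read_cnv_table(cfg$cnv)
  expect_identical(co$deletions[order(co$deletions$patient_id), ]$start,
                   b$cohort$deletions[order(b$cohort$deletions$patient_id), ]$start)
  an <- read_gene_annotation(cfg$annotation)
  expect_identical(tibble::as_tibble(an), tibble::as_tibble(b$annotation))
  cm <- read_category_map(cfg$category_map)
  expect_identical(tibble::as_tibble(cm), tibble::as_tibble(b$category_map))
})

test_that("degenerate sizes produce empty but valid objects", {
  empty_chem <- generate_chemical_screen(small_spec(seed = 212, n_chemicals = 0L))
  expect_identical(nrow(empty_chem$screen), 0L)
  expect_identical(nrow(empty_chem$target_map), 0L)
  empty_cnv <- generate_cnv_cohort(small_spec(seed = 213, n_patients = 0L,
                                              planted_gene_patients = 0L))
  expect_identical(cohort_size(empty_cnv$cohort), 0L)
  expect_gt(nrow(empty_cnv$annotation), 0L)
})

test_that("infeasible planted quantities are spec errors", {
  expect_error(small_spec(planted_target_chemicals = 50L),
               "only 10 hits")
  expect_error(small_spec(planted_gene_patients = 31L),
               "only 30")
  spec <- small_spec(seed = 214)
  expect_error(generate_functional_map(spec, c("A1", "A2"), c("B1", "B2")),
               "cannot plant")
})
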