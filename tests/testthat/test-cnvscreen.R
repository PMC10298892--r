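# Deletion-to-gene mapping, per-patient recurrence counting and the
# patient-fraction focus filter. The indexed engine is checked against an
# exhaustive pairwise scan throughout.

test_that("basic overlap semantics: containment, partial, different chromosome", {
  ann <- gene_annotation("G", "chr1", 200, 300)
  del <- tibble::tibble(chrom = "chr1", start = 100, end = 500)
  expect_identical(map_cnv_to_genes(del, ann), "G")
  expect_identical(map_cnv_to_genes(del, ann, "full_containment"), "G")
  del2 <- tibble::tibble(chrom = "chr2", start = 100, end = 500)
  expect_identical(map_cnv_to_genes(del2, ann), character(0))
  # partial overlap counts under any_overlap only
  del3 <- tibble::tibble(chrom = "chr1", start = 250, end = 600)
  expect_identical(map_cnv_to_genes(del3, ann), "G")
  expect_identical(map_cnv_to_genes(del3, ann, "full_containment"), character(0))
  # half-open: touching intervals do not overlap
  del4 <- tibble::tibble(chrom = "chr1", start = 300, end = 400)
  expect_identical(map_cnv_to_genes(del4, ann), character(0))
})

test_that("indexed engine matches the exhaustive pairwise scan on random fixtures", {
  set.seed(123)
  for (i in 1:20) {
    iv <- random_intervals(200)
    ann <- random_annotation(50)
    for (rule in c("any_overlap", "full_containment")) {
      expect_identical(map_cnv_to_genes(iv, ann, rule),
                       brute_force_genes(iv, ann, rule))
    }
  }
})

test_that("chromosome naming mismatches error with a hint instead of silent zero overlap", {
  ann <- gene_annotation("G", "1", 200, 300)
  del <- tibble::tibble(chrom = "chr1", start = 100, end = 500)
  expect_error(map_cnv_to_genes(del, ann, harmonize_chrom = FALSE),
               "no chromosome names in common.*naming conventions differ")
  # harmonization reconciles chr-prefixed and bare names
  expect_message(res <- map_cnv_to_genes(del, ann, harmonize_chrom = TRUE),
                 "harmonized")
  expect_identical(res, "G")
  # genuinely disjoint chromosomes in the same convention are a legal empty set
  del2 <- tibble::tibble(chrom = "chr9", start = 100, end = 500)
  ann2 <- gene_annotation("G", "chr1", 200, 300)
  expect_identical(map_cnv_to_genes(del2, ann2, harmonize_chrom = FALSE),
                   character(0))
})

test_that("a patient is counted once per gene regardless of deletion multiplicity", {
  ann <- gene_annotation("G", "chr1", 200, 300)
  cohort <- cnv_cohort(tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    chrom = "chr1", start = c(100, 150, 250), end = c(400, 350, 500)))
  gf <- gene_patient_frequency(cohort, ann)
  expect_identical(gf$n_patients, 2L)
  expect_identical(gf$patient_ids[[1]], c("P1", "P2"))
})

test_that("an empty cohort yields an empty table with cohort size zero", {
  ann <- gene_annotation("G", "chr1", 200, 300)
  cohort <- cnv_cohort(tibble::tibble(patient_id = character(0),
                                      chrom = character(0),
                                      start = numeric(0), end = numeric(0)))
  gf <- gene_patient_frequency(cohort, ann)
  expect_identical(nrow(gf), 0L)
  expect_identical(attr(gf, "cohort_size"), 0L)
})

test_that("a planted gene's patient count is recovered and matches the brute-force scan", {
  spec <- small_spec(seed = 21, n_patients = 50L, planted_gene_patients = 12L)
  cnv <- generate_cnv_cohort(spec)
  gf <- gene_patient_frequency(cnv$cohort, cnv$annotation)
  expect_identical(gf$n_patients[gf$gene_symbol == "PLNT1"], 12L)
  oracle <- brute_force_gene_patients(cnv$cohort, cnv$annotation)
  expect_identical(unname(oracle[["PLNT1"]]), 12L)
  got <- stats::setNames(gf$n_patients, gf$gene_symbol)
  expect_identical(got[sort(names(got))], oracle[sort(names(oracle))])
})

test_that("recurrence counting is monotone in interval size and cohort growth", {
  set.seed(31)
  ann <- random_annotation(40)
  iv <- random_intervals(10)
  base <- map_cnv_to_genes(iv, ann)
  iv2 <- iv
  iv2$start <- pmax(0, iv2$start - 2e4)
  iv2$end <- iv2$end + 2e4
  expect_true(all(base %in% map_cnv_to_genes(iv2, ann)))
  expect_true(all(map_cnv_to_genes(iv, ann, "full_containment") %in% base))

  c1 <- cnv_cohort(cbind(patient_id = "P1", iv))
  dels2 <- rbind(cbind(patient_id = "P1", iv), cbind(patient_id = "P2", iv2))
  c2 <- cnv_cohort(dels2)
  g1 <- gene_patient_frequency(c1, ann)
  g2 <- gene_patient_frequency(c2, ann)
  n1 <- stats::setNames(g1$n_patients, g1$gene_symbol)
  n2 <- stats::setNames(g2$n_patients, g2$gene_symbol)
  expect_true(all(names(n1) %in% names(n2)))
  expect_true(all(n2[names(n1)] >= n1))
  expect_true(all(g2$n_patients <= cohort_size(c2)))
})

test_that("the patient-fraction threshold resolves as documented for an 83-patient cohort", {
  tab <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                        n_patients = c(9L, 8L, 1L))
  attr(tab, "cohort_size") <- 83L
  ceil <- filter_genes_by_patient_fraction(tab, 0.10, "ceil")
  expect_identical(attr(ceil, "threshold"), 9L)
  expect_identical(as.character(ceil), "A")
  flo <- filter_genes_by_patient_fraction(tab, 0.10, "floor")
  expect_identical(attr(flo, "threshold"), 8L)
  expect_identical(as.character(flo), c("A", "B"))
  at <- filter_genes_by_patient_fraction(tab, 0.10, "at_least")
  expect_identical(as.character(at), "A")
  # a threshold of one patient keeps every represented gene
  all_g <- filter_genes_by_patient_fraction(tab, 0.01, "ceil")
  expect_identical(as.character(all_g), tab$gene_symbol)
  expect_error(filter_genes_by_patient_fraction(tab, 0), "\\(0, 1\\]")
  expect_error(filter_genes_by_patient_fraction(tab, 1.5), "\\(0, 1\\]")
})

test_that("the fraction filter is antitone in the fraction", {
  spec <- small_spec(seed = 77)
  cnv <- generate_cnv_cohort(spec)
  gf <- gene_patient_frequency(cnv$cohort, cnv$annotation)
  fracs <- c(0.02, 0.05, 0.1, 0.2, 0.5)
  lists <- lapply(fracs, function(f)
    as.character(filter_genes_by_patient_fraction(gf, f)))
  for (i in seq_len(length(fracs) - 1)) {
    expect_true(all(lists[[i + 1]] %in% lists[[i]]))
  }
})
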