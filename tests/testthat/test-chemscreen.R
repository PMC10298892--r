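# Hit calling, phenotype tabulation, target deconvolution and the
# minimum-chemicals focus filter.

toy_map <- function() {
  target_map(chemical_id = c("A", "A", "B", "B", "C", "D"),
             target_symbol = c("T1", "T2", "T1", "T2", "T1", "T3"))
}

test_that("persistent membrane with a stomodeum is a hit; a ruptured membrane is not", {
  sc <- screen_from_classes(list(
    NSCa = rep("persistent_bpm", 6),
    NSCb = rep("open_mouth", 6)))
  calls <- call_hits(sc)
  expect_identical(calls$hit, c(TRUE, FALSE))
  expect_identical(hit_chemicals(calls), "NSCa")
})

test_that("no-mouth embryos are excluded under majority but break the all-embryos rule", {
  sc <- screen_from_classes(list(
    NSC1 = c(rep("persistent_bpm", 4), rep("no_mouth", 2))))
  expect_true(call_hits(sc, hit_rule("majority"))$hit)
  expect_false(call_hits(sc, hit_rule("all"))$hit)
})

test_that("hit calling honours the fraction mode and the exclusion flag", {
  sc <- screen_from_classes(list(
    NSC1 = c(rep("persistent_bpm", 3), rep("open_mouth", 3))))
  expect_true(call_hits(sc, hit_rule("fraction", fraction = 0.5))$hit)
  expect_false(call_hits(sc, hit_rule("majority"))$hit)  # 3/6 is not strict
  sc2 <- screen_from_classes(list(
    NSC1 = c(rep("persistent_bpm", 3), rep("open_mouth", 2), "no_mouth")))
  expect_true(call_hits(sc2, hit_rule("majority"))$hit)               # 3 of 5
  expect_false(call_hits(sc2, hit_rule("majority", exclude_no_mouth = FALSE))$hit)
})

test_that("hit calling is invariant under embryo permutation and errors on empty wells", {
  set.seed(5)
  cls <- sample(c(rep("persistent_bpm", 4), "open_mouth", "no_mouth"))
  a <- call_hits(screen_from_classes(list(N1 = cls)))
  b <- call_hits(screen_from_classes(list(N1 = rev(cls))))
  expect_identical(a$hit, b$hit)

  p <- write_lines_tsv(c(
    "chemical_id\tn_persistent_bpm\tn_open_mouth\tn_cleft_mouth\tn_no_mouth",
    "NSC9\t0\t0\t0\t0"))
  empty <- read_screen_table(p, dialect = "well_counts")
  expect_error(call_hits(empty), "at least one embryo score.*NSC9")
})

test_that("phenotype tabulation reports one-decimal percentages that preserve counts", {
  one <- tabulate_phenotypes(rep("absent", 60))
  expect_identical(one$percent[one$category == "absent"], 100)
  expect_identical(one$n[one$category == "absent"], 60L)

  cat <- c(rep("intact", 30), rep("partial", 19), rep("absent", 11))
  tab <- tabulate_phenotypes(cat)
  expect_identical(tab$percent, c(50.0, 31.7, 18.3))
  expect_identical(sum(tab$n), 60L)
  expect_identical(sum(tab$percent[tab$category %in% c("intact", "partial")]),
                   81.7)

  two <- tabulate_phenotypes(rep(cat, 2), rep(c("g1", "g2"), each = 60))
  expect_identical(two$percent[two$group == "g1"],
                   two$percent[two$group == "g2"])
  expect_error(tabulate_phenotypes("gone"), "unknown membrane category")
})

test_that("hits map to the union of their targets; unmapped chemicals are reported", {
  m <- toy_map()
  res <- map_hits_to_targets(c("A", "B"), m)
  expect_identical(res$targets, c("T1", "T2"))
  expect_identical(res$per_chemical$A, c("T1", "T2"))
  expect_identical(map_hits_to_targets(character(0), m)$targets, character(0))
  expect_message(res2 <- map_hits_to_targets("Z", m), "no known targets: Z")
  expect_identical(res2$targets, character(0))
  expect_identical(res2$unmapped, "Z")
})

test_that("target frequency counts distinct hit chemicals and sorts deterministically", {
  tf <- target_frequency(c("A", "B", "C", "D"), toy_map())
  expect_identical(tf$target_symbol, c("T1", "T2", "T3"))
  expect_identical(tf$n_hit_chemicals, c(3L, 2L, 1L))
  expect_identical(tf$chemical_ids[[1]], c("A", "B", "C"))

  dup <- target_map(c("A", "A"), c("T1", "T1"))
  expect_identical(target_frequency("A", dup)$n_hit_chemicals, 1L)
  expect_identical(nrow(target_frequency(character(0), toy_map())), 0L)
})

test_that("degree-sum identity holds between chemicals and targets", {
  set.seed(9)
  chems <- sprintf("C%02d", 1:20)
  m <- target_map(sample(chems, 80, replace = TRUE),
                  sample(sprintf("T%02d", 1:15), 80, replace = TRUE))
  hits <- sample(chems, 12)
  tf <- target_frequency(hits, m)
  per <- map_hits_to_targets(hits, m)$per_chemical
  expect_identical(sum(tf$n_hit_chemicals), sum(lengths(per)))
})

test_that("the minimum-chemicals filter is correct, monotone and validated", {
  tf <- target_frequency(c("A", "B", "C", "D"), toy_map())
  expect_identical(filter_targets_min_chemicals(tf, 3), "T1")
  expect_identical(filter_targets_min_chemicals(tf, 1), tf$target_symbol)
  expect_error(filter_targets_min_chemicals(tf, 0), ">= 1")
  for (k in 1:4) {
    expect_true(all(filter_targets_min_chemicals(tf, k + 1) %in%
                      filter_targets_min_chemicals(tf, k)))
  }
})
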