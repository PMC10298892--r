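# Independent oracles and fixture builders. The brute-force scans here are
# deliberately naive (exhaustive pairwise loops) and share no code with the
# indexed engines they check.

# Exhaustive interval-to-gene scan: for every gene locus, test every
# deletion interval on the same chromosome. Coordinates 0-based half-open.
brute_force_genes <- function(intervals, annotation,
                              rule = c("any_overlap", "full_containment")) {
  rule <- match.arg(rule)
  found <- character(0)
  for (j in seq_len(nrow(annotation))) {
    gc <- annotation$chrom[j]
    gs <- annotation$start[j]
    ge <- annotation$end[j]
    same <- intervals$chrom == gc
    hit <- if (rule == "any_overlap") {
      intervals$start < ge & intervals$end > gs
    } else {
      intervals$start <= gs & intervals$end >= ge
    }
    if (any(same & hit)) found <- c(found, annotation$symbol[j])
  }
  sort(unique(found))
}

# Per-patient membership scan for gene recurrence counts.
brute_force_gene_patients <- function(cohort, annotation,
                                      rule = "any_overlap") {
  counts <- integer(0)
  for (p in cohort$patients) {
    dels <- cohort$deletions[cohort$deletions$patient_id == p, , drop = FALSE]
    genes <- brute_force_genes(dels, annotation, rule)
    for (g in genes) counts[g] <- (if (g %in% names(counts)) counts[[g]] else 0L) + 1L
  }
  counts
}

random_intervals <- function(n, chroms = paste0("chr", 1:5), max_pos = 1e6,
                             max_len = 5e4) {
  st <- floor(runif(n, 0, max_pos))
  len <- ceiling(runif(n, 1, max_len))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = st, end = st + len)
}

random_annotation <- function(m, chroms = paste0("chr", 1:5), max_pos = 1e6,
                              max_len = 3e4) {
  iv <- random_intervals(m, chroms, max_pos, max_len)
  gene_annotation(sprintf("GN%04d", seq_len(m)), iv$chrom, iv$start, iv$end)
}

# Build a screen_table through the public reader from per-chemical embryo
# phenotype classes (one of persistent_bpm / open_mouth / cleft_mouth /
# no_mouth / no_stomodeum).
screen_from_classes <- function(classes_by_chemical) {
  rows <- lapply(names(classes_by_chemical), function(ch) {
    cls <- classes_by_chemical[[ch]]
    data.frame(
      chemical_id = ch,
      embryo = seq_along(cls),
      stomodeum_present = as.integer(cls %in% c("persistent_bpm", "open_mouth", "cleft_mouth")),
      mouth_open = as.integer(cls %in% c("open_mouth", "cleft_mouth")),
      cleft_like = as.integer(cls == "cleft_mouth"),
      no_mouth = as.integer(cls == "no_mouth")
    )
  })
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(do.call(rbind, rows), path, progress = FALSE)
  read_screen_table(path)
}

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

small_spec <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chemicals = 60L, hit_rate = 10 / 60,
               n_targets = 30L, n_patients = 30L, n_genes = 300L,
               n_chromosomes = 4L, n_categories = 12L,
               n_shared_categories = 3L)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_spec, args)
}

bundle_config <- function(bundle, seed = bundle$spec$seed) {
  dualscreen_config(screen = bundle$screen, target_map = bundle$target_map,
                    cnv = bundle$cohort, annotation = bundle$annotation,
                    category_map = bundle$category_map,
                    min_chemicals = bundle$spec$min_chemicals,
                    patient_fraction = bundle$spec$patient_fraction,
                    min_genes = bundle$spec$min_genes, seed = seed)
}

dir_digest <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}
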