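# Seeded generators emulating every input's statistical structure: a
# chemical screen with a known hit set and a bipartite chemical-target map
# with one planted high-frequency target; a patient cohort whose deletion
# intervals recurrently hit one planted gene; and a functional-category map
# with a planted number of categories shared between the two arms.
# Background signal is kept strictly below the focusing thresholds so that
# planted quantities are recovered exactly: the generators test the
# pipeline, not the biology.

#' Specification for a synthetic dual-screen input bundle
#'
#' Defaults are fixed at the study conditions: 1200 screened chemicals with
#' a hit rate of 41/1200, six embryos per well, a cohort of 83 patients, a
#' focusing threshold of three chemicals per target and approximately 10%
#' of patients per gene, categories of five or more genes, and seven
#' planted shared categories. The genome is a simplified layout of
#' non-overlapping gene loci (5000 genes over 23 chromosomes by default).
#'
#' @param seed Integer seed; every generator is a pure function of the spec
#'   (seed included).
#' @param n_chemicals Number of screened chemicals.
#' @param hit_rate Fraction of chemicals causing the phenotype; the hit
#'   count is `round(hit_rate * n_chemicals)`.
#' @param embryos_per_well Embryos scored per chemical well.
#' @param n_targets Size of the background protein-target pool.
#' @param targets_per_chemical Integer range of targets drawn per chemical.
#' @param planted_target Symbol of the planted high-frequency target.
#' @param planted_target_chemicals Number of distinct hit chemicals linked
#'   to the planted target (default `min_chemicals + 2`).
#' @param min_chemicals Target-focusing threshold the background must stay
#'   strictly below (default 3).
#' @param n_patients Cohort size.
#' @param n_genes,n_chromosomes Genome layout.
#' @param gene_length,gene_spacing Uniform ranges (bp) for gene locus
#'   lengths and intergenic gaps.
#' @param deletions_per_patient Integer range of deletions per patient.
#' @param planted_gene Symbol of the planted recurrently deleted gene; when
#'   a planted cross-arm overlap is requested this must equal
#'   `planted_target` (the default).
#' @param planted_gene_patients Number of distinct patients whose deletions
#'   hit the planted gene (default `ceiling(patient_fraction * n_patients) + 2`).
#' @param patient_fraction Gene-focusing fraction the background must stay
#'   strictly below (default 0.10).
#' @param n_categories Number of functional categories.
#' @param min_genes Category-size threshold (default 5).
#' @param n_shared_categories Number of categories planted to pass the size
#'   threshold in both arms (default 7).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chemicals = 1200L,
                           hit_rate = 41 / 1200,
                           embryos_per_well = 6L,
                           n_targets = 180L,
                           targets_per_chemical = 1:4,
                           planted_target = "PLNT1",
                           planted_target_chemicals = NULL,
                           min_chemicals = 3L,
                           n_patients = 83L,
                           n_genes = 5000L,
                           n_chromosomes = 23L,
                           gene_length = c(5e3, 1e5),
                           gene_spacing = c(1e3, 5e4),
                           deletions_per_patient = 1:3,
                           planted_gene = planted_target,
                           planted_gene_patients = NULL,
                           patient_fraction = 0.10,
                           n_categories = 40L,
                           min_genes = 5L,
                           n_shared_categories = 7L) {
  spec <- list(seed = as.integer(seed), n_chemicals = as.integer(n_chemicals),
               hit_rate = hit_rate, embryos_per_well = as.integer(embryos_per_well),
               n_targets = as.integer(n_targets),
               targets_per_chemical = as.integer(targets_per_chemical),
               planted_target = planted_target,
               min_chemicals = as.integer(min_chemicals),
               n_patients = as.integer(n_patients),
               n_genes = as.integer(n_genes),
               n_chromosomes = as.integer(n_chromosomes),
               gene_length = gene_length, gene_spacing = gene_spacing,
               deletions_per_patient = as.integer(deletions_per_patient),
               planted_gene = planted_gene,
               patient_fraction = patient_fraction,
               n_categories = as.integer(n_categories),
               min_genes = as.integer(min_genes),
               n_shared_categories = as.integer(n_shared_categories))
  spec$patient_threshold <- as.integer(ceiling(patient_fraction * spec$n_patients))
  spec$planted_target_chemicals <- as.integer(
    planted_target_chemicals %||% (spec$min_chemicals + 2L))
  spec$planted_gene_patients <- as.integer(
    planted_gene_patients %||% (spec$patient_threshold + 2L))
  n_hits <- as.integer(round(spec$hit_rate * spec$n_chemicals))
  if (spec$n_chemicals > 0L && spec$planted_target_chemicals > n_hits) {
    stop(sprintf("planted target requires %d hit chemicals but the screen yields only %d hits",
                 spec$planted_target_chemicals, n_hits), call. = FALSE)
  }
  if (spec$n_patients > 0L && spec$planted_gene_patients > spec$n_patients) {
    stop(sprintf("planted gene requires %d patients but the cohort has only %d",
                 spec$planted_gene_patients, spec$n_patients), call. = FALSE)
  }
  if (spec$n_genes > 0L && spec$n_genes < spec$n_chromosomes) {
    stop("n_genes must be at least n_chromosomes", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

sub_seed <- function(spec, offset) {
  as.integer((as.numeric(spec$seed) + offset) %% .Machine$integer.max)
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate a synthetic chemical screen and target map
#'
#' Hit chemicals receive embryo scores satisfying the default majority hit
#' rule (at least a strict majority of scoreable embryos with a stomodeum
#' and an unruptured membrane); non-hit chemicals receive open-mouth (or
#' occasional no-mouth) scores. The planted target is linked to exactly its
#' specified number of distinct hit chemicals, and every background target
#' is linked to strictly fewer hit chemicals than the focusing threshold.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `screen` (a `screen_table`), `target_map` (a
#'   `target_map`), and `hit_ids` (ground-truth hit chemicals).
#' @export
generate_chemical_screen <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(sub_seed(spec, 0))
  m <- spec$embryos_per_well
  chems <- if (spec$n_chemicals > 0L) {
    sprintf("NSC%05d", seq_len(spec$n_chemicals))
  } else character(0)
  n_hits <- as.integer(round(spec$hit_rate * spec$n_chemicals))
  if (spec$n_chemicals == 0L) {
    screen <- new_screen_table(
      tibble::tibble(chemical_id = character(0), embryo = integer(0),
                     stomodeum_present = logical(0), mouth_open = logical(0),
                     cleft_like = logical(0), no_mouth = logical(0),
                     concentration = numeric(0)), character(0))
    return(list(screen = screen,
                target_map = target_map(character(0), character(0)),
                hit_ids = character(0)))
  }
  hit_ids <- sort(sample(chems, n_hits))
  is_hit <- chems %in% hit_ids
  majority <- floor(m / 2) + 1L

  cls <- unlist(lapply(seq_along(chems), function(i) {
    if (is_hit[i]) {
      n_p <- sample1(majority:m)
      rest <- sample(c("open_mouth", "no_mouth"), m - n_p, replace = TRUE,
                     prob = c(0.7, 0.3))
      sample(c(rep("persistent_bpm", n_p), rest))
    } else {
      sample(c("open_mouth", "cleft_mouth", "no_mouth"), m, replace = TRUE,
             prob = c(0.6, 0.25, 0.15))
    }
  }), use.names = FALSE)
  df <- tibble::tibble(chemical_id = rep(chems, each = m),
                       embryo = rep(seq_len(m), times = length(chems)))
  df <- cbind(df, phenotype_class_scores(cls))
  df$concentration <- 30
  screen <- new_screen_table(tibble::as_tibble(df), chems)

  # Bipartite chemical-target map. Hit-chemical links are drawn only from
  # background targets whose current hit-degree is below min_chemicals - 1,
  # so no background target ever reaches the focusing threshold.
  bg_targets <- sprintf("TRG%04d", seq_len(spec$n_targets))
  deg <- stats::setNames(integer(spec$n_targets), bg_targets)
  max_bg <- spec$min_chemicals - 1L
  pair_chem <- vector("list", length(chems))
  for (i in seq_along(chems)) {
    n_t <- sample1(spec$targets_per_chemical)
    if (is_hit[i]) {
      pool <- bg_targets[deg < max_bg]
      n_t <- min(n_t, length(pool))
      sel <- pool[sample.int(length(pool), n_t)]
      deg[sel] <- deg[sel] + 1L
    } else {
      sel <- bg_targets[sample.int(length(bg_targets), n_t)]
    }
    pair_chem[[i]] <- sel
  }
  planted_chems <- sort(sample(hit_ids, spec$planted_target_chemicals))
  map <- target_map(
    chemical_id = c(rep(chems, lengths(pair_chem)), planted_chems),
    target_symbol = c(unlist(pair_chem, use.names = FALSE),
                      rep(spec$planted_target, length(planted_chems))))
  list(screen = screen, target_map = map, hit_ids = hit_ids)
}

#' Generate a synthetic patient CNV cohort and gene annotation
#'
#' Lays out non-overlapping gene loci per chromosome, then draws per-patient
#' deletion intervals with log-uniform lengths (between one mean gene length
#' and half a chromosome). Deletions of the planted patients cover the
#' planted gene's locus without touching its neighbors; background deletions
#' never overlap the planted locus (rejection sampling), so the planted gene
#' is hit by exactly its specified number of distinct patients. If any
#' background gene reaches the patient-fraction threshold, the offending
#' patients' background deletions are redrawn until all background counts
#' sit strictly below it.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `cohort` (a `cnv_cohort`), `annotation` (a
#'   `gene_annotation`), and `planted_patients` (ground truth).
#' @export
generate_cnv_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(sub_seed(spec, 1))

  # genome layout: non-overlapping loci with random lengths and gaps
  n_per <- rep(spec$n_genes %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- spec$n_genes %% spec$n_chromosomes
  if (extra > 0L) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  ann_parts <- vector("list", spec$n_chromosomes)
  chrom_len <- numeric(spec$n_chromosomes)
  idx0 <- 0L
  for (i in seq_len(spec$n_chromosomes)) {
    n_i <- n_per[i]
    if (n_i == 0L) next
    len <- round(runif(n_i, spec$gene_length[1], spec$gene_length[2]))
    gap <- round(runif(n_i, spec$gene_spacing[1], spec$gene_spacing[2]))
    start <- cumsum(gap) + c(0, cumsum(len))[seq_len(n_i)]
    ann_parts[[i]] <- tibble::tibble(
      symbol = sprintf("G%05d", idx0 + seq_len(n_i)),
      chrom = paste0("chr", i),
      start = start, end = start + len,
      strand = sample(c("+", "-"), n_i, replace = TRUE))
    chrom_len[i] <- start[n_i] + len[n_i] + spec$gene_spacing[2]
    idx0 <- idx0 + n_i
  }
  ann <- do.call(rbind, ann_parts)

  patients <- if (spec$n_patients > 0L) {
    sprintf("PT%03d", seq_len(spec$n_patients))
  } else character(0)

  if (spec$n_patients == 0L || spec$n_genes == 0L) {
    annotation <- if (spec$n_genes > 0L) {
      gene_annotation(ann$symbol, ann$chrom, ann$start, ann$end, ann$strand)
    } else {
      gene_annotation(character(0), character(0), numeric(0), numeric(0))
    }
    return(list(cohort = cnv_cohort(tibble::tibble(patient_id = character(0),
                                                   chrom = character(0),
                                                   start = numeric(0),
                                                   end = numeric(0)),
                                    patients = patients),
                annotation = annotation, planted_patients = character(0)))
  }

  # plant one gene; remember its locus and its neighborhood bounds
  planted_idx <- sample.int(nrow(ann), 1L)
  ann$symbol[planted_idx] <- normalize_symbol(spec$planted_gene)
  p_chrom <- ann$chrom[planted_idx]
  p_start <- ann$start[planted_idx]
  p_end <- ann$end[planted_idx]
  same <- which(ann$chrom == p_chrom)
  pos <- match(planted_idx, same)
  left_bound <- if (pos > 1L) ann$end[same[pos - 1L]] else 0
  p_chrom_i <- as.integer(sub("^chr", "", p_chrom))
  right_bound <- if (pos < length(same)) ann$start[same[pos + 1L]] else chrom_len[p_chrom_i]

  min_len <- mean(spec$gene_length)
  draw_background <- function() {
    for (try in 1:200) {
      ci <- sample.int(spec$n_chromosomes, 1L)
      if (chrom_len[ci] <= 0) next
      len <- exp(runif(1, log(min_len), log(max(min_len + 1, chrom_len[ci] / 2))))
      st <- floor(runif(1, 0, max(1, chrom_len[ci] - len)))
      en <- st + round(len)
      # keep the planted locus untouched so its patient count stays exact
      if (paste0("chr", ci) == p_chrom && st < p_end && en > p_start) next
      return(c(ci, st, en))
    }
    stop("synthetic cohort: could not place a background deletion off the planted locus",
         call. = FALSE)
  }
  draw_planted <- function() {
    st <- floor(runif(1, left_bound, p_start))
    en <- ceiling(runif(1, p_end, right_bound))
    c(p_chrom_i, st, max(en, p_end + 1))
  }

  planted_patients <- sort(sample(patients, spec$planted_gene_patients))
  draw_patient <- function(pid) {
    n_d <- sample1(spec$deletions_per_patient)
    rows <- vector("list", n_d)
    j <- 1L
    if (pid %in% planted_patients) {
      rows[[1L]] <- draw_planted()
      j <- 2L
    }
    while (j <= n_d) {
      rows[[j]] <- draw_background()
      j <- j + 1L
    }
    mat <- do.call(rbind, rows)
    tibble::tibble(patient_id = pid, chrom = paste0("chr", mat[, 1]),
                   start = mat[, 2], end = mat[, 3])
  }
  dels <- lapply(stats::setNames(patients, patients), draw_patient)
  annotation <- gene_annotation(ann$symbol, ann$chrom, ann$start, ann$end,
                                ann$strand)

  # enforce background counts strictly below the patient threshold
  threshold <- spec$patient_threshold
  for (iter in 1:200) {
    deletions <- do.call(rbind, dels)
    cohort <- cnv_cohort(deletions, patients = patients,
                         phenotype_tag = "synthetic")
    gfreq <- gene_patient_frequency(cohort, annotation)
    over <- gfreq[gfreq$n_patients >= threshold &
                    gfreq$gene_symbol != normalize_symbol(spec$planted_gene), ]
    if (nrow(over) == 0L) {
      return(list(cohort = cohort, annotation = annotation,
                  planted_patients = planted_patients))
    }
    victim <- over$patient_ids[[1L]][1L]
    dels[[victim]] <- draw_patient(victim)
  }
  stop("synthetic cohort: background recurrence could not be kept below the threshold",
       call. = FALSE)
}

#' Generate a synthetic gene-to-functional-category map
#'
#' Plants exactly `n_shared_categories` categories whose membership reaches
#' the `min_genes` size threshold in *both* input gene lists; remaining
#' categories either pass in only one arm (drawn from arm-exclusive genes)
#' or stay below the threshold everywhere.
#'
#' @param spec A [synthetic_spec()].
#' @param armA_genes,armB_genes Normalized gene symbol lists of the two
#'   arms (chemical-screen targets; deleted genes).
#' @return A `category_map`.
#' @export
generate_functional_map <- function(spec, armA_genes, armB_genes) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(sub_seed(spec, 2))
  a <- unique(normalize_symbol(armA_genes))
  b <- unique(normalize_symbol(armB_genes))
  s <- spec$n_shared_categories
  mg <- spec$min_genes
  if (s > 0L && (length(a) < mg || length(b) < mg)) {
    stop(sprintf("cannot plant %d shared categories: need >= %d genes per arm (have %d and %d)",
                 s, mg, length(a), length(b)), call. = FALSE)
  }
  if (s > spec$n_categories) {
    stop("n_shared_categories exceeds n_categories", call. = FALSE)
  }
  excl_a <- setdiff(a, b)
  excl_b <- setdiff(b, a)
  n_rest <- spec$n_categories - s
  n_a_only <- if (length(excl_a) >= mg) n_rest %/% 3L else 0L
  n_b_only <- if (length(excl_b) >= mg) n_rest %/% 3L else 0L
  n_bg <- n_rest - n_a_only - n_b_only

  take <- function(pool, size) pool[sample.int(length(pool), size)]
  assign_one <- function(role) {
    switch(role,
      shared = unique(c(take(a, min(length(a), mg + 2L)),
                        take(b, min(length(b), mg + 2L)))),
      a_only = take(excl_a, min(length(excl_a), mg + 2L)),
      b_only = take(excl_b, min(length(excl_b), mg + 2L)),
      background = take(union(a, b), sample1(seq_len(max(1L, mg - 1L))))
    )
  }
  roles <- c(rep("shared", s), rep("a_only", n_a_only),
             rep("b_only", n_b_only), rep("background", n_bg))
  members <- lapply(roles, assign_one)
  if (length(roles) == 0L) {
    return(category_map(character(0), character(0), character(0)))
  }
  ids <- sprintf("CAT%03d", seq_along(roles))
  nms <- sprintf("synthetic category %03d", seq_along(roles))
  category_map(gene_symbol = unlist(members, use.names = FALSE),
               category_id = rep(ids, lengths(members)),
               category_name = rep(nms, lengths(members)))
}

#' Generate a complete synthetic input bundle
#'
#' Runs all three generators and derives each arm's gene list (unique hit
#' targets; genes deleted in at least one patient) for the category map.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `spec`, `screen`, `target_map`, `cohort`,
#'   `annotation`, `category_map`, plus ground truth `hit_ids` and
#'   `planted_patients`.
#' @export
generate_bundle <- function(spec) {
  chem <- generate_chemical_screen(spec)
  cnv <- generate_cnv_cohort(spec)
  armA <- sort(unique(chem$target_map$target_symbol[
    chem$target_map$chemical_id %in% chem$hit_ids]))
  armB <- map_cnv_to_genes(cnv$cohort, cnv$annotation)
  fmap <- generate_functional_map(spec, armA, armB)
  list(spec = spec, screen = chem$screen, target_map = chem$target_map,
       hit_ids = chem$hit_ids, cohort = cnv$cohort,
       annotation = cnv$annotation,
       planted_patients = cnv$planted_patients, category_map = fmap)
}

#' Write a synthetic bundle to disk in the canonical dialects
#'
#' @param bundle Output of [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return A [dualscreen_config()] pointing at the written files, with the
#'   spec's thresholds and seed, ready for [run_pipeline()]; the file paths
#'   are available in its input fields.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(screen = file.path(dir, "screen.tsv"),
                target_map = file.path(dir, "target_map.tsv"),
                cnv = file.path(dir, "cnv.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                category_map = file.path(dir, "categories.tsv"))
  write_screen_table(bundle$screen, paths$screen)
  write_target_map(bundle$target_map, paths$target_map)
  write_cnv_table(bundle$cohort, paths$cnv)
  write_gene_annotation(bundle$annotation, paths$annotation)
  write_category_map(bundle$category_map, paths$category_map)
  dualscreen_config(screen = paths$screen, target_map = paths$target_map,
                    cnv = paths$cnv, annotation = paths$annotation,
                    category_map = paths$category_map,
                    min_chemicals = bundle$spec$min_chemicals,
                    patient_fraction = bundle$spec$patient_fraction,
                    min_genes = bundle$spec$min_genes,
                    phenotype_tag = "synthetic",
                    seed = bundle$spec$seed)
}
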