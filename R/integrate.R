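# Pipeline driver: run both screening arms from one configuration,
# intersect the focused lists, and assemble a fully provenance-tracked
# integration report.

#' Build a pipeline configuration
#'
#' One configuration drives the whole analysis; the defaults reproduce the
#' study's stated settings (minimum of three distinct hit chemicals per
#' target, genes deleted in approximately 10% of patients, functional
#' categories with five or more genes).
#'
#' Each of the five inputs may be given either as a file path (read with
#' the matching reader and dialect) or as an already-constructed in-memory
#' object (`screen_table`, `target_map`, `cnv_cohort`, `gene_annotation`,
#' `category_map`).
#'
#' @param screen Screen table path or object.
#' @param target_map Chemical-target map path or object.
#' @param cnv Patient CNV table path or `cnv_cohort`.
#' @param annotation Gene annotation path or object.
#' @param category_map Functional category map path or object.
#' @param screen_dialect Dialect for a screen path (see
#'   [read_screen_table()]).
#' @param cnv_dialect Coordinate dialect for a CNV path.
#' @param annotation_format,annotation_dialect Format/dialect for an
#'   annotation path.
#' @param hit_mode,hit_fraction,exclude_no_mouth Hit rule settings (see
#'   [hit_rule()]).
#' @param min_chemicals Minimum distinct hit chemicals per focused target
#'   (default 3).
#' @param patient_fraction Recurrence fraction for focused genes
#'   (default 0.10).
#' @param threshold_mode Integer-threshold mode for the patient fraction
#'   (see [filter_genes_by_patient_fraction()]).
#' @param overlap_rule Deletion-to-gene overlap rule (see
#'   [map_cnv_to_genes()]).
#' @param min_genes Minimum functional category size (default 5), applied
#'   to both arms; `min_genes_cnv` overrides the CNV arm.
#' @param min_genes_cnv Optional CNV-arm override of `min_genes`.
#' @param synonyms Optional synonym table (named character vector, data
#'   frame, or path to a two-column TSV) applied during symbol
#'   normalization.
#' @param highlight Optional character vector of curator-highlighted
#'   symbols echoed in the report (manual scrutiny is human curation, not
#'   computation).
#' @param phenotype_tag Clinical phenotype label for the cohort.
#' @param seed Seed recorded in provenance when the inputs are synthetic.
#' @return A `dualscreen_config` list.
#' @export
dualscreen_config <- function(screen, target_map, cnv, annotation,
                              category_map,
                              screen_dialect = "embryo_long",
                              cnv_dialect = "bed0half",
                              annotation_format = "tsv",
                              annotation_dialect = "bed0half",
                              hit_mode = "majority", hit_fraction = NULL,
                              exclude_no_mouth = TRUE,
                              min_chemicals = 3L,
                              patient_fraction = 0.10,
                              threshold_mode = "ceil",
                              overlap_rule = "any_overlap",
                              min_genes = 5L, min_genes_cnv = NULL,
                              synonyms = NULL, highlight = NULL,
                              phenotype_tag = "Choanal Atresia",
                              seed = NULL) {
  cfg <- list(screen = screen, target_map = target_map, cnv = cnv,
              annotation = annotation, category_map = category_map,
              screen_dialect = screen_dialect, cnv_dialect = cnv_dialect,
              annotation_format = annotation_format,
              annotation_dialect = annotation_dialect,
              hit_mode = hit_mode, hit_fraction = hit_fraction,
              exclude_no_mouth = exclude_no_mouth,
              min_chemicals = min_chemicals,
              patient_fraction = patient_fraction,
              threshold_mode = threshold_mode, overlap_rule = overlap_rule,
              min_genes = min_genes,
              min_genes_cnv = min_genes_cnv %||% min_genes,
              synonyms = synonyms, highlight = highlight,
              phenotype_tag = phenotype_tag, seed = seed)
  hit_rule(cfg$hit_mode, cfg$hit_fraction, cfg$exclude_no_mouth)
  if (cfg$min_chemicals < 1) stop("min_chemicals must be >= 1", call. = FALSE)
  if (cfg$patient_fraction <= 0 || cfg$patient_fraction > 1) {
    stop("patient_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "dualscreen_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [dualscreen_config()]; relative input paths
#' are resolved against the configuration file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A `dualscreen_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("screen", "target_map", "cnv", "annotation", "category_map",
                "synonyms")) {
    if (is.character(raw[[key]]) && !file.exists(raw[[key]])) {
      cand <- file.path(base, raw[[key]])
      if (file.exists(cand)) raw[[key]] <- cand
    }
  }
  do.call(dualscreen_config, raw)
}

#' Intersect the two focused symbol lists
#'
#' The cross-species evidence intersection: protein targets recurrently hit
#' in the chemical screen against genes recurrently deleted in the patient
#' cohort. Both lists are symbol-normalized (homeolog suffixes stripped, an
#' optional synonym table applied) before intersection; an empty
#' intersection is a valid, explicitly reported outcome.
#'
#' @param targets Focused target symbols (chemical-screen arm).
#' @param genes Focused gene symbols (CNV arm).
#' @param synonyms Optional synonym table (see [normalize_symbol()]).
#' @return Sorted character vector of candidate symbols.
#' @export
intersect_focused_lists <- function(targets, genes, synonyms = NULL) {
  a <- if (length(targets)) normalize_symbol(targets, synonyms) else character(0)
  b <- if (length(genes)) normalize_symbol(genes, synonyms) else character(0)
  sort(intersect(a, b))
}

resolve_synonyms <- function(synonyms) {
  if (is.character(synonyms) && length(synonyms) == 1L &&
      is.null(names(synonyms))) {
    df <- read_tsv_strict(synonyms, character(0), "synonyms")
    if (ncol(df) < 2L) stop("synonym file needs two columns", call. = FALSE)
    return(stats::setNames(as.character(df[[2L]]), as.character(df[[1L]])))
  }
  synonyms
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

input_digest <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    NA_character_
  }
}

#' Run the full dual-evidence prioritization pipeline
#'
#' Executes both arms end to end: hit calling and target frequency ranking
#' on the chemical screen; deletion-to-gene mapping and patient recurrence
#' counting on the CNV cohort; functional-category profiling of each arm's
#' full gene list; shared categories; and the focused-list intersection.
#' Every filter logs its in/out counts so the funnel is visible in the run
#' log. Any stage failure aborts with the stage name and no partial outputs
#' are written. Re-running on identical inputs and configuration is
#' byte-identical.
#'
#' @param config A `dualscreen_config` (or path to a YAML config).
#' @param out_dir Optional output directory; when given, the report is
#'   written with [write_report()] after the whole analysis succeeds.
#' @return An `integration_report`: a list with the hit calls, both
#'   frequency tables, both focused lists (with the thresholds used), both
#'   category tables, the shared categories, the candidate intersection and
#'   a provenance block (configuration snapshot, input digests, package
#'   version, seed).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "dualscreen_config"))
  synonyms <- with_stage("synonyms", resolve_synonyms(config$synonyms))

  screen <- with_stage("read_screen", {
    if (is.character(config$screen)) {
      read_screen_table(config$screen, dialect = config$screen_dialect)
    } else config$screen
  })
  tmap <- with_stage("read_target_map", {
    if (is.character(config$target_map)) {
      read_target_map(config$target_map, synonyms = synonyms)
    } else config$target_map
  })
  cohort <- with_stage("read_cnv", {
    if (is.character(config$cnv)) {
      read_cnv_table(config$cnv, coordinate_dialect = config$cnv_dialect,
                     phenotype_tag = config$phenotype_tag)
    } else config$cnv
  })
  annotation <- with_stage("read_annotation", {
    if (is.character(config$annotation)) {
      read_gene_annotation(config$annotation,
                           format = config$annotation_format,
                           coordinate_dialect = config$annotation_dialect,
                           synonyms = synonyms)
    } else config$annotation
  })
  cmap <- with_stage("read_category_map", {
    if (is.character(config$category_map)) {
      read_category_map(config$category_map, synonyms = synonyms)
    } else config$category_map
  })

  rule <- hit_rule(config$hit_mode, config$hit_fraction,
                   config$exclude_no_mouth)
  calls <- with_stage("hit_calling", call_hits(screen, rule))
  hits <- hit_chemicals(calls)
  message(sprintf("chemical screen: %d chemicals -> %d hits",
                  nrow(calls), length(hits)))

  deconv <- with_stage("target_deconvolution",
                       map_hits_to_targets(hits, tmap))
  tfreq <- with_stage("target_frequency", target_frequency(hits, tmap))
  focused_targets <- with_stage("target_filter",
    filter_targets_min_chemicals(tfreq, config$min_chemicals))
  message(sprintf("target deconvolution: %d hits -> %d unique targets -> %d targets with >= %d chemicals",
                  length(hits), length(deconv$targets),
                  length(focused_targets), config$min_chemicals))

  gfreq <- with_stage("gene_patient_frequency",
    gene_patient_frequency(cohort, annotation,
                           overlap_rule = config$overlap_rule))
  focused_genes <- with_stage("gene_filter",
    filter_genes_by_patient_fraction(gfreq, config$patient_fraction,
                                     config$threshold_mode))
  patient_threshold <- attr(focused_genes, "threshold")
  message(sprintf("CNV screen: %d patients -> %d deleted genes -> %d genes in >= %d patients",
                  cohort_size(cohort), nrow(gfreq), length(focused_genes),
                  patient_threshold))

  cat_chem <- with_stage("classify_chemical_arm",
    classify_functional(deconv$targets, cmap, config$min_genes))
  cat_cnv <- with_stage("classify_cnv_arm",
    classify_functional(gfreq$gene_symbol, cmap, config$min_genes_cnv))
  shared <- with_stage("shared_categories",
                       shared_categories(cat_chem, cat_cnv))
  message(sprintf("functional overlap: %d vs %d categories -> %d shared",
                  nrow(cat_chem), nrow(cat_cnv), nrow(shared)))

  candidates <- with_stage("intersection",
    intersect_focused_lists(focused_targets, focused_genes, synonyms))
  message(sprintf("candidate intersection: %d target(s) x %d gene(s) -> %d candidate(s)%s",
                  length(focused_targets), length(focused_genes),
                  length(candidates),
                  if (length(candidates)) paste0(": ", paste(candidates, collapse = ", "))
                  else " (empty intersection)"))

  highlight <- intersect(
    if (length(config$highlight)) normalize_symbol(config$highlight) else character(0),
    unique(c(deconv$targets, gfreq$gene_symbol)))

  provenance <- list(
    package_version = as.character(utils::packageVersion("dualscreen")),
    seed = config$seed,
    thresholds = list(min_chemicals = as.integer(config$min_chemicals),
                      patient_fraction = config$patient_fraction,
                      patient_threshold = as.integer(patient_threshold),
                      threshold_mode = config$threshold_mode,
                      min_genes = as.integer(config$min_genes),
                      min_genes_cnv = as.integer(config$min_genes_cnv),
                      hit_mode = config$hit_mode,
                      overlap_rule = config$overlap_rule),
    input_digests = list(screen = input_digest(config$screen),
                         target_map = input_digest(config$target_map),
                         cnv = input_digest(config$cnv),
                         annotation = input_digest(config$annotation),
                         category_map = input_digest(config$category_map))
  )

  report <- structure(list(
    hit_calls = calls,
    hits = hits,
    unmapped_chemicals = deconv$unmapped,
    target_frequency = tfreq,
    focused_targets = as.character(focused_targets),
    gene_frequency = gfreq,
    focused_genes = as.character(focused_genes),
    cohort_size = cohort_size(cohort),
    categories_chemical = cat_chem,
    categories_cnv = cat_cnv,
    shared_categories = shared,
    candidates = candidates,
    highlight = highlight,
    provenance = provenance
  ), class = "integration_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.integration_report <- function(x, ...) {
  th <- x$provenance$thresholds
  cat("<integration_report>\n")
  cat(sprintf("  chemical screen : %d chemicals, %d hits, %d unique targets, %d targets with >= %d chemicals\n",
              nrow(x$hit_calls), length(x$hits),
              length(unique(x$target_frequency$target_symbol)),
              length(x$focused_targets), th$min_chemicals))
  cat(sprintf("  CNV screen      : %d patients, %d deleted genes, %d genes in >= %d patients\n",
              x$cohort_size, nrow(x$gene_frequency),
              length(x$focused_genes), th$patient_threshold))
  cat(sprintf("  shared functional categories: %d\n", nrow(x$shared_categories)))
  cat(sprintf("  candidates      : %s\n",
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none)"))
  invisible(x)
}

collapse_ids <- function(ids) vapply(ids, function(v) paste(v, collapse = ","), character(1))

#' Write an integration report to a directory
#'
#' Emits a machine-readable summary (`summary.json`) plus human-readable
#' TSVs: both frequency tables, both focused lists, both category tables,
#' the shared categories and the candidate list. Every printed count is
#' traceable to a table file. The writer contains no timestamps, so
#' identical reports serialize byte-identically.
#'
#' @param report An `integration_report`.
#' @param out_dir Output directory (created if needed). Writability is
#'   checked before any file is created.
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "integration_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  p <- function(f) file.path(out_dir, f)

  tf <- tibble::as_tibble(report$target_frequency)
  tf$chemical_ids <- collapse_ids(tf$chemical_ids)
  readr::write_tsv(tf, p("target_frequency.tsv"), progress = FALSE)

  gf <- tibble::as_tibble(report$gene_frequency)
  gf$patient_ids <- collapse_ids(gf$patient_ids)
  readr::write_tsv(gf, p("gene_frequency.tsv"), progress = FALSE)

  readr::write_tsv(tibble::tibble(target_symbol = report$focused_targets),
                   p("focused_targets.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(gene_symbol = report$focused_genes),
                   p("focused_genes.tsv"), progress = FALSE)

  for (arm in c("chemical", "cnv")) {
    ct <- tibble::as_tibble(report[[paste0("categories_", arm)]])
    ct$genes <- collapse_ids(ct$genes)
    readr::write_tsv(ct, p(sprintf("categories_%s.tsv", arm)), progress = FALSE)
  }
  readr::write_tsv(tibble::as_tibble(report$shared_categories),
                   p("shared_categories.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(candidate = report$candidates),
                   p("candidates.tsv"), progress = FALSE)
  readr::write_tsv(report$hit_calls, p("hit_calls.tsv"), progress = FALSE)

  summary <- list(
    n_chemicals = nrow(report$hit_calls),
    n_hits = length(report$hits),
    n_unique_targets = length(unique(report$target_frequency$target_symbol)),
    n_focused_targets = length(report$focused_targets),
    cohort_size = report$cohort_size,
    n_deleted_genes = nrow(report$gene_frequency),
    n_focused_genes = length(report$focused_genes),
    n_shared_categories = nrow(report$shared_categories),
    candidates = as.list(report$candidates),
    focused_targets = as.list(report$focused_targets),
    focused_genes = as.list(report$focused_genes),
    shared_category_ids = as.list(report$shared_categories$category_id),
    unmapped_chemicals = as.list(report$unmapped_chemicals),
    highlight = as.list(report$highlight),
    provenance = report$provenance
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Re-read the set-valued fields of a written report
#'
#' @param out_dir A directory written by [write_report()].
#' @return A list with `candidates`, `focused_targets`, `focused_genes`,
#'   `shared_category_ids` and the summary counts, parsed back from the
#'   report files.
#' @export
read_report <- function(out_dir) {
  s <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                           simplifyVector = TRUE)
  s$candidates <- as.character(s$candidates %||% character(0))
  s$focused_targets <- as.character(s$focused_targets %||% character(0))
  s$focused_genes <- as.character(s$focused_genes %||% character(0))
  s$shared_category_ids <- as.character(s$shared_category_ids %||% character(0))
  s
}
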