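# Domain types and strict readers/writers for every table the pipeline
# touches. All genomic intervals are held internally in a single canonical
# convention: 0-based, half-open [start, end). Dialects are converted at the
# boundary, never downstream.

PHENO_COLS <- c("stomodeum_present", "mouth_open", "cleft_like", "no_mouth")
WELL_COUNT_COLS <- c("n_persistent_bpm", "n_open_mouth", "n_cleft_mouth", "n_no_mouth")
MEMBRANE_CATEGORIES <- c("intact", "partial", "absent")

# ---- symbol normalization -------------------------------------------------

#' Normalize gene/protein symbols for cross-list comparison
#'
#' Upper-cases, strips surrounding whitespace, and removes trailing *Xenopus
#' laevis* homeolog suffixes (`.L`/`.S`, repeated if stacked) so that frog
#' chemical-screen targets and human gene symbols can be intersected. An
#' optional synonym table is applied before suffix stripping. The function is
#' idempotent: `normalize_symbol(normalize_symbol(x))` equals
#' `normalize_symbol(x)` (synonyms are looked up once).
#'
#' @param x Character vector of raw symbols. Must be non-empty strings.
#' @param synonyms Optional synonym table: either a named character vector
#'   (`names` = raw spelling, values = replacement) or a data frame whose
#'   first two columns are raw spelling and replacement. Keys are matched
#'   case-insensitively after whitespace stripping.
#' @return Character vector of normalized symbols, same length as `x`.
#' @examples
#' normalize_symbol(c("jak2", " JAK2 ", "jak2.L"))
#' @export
normalize_symbol <- function(x, synonyms = NULL) {
  if (length(x) == 0L) return(character(0))
  x <- as.character(x)
  key <- toupper(trimws(x))
  bad <- is.na(key) | !nzchar(key)
  if (any(bad)) {
    stop(sprintf("symbols must be non-empty: %d empty or missing value(s)",
                 sum(bad)), call. = FALSE)
  }
  if (!is.null(synonyms)) {
    syn <- as_synonym_lookup(synonyms)
    hit <- match(key, names(syn))
    key[!is.na(hit)] <- unname(syn[hit[!is.na(hit)]])
    key <- toupper(trimws(key))
  }
  # strip trailing homeolog suffixes and re-trim until stable, so the
  # function is idempotent even for inputs like "X .L .S"
  out <- key
  repeat {
    nxt <- trimws(sub("(\\.(L|S))+$", "", out))
    if (identical(nxt, out)) break
    out <- nxt
  }
  bad <- !nzchar(out)
  if (any(bad)) {
    stop(sprintf("symbol(s) reduce to the empty string after normalization: %s",
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

as_synonym_lookup <- function(synonyms) {
  if (is.data.frame(synonyms)) {
    if (ncol(synonyms) < 2L) {
      stop("synonym table needs at least two columns (raw, replacement)",
           call. = FALSE)
    }
    syn <- stats::setNames(as.character(synonyms[[2L]]),
                           as.character(synonyms[[1L]]))
  } else if (is.character(synonyms) && !is.null(names(synonyms))) {
    syn <- synonyms
  } else {
    stop("synonyms must be a named character vector or a two-column data frame",
         call. = FALSE)
  }
  names(syn) <- toupper(trimws(names(syn)))
  syn
}

# ---- low-level parsing helpers --------------------------------------------

read_tsv_strict <- function(path, required, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s table '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Strict boolean parsing: exactly {1/0, true/false, yes/no, y/n},
# case-insensitive. Anything else is an error, never a silent NA.
parse_flag <- function(x, column, what) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes", "y")] <- TRUE
  out[v %in% c("0", "false", "no", "n")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' has unrecognized boolean value '%s' at row %d",
                 what, column, x[bad[1L]], bad[1L]), call. = FALSE)
  }
  out
}

parse_count <- function(x, column, what, min = 0) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v %% 1 != 0 | v < min)
  if (length(bad)) {
    stop(sprintf("%s: column '%s' has unparseable or negative count at row(s) %s",
                 what, column, paste(head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  as.integer(v)
}

parse_coord <- function(x, column, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v %% 1 != 0)
  if (length(bad)) {
    stop(sprintf("%s: column '%s' has unparseable coordinate at row(s) %s",
                 what, column, paste(head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  v
}

# ---- coordinate dialects --------------------------------------------------

#' Convert interval coordinates between dialects
#'
#' The canonical internal convention is 0-based half-open (`bed0half`).
#' DECIPHER-style extracts are 1-based inclusive and converted on read; BED
#' inputs pass through. Conversion is a bijection: converting to canonical
#' and back reproduces the original integers.
#'
#' @param start,end Numeric vectors of interval coordinates.
#' @param from,to Dialect names, one of `"bed0half"` or
#'   `"one_based_inclusive"`.
#' @return A list with numeric components `start` and `end`.
#' @export
convert_coordinates <- function(start, end,
                                from = c("bed0half", "one_based_inclusive"),
                                to = c("bed0half", "one_based_inclusive")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == "one_based_inclusive") start <- start - 1L
  if (to == "one_based_inclusive") start <- start + 1L
  list(start = start, end = end)
}

check_intervals <- function(start, end, what) {
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval (end <= start, or negative start, after conversion to 0-based half-open) at row(s) %s",
                 what, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(NULL)
}

coord_header_comment <- "# coordinates: 0-based half-open (bed0half)"

write_tsv_commented <- function(df, path, comments) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(comments, con)
  close(con)
  on.exit(NULL)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

# ---- screen table ---------------------------------------------------------

new_screen_table <- function(df, chemicals) {
  out <- tibble::as_tibble(df)
  attr(out, "chemicals") <- chemicals
  class(out) <- c("screen_table", class(out))
  out
}

#' Chemicals screened in a screen table
#'
#' @param screen A `screen_table` as returned by [read_screen_table()].
#' @return Character vector of chemical identifiers, including any chemical
#'   that was read with zero embryo rows.
#' @export
screen_chemicals <- function(screen) {
  attr(screen, "chemicals") %||% unique(screen$chemical_id)
}

#' Read a chemical-screen phenotype table
#'
#' Two dialects are supported. `embryo_long` has one row per embryo with
#' columns `chemical_id`, `stomodeum_present`, `mouth_open`, `cleft_like`,
#' `no_mouth` (strict booleans) plus optional `embryo` (integer id within the
#' well) and `concentration` (micromolar, metadata only). `well_counts` has
#' one row per chemical with integer columns `n_persistent_bpm`,
#' `n_open_mouth`, `n_cleft_mouth`, `n_no_mouth`; it is expanded to the long
#' per-embryo form on read.
#'
#' Score consistency is enforced: `no_mouth` excludes both `stomodeum_present`
#' and `mouth_open`, and `cleft_like` (a cleft-like appearance of the open
#' mouth) requires `mouth_open`.
#'
#' @param path Path to a tab-separated file with a header; lines starting
#'   with `#` are comments.
#' @param dialect `"embryo_long"` (default) or `"well_counts"`.
#' @return A `screen_table`: a tibble with one row per embryo and columns
#'   `chemical_id`, `embryo`, the four phenotype booleans, and
#'   `concentration`; the full chemical roster (including chemicals with zero
#'   embryos in the `well_counts` dialect) is kept in the `chemicals`
#'   attribute (see [screen_chemicals()]).
#' @export
read_screen_table <- function(path, dialect = c("embryo_long", "well_counts")) {
  dialect <- match.arg(dialect)
  what <- "screen"
  if (dialect == "embryo_long") {
    df <- read_tsv_strict(path, c("chemical_id", PHENO_COLS), what)
    for (col in PHENO_COLS) df[[col]] <- parse_flag(df[[col]], col, what)
    if ("embryo" %in% names(df)) {
      df$embryo <- parse_count(df$embryo, "embryo", what, min = 1)
      key <- paste(df$chemical_id, df$embryo, sep = "\r")
      dup <- unique(df$chemical_id[duplicated(key)])
      if (length(dup)) {
        stop(sprintf("screen: duplicate (chemical_id, embryo) rows for: %s",
                     paste(dup, collapse = ", ")), call. = FALSE)
      }
    } else {
      df$embryo <- stats::ave(seq_len(nrow(df)), df$chemical_id,
                              FUN = seq_along)
    }
    df$concentration <- if ("concentration" %in% names(df)) {
      suppressWarnings(as.numeric(df$concentration))
    } else NA_real_
    chemicals <- unique(df$chemical_id)
  } else {
    df0 <- read_tsv_strict(path, c("chemical_id", WELL_COUNT_COLS), what)
    dup <- unique(df0$chemical_id[duplicated(df0$chemical_id)])
    if (length(dup)) {
      stop(sprintf("screen: duplicate chemical_id: %s",
                   paste(dup, collapse = ", ")), call. = FALSE)
    }
    for (col in WELL_COUNT_COLS) df0[[col]] <- parse_count(df0[[col]], col, what)
    conc <- if ("concentration" %in% names(df0)) {
      suppressWarnings(as.numeric(df0$concentration))
    } else rep(NA_real_, nrow(df0))
    cls_levels <- c("persistent_bpm", "open_mouth", "cleft_mouth", "no_mouth")
    n_per <- rowSums(as.matrix(df0[WELL_COUNT_COLS]))
    cls <- unlist(lapply(seq_len(nrow(df0)), function(i) {
      rep(cls_levels, times = as.integer(df0[i, WELL_COUNT_COLS]))
    }))
    df <- tibble::tibble(
      chemical_id = rep(df0$chemical_id, times = n_per),
      embryo = unlist(lapply(n_per, seq_len), use.names = FALSE) %||% integer(0)
    )
    sc <- phenotype_class_scores(cls)
    df <- cbind(df, sc)
    df$concentration <- rep(conc, times = n_per)
    chemicals <- df0$chemical_id
  }
  bad <- df$no_mouth & (df$stomodeum_present | df$mouth_open)
  if (any(bad)) {
    stop(sprintf("screen: no_mouth conflicts with stomodeum_present/mouth_open at row(s) %s",
                 paste(head(which(bad), 5L), collapse = ", ")), call. = FALSE)
  }
  bad <- df$cleft_like & !df$mouth_open
  if (any(bad)) {
    stop(sprintf("screen: cleft_like requires mouth_open at row(s) %s",
                 paste(head(which(bad), 5L), collapse = ", ")), call. = FALSE)
  }
  new_screen_table(df[c("chemical_id", "embryo", PHENO_COLS, "concentration")],
                   chemicals)
}

# Map a phenotype class label to the four recorded booleans.
phenotype_class_scores <- function(cls) {
  tibble::tibble(
    stomodeum_present = cls %in% c("persistent_bpm", "open_mouth", "cleft_mouth"),
    mouth_open = cls %in% c("open_mouth", "cleft_mouth"),
    cleft_like = cls == "cleft_mouth",
    no_mouth = cls == "no_mouth"
  )
}

#' Write a chemical-screen table in the canonical per-embryo dialect
#'
#' @param screen A `screen_table`.
#' @param path Output path (tab-separated, `embryo_long` dialect, booleans
#'   written as 1/0).
#' @return The path, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  df <- tibble::as_tibble(screen)[c("chemical_id", "embryo", PHENO_COLS,
                                    "concentration")]
  for (col in PHENO_COLS) df[[col]] <- as.integer(df[[col]])
  write_tsv_commented(df, path, "# screen table: one row per embryo (dialect embryo_long)")
}

# ---- chemical-target map --------------------------------------------------

#' Read a chemical-to-target mapping table
#'
#' A frozen stand-in for compound-activity database lookups: tab-separated
#' with columns `chemical_id` and `target_symbol`. Target symbols are
#' normalized (see [normalize_symbol()]) and duplicate pairs are collapsed;
#' a chemical absent from the map simply has no known targets.
#'
#' @param path Path to the TSV file.
#' @param synonyms Optional synonym table passed to [normalize_symbol()].
#' @return A `target_map` tibble with columns `chemical_id`,
#'   `target_symbol`, unique after normalization.
#' @export
read_target_map <- function(path, synonyms = NULL) {
  df <- read_tsv_strict(path, c("chemical_id", "target_symbol"), "target map")
  target_map(df$chemical_id, df$target_symbol, synonyms = synonyms)
}

#' Construct a chemical-to-target map from vectors
#'
#' @param chemical_id,target_symbol Parallel character vectors of pairs.
#' @param synonyms Optional synonym table passed to [normalize_symbol()].
#' @param provenance Free-text source tag stored as an attribute.
#' @return A `target_map` tibble of unique normalized pairs.
#' @export
target_map <- function(chemical_id, target_symbol, synonyms = NULL,
                       provenance = "unspecified") {
  stopifnot(length(chemical_id) == length(target_symbol))
  out <- tibble::tibble(
    chemical_id = as.character(chemical_id),
    target_symbol = normalize_symbol(target_symbol, synonyms)
  )
  out <- out[!duplicated(out), ]
  attr(out, "provenance") <- provenance
  class(out) <- c("target_map", class(out))
  out
}

#' Write a chemical-to-target map
#'
#' @param map A `target_map`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_target_map <- function(map, path) {
  write_tsv_commented(tibble::as_tibble(map)[c("chemical_id", "target_symbol")],
                      path, "# chemical-target map: unique normalized pairs")
}

# ---- patient CNV cohort ---------------------------------------------------

#' Construct a patient CNV cohort
#'
#' @param deletions A data frame with columns `patient_id`, `chrom`, `start`,
#'   `end`; coordinates must already be canonical (0-based half-open).
#' @param patients Character vector of all ascertained patient ids (the
#'   cohort roster; the denominator of recurrence fractions). Defaults to the
#'   distinct patient ids in `deletions`. Patients with no deletions are
#'   legal and contribute no genes while still counting in the cohort size.
#' @param phenotype_tag Free-text clinical phenotype label.
#' @return A `cnv_cohort` object: list with elements `deletions` (tibble),
#'   `patients` (character) and `phenotype_tag`.
#' @export
cnv_cohort <- function(deletions, patients = NULL,
                       phenotype_tag = "unspecified") {
  deletions <- tibble::as_tibble(deletions)[, c("patient_id", "chrom",
                                                "start", "end")]
  deletions$patient_id <- as.character(deletions$patient_id)
  deletions$chrom <- as.character(deletions$chrom)
  if (nrow(deletions)) {
    if (any(!nzchar(deletions$chrom))) {
      stop("CNV: empty chromosome name", call. = FALSE)
    }
    check_intervals(deletions$start, deletions$end, "CNV")
  }
  patients <- as.character(patients %||% unique(deletions$patient_id))
  if (anyDuplicated(patients)) {
    stop("CNV: duplicated patient ids in cohort roster", call. = FALSE)
  }
  extra <- setdiff(deletions$patient_id, patients)
  if (length(extra)) {
    stop(sprintf("CNV: deletions reference patient(s) not in roster: %s",
                 paste(head(extra, 5L), collapse = ", ")), call. = FALSE)
  }
  structure(list(deletions = deletions, patients = patients,
                 phenotype_tag = phenotype_tag),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf("<cnv_cohort> %d patients (%s), %d deletion intervals\n",
              length(x$patients), x$phenotype_tag, nrow(x$deletions)))
  invisible(x)
}

#' Cohort size of a patient CNV set
#'
#' @param cohort A `cnv_cohort`.
#' @return Integer number of ascertained patients (including patients with
#'   zero deletions).
#' @export
cohort_size <- function(cohort) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  length(cohort$patients)
}

#' Read a patient copy-number-deletion table
#'
#' Tab-separated with columns `patient_id`, `chrom`, `start`, `end` (one row
#' per deletion interval). DECIPHER-style extracts use 1-based inclusive
#' coordinates and are converted to the canonical 0-based half-open
#' convention on read; BED-style input passes through unchanged. Rows whose
#' interval is empty or inverted after conversion are rejected with their row
#' number.
#'
#' @param path Path to the TSV file.
#' @param coordinate_dialect `"bed0half"` (default) or
#'   `"one_based_inclusive"`.
#' @param patients Optional full cohort roster (see [cnv_cohort()]).
#' @param phenotype_tag Clinical phenotype label for the cohort.
#' @return A `cnv_cohort`.
#' @export
read_cnv_table <- function(path,
                           coordinate_dialect = c("bed0half", "one_based_inclusive"),
                           patients = NULL, phenotype_tag = "unspecified") {
  coordinate_dialect <- match.arg(coordinate_dialect)
  df <- read_tsv_strict(path, c("patient_id", "chrom", "start", "end"), "CNV")
  start <- parse_coord(df$start, "start", "CNV")
  end <- parse_coord(df$end, "end", "CNV")
  cc <- convert_coordinates(start, end, from = coordinate_dialect,
                            to = "bed0half")
  check_intervals(cc$start, cc$end, "CNV")
  cnv_cohort(tibble::tibble(patient_id = df$patient_id, chrom = df$chrom,
                            start = cc$start, end = cc$end),
             patients = patients, phenotype_tag = phenotype_tag)
}

#' Write a patient CNV table in the canonical coordinate convention
#'
#' @param cohort A `cnv_cohort`.
#' @param path Output TSV path. A header comment records the coordinate
#'   convention.
#' @return The path, invisibly.
#' @export
write_cnv_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  write_tsv_commented(cohort$deletions, path, coord_header_comment)
}

# ---- gene annotation ------------------------------------------------------

#' Construct a gene annotation
#'
#' @param symbol,chrom,start,end Parallel vectors of gene loci; coordinates
#'   canonical 0-based half-open. A symbol may map to multiple loci
#'   (multi-locus genes); all loci are indexed and a deletion overlapping any
#'   of them counts the gene.
#' @param strand Optional strand (`+`, `-`, `*`); defaults to `*`.
#' @param synonyms Optional synonym table passed to [normalize_symbol()].
#' @return A `gene_annotation` tibble with columns `symbol`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
gene_annotation <- function(symbol, chrom, start, end, strand = NULL,
                            synonyms = NULL) {
  n <- length(symbol)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n)
  strand <- as.character(strand %||% rep("*", n))
  strand[!strand %in% c("+", "-")] <- "*"
  check_intervals(start, end, "annotation")
  out <- tibble::tibble(
    symbol = normalize_symbol(symbol, synonyms),
    chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end), strand = strand
  )
  if (any(!nzchar(out$chrom))) {
    stop("annotation: empty chromosome name", call. = FALSE)
  }
  class(out) <- c("gene_annotation", class(out))
  out
}

#' Read a gene annotation table
#'
#' Either a headered TSV with columns `symbol`, `chrom`, `start`, `end`
#' (optional `strand`) in a declared coordinate dialect, or a headerless
#' BED file (`chrom`, `start`, `end`, `name`, `score`, `strand`; BED is
#' 0-based half-open by definition).
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @param coordinate_dialect Coordinate dialect of a TSV input;
#'   ignored for BED.
#' @param synonyms Optional synonym table passed to [normalize_symbol()].
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed"),
                                 coordinate_dialect = c("bed0half", "one_based_inclusive"),
                                 synonyms = NULL) {
  format <- match.arg(format)
  coordinate_dialect <- match.arg(coordinate_dialect)
  if (format == "tsv") {
    df <- read_tsv_strict(path, c("symbol", "chrom", "start", "end"),
                          "annotation")
    start <- parse_coord(df$start, "start", "annotation")
    end <- parse_coord(df$end, "end", "annotation")
    cc <- convert_coordinates(start, end, from = coordinate_dialect,
                              to = "bed0half")
    gene_annotation(df$symbol, df$chrom, cc$start, cc$end,
                    strand = if ("strand" %in% names(df)) df$strand else NULL,
                    synonyms = synonyms)
  } else {
    if (!file.exists(path)) stop("annotation file not found: ", path,
                                 call. = FALSE)
    df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                          show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    if (ncol(df) < 4L) {
      stop("annotation: BED input needs at least 4 columns (chrom, start, end, name)",
           call. = FALSE)
    }
    start <- parse_coord(df[[2L]], "start", "annotation")
    end <- parse_coord(df[[3L]], "end", "annotation")
    gene_annotation(df[[4L]], df[[1L]], start, end,
                    strand = if (ncol(df) >= 6L) df[[6L]] else NULL,
                    synonyms = synonyms)
  }
}

#' Write a gene annotation in the canonical dialect
#'
#' @param annotation A `gene_annotation`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  write_tsv_commented(tibble::as_tibble(annotation), path,
                      coord_header_comment)
}

# ---- functional category map ----------------------------------------------

#' Construct a gene-to-functional-category map
#'
#' A frozen stand-in for a functional-classification resource: assignments
#' of genes to named categories. `(gene, category)` pairs must be unique; a
#' gene may belong to many categories.
#'
#' @param gene_symbol,category_id,category_name Parallel vectors of
#'   assignments.
#' @param synonyms Optional synonym table passed to [normalize_symbol()].
#' @return A `category_map` tibble with columns `gene_symbol`,
#'   `category_id`, `category_name`.
#' @export
category_map <- function(gene_symbol, category_id, category_name,
                         synonyms = NULL) {
  n <- length(gene_symbol)
  stopifnot(length(category_id) == n, length(category_name) == n)
  out <- tibble::tibble(
    gene_symbol = normalize_symbol(gene_symbol, synonyms),
    category_id = as.character(category_id),
    category_name = as.character(category_name)
  )
  if (any(!nzchar(out$category_id))) {
    stop("category map: empty category_id", call. = FALSE)
  }
  out <- out[!duplicated(out), ]
  key <- paste(out$gene_symbol, out$category_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- out$category_id[duplicated(key)]
    stop(sprintf("category map: conflicting names for (gene, category) pair(s) in category %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  class(out) <- c("category_map", class(out))
  out
}

#' Read a gene-to-functional-category map
#'
#' Tab-separated with columns `gene_symbol`, `category_id`,
#' `category_name`.
#'
#' @inheritParams read_target_map
#' @return A `category_map`.
#' @export
read_category_map <- function(path, synonyms = NULL) {
  df <- read_tsv_strict(path, c("gene_symbol", "category_id", "category_name"),
                        "category map")
  category_map(df$gene_symbol, df$category_id, df$category_name,
               synonyms = synonyms)
}

#' Write a gene-to-functional-category map
#'
#' @param map A `category_map`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_category_map <- function(map, path) {
  write_tsv_commented(tibble::as_tibble(map), path,
                      "# functional category map: (gene, category) assignments")
}
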