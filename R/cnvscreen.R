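# Arm 2: map patient deletion intervals to overlapped genes, count distinct
# patients per gene, and apply the patient-fraction recurrence filter.
# Interval lookup is backed by IRanges; an exhaustive pairwise scan serves
# as the independent oracle in the test suite.

strip_chr_prefix <- function(x) sub("^chr", "", x, ignore.case = TRUE)

# Interval-to-gene overlap pairs across chromosomes. `intervals` and
# `annotation` carry canonical 0-based half-open coordinates; returns row
# indices into both tables.
overlap_pairs <- function(intervals, annotation,
                          overlap_rule = c("any_overlap", "full_containment"),
                          harmonize_chrom = TRUE) {
  overlap_rule <- match.arg(overlap_rule)
  empty <- data.frame(interval = integer(0), gene = integer(0))
  if (nrow(intervals) == 0L || nrow(annotation) == 0L) return(empty)
  ic <- intervals$chrom
  ac <- annotation$chrom
  # A naming-convention mismatch ("chr1" vs "1") must never degrade into a
  # silent zero-overlap result: either harmonize or raise. Genuinely
  # disjoint chromosome sets in the same convention are a legal empty
  # result, not an error.
  ic2 <- strip_chr_prefix(ic)
  ac2 <- strip_chr_prefix(ac)
  naming_mismatch <- !any(ic %in% ac) && any(ic2 %in% ac2)
  if (harmonize_chrom) {
    if (naming_mismatch) {
      message("chromosome names harmonized across inputs ('chr' prefix stripped for matching)")
    }
    ic <- ic2
    ac <- ac2
  } else if (naming_mismatch) {
    stop(paste0("no chromosome names in common between deletions and the gene ",
                "annotation (e.g. '", intervals$chrom[1L], "' vs '",
                annotation$chrom[1L], "'); the naming conventions differ ",
                "('chr1' vs '1') - rename one input or enable harmonize_chrom"),
         call. = FALSE)
  }
  if (!any(ic %in% ac)) return(empty)
  shared <- intersect(unique(ic), unique(ac))
  res <- lapply(shared, function(ch) {
    qi <- which(ic == ch)
    si <- which(ac == ch)
    q <- IRanges::IRanges(start = intervals$start[qi] + 1, end = intervals$end[qi])
    s <- IRanges::IRanges(start = annotation$start[si] + 1, end = annotation$end[si])
    ov <- as.data.frame(IRanges::findOverlaps(q, s))
    data.frame(interval = qi[ov$queryHits], gene = si[ov$subjectHits])
  })
  out <- do.call(rbind, c(list(empty), res))
  if (overlap_rule == "full_containment" && nrow(out)) {
    keep <- intervals$start[out$interval] <= annotation$start[out$gene] &
      intervals$end[out$interval] >= annotation$end[out$gene]
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Genes deleted in a patient (or a set of deletion intervals)
#'
#' A gene is included iff some deletion interval overlaps some locus of the
#' gene under the chosen rule. Under `any_overlap` (default) a single shared
#' base pair suffices — a deletion removing part of a gene still disrupts
#' it; `full_containment` requires the deletion to span the whole locus.
#'
#' @param deletions A `cnv_cohort`, or a data frame with columns `chrom`,
#'   `start`, `end` in canonical 0-based half-open coordinates.
#' @param annotation A `gene_annotation`.
#' @param overlap_rule `"any_overlap"` (default) or `"full_containment"`.
#' @param harmonize_chrom Reconcile `"chr1"`-style and `"1"`-style
#'   chromosome names before matching (default `TRUE`). If, after optional
#'   harmonization, the deletions and the annotation share no chromosome
#'   names at all, a validation error is raised rather than silently
#'   reporting zero overlaps.
#' @return Sorted character vector of deleted gene symbols (a set;
#'   duplicates impossible).
#' @export
map_cnv_to_genes <- function(deletions, annotation,
                             overlap_rule = c("any_overlap", "full_containment"),
                             harmonize_chrom = TRUE) {
  if (inherits(deletions, "cnv_cohort")) deletions <- deletions$deletions
  ov <- overlap_pairs(deletions, annotation, overlap_rule, harmonize_chrom)
  sort(unique(annotation$symbol[ov$gene]))
}

#' Count, per gene, the distinct patients whose deletions hit it
#'
#' Each patient is counted at most once per gene no matter how many of their
#' deletion intervals overlap it ("duplicates removed"). Patients with no
#' deletions (or none overlapping any gene) contribute nothing but remain in
#' the cohort size — the denominator of the recurrence fraction is
#' ascertained patients.
#'
#' @param cohort A `cnv_cohort`.
#' @param annotation A `gene_annotation`.
#' @inheritParams map_cnv_to_genes
#' @return A tibble with columns `gene_symbol`, `n_patients`, `patient_ids`
#'   (list column of sorted patient ids), sorted by `n_patients` descending
#'   with alphabetical tie-break. The cohort size is stored in the
#'   `cohort_size` attribute.
#' @export
gene_patient_frequency <- function(cohort, annotation,
                                   overlap_rule = c("any_overlap", "full_containment"),
                                   harmonize_chrom = TRUE) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  empty <- tibble::tibble(gene_symbol = character(0), n_patients = integer(0),
                          patient_ids = list())
  if (nrow(cohort$deletions) == 0L || nrow(annotation) == 0L) {
    attr(empty, "cohort_size") <- cohort_size(cohort)
    return(empty)
  }
  ov <- overlap_pairs(cohort$deletions, annotation, overlap_rule,
                      harmonize_chrom)
  pairs <- unique(data.frame(
    patient_id = cohort$deletions$patient_id[ov$interval],
    gene_symbol = annotation$symbol[ov$gene],
    stringsAsFactors = FALSE
  ))
  if (nrow(pairs) == 0L) {
    attr(empty, "cohort_size") <- cohort_size(cohort)
    return(empty)
  }
  sp <- split(pairs$patient_id, pairs$gene_symbol)
  out <- tibble::tibble(
    gene_symbol = names(sp),
    n_patients = unname(lengths(sp)),
    patient_ids = unname(lapply(sp, sort))
  )
  out <- out[order(-out$n_patients, out$gene_symbol), ]
  attr(out, "cohort_size") <- cohort_size(cohort)
  out
}

#' Focus a gene frequency table on recurrently deleted genes
#'
#' Keeps genes deleted in at least a fraction of the cohort. Because the
#' source analysis states the cutoff only as "approximately 10% of the
#' patients", the integer threshold derivation is explicit and configurable
#' rather than hidden.
#'
#' @param table A gene frequency table from [gene_patient_frequency()]
#'   (carrying a `cohort_size` attribute), or any tibble with
#'   `gene_symbol`/`n_patients` plus a `cohort_size` argument.
#' @param fraction Recurrence fraction in (0, 1]; default 0.10.
#' @param threshold_mode How the integer patient threshold `t` is resolved
#'   from `fraction * cohort_size`: `"ceil"` (default), `"floor"` (never
#'   below 1), or `"at_least"` (compare `n_patients >= fraction *
#'   cohort_size` on the real line; for integer counts this coincides with
#'   `"ceil"`).
#' @param cohort_size Override for the cohort size; defaults to the table's
#'   attribute.
#' @return Character vector of gene symbols passing the filter, in the
#'   frequency table's order, with the resolved integer threshold in the
#'   `threshold` attribute. Antitone in `fraction`.
#' @export
filter_genes_by_patient_fraction <- function(table, fraction = 0.10,
                                             threshold_mode = c("ceil", "floor", "at_least"),
                                             cohort_size = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  }
  n <- cohort_size %||% attr(table, "cohort_size")
  if (is.null(n) || is.na(n) || n <= 0) {
    stop("cohort_size must be a positive integer (missing from the table?)",
         call. = FALSE)
  }
  t_real <- fraction * n
  t_int <- switch(threshold_mode,
    ceil = as.integer(ceiling(t_real)),
    floor = max(1L, as.integer(floor(t_real))),
    at_least = as.integer(ceiling(t_real))
  )
  keep <- if (threshold_mode == "at_least") {
    table$n_patients >= t_real
  } else {
    table$n_patients >= t_int
  }
  out <- table$gene_symbol[keep]
  attr(out, "threshold") <- t_int
  out
}
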