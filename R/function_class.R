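# Functional-category profiling of a gene list against a frozen
# gene-to-category map, and cross-arm shared categories. Counting only: the
# source analysis reports raw category sizes, not enrichment statistics.

#' Profile a gene list by functional category
#'
#' Counts, per category, how many of the input genes are assigned to it and
#' keeps categories reaching a minimum size (default five or more genes).
#' Genes absent from the map are never silently dropped: they are reported
#' in a message and stored in the `unclassified` attribute.
#'
#' @param genes Character vector of gene symbols (normalized with
#'   [normalize_symbol()] internally; duplicates collapse).
#' @param map A `category_map` (see [read_category_map()]).
#' @param min_genes Minimum category size retained (default 5).
#' @return A tibble with columns `category_id`, `category_name`, `n_genes`,
#'   `genes` (list column of sorted member symbols), sorted by `n_genes`
#'   descending with alphabetical tie-break on `category_id`. Attributes:
#'   `unclassified` (symbols absent from the map), `n_input` (distinct input
#'   genes), `min_genes`.
#' @export
classify_functional <- function(genes, map, min_genes = 5L) {
  if (!is.numeric(min_genes) || length(min_genes) != 1L || is.na(min_genes) ||
      min_genes < 1) {
    stop("min_genes must be a single integer >= 1", call. = FALSE)
  }
  g <- unique(normalize_symbol(genes))
  asn <- map[map$gene_symbol %in% g, , drop = FALSE]
  unclassified <- setdiff(g, map$gene_symbol)
  if (length(g)) {
    message(sprintf("functional classification: %d of %d gene(s) not in the category map",
                    length(unclassified), length(g)))
  }
  if (nrow(asn) == 0L) {
    out <- tibble::tibble(category_id = character(0),
                          category_name = character(0),
                          n_genes = integer(0), genes = list())
  } else {
    sp <- split(asn$gene_symbol, asn$category_id)
    nm <- asn$category_name[match(names(sp), asn$category_id)]
    out <- tibble::tibble(
      category_id = names(sp),
      category_name = nm,
      n_genes = unname(lengths(sp)),
      genes = unname(lapply(sp, sort))
    )
    out <- out[out$n_genes >= min_genes, , drop = FALSE]
    out <- out[order(-out$n_genes, out$category_id), ]
  }
  attr(out, "unclassified") <- sort(unclassified)
  attr(out, "n_input") <- length(g)
  attr(out, "min_genes") <- as.integer(min_genes)
  out
}

#' Categories shared between two arms' classification tables
#'
#' Matches on `category_id` (display names drift between releases of
#' classification resources); both tables are expected to be already
#' size-filtered by [classify_functional()]. Symmetric: swapping the
#' arguments permutes the count columns but yields the same category set.
#'
#' @param tableA,tableB Category count tables from [classify_functional()].
#' @return A tibble with columns `category_id`, `category_name`,
#'   `n_genes_a`, `n_genes_b`, ordered by combined count descending with
#'   alphabetical tie-break.
#' @export
shared_categories <- function(tableA, tableB) {
  shared <- intersect(tableA$category_id, tableB$category_id)
  ia <- match(shared, tableA$category_id)
  ib <- match(shared, tableB$category_id)
  out <- tibble::tibble(
    category_id = shared,
    category_name = tableA$category_name[ia],
    n_genes_a = tableA$n_genes[ia],
    n_genes_b = tableB$n_genes[ib]
  )
  out[order(-(out$n_genes_a + out$n_genes_b), out$category_id), ]
}
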