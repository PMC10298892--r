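# Arm 1: call persistent-buccopharyngeal-membrane hits from per-embryo
# phenotype scores, deconvolute hit chemicals to protein targets, rank
# targets by distinct-hit-chemical frequency, and apply the
# minimum-chemicals filter.

#' Define a hit-calling rule
#'
#' A chemical is a hit when enough of its scored embryos show the phenotype
#' of interest: a stomodeum present with the mouth not open (a persistent
#' buccopharyngeal membrane). Embryos scored `no_mouth` are never evidence
#' for a hit; by default they are also removed from the denominator, so a
#' well with one unscoreable embryo can still be called.
#'
#' Modes:
#' * `"majority"` (default): a strict majority of scoreable embryos shows
#'   the phenotype.
#' * `"all"`: every embryo in the well (including `no_mouth` embryos, which
#'   by definition cannot show the phenotype) shows it.
#' * `"fraction"`: at least `fraction` of scoreable embryos shows it.
#'
#' @param mode One of `"majority"`, `"all"`, `"fraction"`.
#' @param fraction Required for `mode = "fraction"`; a value in (0, 1].
#' @param exclude_no_mouth Drop `no_mouth` embryos from the denominator
#'   (default `TRUE`; ignored by `mode = "all"`, which counts all embryos).
#' @return A `hit_rule` object.
#' @export
hit_rule <- function(mode = c("majority", "all", "fraction"), fraction = NULL,
                     exclude_no_mouth = TRUE) {
  mode <- match.arg(mode)
  if (mode == "fraction") {
    if (is.null(fraction) || !is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1) {
      stop("hit_rule: 'fraction' must be a single value in (0, 1]",
           call. = FALSE)
    }
  } else {
    fraction <- NULL
  }
  structure(list(mode = mode, fraction = fraction,
                 exclude_no_mouth = isTRUE(exclude_no_mouth)),
            class = "hit_rule")
}

#' Classify each embryo's recorded phenotype
#'
#' @param screen A `screen_table`.
#' @return Character vector (one element per row of `screen`) with values
#'   `"persistent_bpm"` (stomodeum present, mouth not open), `"open_mouth"`,
#'   `"cleft_mouth"` (cleft-like appearance of the open mouth),
#'   `"no_mouth"`, or `"no_stomodeum"`.
#' @export
classify_embryos <- function(screen) {
  ifelse(screen$no_mouth, "no_mouth",
    ifelse(screen$mouth_open,
      ifelse(screen$cleft_like, "cleft_mouth", "open_mouth"),
      ifelse(screen$stomodeum_present, "persistent_bpm", "no_stomodeum")))
}

#' Call persistent-membrane hits for every chemical in a screen
#'
#' @param screen A `screen_table` (see [read_screen_table()]).
#' @param rule A [hit_rule()].
#' @return A tibble with one row per chemical: `chemical_id`, `n_embryos`,
#'   `n_scoreable`, `n_persistent`, `hit`. Row order follows the screen's
#'   chemical roster; hit calling is deterministic and invariant under
#'   permutation of embryo rows.
#' @export
call_hits <- function(screen, rule = hit_rule()) {
  stopifnot(inherits(rule, "hit_rule"))
  roster <- screen_chemicals(screen)
  if (length(roster) == 0L) {
    return(tibble::tibble(chemical_id = character(0), n_embryos = integer(0),
                          n_scoreable = integer(0), n_persistent = integer(0),
                          hit = logical(0)))
  }
  empty <- setdiff(roster, unique(screen$chemical_id))
  if (length(empty)) {
    stop(sprintf("hit calling requires at least one embryo score; none for: %s",
                 paste(head(empty, 5L), collapse = ", ")), call. = FALSE)
  }
  key <- factor(screen$chemical_id, levels = roster)
  cls <- classify_embryos(screen)
  n_total <- as.integer(table(key))
  n_no_mouth <- as.integer(table(key[cls == "no_mouth"]))
  n_persistent <- as.integer(table(key[cls == "persistent_bpm"]))
  n_scoreable <- if (rule$exclude_no_mouth) n_total - n_no_mouth else n_total
  hit <- switch(rule$mode,
    majority = n_scoreable > 0L & n_persistent > n_scoreable / 2,
    all = n_persistent == n_total,
    fraction = n_scoreable > 0L & n_persistent >= rule$fraction * n_scoreable
  )
  tibble::tibble(chemical_id = roster, n_embryos = n_total,
                 n_scoreable = n_scoreable, n_persistent = n_persistent,
                 hit = hit)
}

#' Hit chemicals of a screen
#'
#' @param calls Output of [call_hits()].
#' @return Sorted character vector of hit chemical ids.
#' @export
hit_chemicals <- function(calls) sort(calls$chemical_id[calls$hit])

#' Tabulate membrane phenotype proportions per group
#'
#' Summarizes scored membrane categories (`intact`, `partial`, `absent`)
#' as counts and percentages per group, matching the reporting convention
#' of phenotype proportion panels (percentages to one decimal, summing to
#' 100 within rounding).
#'
#' @param category Character vector of per-embryo membrane categories; each
#'   value must be one of `intact`, `partial`, `absent`.
#' @param group Optional grouping labels (same length as `category`);
#'   defaults to a single group `"all"`.
#' @return A tibble with columns `group`, `category`, `n`, `percent`; every
#'   group carries all three categories (zero counts included) in the fixed
#'   order intact, partial, absent.
#' @export
tabulate_phenotypes <- function(category, group = NULL) {
  category <- as.character(category)
  bad <- setdiff(unique(category), MEMBRANE_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown membrane category label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(MEMBRANE_CATEGORIES, collapse = ", ")), call. = FALSE)
  }
  group <- as.character(group %||% rep("all", length(category)))
  stopifnot(length(group) == length(category))
  gl <- unique(group)
  cf <- factor(category, levels = MEMBRANE_CATEGORIES)
  gf <- factor(group, levels = gl)
  counts <- table(gf, cf)
  totals <- rowSums(counts)
  out <- tibble::tibble(
    group = rep(gl, each = length(MEMBRANE_CATEGORIES)),
    category = rep(MEMBRANE_CATEGORIES, times = length(gl)),
    n = as.integer(t(counts))
  )
  out$percent <- round(100 * out$n / rep(unname(totals), each = length(MEMBRANE_CATEGORIES)), 1)
  out
}

#' Map hit chemicals to their known protein targets
#'
#' @param hits Character vector of hit chemical ids.
#' @param map A `target_map` (see [read_target_map()]).
#' @return A list with components `per_chemical` (named list of target
#'   symbol vectors, one entry per hit chemical), `targets` (sorted unique
#'   union of targets over all hits), and `unmapped` (hit chemicals with no
#'   known targets; these are reported with a message, never dropped
#'   silently).
#' @export
map_hits_to_targets <- function(hits, map) {
  hits <- unique(as.character(hits))
  per <- lapply(stats::setNames(hits, hits), function(ch) {
    sort(unique(map$target_symbol[map$chemical_id == ch]))
  })
  unmapped <- hits[lengths(per) == 0L]
  if (length(unmapped)) {
    message(sprintf("%d hit chemical(s) have no known targets: %s",
                    length(unmapped), paste(unmapped, collapse = ", ")))
  }
  list(per_chemical = per,
       targets = sort(unique(unlist(per, use.names = FALSE))) %||% character(0),
       unmapped = unmapped)
}

#' Rank targets by number of distinct hit chemicals
#'
#' For every protein target touched by at least one hit chemical, counts the
#' number of *distinct* hit chemicals known to act on it (duplicate map
#' pairs never double-count).
#'
#' @param hits Character vector of hit chemical ids.
#' @param map A `target_map`.
#' @return A tibble with columns `target_symbol`, `n_hit_chemicals`,
#'   `chemical_ids` (list column of sorted chemical ids), sorted by
#'   `n_hit_chemicals` descending with alphabetical tie-break.
#' @export
target_frequency <- function(hits, map) {
  hits <- unique(as.character(hits))
  pairs <- map[map$chemical_id %in% hits, c("chemical_id", "target_symbol")]
  pairs <- pairs[!duplicated(pairs), ]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(target_symbol = character(0),
                          n_hit_chemicals = integer(0),
                          chemical_ids = list()))
  }
  sp <- split(pairs$chemical_id, pairs$target_symbol)
  out <- tibble::tibble(
    target_symbol = names(sp),
    n_hit_chemicals = unname(lengths(sp)),
    chemical_ids = unname(lapply(sp, sort))
  )
  out[order(-out$n_hit_chemicals, out$target_symbol), ]
}

#' Focus a target frequency table on recurrently hit targets
#'
#' @param table A target frequency table from [target_frequency()].
#' @param k Minimum number of distinct hit chemicals (default 3). The
#'   filter is antitone in `k`: the focused list for `k + 1` is a subset of
#'   the list for `k`.
#' @return Character vector of target symbols with
#'   `n_hit_chemicals >= k`, in the frequency table's order.
#' @export
filter_targets_min_chemicals <- function(table, k = 3L) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  table$target_symbol[table$n_hit_chemicals >= k]
}
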