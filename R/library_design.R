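#' Guide filter rule set
#'
#' Bundles the sequence-level and count-level rules used to build
#' screen-ready sgRNA libraries: GC content bounds (strict: exactly 20% or
#' 80% passes), a forbidden 3' suffix (a G run that interferes with guide
#' expression/PCR), forbidden substrings (the poly-T Pol III terminator),
#' restriction-enzyme recognition patterns checked on both strands,
#' per-mismatch-class off-target count maxima, and the specificity score
#' cutoff separating confounded (score <= cutoff) from retained guides.
#'
#' @param gc_min,gc_max GC fraction bounds (fail iff gc < gc_min or
#'   gc > gc_max). Defaults 0.20 / 0.80.
#' @param forbidden_suffix Spacer 3' suffix that fails, default `"GGGGG"`.
#' @param forbidden_substrings Substrings that fail anywhere in the spacer,
#'   default `"TTTT"`.
#' @param restriction_patterns IUPAC recognition patterns, default the
#'   cloning-relevant set CTGCAG, GAAGAC, GTCTTC, CCANNNNNNTGG, GCTNAGC.
#' @param count_thresholds Per-class off-target count maxima, see
#'   [legacy_count_filter()].
#' @param exclusion_max_mm Mismatch budget for the exclusion-region overlap
#'   rule, default 1 (exact and 1-mismatch sites).
#' @param specificity_cutoff Score cutoff, default 0.2.
#' @return A list of class `filter_rules`.
#' @export
filter_rules <- function(gc_min = 0.20, gc_max = 0.80,
                         forbidden_suffix = "GGGGG",
                         forbidden_substrings = "TTTT",
                         restriction_patterns = c("CTGCAG", "GAAGAC",
                                                  "GTCTTC", "CCANNNNNNTGG",
                                                  "GCTNAGC"),
                         count_thresholds = c("0" = 2, "1" = 10,
                                              "2" = 50, "3" = 200),
                         exclusion_max_mm = 1L,
                         specificity_cutoff = 0.2) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1,
            specificity_cutoff >= 0, specificity_cutoff <= 1)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 forbidden_suffix = forbidden_suffix,
                 forbidden_substrings = forbidden_substrings,
                 restriction_patterns = restriction_patterns,
                 count_thresholds = count_thresholds,
                 exclusion_max_mm = exclusion_max_mm,
                 specificity_cutoff = specificity_cutoff),
            class = "filter_rules")
}

#' Sequence-level guide filters
#'
#' Evaluates the independent sequence predicates on one spacer: GC bounds,
#' forbidden suffix, forbidden substrings, and restriction patterns
#' (matched against the spacer and its reverse complement, since
#' restriction recognition is double-stranded).
#'
#' @param spacer 20-nt spacer (A/C/G/T).
#' @param rules A [filter_rules] object.
#' @return Named logical vector, `TRUE` = pass. Names: `gc`, `suffix`,
#'   `poly_t` (one per forbidden substring, named after it for others),
#'   and `restriction_<pattern>`.
#' @export
sequence_filters <- function(spacer, rules = filter_rules()) {
  spacer <- toupper(spacer)
  gc <- gc_fraction(spacer)
  flags <- c(gc = gc >= rules$gc_min && gc <= rules$gc_max)
  flags["suffix"] <- !endsWith(spacer, rules$forbidden_suffix)
  for (sub in rules$forbidden_substrings) {
    nm <- if (sub == "TTTT") "poly_t" else paste0("substring_", sub)
    flags[nm] <- !grepl(sub, spacer, fixed = TRUE)
  }
  rc <- revcomp(spacer)
  for (pat in rules$restriction_patterns) {
    rx <- iupac_to_regex(pat)
    flags[paste0("restriction_", pat)] <-
      !(grepl(rx, spacer) || grepl(rx, rc))
  }
  flags
}

#' Exclusion-region overlap filter
#'
#' Fails a guide iff any of its exact or low-mismatch genomic sites (within
#' `max_mm` mismatches, including the on-target) overlaps an exclusion
#' region by at least one base. Used to keep guides out of exons,
#' DNase-hypersensitive sites, or other annotated regions where exact or
#' near-exact cutting would confound the screen.
#'
#' @param spacer 20-nt spacer.
#' @param genome A [genome] object.
#' @param exclusion_regions Data frame of intervals (`chrom`, `start`,
#'   `end`; 0-based half-open), e.g. from [read_bed()].
#' @param max_mm Mismatch budget for the rule, default 1.
#' @param pam_set PAM patterns for the site search.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
exclusion_overlap_filter <- function(spacer, genome, exclusion_regions,
                                     max_mm = 1L,
                                     pam_set = c("NGG", "NAG")) {
  if (is.null(exclusion_regions) || nrow(exclusion_regions) == 0L) {
    return(TRUE)
  }
  sites <- find_offtarget_sites(spacer, genome, max_mismatches = max_mm,
                                pam_set = pam_set)
  if (nrow(sites) == 0L) return(TRUE)
  !any(intervals_overlap(sites, exclusion_regions))
}

# for each row of a: does it share >= 1 base with any row of b?
# both 0-based half-open
intervals_overlap <- function(a, b) {
  ga <- intervals_to_granges(a)
  gb <- intervals_to_granges(b)
  IRanges::overlapsAny(ga, gb, ignore.strand = TRUE)
}

#' Select guides for a motif-level target site
#'
#' Keeps eligible candidate guides whose expected cleavage site falls
#' inside the motif interval. If more than `max_per_site` qualify, keeps
#' the top `max_per_site` by specificity score (descending), breaking ties
#' by distance of the cut from the motif center (ascending), then by guide
#' id. Motifs with fewer than `min_per_site` surviving guides are flagged
#' as under-covered (the design requires at least two guides per site).
#'
#' @param motif One-row data frame (or list) with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param candidates Data frame of eligible guides with `guide_id`,
#'   `chrom`, `cut_pos` and `specificity` columns.
#' @param max_per_site Maximum guides kept per motif, default 5.
#' @param min_per_site Minimum required for full coverage, default 2.
#' @return List with `guides` (selected rows, in selection order) and
#'   `under_covered` (`TRUE` if fewer than `min_per_site` survived).
#' @export
select_motif_guides <- function(motif, candidates, max_per_site = 5L,
                                min_per_site = 2L) {
  inm <- candidates$chrom == motif$chrom[[1]] &
         candidates$cut_pos >= motif$start[[1]] &
         candidates$cut_pos < motif$end[[1]]
  keep <- candidates[inm, , drop = FALSE]
  if (nrow(keep)) {
    center <- (motif$start[[1]] + motif$end[[1]]) / 2
    ord <- order(-keep$specificity, abs(keep$cut_pos + 0.5 - center),
                 keep$guide_id)
    keep <- keep[ord, , drop = FALSE]
    if (nrow(keep) > max_per_site) {
      keep <- keep[seq_len(max_per_site), , drop = FALSE]
    }
    rownames(keep) <- NULL
  }
  list(guides = keep, under_covered = nrow(keep) < min_per_site)
}

#' Element targetability summary
#'
#' For each element, counts eligible guides with specificity score strictly
#' above `score_cutoff` that hit the element: in `cas9` mode the guide's
#' expected cut site must lie inside the element interval (nuclease screens
#' must disrupt the narrow element directly); in `crispri`/`crispra` mode
#' the protospacer must lie within the element window (interval extended by
#' `window` bp on each side), since epigenome editors act over a broader
#' region. An element is targetable iff it has at least `min_guides` such
#' guides.
#'
#' @param elements Data frame with `element_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `window` (bp, default taken from
#'   the `window` argument).
#' @param guides Data frame with `chrom`, `start`, `end`, `cut_pos`,
#'   `specificity`.
#' @param score_cutoff Specificity cutoff (exclusive: scores > cutoff are
#'   kept), default 0.2.
#' @param min_guides Guides required per element, default 5.
#' @param mode `"cas9"`, `"crispri"` or `"crispra"`.
#' @param window Flank added to each element in CRISPRi/a mode when the
#'   element has no `window` column, default 100 bp.
#' @return List with `elements` (input plus `n_guides`, `targetable`) and
#'   `fraction_targetable`.
#' @export
targetability_summary <- function(elements, guides, score_cutoff = 0.2,
                                  min_guides = 5L,
                                  mode = c("cas9", "crispri", "crispra"),
                                  window = 100L) {
  mode <- match.arg(mode)
  ok <- !is.na(guides$specificity) & guides$specificity > score_cutoff
  g <- guides[ok, , drop = FALSE]
  n <- integer(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    if (mode == "cas9") {
      hit <- g$chrom == el$chrom & g$cut_pos >= el$start & g$cut_pos < el$end
    } else {
      w <- if (!is.null(el$window)) el$window else window
      hit <- g$chrom == el$chrom & g$start >= el$start - w &
             g$end <= el$end + w
    }
    n[i] <- sum(hit)
  }
  elements$n_guides <- n
  elements$targetable <- n >= min_guides
  list(elements = elements,
       fraction_targetable = if (nrow(elements)) mean(elements$targetable)
                             else NA_real_)
}

#' Design a motif-targeting guide library
#'
#' End-to-end pipeline: enumerate NGG spacers over the motif intervals
#' (plus `flank` bp so guides cutting at motif edges are found), score each
#' candidate, apply the sequence, count-threshold, searchability,
#' exclusion-overlap and specificity filters, and select up to
#' `max_per_site` guides per motif. Output is deterministic for a given
#' genome and annotation.
#'
#' @param genome A [genome] object.
#' @param motifs Data frame with `element_id`, `chrom`, `start`, `end`.
#' @param weights A [cfd_weights] object.
#' @param rules A [filter_rules] object.
#' @param exclusion_regions Optional exclusion interval data frame.
#' @param max_per_site,min_per_site Per-motif selection bounds.
#' @param pam_set PAM patterns for off-target searches.
#' @param flank bp of context enumerated around each motif, default 25.
#' @return Data frame (one row per selected guide) with columns `guide_id`,
#'   `element_id`, `chrom`, `start`, `end`, `strand`, `spacer`, `pam`,
#'   `cut_pos`, `n2`, `n3`, `specificity`, `under_covered`.
#' @export
design_library <- function(genome, motifs, weights, rules = filter_rules(),
                           exclusion_regions = NULL, max_per_site = 5L,
                           min_per_site = 2L, pam_set = c("NGG", "NAG"),
                           flank = 25L) {
  all_sp <- enumerate_spacers(genome)
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    el <- motifs[i, ]
    cand <- all_sp[all_sp$chrom == el$chrom &
                   all_sp$cut_pos >= el$start - flank &
                   all_sp$cut_pos < el$end + flank, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # cheap sequence filters first, expensive search-backed filters after
    seq_ok <- vapply(cand$spacer,
                     function(sp) all(sequence_filters(sp, rules)),
                     logical(1))
    cand <- cand[seq_ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    cand <- score_guides(cand, genome, weights, pam_set = pam_set)
    tallies_ok <- vapply(seq_len(nrow(cand)), function(j) {
      legacy_count_filter(
        c("0" = cand$n0[j], "1" = cand$n1[j], "2" = cand$n2[j],
          "3" = cand$n3[j]),
        thresholds = rules$count_thresholds)
    }, logical(1))
    cand <- cand[tallies_ok & cand$searchable &
                 !is.na(cand$specificity) &
                 cand$specificity > rules$specificity_cutoff, , drop = FALSE]
    if (!is.null(exclusion_regions) && nrow(cand)) {
      excl_ok <- vapply(cand$spacer, function(sp) {
        exclusion_overlap_filter(sp, genome, exclusion_regions,
                                 max_mm = rules$exclusion_max_mm,
                                 pam_set = pam_set)
      }, logical(1))
      cand <- cand[excl_ok, , drop = FALSE]
    }
    sel <- select_motif_guides(el, cand, max_per_site = max_per_site,
                               min_per_site = min_per_site)
    if (nrow(sel$guides)) {
      g <- sel$guides
      g$element_id <- el$element_id
      g$under_covered <- sel$under_covered
      rows[[length(rows) + 1L]] <- g
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(guide_id = character(), element_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      spacer = character(), pam = character(),
                      cut_pos = integer(), n2 = integer(), n3 = integer(),
                      specificity = numeric(), under_covered = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  cols <- c("guide_id", "element_id", "chrom", "start", "end", "strand",
            "spacer", "pam", "cut_pos", "n2", "n3", "specificity",
            "under_covered")
  out <- out[, cols]
  rownames(out) <- NULL
  out
}

#' Write a guide library to TSV
#'
#' @param library Data frame from [design_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
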