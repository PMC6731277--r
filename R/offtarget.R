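#' Find all genomic off-target sites of a spacer
#'
#' Returns every window on either strand of the genome whose 20-nt
#' protospacer is within `max_mismatches` Hamming distance of `spacer` and
#' whose adjacent 3-nt PAM matches any pattern in `pam_set` (IUPAC).
#' Windows or PAMs containing N never match. The on-target perfect match,
#' if present in the genome, is included (as a 0-mismatch site); callers
#' scoring off-target activity should drop it (see
#' [aggregate_specificity()]).
#'
#' Candidate windows are generated with `Biostrings::matchPattern()` and
#' then annotated with full mismatch descriptors. Mismatch positions are
#' counted 1..20 from the spacer 5' end, so position 20 is PAM-proximal.
#'
#' @param spacer 20-nt spacer (A/C/G/T only), 5'->3'.
#' @param genome A [genome] object.
#' @param max_mismatches Maximum Hamming distance, 0..4. Default 3.
#' @param pam_set Character vector of IUPAC PAM patterns a site may carry.
#'   Default `c("NGG", "NAG")`, the canonical SpCas9 PAM plus its tolerated
#'   alternate.
#' @return Data frame sorted by (chrom, start, strand) with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `site_seq` (protospacer
#'   5'->3' on the site strand), `pam`, `n_mismatch` and `mismatches`
#'   (encoded as `"pos:guide>target"` joined by `";"`, `""` for a perfect
#'   match; see [parse_mismatches()]).
#' @export
find_offtarget_sites <- function(spacer, genome, max_mismatches = 3L,
                                 pam_set = c("NGG", "NAG")) {
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stop("spacer must be exactly 20 nt")
  if (grepl("[^ACGT]", spacer)) stop("spacer must contain only A, C, G, T")
  if (max_mismatches < 0L || max_mismatches > 4L) {
    stop("max_mismatches must be in 0..4")
  }
  stopifnot(inherits(genome, "genome"))
  slen <- 20L
  pam_len <- 3L
  rc_spacer <- revcomp(spacer)

  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < slen + pam_len) next
    subj <- Biostrings::DNAString(s)

    # plus strand: protospacer at [h1, h1+19] 1-based, PAM 3' at [h1+20, ..]
    h1 <- Biostrings::start(Biostrings::matchPattern(
      spacer, subj, max.mismatch = max_mismatches, with.indels = FALSE))
    h1 <- h1[h1 + slen + pam_len - 1L <= L]
    if (length(h1)) {
      site <- substring(s, h1, h1 + slen - 1L)
      pam <- substring(s, h1 + slen, h1 + slen + pam_len - 1L)
      out[[length(out) + 1L]] <- .offtarget_rows(
        chrom, h1 - 1L, "+", site, pam, spacer, max_mismatches, pam_set)
    }

    # minus strand: match reverse-complemented spacer on the plus sequence;
    # the site's PAM sits immediately 5' of the match in plus coordinates
    h1 <- Biostrings::start(Biostrings::matchPattern(
      rc_spacer, subj, max.mismatch = max_mismatches, with.indels = FALSE))
    h1 <- h1[h1 >= pam_len + 1L]
    if (length(h1)) {
      site <- revcomp(substring(s, h1, h1 + slen - 1L))
      pam <- revcomp(substring(s, h1 - pam_len, h1 - 1L))
      out[[length(out) + 1L]] <- .offtarget_rows(
        chrom, h1 - 1L, "-", site, pam, spacer, max_mismatches, pam_set)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(.empty_sites())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), site_seq = character(), pam = character(),
             n_mismatch = integer(), mismatches = character(),
             stringsAsFactors = FALSE)
}

# filter candidate windows by N content / PAM set and attach descriptors
.offtarget_rows <- function(chrom, start0, strand, site, pam, spacer,
                            max_mm, pam_set) {
  keep <- !grepl("N", site, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
  if (!any(keep)) return(NULL)
  pam_ok <- Reduce(`|`, lapply(pam_set, function(p) matches_iupac(pam, p)))
  keep <- keep & pam_ok
  if (!any(keep)) return(NULL)
  start0 <- start0[keep]; site <- site[keep]; pam <- pam[keep]

  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  desc <- character(length(site))
  nmm <- integer(length(site))
  for (i in seq_along(site)) {
    tg <- strsplit(site[i], "", fixed = TRUE)[[1]]
    pos <- which(tg != sp)
    nmm[i] <- length(pos)
    desc[i] <- paste(sprintf("%d:%s>%s", pos, sp[pos], tg[pos]),
                     collapse = ";")
  }
  keep2 <- nmm <= max_mm
  if (!any(keep2)) return(NULL)
  data.frame(chrom = chrom, start = start0[keep2],
             end = start0[keep2] + 20L, strand = strand,
             site_seq = site[keep2], pam = pam[keep2],
             n_mismatch = nmm[keep2], mismatches = desc[keep2],
             stringsAsFactors = FALSE)
}

#' Parse encoded mismatch descriptors
#'
#' @param x A single `mismatches` string as produced by
#'   [find_offtarget_sites()] (`"pos:guide>target"` joined by `";"`).
#' @return Data frame with columns `position` (1..20, 5'->3'),
#'   `guide_base`, `target_base`; zero rows for a perfect match.
#' @export
parse_mismatches <- function(x) {
  if (is.na(x) || x == "") {
    return(data.frame(position = integer(), guide_base = character(),
                      target_base = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "[:>]")
  data.frame(
    position = as.integer(vapply(parts, `[`, character(1), 1L)),
    guide_base = vapply(parts, `[`, character(1), 2L),
    target_base = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Tally off-target sites by mismatch class
#'
#' @param sites Data frame of sites from [find_offtarget_sites()].
#' @return Named integer vector with entries `"0"`, `"1"`, `"2"`, `"3"`;
#'   classes with no sites are 0.
#' @export
tally_offtargets <- function(sites) {
  counts <- stats::setNames(integer(4), as.character(0:3))
  if (nrow(sites)) {
    tab <- table(factor(sites$n_mismatch, levels = 0:3))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Is a guide searchable (scoreable) under the trie-style eligibility rule?
#'
#' A guide is searchable iff it has exactly one perfect genomic match (its
#' on-target site) and no 1-mismatch off-target sites. Guides with more than
#' one perfect match or any 1-mismatch site are excluded from specificity
#' scoring and analysis.
#'
#' @param tally Named count vector from [tally_offtargets()]; class 0 must
#'   include the on-target perfect match.
#' @return `TRUE`/`FALSE`.
#' @export
is_searchable <- function(tally) {
  tally <- .check_tally(tally)
  if (tally[["0"]] == 0L) {
    stop("tally has no perfect match: the guide has no genomic home")
  }
  tally[["0"]] == 1L && tally[["1"]] == 0L
}

#' Count-threshold guide filter
#'
#' Passes a guide iff its off-target tally does not exceed any per-class
#' maximum. Thresholds are worded as strict "greater than fails": boundary
#' values pass. Defaults follow the alignment-based library design rule
#' (at most 2 perfect matches, 10 one-mismatch, 50 two-mismatch and 200
#' three-mismatch genome-wide sites).
#'
#' @param tally Named count vector from [tally_offtargets()].
#' @param thresholds Named maxima for classes `"0"`..`"3"`.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
legacy_count_filter <- function(tally,
                                thresholds = c("0" = 2, "1" = 10,
                                               "2" = 50, "3" = 200)) {
  tally <- .check_tally(tally)
  all(tally[names(thresholds)] <= thresholds)
}

.check_tally <- function(tally) {
  cls <- as.character(0:3)
  if (!all(cls %in% names(tally))) {
    stop("tally must have counts for mismatch classes 0..3")
  }
  if (any(tally[cls] < 0)) stop("negative tally count")
  tally[cls]
}
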