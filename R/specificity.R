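#' Construct a CFD weight table
#'
#' A Cutting Frequency Determination (CFD) weight table assigns each
#' (position, guide base, target base) mismatch a relative cleavage weight
#' in \[0, 1\], and each PAM (keyed by its 2-nt suffix, since SpCas9 PAM
#' recognition is position 2-3) a weight in \[0, 1\]. Matched base pairs
#' contribute no factor (weight 1 implicitly) and the canonical NGG PAM has
#' weight 1.
#'
#' Positions are counted 1..20 from the spacer 5' end (position 20
#' PAM-proximal); keys are guide (RNA, written as DNA) base versus target
#' DNA base read on the protospacer strand. Tables in other conventions
#' must be normalised to this one when loaded.
#'
#' @param mismatch Data frame with columns `position` (1..20), `guide_base`,
#'   `target_base` (A/C/G/T, unequal), `weight` in \[0,1\].
#' @param pam Data frame with columns `pam_suffix` (2-nt) and `weight` in
#'   \[0,1\]; must assign weight 1 to `"GG"`.
#' @param source Free-text label describing where the weights came from.
#' @return An object of class `cfd_weights`.
#' @export
cfd_weights <- function(mismatch, pam, source = "unspecified") {
  req <- c("position", "guide_base", "target_base", "weight")
  if (!all(req %in% names(mismatch))) {
    stop("mismatch table needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(c("pam_suffix", "weight") %in% names(pam))) {
    stop("pam table needs columns pam_suffix, weight")
  }
  with(mismatch, {
    if (any(position < 1 | position > 20)) stop("position out of 1..20")
    if (any(guide_base == target_base)) {
      stop("mismatch table lists a matched base pair")
    }
    if (any(weight < 0 | weight > 1)) stop("mismatch weight out of [0,1]")
  })
  if (any(pam$weight < 0 | pam$weight > 1)) stop("PAM weight out of [0,1]")
  gg <- pam$weight[pam$pam_suffix == "GG"]
  if (length(gg) != 1L || gg != 1) {
    stop("PAM table must assign weight 1 to the canonical GG suffix")
  }
  mm_key <- sprintf("%d:%s>%s", mismatch$position, mismatch$guide_base,
                    mismatch$target_base)
  if (anyDuplicated(mm_key)) stop("duplicate mismatch weight keys")
  structure(
    list(mismatch = stats::setNames(mismatch$weight, mm_key),
         pam = stats::setNames(pam$weight, toupper(pam$pam_suffix)),
         source = source),
    class = "cfd_weights")
}

#' @export
print.cfd_weights <- function(x, ...) {
  cat(sprintf("CFD weight table (%s): %d mismatch entries, %d PAM entries\n",
              x$source, length(x$mismatch), length(x$pam)))
  invisible(x)
}

#' Read a CFD weight table from TSV
#'
#' Expects a mismatch table (columns `position`, `guide_base`,
#' `target_base`, `weight`) and a PAM table (columns `pam_suffix`,
#' `weight`), both tab-separated with headers.
#'
#' @param mismatch_path,pam_path File paths.
#' @param source Label; defaults to the mismatch file name.
#' @return A [cfd_weights] object.
#' @export
read_cfd_weights <- function(mismatch_path, pam_path,
                             source = basename(mismatch_path)) {
  mm <- utils::read.table(mismatch_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  pam <- utils::read.table(pam_path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric"),
                           stringsAsFactors = FALSE)
  cfd_weights(mm, pam, source = source)
}

#' Write a CFD weight table to TSV
#'
#' @param weights A [cfd_weights] object.
#' @param mismatch_path,pam_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cfd_weights <- function(weights, mismatch_path, pam_path) {
  stopifnot(inherits(weights, "cfd_weights"))
  keys <- strsplit(names(weights$mismatch), "[:>]")
  mm <- data.frame(
    position = as.integer(vapply(keys, `[`, character(1), 1L)),
    guide_base = vapply(keys, `[`, character(1), 2L),
    target_base = vapply(keys, `[`, character(1), 3L),
    weight = unname(weights$mismatch),
    stringsAsFactors = FALSE
  )
  pam <- data.frame(pam_suffix = names(weights$pam),
                    weight = unname(weights$pam),
                    stringsAsFactors = FALSE)
  utils::write.table(mm, mismatch_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(pam, pam_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mismatch_path, pam_path))
}

#' Synthetic CFD weight table
#'
#' A deterministic, clearly synthetic stand-in with the same structure as
#' published CFD tables: tolerance of a mismatch decays towards the
#' PAM-proximal end, and depends on the identity of the guide/target pair.
#' It is intended for testing and simulation; for scoring real designs load
#' the published empirical table with [read_cfd_weights()].
#'
#' The weight for a mismatch at position `p` with guide base g and target
#' base t is `round(f(p) * id(g,t), 4)` with positional factor
#' `f(p) = 1 - 0.045 * p` and identity factor 0.9 for purine/pyrimidine
#' transitions, 0.55 for transversions that conserve a purine on the guide,
#' and 0.35 for the remaining transversions. PAM suffix weights are GG = 1,
#' AG = 0.26, GA = 0.07, all others 0.
#'
#' @return A [cfd_weights] object with `source = "synthetic"`.
#' @export
synthetic_cfd_weights <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(position = 1:20, guide_base = bases,
                      target_base = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$guide_base != grid$target_base, ]
  transition <- function(g, t) {
    (g %in% c("A", "G") & t %in% c("A", "G")) |
    (g %in% c("C", "T") & t %in% c("C", "T"))
  }
  idf <- ifelse(transition(grid$guide_base, grid$target_base), 0.9,
                ifelse(grid$guide_base %in% c("A", "G"), 0.55, 0.35))
  grid$weight <- round((1 - 0.045 * grid$position) * idf, 4)
  pam <- data.frame(
    pam_suffix = c("GG", "AG", "GA", "AA", "AC", "AT", "CA", "CC", "CG",
                   "CT", "GC", "GT", "TA", "TC", "TG", "TT"),
    weight = c(1, 0.26, 0.07, rep(0, 13)),
    stringsAsFactors = FALSE
  )
  cfd_weights(grid[order(grid$position, grid$guide_base, grid$target_base), ],
              pam, source = "synthetic")
}

#' Per-site CFD score
#'
#' The CFD score of one off-target site is the product, over its mismatch
#' descriptors, of the (position, guide base, target base) weights, times
#' the PAM weight. A perfect match with an NGG PAM scores 1.
#'
#' @param site One-row data frame (or list) with `mismatches` (encoded
#'   descriptor string, see [parse_mismatches()]) and `pam` fields.
#' @param weights A [cfd_weights] object.
#' @return Numeric score in \[0, 1\].
#' @export
cfd_site_score <- function(site, weights) {
  stopifnot(inherits(weights, "cfd_weights"))
  mm <- parse_mismatches(site$mismatches[[1]])
  if (nrow(mm) > 4L) stop("site has more than 4 mismatches")
  w <- 1
  if (nrow(mm)) {
    keys <- sprintf("%d:%s>%s", mm$position, mm$guide_base, mm$target_base)
    vals <- weights$mismatch[keys]
    if (anyNA(vals)) {
      stop("no CFD weight for mismatch key(s): ",
           paste(keys[is.na(vals)], collapse = ", "))
    }
    w <- prod(vals)
  }
  pam_suffix <- toupper(substring(site$pam[[1]], 2L, 3L))
  pw <- weights$pam[pam_suffix]
  if (is.na(pw)) stop("no PAM weight for suffix: ", pam_suffix)
  unname(w * pw)
}

#' Aggregate specificity score of a guide
#'
#' Sums per-site CFD scores over the off-target sites in the included
#' mismatch classes (2- and 3-mismatch sites by default) and returns the
#' aggregate specificity score `1 / (1 + sum)`. A perfectly specific guide
#' (no qualifying off-targets) scores 1; promiscuous guides approach 0.
#'
#' The site list must exclude the on-target perfect match, and the guide
#' must be searchable (exactly one perfect match, no 1-mismatch sites):
#' passing any 0- or 1-mismatch site is an error, mirroring the convention
#' that unsearchable guides receive no score at all.
#'
#' @param sites Data frame of off-target sites (on-target excluded).
#' @param weights A [cfd_weights] object.
#' @param include_classes Mismatch classes entering the sum. Default
#'   `c(2, 3)`.
#' @return List with `cfd_sum` and `score` (`score = 1/(1 + cfd_sum)`,
#'   always in (0, 1\]).
#' @export
aggregate_specificity <- function(sites, weights, include_classes = c(2, 3)) {
  stopifnot(inherits(weights, "cfd_weights"))
  if (nrow(sites) && any(sites$n_mismatch %in% c(0L, 1L))) {
    stop("site list contains 0- or 1-mismatch sites: the guide is ",
         "unsearchable (or the on-target was not excluded); ",
         "unsearchable guides are not scored")
  }
  use <- which(sites$n_mismatch %in% include_classes)
  cfd_sum <- 0
  for (i in use) {
    cfd_sum <- cfd_sum + cfd_site_score(sites[i, ], weights)
  }
  list(cfd_sum = cfd_sum, score = 1 / (1 + cfd_sum))
}

#' Score a set of guides against a genome
#'
#' For each spacer: finds all sites within 3 mismatches, tallies them,
#' determines searchability, and — for searchable guides — drops the single
#' on-target perfect match and aggregates the CFD scores of the remaining
#' 2-3-mismatch sites into the specificity score. Unsearchable guides get
#' `NA` for `cfd_sum` and `specificity` (they are excluded from analysis,
#' not scored 0).
#'
#' @param spacers Data frame with `guide_id` and `spacer` columns (extra
#'   columns are preserved).
#' @param genome A [genome] object.
#' @param weights A [cfd_weights] object.
#' @param pam_set PAM patterns for the off-target search.
#' @param include_classes Mismatch classes entering the CFD sum.
#' @return `spacers` with added columns `n0`, `n1`, `n2`, `n3`,
#'   `searchable`, `cfd_sum`, `specificity`.
#' @export
score_guides <- function(spacers, genome, weights,
                         pam_set = c("NGG", "NAG"),
                         include_classes = c(2, 3)) {
  stopifnot(is.data.frame(spacers), all(c("guide_id", "spacer") %in%
                                        names(spacers)))
  n <- nrow(spacers)
  res <- data.frame(n0 = integer(n), n1 = integer(n), n2 = integer(n),
                    n3 = integer(n), searchable = logical(n),
                    cfd_sum = rep(NA_real_, n),
                    specificity = rep(NA_real_, n))
  for (i in seq_len(n)) {
    sites <- find_offtarget_sites(spacers$spacer[i], genome,
                                  max_mismatches = 3L, pam_set = pam_set)
    tally <- tally_offtargets(sites)
    res[i, c("n0", "n1", "n2", "n3")] <- as.list(unname(tally))
    searchable <- tally[["0"]] >= 1L && tally[["0"]] == 1L &&
                  tally[["1"]] == 0L
    res$searchable[i] <- searchable
    if (searchable) {
      agg <- aggregate_specificity(sites[sites$n_mismatch > 1L, , drop = FALSE],
                                   weights, include_classes = include_classes)
      res$cfd_sum[i] <- agg$cfd_sum
      res$specificity[i] <- agg$score
    }
  }
  cbind(spacers, res)
}

#' Write per-guide specificity scores to TSV
#'
#' Columns: guide_id, n0..n3, searchable, cfd_sum, specificity.
#'
#' @param scored Data frame from [score_guides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_scores <- function(scored, path) {
  cols <- c("guide_id", "n0", "n1", "n2", "n3", "searchable", "cfd_sum",
            "specificity")
  utils::write.table(scored[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
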