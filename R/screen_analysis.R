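#' Construct a screen count matrix
#'
#' Guide-by-sample matrix of non-negative integer read counts with a role
#' for every sample: `"plasmid"` for the original library pool and
#' `"endpoint"` for end-of-screen replicates. At least one sample of each
#' role is required and guide ids must be unique.
#'
#' @param counts Integer matrix, guides in rows (rownames = guide ids),
#'   samples in columns (colnames = sample labels).
#' @param roles Character vector (`"plasmid"`/`"endpoint"`), one per
#'   column.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, roles) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop("counts must have unique guide-id rownames")
  }
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  if (length(roles) != ncol(counts)) {
    stop("one role per sample column required")
  }
  if (!all(roles %in% c("plasmid", "endpoint"))) {
    stop("roles must be 'plasmid' or 'endpoint'")
  }
  if (!any(roles == "plasmid") || !any(roles == "endpoint")) {
    stop("need at least one plasmid and one endpoint sample")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(list(counts = counts, roles = roles), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d guides x %d samples (%d plasmid, %d endpoint)\n",
              nrow(x$counts), ncol(x$counts), sum(x$roles == "plasmid"),
              sum(x$roles == "endpoint")))
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' First column is the guide id; remaining columns are per-sample integer
#' counts. Sample roles are supplied as a named vector (or all-endpoint
#' except a column named in `plasmid`).
#'
#' @param path TSV path.
#' @param roles Named character vector mapping sample label to role, or
#'   `NULL` with `plasmid` giving the plasmid column name(s).
#' @param plasmid Column name(s) of plasmid samples when `roles` is NULL.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path, roles = NULL, plasmid = "plasmid") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(roles)) {
    roles <- ifelse(colnames(m) %in% plasmid, "plasmid", "endpoint")
  } else {
    roles <- roles[colnames(m)]
  }
  count_matrix(m, unname(roles))
}

#' Guide-level enrichment (log2 fold-change versus plasmid)
#'
#' Counts are first normalised to counts-per-million within each sample;
#' a pseudocount is then added to the CPM values. For each endpoint
#' replicate r the guide enrichment is
#' `log2((cpm_r + pseudocount) / (cpm_plasmid + pseudocount))`, where
#' `cpm_plasmid` is the mean plasmid CPM when several plasmid samples are
#' present. The per-guide summary is the arithmetic mean across endpoint
#' replicates with standard error `sd / sqrt(k)`.
#'
#' @param cm A [count_matrix].
#' @param pseudocount Added to CPM values, default 1.
#' @return Data frame with `guide_id`, one `log2fc.<sample>` column per
#'   endpoint replicate, `mean_log2fc` and `se` (`NA` for a single
#'   replicate).
#' @export
guide_enrichment <- function(cm, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(cm$counts)[totals == 0], collapse = ", "))
  }
  cpm <- sweep(cm$counts, 2, totals, "/") * 1e6
  plasmid <- rowMeans(cpm[, cm$roles == "plasmid", drop = FALSE])
  ep <- cpm[, cm$roles == "endpoint", drop = FALSE]
  lfc <- log2(sweep(ep + pseudocount, 1, plasmid + pseudocount, "/"))
  k <- ncol(lfc)
  out <- data.frame(guide_id = rownames(cm$counts),
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0("log2fc.", colnames(lfc)[j])]] <- lfc[, j]
  out$mean_log2fc <- rowMeans(lfc)
  out$se <- if (k > 1) apply(lfc, 1, stats::sd) / sqrt(k) else NA_real_
  rownames(out) <- NULL
  out
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Computes the two-sided p-value by the minimum-likelihood rule: the sum
#' of hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table
#' (within relative tolerance 1e-12 for ties). One-sided variants sum the
#' corresponding tail. A table with any zero margin carries no information;
#' by convention it returns p = 1 with a warning.
#'
#' @param cells 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @param sidedness `"two.sided"` (default), `"less"` or `"greater"` (tail
#'   of the \[1,1\] cell).
#' @return p-value in (0, 1\].
#' @export
fisher_exact_2x2 <- function(cells, sidedness = c("two.sided", "less",
                                                  "greater")) {
  sidedness <- match.arg(sidedness)
  if (!is.matrix(cells)) cells <- matrix(cells, 2, 2, byrow = TRUE)
  stopifnot(all(dim(cells) == 2), all(cells >= 0),
            all(cells == round(cells)))
  a <- cells[1, 1]
  r1 <- sum(cells[1, ]); r2 <- sum(cells[2, ])
  c1 <- sum(cells[, 1]); c2 <- sum(cells[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  p <- switch(sidedness,
    two.sided = sum(probs[probs <= pobs * (1 + 1e-12)]),
    less = sum(probs[support <= a]),
    greater = sum(probs[support >= a]))
  min(p, 1)
}

#' Quadrant association between fitness effect and specificity
#'
#' Cross-tabulates searchable, scored guides by depletion
#' (`mean_log2fc <= fc_threshold`) and low specificity
#' (`score <= score_threshold`), and tests independence with the exact
#' Fisher test. The odds ratio is `(a*d)/(b*c)` for cells a = depleted &
#' low-specificity, b = depleted & high-specificity, c = not-depleted &
#' low, d = not-depleted & high; `Inf` is reported when b*c = 0 (and `NaN`
#' if both products are 0). With `haldane = TRUE` a 0.5 continuity
#' correction is added to every cell for a finite odds ratio.
#'
#' @param enrich Data frame from [guide_enrichment()].
#' @param scores Data frame with `guide_id`, `searchable`, `specificity`
#'   (e.g. from [score_guides()]), or just `guide_id` + `specificity`.
#' @param fc_threshold Depletion threshold on mean log2FC, default -2.
#' @param score_threshold Low-specificity threshold, default 0.2.
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the odds
#'   ratio (not the test), default FALSE.
#' @return List of class `quadrant_table`: `cells` (2x2 matrix,
#'   depleted/not x low/high specificity), `odds_ratio`, `p_value`, `n`,
#'   and the thresholds used.
#' @export
quadrant_association <- function(enrich, scores, fc_threshold = -2,
                                 score_threshold = 0.2, haldane = FALSE) {
  d <- merge(enrich[, c("guide_id", "mean_log2fc")],
             scores, by = "guide_id")
  if (!is.null(d$searchable)) d <- d[d$searchable, , drop = FALSE]
  d <- d[!is.na(d$specificity) & !is.na(d$mean_log2fc), , drop = FALSE]
  if (nrow(d) < 1L) stop("no searchable, scored guides to analyse")
  dep <- d$mean_log2fc <= fc_threshold
  low <- d$specificity <= score_threshold
  cells <- matrix(c(sum(dep & low), sum(dep & !low),
                    sum(!dep & low), sum(!dep & !low)),
                  2, 2, byrow = TRUE,
                  dimnames = list(c("depleted", "not_depleted"),
                                  c("low_specificity", "high_specificity")))
  cc <- if (haldane) cells + 0.5 else cells
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  p <- tryCatch(fisher_exact_2x2(cells),
                warning = function(w) { warning(w); 1 })
  structure(list(cells = cells, odds_ratio = or, p_value = p,
                 n = nrow(d), fc_threshold = fc_threshold,
                 score_threshold = score_threshold),
            class = "quadrant_table")
}

#' @export
print.quadrant_table <- function(x, ...) {
  cat(sprintf("quadrant association (n = %d guides)\n", x$n))
  cat(sprintf("  thresholds: log2FC <= %g, specificity <= %g\n",
              x$fc_threshold, x$score_threshold))
  print(x$cells)
  cat(sprintf("  odds ratio = %.3g, Fisher p = %.3g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Element-level essentiality calls from guide depletion
#'
#' An element is called essential when at least `min_concordant` of its
#' guides are depleted (`mean_log2fc <= fc_threshold`). Elements whose
#' depletion evidence comes from a single guide are reported separately
#' (`evidence = "single"`): concordance across multiple independent guides
#' distinguishes on-target signal from guide-specific off-target toxicity.
#'
#' @param enrich Data frame from [guide_enrichment()].
#' @param guide_elements Data frame with `guide_id`, `element_id` (each
#'   guide maps to at most one element).
#' @param fc_threshold Depletion threshold, default -2.
#' @param min_concordant Depleted guides required for a call, default 2.
#' @return Data frame with `element_id`, `n_guides`, `n_depleted`,
#'   `called`, `evidence` (`"none"`, `"single"`, `"multiple"`).
#' @export
call_elements <- function(enrich, guide_elements, fc_threshold = -2,
                          min_concordant = 2L) {
  if (anyDuplicated(guide_elements$guide_id)) {
    stop("each guide must map to at most one element")
  }
  d <- merge(enrich[, c("guide_id", "mean_log2fc")], guide_elements,
             by = "guide_id")
  ids <- unique(guide_elements$element_id)
  n_tot <- table(factor(d$element_id, levels = ids))
  n_dep <- table(factor(d$element_id[d$mean_log2fc <= fc_threshold],
                        levels = ids))
  out <- data.frame(element_id = ids,
                    n_guides = as.integer(n_tot),
                    n_depleted = as.integer(n_dep),
                    stringsAsFactors = FALSE)
  out$called <- out$n_depleted >= min_concordant
  out$evidence <- ifelse(out$called, "multiple",
                         ifelse(out$n_depleted >= 1L, "single", "none"))
  out
}

#' Remove low-specificity and unsearchable guides from a screen
#'
#' Retains guides with specificity score strictly above the cutoff and
#' `searchable = TRUE`; guides with score <= cutoff, an absent (`NA`)
#' score, or an unsearchable flag are removed. The removed fraction is
#' attached as attribute `"removed_fraction"`.
#'
#' @param enrich Data frame from [guide_enrichment()].
#' @param scores Data frame with `guide_id`, `specificity` and optionally
#'   `searchable`.
#' @param cutoff Score cutoff (inclusive on the removal side), default 0.2.
#' @return Filtered enrichment data frame with `removed_fraction`
#'   attribute.
#' @export
specificity_filter_screen <- function(enrich, scores, cutoff = 0.2) {
  d <- merge(enrich, scores, by = "guide_id")
  keep <- !is.na(d$specificity) & d$specificity > cutoff
  if (!is.null(d$searchable)) keep <- keep & d$searchable
  out <- enrich[enrich$guide_id %in% d$guide_id[keep], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_fraction") <- 1 - nrow(out) / nrow(enrich)
  out
}

#' Write a screen QC report
#'
#' Plain-text summary of the quadrant association plus element calls
#' before and after specificity filtering, alongside a TSV of the
#' post-filter calls.
#'
#' @param quadrant A `quadrant_table` from [quadrant_association()].
#' @param calls_pre,calls_post Data frames from [call_elements()].
#' @param removed_fraction Fraction of guides removed by the filter.
#' @param path Output path for the text report; the element calls are
#'   written next to it as `<path>.calls.tsv`.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(quadrant, calls_pre, calls_post,
                            removed_fraction, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "screen specificity QC",
    sprintf("guides analysed: %d", quadrant$n),
    sprintf("thresholds: log2FC <= %g, specificity <= %g",
            quadrant$fc_threshold, quadrant$score_threshold),
    sprintf("quadrant cells (depleted/not x low/high spec): %s",
            paste(as.vector(t(quadrant$cells)), collapse = " ")),
    sprintf("odds ratio: %.4g", quadrant$odds_ratio),
    sprintf("fisher p: %.4g", quadrant$p_value),
    sprintf("removed guide fraction: %.4f", removed_fraction),
    sprintf("elements called pre-filter: %d (multiple-guide), %d single-guide",
            sum(calls_pre$called), sum(calls_pre$evidence == "single")),
    sprintf("elements called post-filter: %d (multiple-guide), %d single-guide",
            sum(calls_post$called), sum(calls_post$evidence == "single"))
  ), con)
  utils::write.table(calls_post, paste0(path, ".calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
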