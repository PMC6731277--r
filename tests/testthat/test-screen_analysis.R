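mk_cm <- function(counts, roles) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  count_matrix(m, roles)
}

test_that("guide enrichment reproduces exact CPM arithmetic", {
  # equal CPM in plasmid and endpoint -> log2fc 0 (pseudocount 0)
  cm <- mk_cm(cbind(plasmid = c(100L, 300L), end = c(200L, 600L)),
              c("plasmid", "endpoint"))
  e <- guide_enrichment(cm, pseudocount = 0)
  expect_equal(e$mean_log2fc, c(0, 0))

  # plasmid 100 CPM vs endpoint 25 CPM -> -2
  cm <- mk_cm(cbind(plasmid = c(100L, 999900L), end = c(25L, 999975L)),
              c("plasmid", "endpoint"))
  e <- guide_enrichment(cm, pseudocount = 0)
  expect_equal(e$mean_log2fc[1], -2)

  # endpoint raw count 0 with pseudocount 1: log2(1 / (cpm_plasmid + 1))
  cm <- mk_cm(cbind(plasmid = c(50L, 950L), end = c(0L, 1000L)),
              c("plasmid", "endpoint"))
  e <- guide_enrichment(cm, pseudocount = 1)
  cpm_plasmid <- 50 / 1000 * 1e6
  expect_equal(e$mean_log2fc[1], log2(1 / (cpm_plasmid + 1)))

  expect_error(guide_enrichment(
    mk_cm(cbind(plasmid = c(0L, 0L), end = c(1L, 1L)),
          c("plasmid", "endpoint"))), "all-zero")
})

test_that("enrichment is invariant to sample scaling (CPM property)", {
  set.seed(19)
  base <- matrix(rpois(60, 400), nrow = 20)
  colnames(base) <- c("plasmid", "r1", "r2")
  rownames(base) <- sprintf("g%d", 1:20)
  roles <- c("plasmid", "endpoint", "endpoint")
  e1 <- guide_enrichment(count_matrix(base, roles), pseudocount = 0)
  scaled <- base
  scaled[, "r1"] <- scaled[, "r1"] * 7L
  e2 <- guide_enrichment(count_matrix(scaled, roles), pseudocount = 0)
  expect_equal(e1$mean_log2fc, e2$mean_log2fc)
})

test_that("replicate summary is mean and sd/sqrt(k)", {
  cm <- mk_cm(cbind(plasmid = c(100L, 100L), r1 = c(50L, 150L),
                    r2 = c(25L, 175L)),
              c("plasmid", "endpoint", "endpoint"))
  e <- guide_enrichment(cm, pseudocount = 0)
  lfc <- as.matrix(e[, c("log2fc.r1", "log2fc.r2")])
  expect_equal(e$mean_log2fc, rowMeans(lfc))
  expect_equal(e$se, apply(lfc, 1, sd) / sqrt(2))
})

test_that("fisher_exact_2x2 matches exhaustive enumeration and fisher.test", {
  tables <- list(matrix(c(1, 9, 11, 3), 2, byrow = TRUE),
                 matrix(c(5, 0, 0, 5), 2, byrow = TRUE),
                 matrix(c(10, 10, 10, 10), 2, byrow = TRUE),
                 matrix(c(3, 7, 2, 8), 2, byrow = TRUE),
                 matrix(c(20, 0, 0, 20), 2, byrow = TRUE))
  for (tb in tables) {
    p <- fisher_exact_2x2(tb)
    expect_equal(p, oracle_fisher_two_sided(tb), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-6)
  }
  # identical rows -> p = 1
  expect_equal(fisher_exact_2x2(matrix(c(4, 6, 4, 6), 2, byrow = TRUE)), 1)
  # zero margin -> 1 with a warning
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2,
                                               byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("one-sided tails sum the hypergeometric tail", {
  tb <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tb, "greater"),
               sum(dhyper(8:10, 10, 10, 11)))
  expect_equal(fisher_exact_2x2(tb, "less"), sum(dhyper(0:8, 10, 10, 11)))
})

test_that("quadrant association counts, OR and p behave as specified", {
  mk <- function(n, lfc, score) {
    list(enrich = data.frame(guide_id = sprintf("g%d", 1:n),
                             mean_log2fc = lfc, stringsAsFactors = FALSE),
         scores = data.frame(guide_id = sprintf("g%d", 1:n),
                             searchable = TRUE, specificity = score,
                             stringsAsFactors = FALSE))
  }
  # balanced table: OR 1, p 1
  d <- mk(40, rep(c(-3, 0), each = 20), rep(c(0.1, 0.9), times = 20))
  q <- quadrant_association(d$enrich, d$scores)
  expect_equal(unname(as.vector(q$cells)), c(10, 10, 10, 10))
  expect_equal(q$odds_ratio, 1)
  expect_equal(q$p_value, 1)
  expect_equal(sum(q$cells), 40)

  # perfectly diagonal: OR Inf, p from enumeration
  d <- mk(40, rep(c(-3, 0), each = 20), rep(c(0.1, 0.9), each = 20))
  q <- quadrant_association(d$enrich, d$scores)
  expect_equal(unname(q$cells[1, ]), c(20, 0))
  expect_equal(q$odds_ratio, Inf)
  expect_equal(q$p_value,
               oracle_fisher_two_sided(matrix(c(20, 0, 0, 20), 2)))
  qh <- quadrant_association(d$enrich, d$scores, haldane = TRUE)
  expect_true(is.finite(qh$odds_ratio))

  # unsearchable and unscored guides never enter the table
  d <- mk(10, rep(-3, 10), rep(0.1, 10))
  d$scores$searchable[1:3] <- FALSE
  d$scores$specificity[4] <- NA
  # every remaining guide falls in one quadrant: degenerate margins warn
  expect_warning(q <- quadrant_association(d$enrich, d$scores),
                 "zero margin")
  expect_equal(q$n, 6)
})

test_that("swapping both threshold senses transposes the table, same p", {
  set.seed(40)
  n <- 200
  enrich <- data.frame(guide_id = sprintf("g%d", 1:n),
                       mean_log2fc = rnorm(n, -1, 1.5),
                       stringsAsFactors = FALSE)
  scores <- data.frame(guide_id = sprintf("g%d", 1:n), searchable = TRUE,
                       specificity = runif(n), stringsAsFactors = FALSE)
  q <- quadrant_association(enrich, scores)
  # flip: treat "not depleted" as the event and "high spec" as exposure
  enrich2 <- enrich; enrich2$mean_log2fc <- -enrich2$mean_log2fc
  scores2 <- scores; scores2$specificity <- 1 - scores2$specificity
  q2 <- quadrant_association(enrich2, scores2, fc_threshold = 2,
                             score_threshold = 0.8)
  expect_equal(unname(q2$cells), unname(q$cells[2:1, 2:1]))
  expect_equal(q2$p_value, q$p_value)
})

test_that("element calls require concordant multi-guide depletion", {
  enrich <- data.frame(
    guide_id = sprintf("g%d", 1:6),
    mean_log2fc = c(-3.1, -2.4, -4.0, -0.1, -0.5, -1.0),
    stringsAsFactors = FALSE)
  gmap <- data.frame(guide_id = sprintf("g%d", 1:6),
                     element_id = c("e1", "e1", "e2", "e2", "e3", "e3"),
                     stringsAsFactors = FALSE)
  calls <- call_elements(enrich, gmap)
  expect_equal(calls$called, c(TRUE, FALSE, FALSE))
  expect_equal(calls$evidence, c("multiple", "single", "none"))
  expect_true(all(calls$n_depleted <= calls$n_guides))
  expect_error(call_elements(enrich, rbind(gmap, gmap[1, ])), "at most one")
})

test_that("specificity filter removes <= cutoff, NA and unsearchable guides", {
  enrich <- data.frame(guide_id = sprintf("g%d", 1:5),
                       mean_log2fc = rep(-1, 5), stringsAsFactors = FALSE)
  scores <- data.frame(
    guide_id = sprintf("g%d", 1:5),
    searchable = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    specificity = c(0.2, 0.21, 0.9, 0.9, NA),
    stringsAsFactors = FALSE)
  out <- specificity_filter_screen(enrich, scores, cutoff = 0.2)
  expect_setequal(out$guide_id, c("g2", "g3"))
  expect_equal(attr(out, "removed_fraction"), 3 / 5)

  all_high <- scores
  all_high$specificity <- 0.9
  all_high$searchable <- TRUE
  out2 <- specificity_filter_screen(enrich, all_high, cutoff = 0.2)
  expect_equal(out2$guide_id, enrich$guide_id)
  expect_equal(attr(out2, "removed_fraction"), 0)
})

test_that("count matrices round-trip through TSV", {
  m <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("plasmid", "r1", "r2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(guide_id = rownames(m), m, check.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_count_matrix(tsv, plasmid = "plasmid")
  expect_equal(cm$counts, m)
  expect_equal(cm$roles, c("plasmid", "endpoint", "endpoint"))
})
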