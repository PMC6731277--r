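site_row <- function(mismatches = "", pam = "TGG",
                     n_mismatch = if (mismatches == "") 0L else
                       length(strsplit(mismatches, ";")[[1]])) {
  data.frame(mismatches = mismatches, pam = pam, n_mismatch = n_mismatch,
             stringsAsFactors = FALSE)
}

test_that("per-site CFD is the product of mismatch weights and PAM weight", {
  w <- test_weights()
  expect_equal(cfd_site_score(site_row("", pam = "TGG"), w), 1.0)

  w1 <- unname(w$mismatch["7:A>C"])
  expect_equal(cfd_site_score(site_row("7:A>C", pam = "AGG"), w), w1)

  w2 <- unname(w$mismatch["12:G>T"])
  wp <- unname(w$pam["AG"])
  expect_equal(cfd_site_score(site_row("7:A>C;12:G>T", pam = "TAG"), w),
               w1 * w2 * wp)
})

test_that("random site scores match an independent first-principles product", {
  w <- test_weights()
  mm_tab <- utils::read.table(
    system.file("extdata", "cfd_weights_synthetic.tsv",
                package = "guidespec"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pam_tab <- utils::read.table(
    system.file("extdata", "cfd_pam_weights_synthetic.tsv",
                package = "guidespec"),
    header = TRUE, sep = "\t", colClasses = c("character", "numeric"),
    stringsAsFactors = FALSE)
  set.seed(404)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    k <- sample(1:4, 1)
    pos <- sort(sample(1:20, k))
    gb <- sample(bases, k, replace = TRUE)
    tb <- vapply(gb, function(g) sample(setdiff(bases, g), 1),
                 character(1))
    pam <- paste0(sample(bases, 1), sample(c("GG", "AG", "GA"), 1))
    desc <- paste(sprintf("%d:%s>%s", pos, gb, tb), collapse = ";")
    expected <- prod(vapply(seq_len(k), function(j) {
      mm_tab$weight[mm_tab$position == pos[j] &
                    mm_tab$guide_base == gb[j] &
                    mm_tab$target_base == tb[j]]
    }, numeric(1))) * pam_tab$weight[pam_tab$pam_suffix ==
                                     substring(pam, 2, 3)]
    expect_equal(cfd_site_score(site_row(desc, pam = pam), w), expected)
  }
})

test_that("missing table entries raise an error naming the key", {
  w <- test_weights()
  w$mismatch <- w$mismatch[names(w$mismatch) != "5:A>G"]
  expect_error(cfd_site_score(site_row("5:A>G"), w), "5:A>G")
  expect_error(cfd_site_score(
    site_row("1:A>C;2:A>C;3:A>C;4:A>C;5:A>C", n_mismatch = 5L),
    test_weights()), "more than 4")
})

test_that("aggregate specificity is 1/(1 + CFD sum) over classes 2-3", {
  w <- all_one_weights()
  none <- site_row("")[0, ]
  expect_equal(aggregate_specificity(none, w)$score, 1.0)

  one <- site_row("3:A>C;9:G>T", pam = "TGG")     # CFD 1 under all-one
  expect_equal(aggregate_specificity(one, w)$score, 0.5)

  # sites with CFDs 0.5, 0.25, 0.25 -> sum 1 -> score 0.5, using a table
  # where the weights are the CFDs directly (single-mismatch sites)
  mmtab <- data.frame(position = c(1L, 2L, 3L),
                      guide_base = "A", target_base = "C",
                      weight = c(0.5, 0.25, 0.25))
  pamtab <- data.frame(pam_suffix = "GG", weight = 1)
  # pad to a valid table: positions 1..3 only are referenced
  wt <- cfd_weights(mmtab, pamtab, source = "handmade")
  sites <- rbind(site_row("1:A>C", n_mismatch = 2L),
                 site_row("2:A>C", n_mismatch = 2L),
                 site_row("3:A>C", n_mismatch = 3L))
  agg <- aggregate_specificity(sites, wt)
  expect_equal(agg$cfd_sum, 1.0)
  expect_equal(agg$score, 0.5)
})

test_that("hand-computed sums verify the aggregate on randomized site lists", {
  w <- test_weights()
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:100) {
    n_sites <- sample(0:8, 1)
    sites <- NULL
    hand_sum <- 0
    for (s in seq_len(n_sites)) {
      k <- sample(2:3, 1)
      pos <- sort(sample(1:20, k))
      gb <- sample(bases, k, replace = TRUE)
      tb <- vapply(gb, function(g) sample(setdiff(bases, g), 1),
                   character(1))
      pam <- paste0(sample(bases, 1), sample(c("GG", "AG"), 1))
      desc <- paste(sprintf("%d:%s>%s", pos, gb, tb), collapse = ";")
      row <- site_row(desc, pam = pam)
      sites <- if (is.null(sites)) row else rbind(sites, row)
      hand_sum <- hand_sum +
        prod(w$mismatch[sprintf("%d:%s>%s", pos, gb, tb)]) *
        w$pam[substring(pam, 2, 3)]
    }
    if (is.null(sites)) sites <- site_row("")[0, ]
    agg <- aggregate_specificity(sites, w)
    expect_equal(agg$cfd_sum, unname(hand_sum))
    expect_equal(agg$score, unname(1 / (1 + hand_sum)))
  }
})

test_that("appending a positive-CFD site strictly decreases the score", {
  w <- test_weights()
  sites <- site_row("4:C>T;16:G>A")
  prev <- aggregate_specificity(sites, w)$score
  set.seed(5)
  for (i in 1:10) {
    extra <- site_row(sprintf("%d:A>G;%d:T>C", sample(1:10, 1),
                              sample(11:20, 1)))
    sites <- rbind(sites, extra)
    cur <- aggregate_specificity(sites, w)$score
    expect_lt(cur, prev)
    expect_gt(cur, 0)
    prev <- cur
  }
})

test_that("the aggregate is permutation invariant in the site list", {
  w <- test_weights()
  sites <- rbind(site_row("1:A>C;20:T>G"), site_row("5:G>A;6:G>T"),
                 site_row("2:C>A;3:C>G;4:C>T"))
  a <- aggregate_specificity(sites, w)
  set.seed(2)
  for (i in 1:5) {
    b <- aggregate_specificity(sites[sample(nrow(sites)), ], w)
    expect_equal(b$cfd_sum, a$cfd_sum)
  }
})

test_that("the degenerate all-1 table gives score 1/(1 + n sites)", {
  w <- all_one_weights()
  set.seed(31)
  for (i in 1:10) {
    n2 <- sample(0:5, 1); n3 <- sample(0:5, 1)
    rows <- list()
    for (j in seq_len(n2)) rows[[length(rows) + 1L]] <-
      site_row("1:A>C;2:A>C")
    for (j in seq_len(n3)) rows[[length(rows) + 1L]] <-
      site_row("1:A>C;2:A>C;3:A>C")
    sites <- if (length(rows)) do.call(rbind, rows) else site_row("")[0, ]
    expect_equal(aggregate_specificity(sites, w)$score,
                 1 / (1 + n2 + n3))
  }
})

test_that("unsearchable guides are never scored", {
  w <- test_weights()
  bad <- rbind(site_row(""), site_row("10:A>C"))
  expect_error(aggregate_specificity(bad, w), "unsearchable")
})

test_that("the weight table TSV round-trips through read/write", {
  w <- synthetic_cfd_weights()
  mm <- withr::local_tempfile(fileext = ".tsv")
  pam <- withr::local_tempfile(fileext = ".tsv")
  write_cfd_weights(w, mm, pam)
  back <- read_cfd_weights(mm, pam)
  expect_equal(back$mismatch[names(w$mismatch)], w$mismatch)
  expect_equal(back$pam[names(w$pam)], w$pam)
})

test_that("score_guides scores searchable guides and withholds others", {
  spacer <- "ACCGTTGAGTCAGGATCCAT"
  base <- random_genome(12000L, seed = 64L)
  planted <- implant_sites(
    base, spacer,
    list(list(n_mismatch = 0L, pam = "TGG"),
         list(n_mismatch = 2L, positions = c(2L, 11L), pam = "CGG"),
         list(n_mismatch = 3L, positions = c(1L, 5L, 19L), pam = "TAG")),
    seed = 13L)
  w <- all_one_weights()
  scored <- score_guides(
    data.frame(guide_id = "g1", spacer = spacer,
               stringsAsFactors = FALSE),
    planted$genome, w)
  expect_true(scored$searchable)
  expect_equal(scored$n0, 1L)
  expect_equal(scored$n2, 1L)
  expect_equal(scored$n3, 1L)
  expect_equal(scored$specificity, 1 / 3)   # all-one weights: 1/(1+2)

  # plant a second perfect copy -> unsearchable, score absent
  planted2 <- implant_sites(
    base, spacer,
    list(list(n_mismatch = 0L, pam = "TGG", count = 2L)), seed = 14L)
  scored2 <- score_guides(
    data.frame(guide_id = "g1", spacer = spacer,
               stringsAsFactors = FALSE),
    planted2$genome, w)
  expect_false(scored2$searchable)
  expect_true(is.na(scored2$specificity))
})
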