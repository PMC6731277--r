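# All generators run under a private RNG scope: the caller's .Random.seed
# is saved and restored, so simulation seeds never leak into user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random genome
#'
#' i.i.d. bases with `P(G) + P(C) = gc`; deterministic for a given seed.
#'
#' @param length Sequence length (>= 23 so at least one spacer+PAM fits).
#' @param gc GC fraction in \[0, 1\], default 0.41 (human-like).
#' @param seed Integer seed.
#' @param chrom Record name, default `"chrS"`.
#' @return A [genome] object with one record.
#' @export
random_genome <- function(length, gc = 0.41, seed = 1L, chrom = "chrS") {
  stopifnot(length >= 23, gc >= 0, gc <= 1)
  seq <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  g <- genome(stats::setNames(seq, chrom), build = "synthetic")
  g
}

#' Implant protospacer sites into a genome
#'
#' Writes copies of a spacer (with requested mismatches and PAM) at random
#' non-overlapping positions, on random strands, and returns both the
#' modified genome and the ground-truth site list in the same format as
#' [find_offtarget_sites()]. Before planting, the background is scanned
#' and any window that already matches the spacer within `prescan_mm`
#' mismatches (with any PAM in `prescan_pams`) is mutated away, so the
#' truth list is exactly what a search must return.
#'
#' @param genome A [genome] object (single record).
#' @param spacer 20-nt spacer to plant sites for.
#' @param site_specs List of site specifications, each a list with
#'   `n_mismatch` (0..3), optional `positions` (mismatch positions 1..20;
#'   chosen at random if omitted), `pam` (3-nt, default `"TGG"`), `count`
#'   (number of copies, default 1).
#' @param seed Integer seed.
#' @param prescan_mm Mismatch radius cleared in the background, default 3.
#' @param prescan_pams PAM set used when clearing the background, default
#'   `c("NGG", "NAG")`.
#' @return List with `genome` (modified) and `truth` (site data frame
#'   sorted like [find_offtarget_sites()] output).
#' @export
implant_sites <- function(genome, spacer, site_specs, seed = 1L,
                          prescan_mm = 3L, prescan_pams = c("NGG", "NAG")) {
  stopifnot(inherits(genome, "genome"), length(genome) == 1L)
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stop("spacer must be 20 nt")
  chrom <- names(genome)[1]

  with_seed(seed, {
    s <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
    L <- length(s)
    bases <- c("A", "C", "G", "T")

    # clear chance matches: bump the Hamming distance of any background
    # window within prescan_mm of the spacer (either strand, any PAM)
    repeat {
      g0 <- genome(stats::setNames(paste(s, collapse = ""), chrom),
                   build = attr(genome, "build"))
      hits <- find_offtarget_sites(spacer, g0, max_mismatches = prescan_mm,
                                   pam_set = prescan_pams)
      if (nrow(hits) == 0L) break
      for (i in seq_len(nrow(hits))) {
        # flip one base inside the window to a base that differs from both
        # the current genome base and the spacer base at that position
        pos0 <- hits$start[i] + sample.int(20L, 1L) - 1L
        cur <- s[pos0 + 1L]
        s[pos0 + 1L] <- sample(setdiff(bases, cur), 1L)
      }
    }

    # plant requested sites at non-overlapping positions (23-nt footprint)
    occupied <- integer(0)
    truth <- list()
    total <- sum(vapply(site_specs, function(x) {
      if (is.null(x$count)) 1L else as.integer(x$count)
    }, integer(1)))
    if (L < 23L * total * 3L) stop("genome too short for requested sites")
    for (spec in site_specs) {
      count <- if (is.null(spec$count)) 1L else spec$count
      pam <- toupper(if (is.null(spec$pam)) "TGG" else spec$pam)
      for (k in seq_len(count)) {
        # choose a free plus-strand footprint [st, st+22] (1-based)
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 1000L) stop("insufficient space to plant sites")
          st <- sample.int(L - 22L, 1L)
          if (!any((st:(st + 22L)) %in% occupied)) break
        }
        occupied <- c(occupied, (st - 22L):(st + 44L)) # keep sites apart
        strand <- sample(c("+", "-"), 1L)
        site_seq <- strsplit(spacer, "", fixed = TRUE)[[1]]
        nmm <- spec$n_mismatch
        pos <- spec$positions
        if (is.null(pos) && nmm > 0L) pos <- sort(sample.int(20L, nmm))
        if (length(pos) != nmm) stop("positions must match n_mismatch")
        for (p in pos) {
          site_seq[p] <- sample(setdiff(bases, site_seq[p]), 1L)
        }
        site_str <- paste(site_seq, collapse = "")
        if (strand == "+") {
          # protospacer at [st, st+19], PAM at [st+20, st+22]
          s[st:(st + 19L)] <- site_seq
          s[(st + 20L):(st + 22L)] <- strsplit(pam, "", fixed = TRUE)[[1]]
          start0 <- st - 1L
        } else {
          # PAM (rc) at [st, st+2], protospacer (rc) at [st+3, st+22]
          s[st:(st + 2L)] <- strsplit(revcomp(pam), "", fixed = TRUE)[[1]]
          s[(st + 3L):(st + 22L)] <-
            strsplit(revcomp(site_str), "", fixed = TRUE)[[1]]
          start0 <- st + 2L
        }
        sp_ch <- strsplit(spacer, "", fixed = TRUE)[[1]]
        mmpos <- which(site_seq != sp_ch)
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = chrom, start = start0, end = start0 + 20L,
          strand = strand, site_seq = site_str, pam = pam,
          n_mismatch = length(mmpos),
          mismatches = paste(sprintf("%d:%s>%s", mmpos, sp_ch[mmpos],
                                     site_seq[mmpos]), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$chrom, truth$start, truth$strand), ,
                   drop = FALSE]
    rownames(truth) <- NULL
    list(genome = genome(stats::setNames(paste(s, collapse = ""), chrom),
                         build = attr(genome, "build")),
         truth = truth)
  })
}

#' Screen simulation configuration
#'
#' Defines the generative model for a pooled growth screen with off-target
#' confounding. Guides are grouped into elements; a fraction of elements is
#' truly essential (their guides carry an on-target per-doubling depletion
#' `e_on`), and an independent random fraction of guides is "confounded":
#' low specificity (score drawn in (0, 0.2\]) with an additional per-doubling
#' off-target toxicity `e_tox`. Unconfounded guides draw scores in
#' (0.2, 1\]. Plasmid abundances are Dirichlet-uniform; endpoint expected
#' abundance is proportional to `plasmid * 2^(g * fitness)`; counts are
#' negative binomial (mean = depth share, dispersion `phi`, i.e.
#' variance = mu + phi * mu^2) in each sample.
#'
#' Defaults describe a motif-style screen: 1000 guides over 200 elements
#' (5 per element), 10% essential elements with `e_on = -0.6` per doubling,
#' 30% confounded guides with `e_tox = -1.5` per doubling, 7 population
#' doublings, 500x per-guide sequencing depth, dispersion 0.05, 2 endpoint
#' replicates.
#'
#' @param n_guides Number of guides.
#' @param guides_per_element Guides per element.
#' @param frac_essential Fraction of elements that are truly essential.
#' @param e_on On-target fitness effect (log2 per doubling) of guides in
#'   essential elements.
#' @param frac_confounded Fraction of guides flagged low-specificity.
#' @param e_tox Off-target toxicity (log2 per doubling) for confounded
#'   guides; 0 disables confounding.
#' @param g Population doublings over the screen.
#' @param depth Expected total reads per sample (default 500 * n_guides).
#' @param phi Negative-binomial dispersion.
#' @param k Endpoint replicates.
#' @param seed Integer seed.
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_guides = 1000L, guides_per_element = 5L,
                              frac_essential = 0.1, e_on = -0.6,
                              frac_confounded = 0.3, e_tox = -1.5,
                              g = 7, depth = 500 * n_guides, phi = 0.05,
                              k = 2L, seed = 1L) {
  stopifnot(depth > 0, phi > 0, k >= 1, n_guides >= guides_per_element)
  structure(as.list(environment()), class = "screen_sim_config")
}

#' Simulate a pooled growth screen
#'
#' Draws a [count_matrix] (one plasmid sample + `k` endpoint replicates)
#' from the generative model in [screen_sim_config()], with full ground
#' truth. Deterministic for a given config (bit-identical counts).
#'
#' @param config A [screen_sim_config].
#' @return List with `counts` (a [count_matrix]), `truth` (per-guide data
#'   frame: `guide_id`, `element_id`, `essential`, `confounded`,
#'   `searchable`, `specificity`, `e_on`, `e_tox`, `expected_log2fc`) and
#'   `elements` (per-element data frame with planted `essential` flag).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    n <- config$n_guides
    gpe <- config$guides_per_element
    n_el <- ceiling(n / gpe)
    element_id <- sprintf("el_%04d", rep(seq_len(n_el), each = gpe)[1:n])
    essential_el <- stats::runif(n_el) < config$frac_essential
    essential <- essential_el[rep(seq_len(n_el), each = gpe)[1:n]]
    confounded <- stats::runif(n) < config$frac_confounded
    specificity <- ifelse(confounded,
                          stats::runif(n, 0.01, 0.2),
                          stats::runif(n, 0.2 + 1e-6, 1))
    e_on <- ifelse(essential, config$e_on, 0)
    e_tox <- ifelse(confounded, config$e_tox, 0)
    fitness <- e_on + e_tox
    expected_lfc <- config$g * fitness

    abundance <- stats::rgamma(n, shape = 1)  # Dirichlet(1) up to norm
    abundance <- abundance / sum(abundance)
    mu_plasmid <- config$depth * abundance
    end_w <- abundance * 2^(config$g * fitness)
    mu_end <- config$depth * end_w / sum(end_w)

    draw <- function(mu) stats::rnbinom(n, mu = mu, size = 1 / config$phi)
    counts <- cbind(plasmid = draw(mu_plasmid))
    for (r in seq_len(config$k)) {
      counts <- cbind(counts, draw(mu_end))
      colnames(counts)[ncol(counts)] <- paste0("endpoint_rep", r)
    }
    guide_id <- sprintf("sg_%04d", seq_len(n))
    rownames(counts) <- guide_id
    cm <- count_matrix(counts, c("plasmid", rep("endpoint", config$k)))
    truth <- data.frame(guide_id = guide_id, element_id = element_id,
                        essential = essential, confounded = confounded,
                        searchable = TRUE, specificity = specificity,
                        e_on = e_on, e_tox = e_tox,
                        expected_log2fc = expected_lfc,
                        stringsAsFactors = FALSE)
    elements <- data.frame(element_id = sprintf("el_%04d", seq_len(n_el)),
                           essential = essential_el,
                           stringsAsFactors = FALSE)
    list(counts = cm, truth = truth, elements = elements)
  })
}
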