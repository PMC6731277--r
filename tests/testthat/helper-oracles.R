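# Independent oracles used across the suite. These deliberately avoid the
# package's search/scoring code paths: plain vectorised base R only.

# reverse complement without using guidespec::revcomp's vapply path
oracle_rc <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

iupac_classes <- c(A = "A", C = "C", G = "G", T = "T",
                   R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                   M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                   N = "ACGT")

oracle_pam_ok <- function(pams, patterns) {
  ok <- rep(FALSE, length(pams))
  for (pat in patterns) {
    cls <- iupac_classes[strsplit(pat, "", fixed = TRUE)[[1]]]
    rx <- paste0("^", paste0("[", cls, "]", collapse = ""), "$")
    ok <- ok | grepl(rx, pams)
  }
  ok
}

# Naive all-window Hamming scan of one-record genome for a spacer.
# Returns a data frame matching find_offtarget_sites() columns/sort order.
oracle_offtarget_scan <- function(spacer, genome_seq, chrom = "chrS",
                                  max_mm = 3L, pam_set = c("NGG", "NAG")) {
  slen <- 20L
  scan_strand <- function(s) {
    L <- nchar(s)
    g <- strsplit(s, "", fixed = TRUE)[[1]]
    sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
    n_win <- L - slen - 3L + 1L
    if (n_win < 1L) return(NULL)
    i <- seq_len(n_win)                       # 1-based window starts
    mm <- integer(n_win)
    has_n <- rep(FALSE, n_win)
    for (p in 1:slen) {
      b <- g[i + p - 1L]
      mm <- mm + (b != sp[p])
      has_n <- has_n | b == "N"
    }
    pam <- substring(s, i + slen, i + slen + 2L)
    keep <- mm <= max_mm & !has_n & !grepl("N", pam, fixed = TRUE) &
            oracle_pam_ok(pam, pam_set)
    if (!any(keep)) return(NULL)
    data.frame(i = i[keep],
               site_seq = substring(s, i[keep], i[keep] + slen - 1L),
               pam = pam[keep], n_mismatch = mm[keep],
               stringsAsFactors = FALSE)
  }
  out <- list()
  plus <- scan_strand(genome_seq)
  L <- nchar(genome_seq)
  if (!is.null(plus)) {
    plus$chrom <- chrom; plus$strand <- "+"
    plus$start <- plus$i - 1L
    out[[1]] <- plus
  }
  minus <- scan_strand(oracle_rc(genome_seq))
  if (!is.null(minus)) {
    minus$chrom <- chrom; minus$strand <- "-"
    # rc-coordinate window [j, j+19] maps to plus 0-based [L-j-19, L-j+1)
    minus$start <- L - minus$i - 19L
    out[[2]] <- minus
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), site_seq = character(),
                      pam = character(), n_mismatch = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)[, c("chrom", "start", "strand", "site_seq",
                                 "pam", "n_mismatch")]
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# canonical comparable form of a site table from either route
site_key <- function(df) {
  sprintf("%s:%d:%s:%s:%s:%d", df$chrom, df$start, df$strand, df$site_seq,
          df$pam, df$n_mismatch)
}

# Exhaustive fixed-margin enumeration for the two-sided Fisher p-value,
# computed from log-binomial coefficients (no dhyper).
oracle_fisher_two_sided <- function(cells) {
  a <- cells[1, 1]; b <- cells[1, 2]; c <- cells[2, 1]; d <- cells[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  pobs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  min(sum(p[p <= pobs * (1 + 1e-12)]), 1)
}

# shared synthetic weight table for specificity tests
test_weights <- function() synthetic_cfd_weights()

# weight table where every mismatch weight is 1 (degenerate closed form)
all_one_weights <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(position = 1:20, guide_base = bases,
                      target_base = bases, stringsAsFactors = FALSE)
  grid <- grid[grid$guide_base != grid$target_base, ]
  grid$weight <- 1
  pam <- data.frame(pam_suffix = c("GG", "AG"), weight = c(1, 1),
                    stringsAsFactors = FALSE)
  cfd_weights(grid, pam, source = "all-one")
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
}
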