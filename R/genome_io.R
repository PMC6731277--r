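#' Construct a genome object
#'
#' A genome is represented as a named character vector of uppercase
#' nucleotide sequences over the alphabet A, C, G, T, N. Sequence ids must
#' be unique and every sequence must be non-empty.
#'
#' @param records Named character vector (or coercible list) of sequences.
#' @param build Free-text build label (e.g. `"hg19"`, `"synthetic"`).
#' @return An object of class `genome`: a named character vector with a
#'   `build` attribute.
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT"), build = "toy")
#' @export
genome <- function(records, build = "unspecified") {
  records <- unlist(records)
  if (length(records) == 0L) stop("genome must contain at least one record")
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all genome records must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- toupper(records)
  if (any(nchar(records) < 1L)) stop("zero-length sequence in genome")
  bad <- grepl("[^ACGTN]", records)
  if (any(bad)) {
    stop("non-IUPAC characters (only ACGTN allowed) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  structure(records, build = build, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome (%s): %d sequence(s), %s bp total\n",
              attr(x, "build"), length(x),
              format(sum(nchar(x)), big.mark = ",")))
  for (i in seq_along(x)) {
    cat(sprintf("  %s  %d bp\n", names(x)[i], nchar(x[[i]])))
  }
  invisible(x)
}

#' Read a (multi-)FASTA genome
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Characters other than A, C, G, T, N are rejected.
#'
#' @param path Path to a FASTA file.
#' @param build Build label stored on the returned genome.
#' @return A [genome] object.
#' @export
read_genome <- function(path, build = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  recs <- as.character(set)
  names(recs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  genome(recs, build = build)
}

#' Write a genome to FASTA
#'
#' @param x A [genome] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(x, path) {
  stopifnot(inherits(x, "genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(x)[seq_along(x)]), path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' Reads 3- or 6-column BED (0-based half-open; strand in column 6) and
#' returns a data frame in the same convention. Intervals with no strand are
#' given strand `"."`.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (`start` 0-based inclusive, `end` exclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr),
    name   = if (!is.null(gr$name)) as.character(gr$name) else
               paste0("interval_", seq_along(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  df
}

#' Write genomic intervals to BED
#'
#' @param df Data frame with `chrom`, `start`, `end` and optionally `name`,
#'   `strand` columns, 0-based half-open.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  if (!is.null(df$name)) gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# 0-based half-open data frame -> GRanges (1-based closed)
intervals_to_granges <- function(df) {
  strand <- if (!is.null(df$strand)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' GC fraction of a nucleotide sequence
#'
#' @param seq Non-empty string over A, C, G, T.
#' @return `(#G + #C) / nchar(seq)`, in \[0, 1\].
#' @examples
#' gc_fraction("ACGT") # 0.5
#' @export
gc_fraction <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || nchar(seq) == 0L) {
    stop("seq must be a single non-empty string")
  }
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("seq must contain only A, C, G, T")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Reverse complement of a DNA string
#'
#' @param seq String over A, C, G, T, N (case preserved as uppercase).
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(toupper(seq), "", fixed = TRUE),
                                  function(ch) paste(rev(ch), collapse = ""),
                                  character(1)))
}

# IUPAC code -> regex character class
iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(map))) {
    stop("invalid IUPAC code in pattern: ", pattern)
  }
  paste(map[chars], collapse = "")
}

# vectorised IUPAC match of equal-length sequences against one pattern
matches_iupac <- function(seqs, pattern) {
  grepl(paste0("^", iupac_to_regex(pattern), "$"), seqs)
}

#' Enumerate candidate spacers adjacent to PAM sites
#'
#' Scans both strands of every genome record for positions where a
#' full-length spacer lies immediately 5' of a PAM matching `pam_pattern`
#' (IUPAC). Spacers containing N are excluded. The cut position is the
#' standard SpCas9 blunt cut between spacer positions 17 and 18 (3 nt 5' of
#' the PAM), recorded as the 0-based coordinate of the base immediately 3'
#' of the cut on the plus strand.
#'
#' @param genome A [genome] object.
#' @param pam_pattern IUPAC PAM pattern, default `"NGG"`.
#' @param spacer_len Spacer length, default 20.
#' @return Data frame sorted by (chrom, start, strand) with columns
#'   `guide_id`, `chrom`, `start`, `end` (0-based half-open protospacer
#'   interval), `strand`, `spacer` (5'->3' on the protospacer strand),
#'   `pam`, `cut_pos`.
#' @export
enumerate_spacers <- function(genome, pam_pattern = "NGG", spacer_len = 20L) {
  stopifnot(inherits(genome, "genome"), spacer_len >= 1L)
  pam_len <- nchar(pam_pattern)
  out <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    L <- nchar(s)
    if (L < spacer_len + pam_len) next
    subj <- Biostrings::DNAString(s)

    # plus strand: PAM matches at p1 (1-based), spacer at [p1-spacer_len, p1-1]
    hits <- Biostrings::matchPattern(pam_pattern, subj, fixed = FALSE)
    p1 <- Biostrings::start(hits)
    p1 <- p1[p1 - spacer_len >= 1L & p1 + pam_len - 1L <= L]
    if (length(p1)) {
      spacer <- substring(s, p1 - spacer_len, p1 - 1L)
      pam <- substring(s, p1, p1 + pam_len - 1L)
      keep <- !grepl("N", spacer, fixed = TRUE) &
              !grepl("N", pam, fixed = TRUE)
      if (any(keep)) {
        p1k <- p1[keep]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          start = p1k - spacer_len - 1L,
          end = p1k - 1L,
          strand = "+",
          spacer = spacer[keep],
          pam = pam[keep],
          cut_pos = p1k - spacer_len - 1L + (spacer_len - 3L),
          stringsAsFactors = FALSE
        )
      }
    }

    # minus strand: a minus-strand PAM is the reverse complement pattern on
    # the plus strand at [q1, q1+pam_len-1]; the protospacer occupies
    # [q1+pam_len, q1+pam_len+spacer_len-1] and reads 3'->5' in plus coords
    rc_pat <- revcomp(pam_pattern)
    hits <- Biostrings::matchPattern(rc_pat, subj, fixed = FALSE)
    q1 <- Biostrings::start(hits)
    q1 <- q1[q1 + pam_len + spacer_len - 1L <= L]
    if (length(q1)) {
      slice <- substring(s, q1 + pam_len, q1 + pam_len + spacer_len - 1L)
      pam_slice <- substring(s, q1, q1 + pam_len - 1L)
      keep <- !grepl("N", slice, fixed = TRUE) &
              !grepl("N", pam_slice, fixed = TRUE)
      if (any(keep)) {
        q1k <- q1[keep]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          start = q1k + pam_len - 1L,
          end = q1k + pam_len + spacer_len - 1L,
          strand = "-",
          spacer = revcomp(slice[keep]),
          pam = revcomp(pam_slice[keep]),
          cut_pos = q1k + pam_len + 2L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(guide_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), spacer = character(),
                      pam = character(), cut_pos = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  res <- cbind(guide_id = sprintf("sg_%s_%d_%s", res$chrom, res$start,
                                  res$strand),
               res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Write a spacer table to TSV
#'
#' Columns: guide_id, chrom, start, end, strand, spacer, pam, cut_pos.
#'
#' @param spacers Data frame as returned by [enumerate_spacers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spacers <- function(spacers, path) {
  utils::write.table(spacers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
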