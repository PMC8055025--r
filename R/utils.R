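## Internal helpers shared across modules.
## Coordinate convention: internal intervals are 0-based half-open [start, end);
## GTF I/O converts to/from 1-based closed; BED output stays 0-based half-open.

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(strand)
}

## Single-linkage merge of 1D positions: positions whose gap to the nearest
## member of a group is <= window end up in the same group. Returns group ids
## in input order.
.merge_positions <- function(pos, window) {
  if (length(pos) == 0L) return(integer(0))
  o <- order(pos)
  sorted <- pos[o]
  grp_sorted <- cumsum(c(1L, as.integer(diff(sorted) > window)))
  grp <- integer(length(pos))
  grp[o] <- grp_sorted
  grp
}

## Normalize a nucleotide string to an RNA alphabet, uppercase (T -> U).
.norm_rna <- function(x) {
  chartr("tT", "uU", toupper(x))
}

## Convert internal [start, end) to an IRanges (1-based closed).
.to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

## Strand-oriented window extraction from a genome (a named DNAStringSet).
## `pos` is the 0-based genomic coordinate of the anchor nucleotide.
## `up`/`down` count nucleotides up/downstream in *transcript* orientation;
## the returned string is in transcript orientation (minus strand sequences
## are reverse-complemented). The anchor itself is included when up >= 0.
## Out-of-chromosome overhang is truncated; the attribute "offset" gives the
## number of upstream positions actually present.
extract_anchor_window <- function(genome, chrom, pos, strand, up, down) {
  .check_strand(strand)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom, call. = FALSE)
  len <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    s0 <- pos - up
    e0 <- pos + down + 1L
  } else {
    s0 <- pos - down
    e0 <- pos + up + 1L
  }
  s <- max(s0, 0L)
  e <- min(e0, len)
  if (s >= e) {
    res <- ""
    attr(res, "offset") <- 0L
    return(res)
  }
  seq <- Biostrings::subseq(genome[[chrom]], start = s + 1L, end = e)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  res <- as.character(seq)
  attr(res, "offset") <- if (strand == "+") pos - s else e - 1L - pos
  res
}
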