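## Shared fixtures and independent oracles for the test suite.
## All fixtures are built in code; no binary data.

mk_tx <- function(id, gene, strand, exons, chrom = "chr1", cds_end = NA) {
  transcript(id, gene, chrom, strand,
             data.frame(start = exons[, 1L], end = exons[, 2L]),
             cds_end = cds_end)
}

## Two-ALE gene on the requested strand: shared first exon, a proximal last
## exon inside the intron of the distal isoform, and a distal last exon.
toy_ale_gene <- function(strand = "+", gene = "gA") {
  tp <- paste0(gene, ".tP"); td <- paste0(gene, ".tD")
  if (strand == "+") {
    list(
      mk_tx(tp, gene, "+", rbind(c(100, 200), c(400, 700))),
      mk_tx(td, gene, "+", rbind(c(100, 200), c(1200, 1600)))
    )
  } else {
    list(
      mk_tx(tp, gene, "-", rbind(c(1400, 1500), c(900, 1200))),
      mk_tx(td, gene, "-", rbind(c(1400, 1500), c(100, 400)))
    )
  }
}

toy_tutr_gene <- function(gene = "gT") {
  list(
    mk_tx("tS", gene, "+", rbind(c(100, 200), c(400, 700))),
    mk_tx("tL", gene, "+", rbind(c(100, 200), c(400, 1000)))
  )
}

toy_mixed_gene <- function(gene = "gM") {
  list(
    mk_tx("t1", gene, "+", rbind(c(100, 200), c(400, 650))),
    mk_tx("t2", gene, "+", rbind(c(100, 200), c(400, 800))),
    mk_tx("t3", gene, "+", rbind(c(100, 200), c(1200, 1500)))
  )
}

## Independent greedy-clustering oracle: a recursive re-statement of the
## summit-first rule working on explicit sets, used to check
## cluster_read_ends() on small inputs.
brute_cluster <- function(pos, weight, window) {
  agg <- tapply(weight, pos, sum)
  p <- as.numeric(names(agg))
  w <- as.numeric(agg)
  recurse <- function(p, w) {
    if (length(p) == 0L) return(NULL)
    best <- which(w == max(w))
    i <- best[which.min(p[best])]
    member <- abs(p - p[i]) <= window / 2
    rbind(data.frame(summit_pos = p[i], count = sum(w[member])),
          recurse(p[!member], w[!member]))
  }
  res <- recurse(p, w)
  res[order(res$summit_pos), , drop = FALSE]
}

## Exhaustive PWM-window oracle: naive per-window scoring with explicit
## loops, independent of the vectorized scanner.
brute_scan <- function(seq, p, threshold) {
  s <- chartr("tT", "uU", toupper(seq))
  bases <- c("A", "C", "G", "U")
  q <- (p$matrix + p$pseudo / 4) / (1 + p$pseudo)
  lo <- log2(q / 0.25)
  L <- nrow(lo)
  smin <- sum(apply(lo, 1, min)); smax <- sum(apply(lo, 1, max))
  ch <- strsplit(s, "")[[1L]]
  out <- NULL
  for (st in seq_len(max(0L, length(ch) - L + 1L))) {
    sc <- 0; ok <- TRUE
    for (j in seq_len(L)) {
      b <- match(ch[st + j - 1L], bases)
      if (is.na(b)) { ok <- FALSE; break }
      sc <- sc + lo[j, b]
    }
    if (!ok) next
    frac <- (sc - smin) / (smax - smin)
    if (frac >= threshold) {
      out <- rbind(out, data.frame(start = st, center_pos = st + (L - 1L) %/% 2L,
                                   score_fraction = frac))
    }
  }
  out
}

## Random DNA string.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
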