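## Sequence analyses around cleavage sites and cassette exons: PAS hexamer
## classes, PWM scanning with a fractional match threshold, nucleotide
## metaprofiles, positional motif density and group-wise tests.

.RNA_BASES <- c("A", "C", "G", "U")

#' Construct a position weight matrix
#'
#' @param name motif name.
#' @param mat numeric matrix, positions x 4, columns in A, C, G, U order
#'   (T accepted and relabeled). Each row must sum to 1 (within 1e-6).
#' @param pseudo pseudocount mixed into the probabilities before the
#'   log-odds transform (default 0.01).
#' @return object of class `pwm`.
#' @export
pwm <- function(name, mat, pseudo = 0.01) {
  mat <- as.matrix(mat)
  if (!is.null(colnames(mat))) {
    colnames(mat) <- sub("T", "U", toupper(colnames(mat)))
    mat <- mat[, .RNA_BASES, drop = FALSE]
  } else {
    colnames(mat) <- .RNA_BASES
  }
  if (nrow(mat) < 4L) stop("PWM must have length >= 4", call. = FALSE)
  if (any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("PWM rows must sum to 1", call. = FALSE)
  }
  structure(list(name = name, matrix = mat, pseudo = pseudo), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: %d positions, consensus %s>\n",
              x$name, nrow(x$matrix), pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (highest-probability base per position)
#' @param x a `pwm`.
#' @return character string over A/C/G/U.
#' @export
pwm_consensus <- function(x) {
  paste(.RNA_BASES[apply(x$matrix, 1L, which.max)], collapse = "")
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections.
#' DNA alphabets are relabeled to RNA (T -> U).
#'
#' @param path path to a MEME minimal text file.
#' @param pseudo pseudocount passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_meme_pwm <- function(path, pseudo = 0.01) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF", lines)
  if (length(motif_idx) == 0L) stop("no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (mi in motif_idx) {
    name <- strsplit(trimws(lines[mi]), "\\s+")[[1L]][2L]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- hdr[hdr > mi][1L]
    if (is.na(hdr)) stop("MOTIF ", name, " lacks a letter-probability matrix",
                         call. = FALSE)
    w <- regmatches(lines[hdr], regexec("w=\\s*(\\d+)", lines[hdr]))[[1L]]
    rows <- list()
    i <- hdr + 1L
    while (i <= length(lines)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(tok))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    mat <- do.call(rbind, rows)
    if (length(w) == 2L && nrow(mat) != as.integer(w[2L])) {
      stop("MOTIF ", name, ": matrix has ", nrow(mat),
           " rows but header says w=", w[2L], call. = FALSE)
    }
    out[[name]] <- pwm(name, mat, pseudo = pseudo)
  }
  out
}

#' Write PWMs to a MEME minimal-format file
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_meme_pwm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$matrix)), con)
    writeLines(apply(p$matrix, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

## Per-position log-odds (vs uniform background) with pseudocount smoothing.
.pwm_logodds <- function(p) {
  q <- (p$matrix + p$pseudo / 4) / (1 + p$pseudo)
  log2(q / 0.25)
}

#' Scan sequences with a PWM at a fractional match threshold
#'
#' Slides the PWM over each sequence (single strand, transcript orientation)
#' and scores every window by its summed log-odds versus a uniform
#' background. The score is min-max normalized over the achievable window
#' scores, `score_fraction = (score - min) / (max - min)`, so a "80% match"
#' is robust to motif length and information content. Windows at or above
#' `threshold` are emitted, each centered on the window's middle nucleotide.
#' Windows containing characters outside A/C/G/U(T) are skipped.
#'
#' @param seqs character vector of sequences (names become `seq_id`; unnamed
#'   sequences are numbered).
#' @param pwm a `pwm` object.
#' @param threshold minimum `score_fraction`, inclusive (default 0.8).
#' @return data.frame with columns `seq_id`, `start` (1-based window start),
#'   `center_pos` (1-based), `score_fraction`, `pwm_name`.
#' @export
scan_pwm <- function(seqs, pwm, threshold = 0.8) {
  stopifnot(inherits(pwm, "pwm"), threshold > 0, threshold <= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lo <- .pwm_logodds(pwm)
  L <- nrow(lo)
  smin <- sum(apply(lo, 1L, min))
  smax <- sum(apply(lo, 1L, max))
  out <- lapply(names(seqs), function(id) {
    s <- .norm_rna(seqs[[id]])
    n <- nchar(s)
    if (n < L) return(NULL)
    code <- match(strsplit(s, "")[[1L]], .RNA_BASES)  # NA for ambiguity codes
    nw <- n - L + 1L
    score <- numeric(nw)
    valid <- rep(TRUE, nw)
    for (j in seq_len(L)) {
      b <- code[j:(j + nw - 1L)]
      bad <- is.na(b)
      valid <- valid & !bad
      b[bad] <- 1L
      score <- score + lo[j, b]
    }
    frac <- (score - smin) / (smax - smin)
    hit <- which(valid & frac >= threshold)
    if (length(hit) == 0L) return(NULL)
    data.frame(seq_id = id, start = hit,
               center_pos = hit + (L - 1L) %/% 2L,
               score_fraction = frac[hit], pwm_name = pwm$name,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seq_id = character(0), start = integer(0),
                      center_pos = integer(0), score_fraction = numeric(0),
                      pwm_name = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Count motif matches with exact-position de-duplication
#'
#' Matches of different PWMs centered at the same nucleotide of the same
#' sequence are counted once; matches at different centers (even off by one)
#' are counted separately.
#'
#' @param matches data.frame of matches (from one or several [scan_pwm()]
#'   calls row-bound together) with columns `seq_id` and `center_pos`.
#' @return integer total of distinct (sequence, center) matches.
#' @export
count_motifs_dedup <- function(matches) {
  if (is.null(matches) || nrow(matches) == 0L) return(0L)
  nrow(unique(matches[, c("seq_id", "center_pos")]))
}

#' Classify the polyadenylation signal in an upstream window
#'
#' Searches the window (normally the 10-30 nt upstream of the cleavage site)
#' for the canonical PAS hexamer and its top variants in priority order
#' AAUAAA > AUUAAA > AAUAUA; sequences lacking all three are `OTHER`.
#' Case- and T/U-insensitive.
#'
#' @param upstream_seq character vector of windows in transcript orientation
#'   (each at least 6 nt).
#' @return character vector of classes.
#' @export
classify_pas_hexamer <- function(upstream_seq) {
  if (any(nchar(upstream_seq) < 6L)) {
    stop("PAS window shorter than 6 nt", call. = FALSE)
  }
  s <- .norm_rna(upstream_seq)
  res <- rep("OTHER", length(s))
  res[grepl("AAUAUA", s, fixed = TRUE)] <- "AAUAUA"
  res[grepl("AUUAAA", s, fixed = TRUE)] <- "AUUAAA"
  res[grepl("AAUAAA", s, fixed = TRUE)] <- "AAUAAA"
  res
}

#' Nucleotide frequency metaprofile around anchors
#'
#' Computes per-position A/C/G/U frequencies across anchored sequences for
#' positions `-window .. +window` relative to each anchor (position 0 is the
#' anchor nucleotide; negative positions are upstream in transcript
#' orientation). Positions truncated at a sequence edge drop out of that
#' sequence's contribution; `n` reports per-position coverage.
#'
#' @param seqs character vector of strand-oriented sequences.
#' @param anchors integer vector of 1-based anchor positions within each
#'   sequence.
#' @param window half-width in nt (default 100).
#' @return data.frame with columns `position`, `A`, `C`, `G`, `U`, `n`.
#'   Frequencies sum to 1 at every position with coverage.
#' @export
nt_frequency_profile <- function(seqs, anchors, window = 100L) {
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  stopifnot(length(seqs) == length(anchors),
            all(anchors >= 1L), all(anchors <= nchar(seqs)))
  positions <- (-window):window
  counts <- matrix(0L, length(positions), 4L,
                   dimnames = list(NULL, .RNA_BASES))
  cov <- integer(length(positions))
  for (i in seq_along(seqs)) {
    ch <- strsplit(.norm_rna(seqs[[i]]), "")[[1L]]
    idx <- anchors[i] + positions
    ok <- idx >= 1L & idx <= length(ch)
    b <- match(ch[idx[ok]], .RNA_BASES)
    known <- !is.na(b)
    rows <- which(ok)[known]
    for (k in seq_along(rows)) {
      counts[rows[k], b[known][k]] <- counts[rows[k], b[known][k]] + 1L
    }
    cov[which(ok)[known]] <- cov[which(ok)[known]] + 1L
  }
  freq <- counts / ifelse(cov == 0L, NA_integer_, cov)
  data.frame(position = positions, freq, n = cov)
}

#' Positional motif density around anchors
#'
#' For each position relative to the anchor, the fraction of sequences with a
#' PWM match centered there (matches from [scan_pwm()] at the given
#' threshold), among sequences covering that position.
#'
#' @inheritParams nt_frequency_profile
#' @param pwm a `pwm` object.
#' @param threshold fractional match threshold (default 0.8).
#' @return data.frame with columns `position`, `density`, `n`.
#' @export
positional_motif_density <- function(seqs, anchors, pwm, threshold = 0.8,
                                     window = 100L) {
  stopifnot(length(seqs) == length(anchors))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  matches <- scan_pwm(seqs, pwm, threshold)
  positions <- (-window):window
  hits <- integer(length(positions))
  cov <- integer(length(positions))
  for (i in seq_along(seqs)) {
    idx <- anchors[i] + positions
    ok <- idx >= 1L & idx <= nchar(seqs[[i]])
    cov[ok] <- cov[ok] + 1L
    mi <- matches$center_pos[matches$seq_id == names(seqs)[i]]
    rel <- unique(mi - anchors[i])
    rel <- rel[rel >= -window & rel <= window]
    if (length(rel) > 0L) {
      j <- match(rel, positions)
      hits[j] <- hits[j] + 1L
    }
  }
  data.frame(position = positions,
             density = ifelse(cov == 0L, 0, hits / pmax(cov, 1L)),
             n = cov)
}

#' Compare a quantity between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test with normal approximation and continuity
#' correction, as used for uridine content and motif-frequency comparisons
#' between gene groups.
#'
#' @param values_a,values_b numeric vectors (each with at least 3 values).
#' @return named numeric vector `c(statistic, p)`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each group needs at least 3 values", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE,
                                     correct = TRUE))
  c(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Correlate per-gene motif counts with bypass change
#'
#' Spearman rank correlation over the genes present in both maps, testing
#' whether downstream motif load tracks the change in pA-site bypass.
#'
#' @param motif_counts named numeric/integer vector, gene -> motif count.
#' @param bypass_change named numeric vector, gene -> bypass change.
#' @return named numeric vector `c(rho, p)`. With degenerate (constant)
#'   ranks, `rho` is `NA` and a warning is raised.
#' @export
correlate_motif_with_bypass <- function(motif_counts, bypass_change) {
  genes <- intersect(names(motif_counts), names(bypass_change))
  if (length(genes) < 5L) {
    stop("fewer than 5 shared genes between motif counts and bypass changes",
         call. = FALSE)
  }
  x <- as.numeric(motif_counts[genes])
  y <- as.numeric(bypass_change[genes])
  if (sd(x) == 0 || sd(y) == 0) {
    warning("degenerate ranks (constant input); rho undefined")
    return(c(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}
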