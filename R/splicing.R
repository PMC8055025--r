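## Simplified cassette-exon PSI from junction counts, delta-PSI filtering,
## the union rule across comparisons and flanking-intron window extraction.

#' Cassette-exon PSI from junction counts
#'
#' `psi = (I/2) / (I/2 + S)`: inclusion junction counts are halved because an
#' included exon is supported by two junctions while skipping is supported by
#' one.
#'
#' @param inclusion_jc,skipping_jc non-negative junction read counts
#'   (vectorized).
#' @return psi in `[0, 1]`; `NA` where both counts are zero.
#' @export
exon_psi <- function(inclusion_jc, skipping_jc) {
  if (any(inclusion_jc < 0) || any(skipping_jc < 0)) {
    stop("negative junction counts", call. = FALSE)
  }
  ifelse(inclusion_jc + skipping_jc == 0, NA_real_,
         (inclusion_jc / 2) / (inclusion_jc / 2 + skipping_jc))
}

#' Delta-PSI with the junction-read / FDR / delta-PSI filter
#'
#' For each cassette exon, PSI is computed per replicate and delta-PSI is the
#' difference of condition means (condition B minus condition A). Pooled
#' inclusion/skipping counts feed a two-proportion test whose p-values are
#' Benjamini-Hochberg adjusted to an FDR. An event is called regulated when
#' it has more than `min_jc` junction reads in each condition, FDR below
#' `alpha`, and |delta-PSI| above `dpsi`.
#'
#' @param events data.frame with columns `gene_id`, `exon_start`, `exon_end`,
#'   `condition` (exactly two levels), `replicate`, `inclusion_jc`,
#'   `skipping_jc`.
#' @param min_jc pooled junction reads required per condition, strict
#'   (default 5: "more than 5").
#' @param dpsi |delta-PSI| cutoff, strict (default 0.3).
#' @param alpha FDR cutoff (default 0.05).
#' @return data.frame, one row per event: `gene_id`, `exon_start`,
#'   `exon_end`, `psi_a`, `psi_b`, `delta_psi`, `jc_a`, `jc_b`, `p`, `fdr`,
#'   `direction` (`included`/`excluded`), `regulated`.
#' @export
delta_psi_and_filter <- function(events, min_jc = 5L, dpsi = 0.3, alpha = 0.05) {
  conds <- sort(unique(as.character(events$condition)))
  if (length(conds) != 2L) stop("exactly two conditions required", call. = FALSE)
  key <- paste(events$gene_id, events$exon_start, events$exon_end, sep = "\r")
  out <- lapply(split(seq_len(nrow(events)), key), function(ii) {
    ev <- events[ii, , drop = FALSE]
    a <- ev[ev$condition == conds[1L], ]
    b <- ev[ev$condition == conds[2L], ]
    psi_a <- mean(exon_psi(a$inclusion_jc, a$skipping_jc), na.rm = TRUE)
    psi_b <- mean(exon_psi(b$inclusion_jc, b$skipping_jc), na.rm = TRUE)
    ia <- sum(a$inclusion_jc); sa <- sum(a$skipping_jc)
    ib <- sum(b$inclusion_jc); sb <- sum(b$skipping_jc)
    xa <- round(ia / 2); xb <- round(ib / 2)
    p <- if (xa + sa > 0 && xb + sb > 0) {
      suppressWarnings(prop.test(c(xa, xb), c(xa + sa, xb + sb)))$p.value
    } else NA_real_
    data.frame(gene_id = ev$gene_id[1L], exon_start = ev$exon_start[1L],
               exon_end = ev$exon_end[1L],
               psi_a = psi_a, psi_b = psi_b, delta_psi = psi_b - psi_a,
               jc_a = ia + sa, jc_b = ib + sb, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fdr <- p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$delta_psi > 0, "included", "excluded")
  res$regulated <- !is.na(res$fdr) & !is.na(res$delta_psi) &
    res$jc_a > min_jc & res$jc_b > min_jc &
    res$fdr < alpha & abs(res$delta_psi) > dpsi
  res
}

#' Union of regulated cassette exons across comparisons
#'
#' Events are keyed by (gene, exon interval); each union member records the
#' comparisons that called it and is flagged discordant when those
#' comparisons disagree on direction.
#'
#' @param per_comparison named list of data.frames (each the regulated subset
#'   of a [delta_psi_and_filter()] result, with `gene_id`, `exon_start`,
#'   `exon_end`, `direction`).
#' @return data.frame with `gene_id`, `exon_start`, `exon_end`, `direction`
#'   (or `"discordant"`), `comparisons` (comma-joined), `discordant`.
#' @export
union_regulated <- function(per_comparison) {
  if (length(per_comparison) == 0L) {
    return(data.frame(gene_id = character(0), exon_start = integer(0),
                      exon_end = integer(0), direction = character(0),
                      comparisons = character(0), discordant = logical(0)))
  }
  if (is.null(names(per_comparison))) {
    names(per_comparison) <- paste0("comparison", seq_along(per_comparison))
  }
  rows <- do.call(rbind, lapply(names(per_comparison), function(nm) {
    d <- per_comparison[[nm]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(gene_id = d$gene_id, exon_start = d$exon_start,
               exon_end = d$exon_end, direction = d$direction,
               comparison = nm, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(union_regulated(list()))
  }
  key <- paste(rows$gene_id, rows$exon_start, rows$exon_end, sep = "\r")
  out <- lapply(split(seq_len(nrow(rows)), key), function(ii) {
    r <- rows[ii, , drop = FALSE]
    dirs <- unique(r$direction)
    data.frame(gene_id = r$gene_id[1L], exon_start = r$exon_start[1L],
               exon_end = r$exon_end[1L],
               direction = if (length(dirs) == 1L) dirs else "discordant",
               comparisons = paste(sort(unique(r$comparison)), collapse = ","),
               discordant = length(dirs) > 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$exon_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flanking intronic windows of a cassette exon
#'
#' Extracts the `n`-nt intronic windows adjacent to the exon's two splice
#' sites: the window upstream of the 3' splice site (end of the upstream
#' intron) and the window downstream of the 5' splice site (start of the
#' downstream intron), both in transcript orientation (minus-strand windows
#' are reverse-complemented). Introns shorter than `n` yield truncated
#' windows whose realized length is recorded.
#'
#' @param exon length-2 numeric `[start, end)` of the cassette exon (0-based
#'   half-open genomic), which must be an interior exon of `tx`.
#' @param tx a `transcript`.
#' @param genome named `DNAStringSet`.
#' @param n window size in nt (default 100).
#' @return list with `upstream_seq`, `downstream_seq`, `upstream_coords`,
#'   `downstream_coords` (each `c(start, end)` genomic 0-based half-open)
#'   and `upstream_len`, `downstream_len`.
#' @export
flanking_intron_windows <- function(exon, tx, genome, n = 100L) {
  ex <- tx$exons
  i <- which(ex$start == exon[1L] & ex$end == exon[2L])
  if (length(i) != 1L) stop("exon not found in transcript", call. = FALSE)
  if (i == 1L || i == nrow(ex)) {
    stop("first/last exon has no flanking intron on one side", call. = FALSE)
  }
  prev <- ex[i - 1L, ]  # 5' neighbor in transcript orientation
  nxt <- ex[i + 1L, ]   # 3' neighbor
  if (tx$strand == "+") {
    up_intron <- c(prev$end, exon[1L])
    down_intron <- c(exon[2L], nxt$start)
    up_win <- c(max(up_intron[1L], up_intron[2L] - n), up_intron[2L])
    down_win <- c(down_intron[1L], min(down_intron[2L], down_intron[1L] + n))
  } else {
    up_intron <- c(exon[2L], prev$start)
    down_intron <- c(nxt$end, exon[1L])
    up_win <- c(up_intron[1L], min(up_intron[2L], up_intron[1L] + n))
    down_win <- c(max(down_intron[1L], down_intron[2L] - n), down_intron[2L])
  }
  get_seq <- function(win) {
    if (win[2L] <= win[1L]) return("")
    s <- Biostrings::subseq(genome[[tx$chrom]], start = win[1L] + 1L, end = win[2L])
    if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }
  list(upstream_seq = get_seq(up_win), downstream_seq = get_seq(down_win),
       upstream_coords = up_win, downstream_coords = down_win,
       upstream_len = max(0L, up_win[2L] - up_win[1L]),
       downstream_len = max(0L, down_win[2L] - down_win[1L]))
}
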