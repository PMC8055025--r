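## Gene models: annotation parsing, 3'-end structure classification,
## unique 3'UTR derivation and categorized pA sites.

#' Construct a transcript
#'
#' A transcript is a minimal gene-model record: an id, its gene, chromosome,
#' strand, an exon table and optionally the genomic coordinate where the CDS
#' ends (the 3'UTR then runs from `cds_end` to the transcript 3' terminus).
#'
#' @param id transcript identifier.
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame (or matrix) with columns `start`, `end`: genomic
#'   0-based half-open intervals. They may be given in any order; they are
#'   stored sorted 5' to 3' in transcript orientation and must not overlap.
#' @param cds_end optional genomic 0-based coordinate of the 3' boundary of
#'   the coding region (the position where the 3'UTR starts): for `+` strand
#'   transcripts the half-open end of the CDS, for `-` strand its start.
#' @return an object of class `transcript`.
#' @export
transcript <- function(id, gene_id, chrom, strand, exons, cds_end = NA_integer_) {
  .check_strand(strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("transcript '", id, "' has zero exons", call. = FALSE)
  if (any(exons$end <= exons$start)) {
    stop("transcript '", id, "' has an empty or inverted exon", call. = FALSE)
  }
  o <- order(exons$start)
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("transcript '", id, "' has overlapping exons", call. = FALSE)
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(
    list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds_end = as.integer(cds_end)),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s)>\n",
              x$id, x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

## 0-based genomic coordinate of the final transcribed nucleotide (strand-aware).
pa_site_pos <- function(tx) {
  if (tx$strand == "+") max(tx$exons$end) - 1L else min(tx$exons$start)
}

## Last exon (3'-most in transcript orientation) as a one-row data.frame.
last_exon <- function(tx) {
  tx$exons[nrow(tx$exons), , drop = FALSE]
}

## Identifier of the 5' edge of the last exon (strand-aware); used to decide
## whether two termini live in "the same" last exon.
.last_exon_start5 <- function(tx) {
  le <- last_exon(tx)
  if (tx$strand == "+") le$start else le$end
}

## Project a genomic coordinate onto the transcript 5'->3' axis so larger
## values are more 3'.
.downstream_coord <- function(pos, strand) {
  if (strand == "+") pos else -pos
}

#' Parse a GTF annotation into a gene model set
#'
#' Reads exon (and optionally CDS) features and assembles per-gene transcript
#' models. GTF coordinates (1-based closed) are converted to the internal
#' 0-based half-open convention. Every gene is classified by its 3'-end
#' structure via [classify_apa_structure()].
#'
#' @param gtf_path path to a GTF file whose exon features carry
#'   `transcript_id` and `gene_id` attributes.
#' @param fasta_path optional path to the matching genome FASTA; when given it
#'   is loaded with `Biostrings::readDNAStringSet` and attached as `$genome`.
#' @param merge_window termini closer than this many nt are merged into one pA
#'   site before structure classification (default 25, the 3'-seq clustering
#'   window).
#' @return an object of class `gene_model_set`: a list with `genes` (named
#'   list of gene_id -> list of `transcript`), `structure` (named character:
#'   SINGLE/TUTR/ALE/MIXED) and optionally `genome`.
#' @export
parse_annotation <- function(gtf_path, fasta_path = NULL, merge_window = 25L) {
  lines <- readLines(gtf_path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no feature lines in ", gtf_path, call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", gtf_path,
         " (expected 9 tab-separated fields, got ", nf[which(nf != 9L)[1L]], ")",
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  feat <- m[, 3L]
  sel <- feat %in% c("exon", "CDS")
  if (!any(sel)) stop("no exon features in ", gtf_path, call. = FALSE)
  m <- m[sel, , drop = FALSE]
  line_no <- idx[sel]
  start <- suppressWarnings(as.integer(m[, 4L])) - 1L  # to 0-based half-open
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- line_no[which(is.na(start) | is.na(end))[1L]]
    stop("malformed GTF line ", bad, ": non-numeric coordinates", call. = FALSE)
  }
  strand <- m[, 7L]
  if (!all(strand %in% c("+", "-"))) {
    bad <- line_no[which(!strand %in% c("+", "-"))[1L]]
    stop("malformed GTF line ", bad, ": strand must be + or -", call. = FALSE)
  }
  attr_get <- function(attrs, key) {
    pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
    hit <- regmatches(attrs, regexec(pat, attrs))
    vapply(hit, function(h) if (length(h) == 2L) h[2L] else NA_character_, "")
  }
  tx_id <- attr_get(m[, 9L], "transcript_id")
  gene_id <- attr_get(m[, 9L], "gene_id")
  if (anyNA(tx_id) || anyNA(gene_id)) {
    bad <- line_no[which(is.na(tx_id) | is.na(gene_id))[1L]]
    stop("malformed GTF line ", bad, ": missing transcript_id or gene_id attribute",
         call. = FALSE)
  }

  df <- data.frame(chrom = m[, 1L], feature = m[, 3L], start = start, end = end,
                   strand = strand, tx_id = tx_id, gene_id = gene_id,
                   stringsAsFactors = FALSE)
  exon_df <- df[df$feature == "exon", , drop = FALSE]
  cds_df <- df[df$feature == "CDS", , drop = FALSE]

  genes <- list()
  for (tid in unique(df$tx_id)) {
    ex <- exon_df[exon_df$tx_id == tid, , drop = FALSE]
    if (nrow(ex) == 0L) {
      warning("transcript '", tid, "' has zero exon features; skipped")
      next
    }
    gid <- ex$gene_id[1L]
    str <- ex$strand[1L]
    cds_end <- NA_integer_
    cd <- cds_df[cds_df$tx_id == tid, , drop = FALSE]
    if (nrow(cd) > 0L) {
      cds_end <- if (str == "+") max(cd$end) else min(cd$start)
    }
    tx <- transcript(tid, gid, ex$chrom[1L], str,
                     ex[, c("start", "end")], cds_end = cds_end)
    genes[[gid]] <- c(genes[[gid]], list(tx))
  }

  structure_map <- vapply(genes, classify_apa_structure,
                          merge_window = merge_window, FUN.VALUE = "")
  gms <- structure(
    list(genes = genes, structure = structure_map, genome = NULL),
    class = "gene_model_set"
  )
  if (!is.null(fasta_path)) {
    gms$genome <- Biostrings::readDNAStringSet(fasta_path)
    names(gms$genome) <- sub("\\s.*$", "", names(gms$genome))
  }
  gms
}

#' @export
print.gene_model_set <- function(x, ...) {
  tab <- table(factor(x$structure, levels = c("SINGLE", "TUTR", "ALE", "MIXED")))
  cat(sprintf("<gene_model_set: %d genes (%s)>\n", length(x$genes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write a gene model set to GTF
#'
#' Emits one exon line per exon (1-based closed coordinates) with
#' `gene_id`/`transcript_id` attributes, so that [parse_annotation()] round
#' trips intervals and strands exactly.
#'
#' @param gms a `gene_model_set`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(gms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (gid in names(gms$genes)) {
    for (tx in gms$genes[[gid]]) {
      ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
      lines <- sprintf(
        "%s\tapabypass\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        tx$chrom, ex$start + 1L, ex$end, tx$strand, gid, tx$id)
      writeLines(lines, con)
      if (!is.na(tx$cds_end)) {
        ## a 1-nt CDS placeholder carrying the 3' CDS boundary
        cs <- if (tx$strand == "+") tx$cds_end - 1L else tx$cds_end
        writeLines(sprintf(
          "%s\tapabypass\tCDS\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          tx$chrom, cs + 1L, cs + 1L, tx$strand, gid, tx$id), con)
      }
    }
  }
  invisible(path)
}

## Merged pA sites of a gene: termini within `merge_window` nt are collapsed.
## Returns a data.frame (pos, rank, tx_ids) sorted 5'->3' in transcript
## orientation; the representative position is the 3'-most terminus of the
## group (the longest isoform's cleavage site).
.merged_termini <- function(txs, merge_window = 25L) {
  strand <- txs[[1L]]$strand
  pos <- vapply(txs, pa_site_pos, 0L)
  grp <- .merge_positions(pos, merge_window)
  reps <- vapply(split(pos, grp), function(p) {
    if (strand == "+") max(p) else min(p)
  }, 0L)
  members <- split(vapply(txs, `[[`, "", "id"), grp)
  down <- .downstream_coord(reps, strand)
  o <- order(down)
  data.frame(pos = as.integer(reps[o]), rank = seq_along(o),
             tx_ids = I(unname(members[o])), stringsAsFactors = FALSE)
}

## Transcript whose terminus is the 3'-most within a merged pA group.
.group_rep_tx <- function(txs, tx_ids, strand) {
  cand <- Filter(function(t) t$id %in% tx_ids, txs)
  down <- vapply(cand, function(t) .downstream_coord(pa_site_pos(t), strand), 0)
  cand[[which.max(down)]]
}

#' Classify a gene's 3'-end structure
#'
#' A gene is `SINGLE` when it has one distinct 3' terminus (after merging
#' termini closer than `merge_window`), `TUTR` when all termini lie in one
#' shared last exon (tandem 3'UTRs), `ALE` when every terminus lies in a
#' distinct last exon, and `MIXED` otherwise.
#'
#' @param txs list of `transcript` objects of one gene.
#' @param merge_window terminus merge distance in nt (default 25).
#' @return one of `"SINGLE"`, `"TUTR"`, `"ALE"`, `"MIXED"`.
#' @export
classify_apa_structure <- function(txs, merge_window = 25L) {
  stopifnot(length(txs) >= 1L)
  strand <- txs[[1L]]$strand
  mt <- .merged_termini(txs, merge_window)
  if (nrow(mt) == 1L) return("SINGLE")
  le5 <- vapply(seq_len(nrow(mt)), function(i) {
    .last_exon_start5(.group_rep_tx(txs, mt$tx_ids[[i]], strand))
  }, 0)
  n_exon <- length(unique(le5))
  if (n_exon == 1L) return("TUTR")
  if (n_exon == nrow(mt)) return("ALE")
  "MIXED"
}

#' Extract categorized pA sites of a gene
#'
#' Each merged 3' terminus becomes one pA site with a strand-aware 5'->3'
#' rank and a category reflecting the gene structure: the single terminus of
#' a `SINGLE` gene is `SINGLE_END`; internal/most-distal termini of a `TUTR`
#' gene are `TUTR_INTERNAL`/`TUTR_DISTAL`; internal/most-distal termini of an
#' `ALE` gene are `PROX_ALE_END`/`DIST_ALE_END`. In `MIXED` genes a terminus
#' sharing its last exon with another terminus is tandem-type
#' (`TUTR_INTERNAL`, or `TUTR_DISTAL` if gene-distal-most), otherwise
#' ALE-type (`PROX_ALE_END`, or `DIST_ALE_END` if gene-distal-most).
#'
#' @inheritParams classify_apa_structure
#' @param structure the gene's structure label; computed when `NULL`.
#' @return data.frame with columns `gene_id`, `pos`, `category`, `rank`.
#' @export
extract_pa_sites <- function(txs, structure = NULL, merge_window = 25L) {
  strand <- txs[[1L]]$strand
  gid <- txs[[1L]]$gene_id
  structure <- structure %||% classify_apa_structure(txs, merge_window)
  mt <- .merged_termini(txs, merge_window)
  n <- nrow(mt)
  cat_v <- character(n)
  if (structure == "SINGLE") {
    cat_v <- "SINGLE_END"
  } else if (structure == "TUTR") {
    cat_v <- c(rep("TUTR_INTERNAL", n - 1L), "TUTR_DISTAL")
  } else if (structure == "ALE") {
    cat_v <- c(rep("PROX_ALE_END", n - 1L), "DIST_ALE_END")
  } else {
    le5 <- vapply(seq_len(n), function(i) {
      .last_exon_start5(.group_rep_tx(txs, mt$tx_ids[[i]], strand))
    }, 0)
    shared <- table(le5)
    for (i in seq_len(n)) {
      tandem <- shared[[as.character(le5[i])]] > 1L
      cat_v[i] <- if (i == n) {
        if (tandem) "TUTR_DISTAL" else "DIST_ALE_END"
      } else {
        if (tandem) "TUTR_INTERNAL" else "PROX_ALE_END"
      }
    }
  }
  data.frame(gene_id = gid, pos = mt$pos, category = cat_v, rank = mt$rank,
             stringsAsFactors = FALSE)
}

## 3'UTR of one transcript as a genomic interval [start, end). With an
## annotated CDS the UTR runs from cds_end to the terminus; otherwise the
## full last exon stands in.
.tx_utr3 <- function(tx, use_cds = TRUE) {
  le <- last_exon(tx)
  if (use_cds && !is.na(tx$cds_end)) {
    if (tx$strand == "+") {
      c(start = tx$cds_end, end = max(tx$exons$end))
    } else {
      c(start = min(tx$exons$start), end = tx$cds_end)
    }
  } else {
    c(start = le$start, end = le$end)
  }
}

#' Derive the unique 3'UTRs of an ALE or MIXED gene
#'
#' Among isoform 3'UTRs sharing the same (strand-aware) start site, the
#' longest is kept. A kept 3'UTR must additionally extend beyond the exonic
#' sequence of at least one isoform with a different 3'UTR start — a 3'UTR
#' lying entirely within exonic sequence of every other isoform is a nested
#' tandem extension, not an ALE-specific segment, and is dropped. Output is
#' sorted 5'->3' by the rank of the merged pA site each UTR ends at.
#'
#' @inheritParams classify_apa_structure
#' @param structure gene structure; must be `ALE` or `MIXED`.
#' @param use_cds when `TRUE` (default) the 3'UTR starts at the annotated CDS
#'   end where present; otherwise the full last exon is used.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `role` (`NA` until [assign_utr_roles()]), `source_pa` (the pA
#'   rank). If fewer than two unique 3'UTRs survive, the result carries
#'   attribute `unquantifiable = TRUE` and a warning is raised.
#' @export
extract_unique_3utrs <- function(txs, structure = NULL, use_cds = TRUE,
                                 merge_window = 25L) {
  strand <- txs[[1L]]$strand
  gid <- txs[[1L]]$gene_id
  chrom <- txs[[1L]]$chrom
  structure <- structure %||% classify_apa_structure(txs, merge_window)
  if (!structure %in% c("ALE", "MIXED")) {
    stop("unique 3'UTR extraction applies to ALE or MIXED genes; gene '",
         gid, "' is ", structure, call. = FALSE)
  }
  utr <- t(vapply(txs, .tx_utr3, c(start = 0, end = 0), use_cds = use_cds))
  u5 <- if (strand == "+") utr[, "start"] else utr[, "end"]
  len <- utr[, "end"] - utr[, "start"]
  keep_idx <- vapply(split(seq_along(txs), u5), function(ii) {
    ii[which.max(len[ii])]
  }, 0L)

  mt <- .merged_termini(txs, merge_window)
  tx_rank <- setNames(rep(mt$rank, lengths(mt$tx_ids)), unlist(mt$tx_ids))

  out <- lapply(keep_idx, function(i) {
    this <- .to_iranges(utr[i, "start"], utr[i, "end"])
    others <- which(u5 != u5[i])
    if (length(others) > 0L) {
      covered <- vapply(others, function(j) {
        ex <- txs[[j]]$exons
        left <- IRanges::setdiff(this, .to_iranges(ex$start, ex$end))
        sum(IRanges::width(left)) == 0L
      }, NA)
      if (all(covered)) return(NULL)  # nested inside every other isoform
    }
    data.frame(gene_id = gid, chrom = chrom, strand = strand,
               start = as.integer(utr[i, "start"]), end = as.integer(utr[i, "end"]),
               role = NA_character_, source_pa = unname(tx_rank[txs[[i]]$id]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      role = character(0), source_pa = integer(0))
  }
  res <- res[order(res$source_pa), , drop = FALSE]
  rownames(res) <- NULL
  if (nrow(res) < 2L) {
    warning("gene '", gid, "' yields fewer than two unique 3'UTRs; ",
            "flagged unquantifiable")
    attr(res, "unquantifiable") <- TRUE
  }
  res
}

#' Assign proximal/universal/distal roles to unique 3'UTRs
#'
#' The dominant unique 3'UTR (highest control count) is labeled `UNIVERSAL`;
#' UTRs 5' of it are `PROXIMAL` and UTRs 3' of it are `DISTAL`.
#'
#' @param utrs data.frame from [extract_unique_3utrs()].
#' @param dominant_rank `source_pa` rank of the dominant UTR.
#' @return `utrs` with the `role` column filled.
#' @export
assign_utr_roles <- function(utrs, dominant_rank) {
  if (!dominant_rank %in% utrs$source_pa) {
    stop("dominant_rank ", dominant_rank, " not among source_pa ranks", call. = FALSE)
  }
  utrs$role <- ifelse(utrs$source_pa < dominant_rank, "PROXIMAL",
                      ifelse(utrs$source_pa == dominant_rank, "UNIVERSAL", "DISTAL"))
  utrs
}

#' Write unique 3'UTR intervals as BED6
#'
#' Names are `gene_id|role` (or `gene_id|rank<k>` while roles are unassigned);
#' coordinates stay 0-based half-open per the BED dialect.
#'
#' @param utrs data.frame of unique 3'UTRs (possibly several genes).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_utr_bed <- function(utrs, path) {
  name <- ifelse(is.na(utrs$role),
                 paste0(utrs$gene_id, "|rank", utrs$source_pa),
                 paste0(utrs$gene_id, "|", utrs$role))
  bed <- data.frame(utrs$chrom, utrs$start, utrs$end, name, 0L, utrs$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
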