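## Gene-level orchestration helpers tying the modules together: from raw
## read ends to per-gene ALE usage and bypass tables.

#' Unique 3'UTR table for all quantifiable (ALE/MIXED) genes
#'
#' @param gms a `gene_model_set`.
#' @param use_cds forwarded to [extract_unique_3utrs()].
#' @param structures gene structures to include; quantification defaults to
#'   ALE genes only (MIXED genes are excluded from usage statistics).
#' @return data.frame of unique 3'UTRs across genes; genes yielding fewer
#'   than two UTRs are dropped (they are unquantifiable).
#' @export
gene_set_utrs <- function(gms, use_cds = TRUE, structures = "ALE") {
  gids <- names(gms$genes)[gms$structure %in% structures]
  out <- lapply(gids, function(g) {
    res <- suppressWarnings(
      extract_unique_3utrs(gms$genes[[g]], gms$structure[[g]], use_cds = use_cds))
    if (isTRUE(attr(res, "unquantifiable"))) return(NULL)
    res
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), role = character(0),
                      source_pa = integer(0))
  }
  res
}

#' Per-replicate UTR count maps from raw 3'-seq read ends
#'
#' Clusters read ends within the 25-bp window (per sample and replicate) and
#' assigns cluster counts to the unique 3'UTRs of every quantifiable gene.
#'
#' @param gms a `gene_model_set`.
#' @param ends data.frame of read ends (`chrom`, `strand`, `pos`, `weight`,
#'   `sample`, `replicate`).
#' @param window clustering window (default 25).
#' @param slop downstream assignment slop (default 25).
#' @param utrs optional precomputed [gene_set_utrs()] table.
#' @return nested list: `counts[[sample]][[replicate]]` is a data.frame with
#'   `gene_id`, `source_pa`, `count`.
#' @export
utr_count_maps <- function(gms, ends, window = 25L, slop = 25L, utrs = NULL) {
  utrs <- utrs %||% gene_set_utrs(gms)
  clusters <- cluster_read_ends(ends, window = window)
  out <- list()
  for (s in unique(clusters$sample)) {
    cs <- clusters[clusters$sample == s, , drop = FALSE]
    out[[s]] <- lapply(sort(unique(cs$replicate)), function(r) {
      cr <- cs[cs$replicate == r, , drop = FALSE]
      a <- assign_counts(cr, utrs, slop = slop)$assigned
      a[, c("gene_id", "source_pa", "count"), drop = FALSE]
    })
  }
  out
}

#' Per-gene ALE usage ratios and significance calls
#'
#' Runs [ale_usage_ratio_and_test()] for every gene present in the control
#' count maps.
#'
#' @param counts nested count maps from [utr_count_maps()].
#' @param control,sample condition names indexing `counts`.
#' @param alpha,fold significance cutoffs (defaults 0.05 and 2).
#' @return data.frame, one row per gene.
#' @export
ale_usage_table <- function(counts, control, sample, alpha = 0.05, fold = 2) {
  per_gene <- function(reps, g) {
    lapply(reps, function(d) d[d$gene_id == g, c("source_pa", "count"), drop = FALSE])
  }
  genes <- sort(unique(unlist(lapply(counts[[control]], function(d) d$gene_id))))
  out <- lapply(genes, function(g) {
    ale_usage_ratio_and_test(per_gene(counts[[control]], g),
                             per_gene(counts[[sample]], g),
                             gene_id = g, alpha = alpha, fold = fold)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-gene bypass scores and ratios between two conditions
#'
#' Pools replicate counts per condition, computes the bypass score of every
#' internal (non-distal) pA rank in both conditions and the bypass /
#' unbypassed ratios of sample versus control.
#'
#' @inheritParams ale_usage_table
#' @return data.frame with `gene_id`, `pa_rank`, `score_control`,
#'   `score_sample`, `bypass_ratio`, `unbypassed_ratio`.
#' @export
bypass_table <- function(counts, control, sample) {
  pool <- function(reps) {
    all <- do.call(rbind, reps)
    agg <- tapply(all$count, list(all$gene_id, all$source_pa), sum)
    agg[is.na(agg)] <- 0
    agg
  }
  cm <- pool(counts[[control]])
  sm <- pool(counts[[sample]])
  genes <- intersect(rownames(cm), rownames(sm))
  all_ranks <- sort(as.integer(colnames(cm)))
  out <- list()
  for (g in genes) {
    cv_all <- as.numeric(cm[g, as.character(all_ranks)])
    sv_all <- as.numeric(sm[g, as.character(all_ranks)])
    ## the gene's own pA ranks: up to the most distal rank with any signal
    hi <- max(which(cv_all + sv_all > 0), 1L)
    ranks <- all_ranks[seq_len(hi)]
    cv <- cv_all[seq_len(hi)]
    sv <- sv_all[seq_len(hi)]
    if (length(ranks) < 2L) next
    for (k in seq_along(ranks)[-length(ranks)]) {
      sc <- as.numeric(bypass_score(cv, k))
      ss <- as.numeric(bypass_score(sv, k))
      br <- bypass_ratios(ss, sc)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, pa_rank = ranks[k], score_control = sc, score_sample = ss,
        bypass_ratio = unname(br["bypass_ratio"]),
        unbypassed_ratio = unname(br["unbypassed_ratio"]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), pa_rank = integer(0),
                      score_control = numeric(0), score_sample = numeric(0),
                      bypass_ratio = numeric(0), unbypassed_ratio = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' psi matrix from a transcript-abundance table
#'
#' Computes psi for every two-pA-site TUTR/ALE gene in each sample and
#' assembles the [build_psi_matrix()] result. Gene expression is the summed
#' transcript abundance.
#'
#' @param gms a `gene_model_set`.
#' @param abundance data.frame with `transcript_id`, `sample`, `TPM`.
#' @param samples ordered sample (timepoint) labels; defaults to order of
#'   appearance.
#' @param min_expression expression mask threshold (default 1).
#' @param merge_window terminus merge distance (default 25).
#' @return a `psi_matrix`.
#' @export
psi_matrix_from_abundance <- function(gms, abundance, samples = NULL,
                                      min_expression = 1, merge_window = 25L) {
  samples <- samples %||% unique(abundance$sample)
  gids <- names(gms$genes)[gms$structure %in% c("TUTR", "ALE")]
  two_site <- gids[vapply(gids, function(g) {
    nrow(.merged_termini(gms$genes[[g]], merge_window)) == 2L
  }, NA)]
  psi_by_sample <- list()
  expr <- matrix(0, length(two_site), length(samples),
                 dimnames = list(two_site, samples))
  for (s in samples) {
    ab <- abundance[abundance$sample == s, , drop = FALSE]
    v <- setNames(ab$TPM, ab$transcript_id)
    psis <- vapply(two_site, function(g) {
      txs <- gms$genes[[g]]
      ids <- vapply(txs, `[[`, "", "id")
      expr[g, s] <<- sum(v[intersect(ids, names(v))])
      p <- compute_psi(v[intersect(ids, names(v))], txs, merge_window)
      as.numeric(p)
    }, 0)
    psi_by_sample[[s]] <- psis
  }
  build_psi_matrix(psi_by_sample, expr, gms$structure,
                   min_expression = min_expression)
}
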