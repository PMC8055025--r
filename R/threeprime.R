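## 3'-seq quantification: read-end clustering, count assignment to unique
## 3'UTRs, ALE usage / usage-ratio statistics and pA-site bypass scores.

#' Cluster 3'-seq read ends within a fixed window
#'
#' Greedy summit-first clustering: the highest-weight unclustered position is
#' taken as a cluster summit, all positions on the same chromosome and strand
#' within `window/2` nt are absorbed and their weights summed, and the
#' procedure repeats. Weight ties are broken toward the leftmost coordinate,
#' so the result is deterministic.
#'
#' @param ends data.frame with columns `chrom`, `strand`, `pos` (0-based
#'   genomic position of a read 3' terminus) and `weight` (non-negative).
#'   Optional columns `sample` and `replicate` are treated as additional
#'   grouping keys and carried through.
#' @param window clustering window in nt (default 25).
#' @return data.frame with columns (`sample`, `replicate` if present,)
#'   `chrom`, `strand`, `summit_pos`, `count`.
#' @export
cluster_read_ends <- function(ends, window = 25L) {
  stopifnot(window >= 1L)
  req <- c("chrom", "strand", "pos", "weight")
  if (!all(req %in% names(ends))) {
    stop("ends must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(ends$weight < 0)) stop("negative read-end weight", call. = FALSE)
  extra <- intersect(c("sample", "replicate"), names(ends))
  empty <- ends[0L, c(extra, "chrom", "strand", "pos", "weight"), drop = FALSE]
  names(empty)[names(empty) == "pos"] <- "summit_pos"
  names(empty)[names(empty) == "weight"] <- "count"
  if (nrow(ends) == 0L) return(empty)
  .check_strand(ends$strand)

  key <- do.call(paste, c(ends[c(extra, "chrom", "strand")], sep = "\r"))
  half <- window / 2
  out <- lapply(split(seq_len(nrow(ends)), key), function(ii) {
    sub <- ends[ii, , drop = FALSE]
    agg <- tapply(sub$weight, sub$pos, sum)
    pos <- as.integer(names(agg))
    w <- as.numeric(agg)
    o <- order(pos)
    pos <- pos[o]; w <- w[o]
    active <- rep(TRUE, length(pos))
    summits <- integer(0); counts <- numeric(0)
    while (any(active)) {
      cand <- which(active)
      i <- cand[which.max(w[cand])]  # ties -> leftmost (positions sorted)
      take <- active & abs(pos - pos[i]) <= half
      summits <- c(summits, pos[i])
      counts <- c(counts, sum(w[take]))
      active <- active & !take
    }
    o2 <- order(summits)
    cbind(sub[rep(1L, length(summits)), c(extra, "chrom", "strand"), drop = FALSE],
          data.frame(summit_pos = summits[o2], count = counts[o2]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[do.call(order, res[c(extra, "chrom", "strand", "summit_pos")]), , drop = FALSE]
}

#' Assign 3'-seq clusters to unique 3'UTRs
#'
#' A cluster is assigned to a unique 3'UTR when its summit falls within the
#' UTR interval extended by `slop` nt downstream (strand-aware), absorbing
#' cleavage heterogeneity past the annotated terminus. A summit matching UTRs
#' of two genes goes to the one whose 3' terminus is nearer; unmatched
#' clusters are reported unassigned.
#'
#' @param clusters data.frame from [cluster_read_ends()].
#' @param utrs data.frame of unique 3'UTRs (several genes allowed), as from
#'   [extract_unique_3utrs()].
#' @param slop downstream extension in nt (default 25).
#' @return list with `assigned` (data.frame `gene_id`, `source_pa`, `role`,
#'   `count`, plus `sample`/`replicate` when present) and `unassigned` (the
#'   unmatched cluster rows).
#' @export
assign_counts <- function(clusters, utrs, slop = 25L) {
  extra <- intersect(c("sample", "replicate"), names(clusters))
  n <- nrow(clusters)
  hit_gene <- rep(NA_character_, n)
  hit_rank <- rep(NA_integer_, n)
  hit_role <- rep(NA_character_, n)
  if (n > 0L && nrow(utrs) > 0L) {
    ext_start <- ifelse(utrs$strand == "+", utrs$start, utrs$start - slop)
    ext_end <- ifelse(utrs$strand == "+", utrs$end + slop, utrs$end)
    term <- ifelse(utrs$strand == "+", utrs$end - 1L, utrs$start)
    for (i in seq_len(n)) {
      ok <- which(utrs$chrom == clusters$chrom[i] &
                  utrs$strand == clusters$strand[i] &
                  clusters$summit_pos[i] >= ext_start &
                  clusters$summit_pos[i] < ext_end)
      if (length(ok) == 0L) next
      if (length(unique(utrs$gene_id[ok])) > 1L) {
        ok <- ok[order(abs(term[ok] - clusters$summit_pos[i]))]
        message("cluster at ", clusters$chrom[i], ":", clusters$summit_pos[i],
                " overlaps UTRs of multiple genes; assigned to nearer terminus (",
                utrs$gene_id[ok[1L]], ")")
      }
      j <- ok[1L]
      hit_gene[i] <- utrs$gene_id[j]
      hit_rank[i] <- utrs$source_pa[j]
      hit_role[i] <- utrs$role[j]
    }
  }
  hit <- !is.na(hit_gene)
  assigned <- cbind(clusters[hit, extra, drop = FALSE],
                    data.frame(gene_id = hit_gene[hit], source_pa = hit_rank[hit],
                               role = hit_role[hit], count = clusters$count[hit],
                               stringsAsFactors = FALSE))
  if (nrow(assigned) > 0L) {
    key_cols <- c(extra, "gene_id", "source_pa", "role")
    key <- do.call(paste, c(assigned[key_cols], sep = "\r"))
    agg <- tapply(assigned$count, key, sum)
    first <- assigned[!duplicated(key), key_cols, drop = FALSE]
    first$count <- as.numeric(agg[do.call(paste, c(first[key_cols], sep = "\r"))])
    assigned <- first
    rownames(assigned) <- NULL
  }
  list(assigned = assigned, unassigned = clusters[!hit, , drop = FALSE])
}

#' ALE usage from role-wise 3'-seq counts
#'
#' ALE usage is the sum of counts on the universal and distal unique 3'UTRs
#' divided by the sum of counts on the universal and proximal unique 3'UTRs:
#' `(U + D) / (U + P)`. It is undefined (`NA`) when `U + P` is zero.
#'
#' @param counts numeric counts, one per unique 3'UTR.
#' @param roles character vector parallel to `counts` with values
#'   `PROXIMAL`, `UNIVERSAL`, `DISTAL`.
#' @return the ALE usage, or `NA` when undefined.
#' @export
ale_usage <- function(counts, roles) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  stopifnot(length(counts) == length(roles),
            all(roles %in% c("PROXIMAL", "UNIVERSAL", "DISTAL")))
  U <- sum(counts[roles == "UNIVERSAL"])
  P <- sum(counts[roles == "PROXIMAL"])
  D <- sum(counts[roles == "DISTAL"])
  if (U + P == 0) return(NA_real_)
  (U + D) / (U + P)
}

#' ALE usage ratio between sample and control with a two-way ANOVA call
#'
#' The dominant unique 3'UTR is the one with the highest pooled control
#' count; it is labeled `UNIVERSAL` and the remaining UTRs become
#' `PROXIMAL`/`DISTAL` by position. ALE usage is computed per replicate, the
#' usage ratio is `mean(sample usages) / mean(control usages)`, and a two-way
#' ANOVA on `log2(count + 1)` with factors condition and UTR tests the
#' condition-by-UTR interaction (the isoform-shift term). A gene is called
#' significant when the interaction p-value is below `alpha` and the usage
#' ratio differs at least `fold`-fold in either direction.
#'
#' @param control_reps,sample_reps lists (one element per replicate) of
#'   data.frames with columns `source_pa` and `count` for one gene.
#' @param gene_id gene identifier carried into the result.
#' @param alpha significance level (default 0.05).
#' @param fold fold-change cutoff (default 2).
#' @return one-row data.frame: `gene_id`, `usage_control`, `usage_sample`,
#'   `usage_ratio`, `p_value`, `significant`, `dominant_rank`.
#' @export
ale_usage_ratio_and_test <- function(control_reps, sample_reps,
                                     gene_id = NA_character_,
                                     alpha = 0.05, fold = 2) {
  stopifnot(length(control_reps) >= 1L, length(sample_reps) >= 1L)
  ranks <- sort(unique(unlist(lapply(c(control_reps, sample_reps),
                                     function(d) d$source_pa))))
  mat <- function(reps) {
    vapply(reps, function(d) {
      v <- setNames(rep(0, length(ranks)), ranks)
      v[as.character(d$source_pa)] <- d$count
      v
    }, numeric(length(ranks)))
  }
  cm <- mat(control_reps)  # ranks x reps
  sm <- mat(sample_reps)
  pooled <- rowSums(cm)
  dom <- ranks[which.max(pooled)]
  roles <- ifelse(ranks < dom, "PROXIMAL", ifelse(ranks == dom, "UNIVERSAL", "DISTAL"))
  usage_c <- apply(cm, 2L, ale_usage, roles = roles)
  usage_s <- apply(sm, 2L, ale_usage, roles = roles)
  uc <- mean(usage_c, na.rm = TRUE)
  us <- mean(usage_s, na.rm = TRUE)
  ratio <- if (is.finite(uc) && uc > 0) us / uc else NA_real_

  p <- NA_real_
  if (ncol(cm) >= 2L && ncol(sm) >= 2L && length(ranks) >= 2L) {
    df <- data.frame(
      y = log2(c(as.vector(cm), as.vector(sm)) + 1),
      condition = factor(rep(c("control", "sample"), c(length(cm), length(sm)))),
      utr = factor(rep(rep(ranks, ncol(cm) + ncol(sm))))
    )
    fit <- aov(y ~ condition * utr, data = df)
    tab <- summary(fit)[[1L]]
    row <- grep("condition:utr", rownames(tab))
    if (length(row) == 1L) p <- tab[row, "Pr(>F)"]
  }
  significant <- isTRUE(!is.na(p) && !is.na(ratio) && p < alpha &&
                          (ratio >= fold || ratio <= 1 / fold))
  data.frame(gene_id = gene_id, usage_control = uc, usage_sample = us,
             usage_ratio = ratio, p_value = p, significant = significant,
             dominant_rank = dom, stringsAsFactors = FALSE)
}

#' Bypass score of a pA site
#'
#' The percentage of the gene's 3'-seq reads that fall on unique 3'UTRs
#' downstream of the given 3' end: `100 * sum(counts at ranks > rank) /
#' sum(all counts)`. The most distal terminus scores 0 by construction, as
#' does a gene with zero coverage (then flagged via attribute
#' `zero_coverage`).
#'
#' @param counts_by_rank numeric counts ordered 5'->3' (index = pA rank).
#' @param rank rank of the queried 3' end.
#' @return bypass score in `[0, 100]`.
#' @export
bypass_score <- function(counts_by_rank, rank) {
  n <- length(counts_by_rank)
  if (rank < 1L || rank > n) stop("rank out of range", call. = FALSE)
  if (any(counts_by_rank < 0)) stop("negative counts", call. = FALSE)
  total <- sum(counts_by_rank)
  if (total == 0) {
    res <- 0
    attr(res, "zero_coverage") <- TRUE
    return(res)
  }
  if (rank == n) return(0)
  100 * sum(counts_by_rank[(rank + 1L):n]) / total
}

#' Bypass and unbypassed ratios between two samples
#'
#' The bypass ratio compares the bypass score of one ALE 3' end between
#' sample and control, `score_sample / score_control`; the unbypassed ratio
#' compares how much of the 3' end is *not* bypassed,
#' `(100 - score_sample) / (100 - score_control)`. Each is undefined (`NA`)
#' when its control denominator is zero.
#'
#' @param score_sample,score_control bypass scores in `[0, 100]`.
#' @return named numeric vector `c(bypass_ratio, unbypassed_ratio)`.
#' @export
bypass_ratios <- function(score_sample, score_control) {
  if (score_sample < 0 || score_sample > 100 ||
      score_control < 0 || score_control > 100) {
    stop("bypass scores must lie in [0, 100]", call. = FALSE)
  }
  br <- if (score_control == 0) NA_real_ else score_sample / score_control
  ur <- if (score_control == 100) NA_real_ else (100 - score_sample) / (100 - score_control)
  c(bypass_ratio = br, unbypassed_ratio = ur)
}
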