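## psi-based APA quantification over a differentiation timecourse and
## k-means detection of neurally-restricted (NR) isoform shifts.

#' Compute psi for a two-pA-site gene
#'
#' psi is the fractional usage of the gene-distal polyadenylation site:
#' `A_distal / (A_proximal + A_distal)`, where each term sums the abundances
#' of the transcripts terminating at that pA site. psi = 0 means exclusive
#' proximal usage, psi = 1 exclusive distal usage. Genes whose termini do not
#' collapse to exactly two pA sites (after merging termini closer than
#' `merge_window`) are rejected.
#'
#' @param tx_abundance named numeric vector of transcript abundances
#'   (TPM-like, non-negative), named by transcript id.
#' @param txs list of `transcript` objects of the gene.
#' @param merge_window terminus merge distance in nt (default 25).
#' @param min_expression genes whose summed abundance is below this are
#'   reported undefined (default 0).
#' @return psi in `[0, 1]`, or `NA` with attribute `reason` when undefined.
#' @export
compute_psi <- function(tx_abundance, txs, merge_window = 25L,
                        min_expression = 0) {
  if (any(tx_abundance < 0)) stop("negative abundances", call. = FALSE)
  mt <- .merged_termini(txs, merge_window)
  if (nrow(mt) != 2L) {
    stop("gene '", txs[[1L]]$gene_id, "' has ", nrow(mt),
         " pA sites; psi is defined for exactly two", call. = FALSE)
  }
  sum_at <- function(ids) {
    ids <- intersect(ids, names(tx_abundance))
    sum(tx_abundance[ids])
  }
  a_prox <- sum_at(mt$tx_ids[[1L]])
  a_dist <- sum_at(mt$tx_ids[[2L]])
  total <- a_prox + a_dist
  if (total == 0 || total < min_expression) {
    res <- NA_real_
    attr(res, "reason") <- if (total == 0) "zero abundance" else "below expression threshold"
    return(res)
  }
  a_dist / total
}

#' Assemble a psi matrix across samples
#'
#' Builds the genes-by-samples psi matrix, masking entries where the gene's
#' expression is below `min_expression`, and attaches gene structure labels.
#' MIXED and SINGLE genes are dropped (with a message): only tandem-UTR and
#' ALE genes are quantified.
#'
#' @param psi_by_sample named list (sample -> named numeric vector of psi per
#'   gene). Sample names must be unique and ordered as the timecourse.
#' @param expression matrix or data.frame genes x samples of abundances used
#'   for the expression mask (same sample order).
#' @param structure named character vector gene -> structure label.
#' @param min_expression mask threshold (default 1 TPM-equivalent).
#' @return object of class `psi_matrix`: list with `psi` (matrix), `expression`
#'   (matrix), `structure`, `samples`.
#' @export
build_psi_matrix <- function(psi_by_sample, expression, structure,
                             min_expression = 1) {
  samples <- names(psi_by_sample)
  if (anyDuplicated(samples)) stop("sample label collision", call. = FALSE)
  genes <- sort(unique(unlist(lapply(psi_by_sample, names))))
  drop <- genes[structure[genes] %in% c("MIXED", "SINGLE")]
  if (length(drop) > 0L) {
    message(length(drop), " MIXED/SINGLE gene(s) dropped from psi matrix: ",
            paste(head(drop, 5L), collapse = ", "),
            if (length(drop) > 5L) ", ..." else "")
    genes <- setdiff(genes, drop)
  }
  psi <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (s in samples) {
    v <- psi_by_sample[[s]]
    common <- intersect(names(v), genes)
    psi[common, s] <- v[common]
  }
  expr <- as.matrix(expression)[genes, samples, drop = FALSE]
  psi[expr < min_expression] <- NA_real_
  structure(list(psi = psi, expression = expr,
                 structure = structure[genes], samples = samples),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("<psi_matrix: %d genes x %d samples (%.1f%% defined)>\n",
              nrow(x$psi), ncol(x$psi), 100 * mean(!is.na(x$psi))))
  invisible(x)
}

#' Detect neurally-restricted (NR) genes by k-means over psi trajectories
#'
#' Genes with complete psi trajectories are clustered by k-means on their
#' delta-psi profile (psi at each timepoint minus psi at the first), which
#' removes baseline offsets so that "steadily increasing" becomes a centroid
#' shape criterion. NR genes are the members of clusters whose centroid is
#' non-decreasing across consecutive timepoints (within tolerance `tau`) and
#' ends at least `delta` above its start. NR genes are split into tandem-UTR
#' and ALE sets by gene structure.
#'
#' @param pm a `psi_matrix` with at least 3 timepoints.
#' @param k number of clusters (default 6).
#' @param seed RNG seed for k-means reproducibility.
#' @param tau per-step decrease tolerance on the centroid (default 0.02).
#' @param delta minimum centroid rise start-to-end (default 0.15).
#' @return object of class `nr_call_set`: list with `nr_tutr`, `nr_ale`,
#'   `controls` (empty here; see [define_control_set()]),
#'   `cluster_assignments`, `nr_clusters`, `centers`, `k`, `seed`.
#' @export
detect_nr_genes <- function(pm, k = 6L, seed = 1L, tau = 0.02, delta = 0.15) {
  stopifnot(inherits(pm, "psi_matrix"))
  if (ncol(pm$psi) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  complete <- pm$psi[complete.cases(pm$psi), , drop = FALSE]
  if (nrow(complete) < k) {
    stop("fewer complete-trajectory genes (", nrow(complete),
         ") than clusters k = ", k, call. = FALSE)
  }
  feats <- complete - complete[, 1L]
  set.seed(seed)
  km <- kmeans(feats, centers = k, nstart = 10L, iter.max = 100L)
  rising <- vapply(seq_len(k), function(i) {
    ce <- km$centers[i, ]
    all(diff(ce) >= -tau) && (ce[length(ce)] - ce[1L] >= delta)
  }, NA)
  nr_genes <- rownames(complete)[km$cluster %in% which(rising)]
  str <- pm$structure[nr_genes]
  structure(list(
    nr_tutr = nr_genes[str == "TUTR"],
    nr_ale = nr_genes[str == "ALE"],
    controls = character(0),
    cluster_assignments = setNames(km$cluster, rownames(complete)),
    nr_clusters = which(rising),
    centers = km$centers,
    k = k, seed = seed
  ), class = "nr_call_set")
}

#' @export
print.nr_call_set <- function(x, ...) {
  cat(sprintf("<nr_call_set: %d NR-TUTR, %d NR-ALE, %d controls (k=%d, seed=%d)>\n",
              length(x$nr_tutr), length(x$nr_ale), length(x$controls),
              x$k, x$seed))
  invisible(x)
}

#' Define the flat/decreasing control gene set
#'
#' Controls are genes expressed at all late timepoints whose psi trajectory
#' is flat (|psi_last - psi_first| <= `flat_tolerance`) or decreasing
#' (psi_last < psi_first), excluding any NR gene.
#'
#' @param pm a `psi_matrix`.
#' @param late_timepoints sample labels that must all pass the expression
#'   threshold.
#' @param flat_tolerance flatness tolerance on |psi_last - psi_first|
#'   (default 0.05).
#' @param nr an optional `nr_call_set` whose NR genes are excluded.
#' @param min_expression expression threshold at the late timepoints
#'   (default 1).
#' @return character vector of control gene ids.
#' @export
define_control_set <- function(pm, late_timepoints, flat_tolerance = 0.05,
                               nr = NULL, min_expression = 1) {
  stopifnot(inherits(pm, "psi_matrix"),
            all(late_timepoints %in% pm$samples))
  expr_ok <- rownames(pm$expression)[
    apply(pm$expression[, late_timepoints, drop = FALSE] >= min_expression, 1L, all)]
  first <- pm$psi[expr_ok, 1L]
  last <- pm$psi[expr_ok, ncol(pm$psi)]
  ok <- !is.na(first) & !is.na(last) &
    (abs(last - first) <= flat_tolerance | last < first)
  controls <- expr_ok[ok]
  if (!is.null(nr)) controls <- setdiff(controls, c(nr$nr_tutr, nr$nr_ale))
  controls
}
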