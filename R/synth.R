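## Synthetic-data generator with known ground truth: genome + annotation,
## motif-dependent 3'-seq counts (pA-site bypass forward model), cassette
## junction counts, and psi trajectories over a differentiation timecourse.

#' Simulation configuration
#'
#' Defaults describe the emulated regime: an RNA-binding-protein activity
#' that increases bypass of proximal pA sites in proportion to the U-rich
#' motif load planted immediately downstream of them, negative-binomial
#' 3'-seq counts with realistic overdispersion, binomial junction counts,
#' and a timecourse in which a subset of genes ramps psi monotonically.
#'
#' @param seed RNG seed; every generator output is deterministic given it.
#' @param n_single,n_tutr,n_ale,n_mixed genes per 3'-end structure class.
#' @param bypass_base baseline proximal pA bypass probability (no motif, no
#'   RBP activity).
#' @param bypass_motif_gain logistic slope: log-odds of bypass gained per
#'   planted motif per unit RBP activity.
#' @param rbp_activity named vector of RBP activity per condition.
#' @param nb_mean,nb_dispersion negative-binomial mean total 3'-seq count per
#'   gene and dispersion (var = mu + dispersion * mu^2).
#' @param n_replicates replicates per condition.
#' @param timepoints ordered timecourse labels.
#' @param nr_fraction fraction of quantifiable (TUTR/ALE) genes given a
#'   monotone rising psi trajectory.
#' @param psi_noise_sd Gaussian noise on psi per timepoint (truncated to
#'   `[0, 1]`).
#' @param target_fraction fraction of ALE genes given downstream motifs
#'   ("bypassable" targets).
#' @param motif_count_range inclusive range of planted motif copies per
#'   target gene.
#' @param jitter read 3' ends are jittered uniformly within +/- this many nt
#'   of the cleavage site (default 12, exercising the 25-bp clustering).
#' @param junction_depth junction reads per cassette event per replicate.
#' @param n_exons cassette exon events.
#' @param regulated_fraction fraction of cassette events with a planted
#'   delta-PSI.
#' @param delta_psi planted delta-PSI of regulated events.
#' @param gene_window genomic span reserved per gene.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_single = 5L, n_tutr = 10L, n_ale = 20L, n_mixed = 3L,
                       bypass_base = 0.2,
                       bypass_motif_gain = 1.5,
                       rbp_activity = c(control = 0, treatment = 1),
                       nb_mean = 500, nb_dispersion = 0.1,
                       n_replicates = 3L,
                       timepoints = paste0("day", c(0, 7, 14, 21, 35, 47, 63, 77)),
                       nr_fraction = 0.1, psi_noise_sd = 0.05,
                       target_fraction = 0.5, motif_count_range = c(1L, 3L),
                       jitter = 12L,
                       junction_depth = 100L, n_exons = 100L,
                       regulated_fraction = 0.2, delta_psi = 0.5,
                       gene_window = 3000L) {
  stopifnot(bypass_base > 0, bypass_base < 1, nb_mean > 0, nb_dispersion > 0,
            nr_fraction >= 0, nr_fraction <= 1, psi_noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

## Plus-strand gene layouts in coordinates relative to the gene window.
## Termini are kept > 25 nt apart so merging never collapses them.
.gene_layout <- function(structure) {
  switch(structure,
    SINGLE = list(txs = list(list(suffix = "t1", exons = rbind(c(0, 200), c(400, 900))))),
    TUTR = list(txs = list(
      list(suffix = "t1", exons = rbind(c(0, 200), c(400, 700))),
      list(suffix = "t2", exons = rbind(c(0, 200), c(400, 1000))))),
    ALE = list(txs = list(
      list(suffix = "t1", exons = rbind(c(0, 200), c(400, 700))),
      list(suffix = "t2", exons = rbind(c(0, 200), c(1200, 1600))))),
    MIXED = list(txs = list(
      list(suffix = "t1", exons = rbind(c(0, 200), c(400, 650))),
      list(suffix = "t2", exons = rbind(c(0, 200), c(400, 800))),
      list(suffix = "t3", exons = rbind(c(0, 200), c(1200, 1500))))),
    stop("unknown structure ", structure)
  )
}

#' The synthetic ELAV-like U-rich test PWM
#'
#' An 8-nt U-rich matrix with an interior G, loosely imitating ELAV/Hu-class
#' binding preferences. It is synthetic — constructed for testing, not
#' derived from any binding assay.
#'
#' @param pseudo pseudocount (default 0.01).
#' @return a `pwm` named `ELAVlike_synth`.
#' @export
synthetic_elav_pwm <- function(pseudo = 0.01) {
  u <- c(0.04, 0.02, 0.02, 0.92)
  g <- c(0.05, 0.05, 0.80, 0.10)
  mat <- rbind(u, u, u, g, u, u, u, u)
  colnames(mat) <- c("A", "C", "G", "U")
  rownames(mat) <- NULL
  pwm("ELAVlike_synth", mat, pseudo = pseudo)
}

#' Generate a synthetic genome, annotation and gene-level truth
#'
#' Builds a random genome holding genes of all four 3'-end structure
#' classes, plants a canonical AAUAAA PAS 10-30 nt upstream of distal and
#' single 3' termini (and the weaker AUUAAA variant upstream of proximal ALE
#' termini), and plants copies of the synthetic ELAV-like motif consensus in
#' the +1..+50 window downstream of the proximal pA site of designated
#' "target" ALE genes. Writes FASTA and GTF when `outdir` is given; output
#' is byte-identical for a given seed.
#'
#' @param config a `sim_config`.
#' @param outdir optional directory for `genome.fa` / `annotation.gtf` /
#'   `truth.tsv`.
#' @return list with `gms` (a `gene_model_set` with `$genome` attached),
#'   `truth` (data.frame), `exon_truth` (data.frame for the splicing stage)
#'   and, when written, `fasta`/`gtf`/`truth_path`.
#' @export
generate_reference <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  classes <- rep(c("SINGLE", "TUTR", "ALE", "MIXED"),
                 c(config$n_single, config$n_tutr, config$n_ale, config$n_mixed))
  n_genes <- length(classes)
  gw <- config$gene_window
  chrom <- "chrS1"
  glen <- n_genes * gw + 200L
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  consensus_dna <- chartr("U", "T", pwm_consensus(synthetic_elav_pwm()))
  clen <- nchar(consensus_dna)
  cons_chars <- strsplit(consensus_dna, "")[[1L]]
  rc <- function(chars) rev(chartr("ACGT", "TGCA", chars))

  plant <- function(pos0, chars, strand) {
    ## pos0: 0-based genomic start of the planted block on the + reference
    if (strand == "-") chars <- rc(chars)
    idx <- (pos0 + 1L):(pos0 + length(chars))
    genome_chars[idx] <<- chars
  }

  genes <- list()
  truth_rows <- list()
  for (g in seq_len(n_genes)) {
    cls <- classes[g]
    gid <- sprintf("g%03d_%s", g, tolower(cls))
    off <- (g - 1L) * gw + 100L
    strand <- if (runif(1) < 0.5) "+" else "-"
    layout <- .gene_layout(cls)
    txs <- lapply(layout$txs, function(t) {
      ex <- t$exons
      if (strand == "-") ex <- cbind(2000L - ex[, 2L], 2000L - ex[, 1L])
      transcript(paste0(gid, ".", t$suffix), gid, chrom, strand,
                 data.frame(start = ex[, 1L] + off, end = ex[, 2L] + off))
    })
    pa <- vapply(txs, pa_site_pos, 0L)
    down <- vapply(pa, .downstream_coord, 0, strand = strand)
    prox_pa <- pa[which.min(down)]
    dist_pa <- pa[which.max(down)]
    tx_prox <- txs[[which.min(down)]]$id
    tx_dist <- txs[[which.max(down)]]$id

    ## PAS hexamers 10-30 nt upstream of termini (AAUAAA at strong ends,
    ## AUUAAA at bypassable proximal ALE ends).
    pas_at <- function(pos, hex) {
      hc <- strsplit(hex, "")[[1L]]
      if (strand == "+") plant(pos - 20L, hc, strand) else plant(pos + 20L - 5L, hc, strand)
    }
    if (cls == "SINGLE") {
      pas_at(prox_pa, "AATAAA")
    } else {
      for (p in pa[pa != dist_pa]) {
        pas_at(p, if (cls == "ALE") "ATTAAA" else "AATAAA")
      }
      pas_at(dist_pa, "AATAAA")
    }

    is_target <- FALSE
    motif_count <- 0L
    if (cls == "ALE") {
      is_target <- runif(1) < config$target_fraction
      if (is_target) {
        motif_count <- sample(config$motif_count_range[1L]:config$motif_count_range[2L], 1L)
        offsets <- c(2L, 16L, 30L, 44L)[seq_len(motif_count)]
        for (o in offsets) {
          if (strand == "+") {
            plant(prox_pa + o, cons_chars, strand)
          } else {
            plant(prox_pa - o - clen, cons_chars, strand)
          }
        }
      }
    }
    genes[[gid]] <- txs
    truth_rows[[gid]] <- data.frame(
      gene_id = gid, structure = cls, chrom = chrom, strand = strand,
      prox_pa = prox_pa, dist_pa = if (cls == "SINGLE") NA_integer_ else dist_pa,
      tx_prox = tx_prox, tx_dist = if (cls == "SINGLE") NA_character_ else tx_dist,
      is_target = is_target, motif_count = motif_count,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  ## NR / control trajectory assignment for quantifiable two-site genes
  quant <- truth$gene_id[truth$structure %in% c("TUTR", "ALE")]
  n_nr <- round(config$nr_fraction * length(quant))
  nr_genes <- if (n_nr > 0) sample(quant, n_nr) else character(0)
  truth$nr <- truth$gene_id %in% nr_genes
  bg <- setdiff(quant, nr_genes)
  decreasing <- if (length(bg) > 0) sample(bg, floor(length(bg) / 3)) else character(0)
  truth$decreasing <- truth$gene_id %in% decreasing
  truth$psi_start <- ifelse(truth$nr, 0.2,
                            round(runif(nrow(truth), 0.2, 0.8), 3))
  truth$psi_end <- ifelse(truth$nr, 0.8,
                          ifelse(truth$decreasing,
                                 pmax(truth$psi_start - 0.3, 0.05),
                                 truth$psi_start))
  truth$psi_start[!truth$gene_id %in% quant] <- NA_real_
  truth$psi_end[!truth$gene_id %in% quant] <- NA_real_

  ## cassette-exon truth for the splicing stage
  ex <- data.frame(
    gene_id = sprintf("sx%04d", seq_len(config$n_exons)),
    exon_start = 1000L + 5000L * seq_len(config$n_exons),
    exon_end = 1150L + 5000L * seq_len(config$n_exons),
    stringsAsFactors = FALSE)
  ex$regulated <- seq_len(config$n_exons) <= round(config$regulated_fraction * config$n_exons)
  ex$psi_a <- round(runif(config$n_exons, 0.15, 0.45), 3)
  ex$true_delta <- ifelse(ex$regulated, config$delta_psi, 0)
  ex$psi_b <- pmin(ex$psi_a + ex$true_delta, 0.99)
  exon_truth <- ex

  seqs <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(seqs) <- chrom
  gms <- structure(list(
    genes = genes,
    structure = vapply(genes, classify_apa_structure, ""),
    genome = seqs), class = "gene_model_set")

  out <- list(gms = gms, truth = truth, exon_truth = exon_truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out$fasta <- file.path(outdir, "genome.fa")
    Biostrings::writeXStringSet(seqs, out$fasta)
    out$gtf <- file.path(outdir, "annotation.gtf")
    write_gtf(gms, out$gtf)
    out$truth_path <- file.path(outdir, "truth.tsv")
    .write_tsv(truth, out$truth_path)
    .write_tsv(exon_truth, file.path(outdir, "exon_truth.tsv"))
  }
  out
}

#' True bypass probability per gene under a condition
#'
#' The forward model: `b = plogis(qlogis(bypass_base) +
#' bypass_motif_gain * motif_count * rbp_activity[condition])`. Genes without
#' motifs keep the baseline bypass in every condition.
#'
#' @param truth gene truth from [generate_reference()].
#' @param config the `sim_config`.
#' @param condition condition name (must index `config$rbp_activity`).
#' @return named numeric vector gene -> bypass probability (ALE genes only).
#' @export
true_bypass_prob <- function(truth, config, condition) {
  act <- config$rbp_activity[[condition]]
  ale <- truth[truth$structure == "ALE", , drop = FALSE]
  setNames(plogis(qlogis(config$bypass_base) +
                    config$bypass_motif_gain * ale$motif_count * act),
           ale$gene_id)
}

#' Simulate 3'-seq read ends for one condition
#'
#' Per gene and replicate, a negative-binomial count is split between the
#' proximal and distal pA site by the gene's bypass probability (ALE genes;
#' TUTR and MIXED genes split evenly, SINGLE genes use one site) and each
#' read 3' end is jittered uniformly within `config$jitter` nt of the
#' cleavage site so downstream clustering is exercised.
#'
#' @param truth gene truth from [generate_reference()].
#' @param config the `sim_config`.
#' @param condition condition name.
#' @return data.frame of weighted read-end positions with columns `chrom`,
#'   `strand`, `pos`, `weight`, `sample`, `replicate`.
#' @export
simulate_3pseq <- function(truth, config, condition) {
  b_ale <- true_bypass_prob(truth, config, condition)
  size <- 1 / config$nb_dispersion
  jit <- -config$jitter:config$jitter
  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    for (g in seq_len(nrow(truth))) {
      tr <- truth[g, ]
      sites <- if (tr$structure == "SINGLE") {
        c(tr$prox_pa)
      } else {
        c(tr$prox_pa, tr$dist_pa)
      }
      frac <- if (tr$structure == "SINGLE") {
        1
      } else if (tr$structure == "ALE") {
        b <- b_ale[[tr$gene_id]]
        c(1 - b, b)
      } else {
        c(0.5, 0.5)
      }
      for (s in seq_along(sites)) {
        cnt <- rnbinom(1L, mu = config$nb_mean * frac[s], size = size)
        if (cnt == 0L) next
        ends <- sites[s] + sample(jit, cnt, replace = TRUE)
        agg <- table(ends)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = tr$chrom, strand = tr$strand,
          pos = as.integer(names(agg)), weight = as.integer(agg),
          sample = condition, replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate cassette-exon junction counts for one condition
#'
#' Draws, per event and replicate, `X ~ Binomial(depth, psi)` supporting
#' inclusion and `S = depth - X` supporting skipping; inclusion junction
#' reads are reported as `2 X` (two junctions support an included exon), so
#' [exon_psi()] is unbiased for the planted psi.
#'
#' @param exon_truth exon truth from [generate_reference()].
#' @param config the `sim_config`.
#' @param condition `"A"` (baseline psi) or `"B"` (shifted by the planted
#'   delta-PSI on regulated events).
#' @return data.frame with columns `gene_id`, `exon_start`, `exon_end`,
#'   `condition`, `replicate`, `inclusion_jc`, `skipping_jc`.
#' @export
simulate_junction_counts <- function(exon_truth, config, condition = c("A", "B")) {
  condition <- match.arg(condition)
  psi <- if (condition == "A") exon_truth$psi_a else exon_truth$psi_b
  depth <- config$junction_depth
  out <- list()
  for (r in seq_len(config$n_replicates)) {
    x <- if (depth > 0) rbinom(nrow(exon_truth), depth, psi) else rep(0L, nrow(exon_truth))
    out[[r]] <- data.frame(
      gene_id = exon_truth$gene_id, exon_start = exon_truth$exon_start,
      exon_end = exon_truth$exon_end, condition = condition, replicate = r,
      inclusion_jc = 2L * x, skipping_jc = depth - x,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate timecourse transcript abundances
#'
#' NR genes follow a logistic psi ramp from `psi_start` to `psi_end` across
#' the timepoints; control genes stay flat or decrease linearly. Gaussian
#' noise of sd `psi_noise_sd` is added and truncated to `[0, 1]`. The two
#' transcripts of each quantifiable gene get abundances `total * (1 - psi)`
#' (proximal) and `total * psi` (distal).
#'
#' @param truth gene truth from [generate_reference()].
#' @param config the `sim_config`.
#' @param total_tpm total gene abundance (default 20).
#' @return list with `abundance` (data.frame `transcript_id`, `sample`,
#'   `TPM`), `psi_true` (genes x timepoints matrix) and `expression`
#'   (genes x timepoints total TPM).
#' @export
simulate_timecourse <- function(truth, config, total_tpm = 20) {
  tp <- config$timepoints
  nt <- length(tp)
  quant <- truth[truth$structure %in% c("TUTR", "ALE"), , drop = FALSE]
  ramp <- plogis(seq(-3, 3, length.out = nt))
  ramp <- (ramp - min(ramp)) / (max(ramp) - min(ramp))
  psi_true <- matrix(NA_real_, nrow(quant), nt,
                     dimnames = list(quant$gene_id, tp))
  for (i in seq_len(nrow(quant))) {
    base <- if (quant$nr[i]) {
      quant$psi_start[i] + (quant$psi_end[i] - quant$psi_start[i]) * ramp
    } else {
      seq(quant$psi_start[i], quant$psi_end[i], length.out = nt)
    }
    noise <- if (config$psi_noise_sd > 0) rnorm(nt, 0, config$psi_noise_sd) else 0
    psi_true[i, ] <- pmin(pmax(base + noise, 0), 1)
  }
  rows <- list()
  for (j in seq_len(nt)) {
    rows[[j]] <- data.frame(
      transcript_id = c(quant$tx_prox, quant$tx_dist),
      sample = tp[j],
      TPM = c(total_tpm * (1 - psi_true[, j]), total_tpm * psi_true[, j]),
      stringsAsFactors = FALSE)
  }
  abundance <- do.call(rbind, rows)
  rownames(abundance) <- NULL
  expression <- matrix(total_tpm, nrow(quant), nt,
                       dimnames = list(quant$gene_id, tp))
  list(abundance = abundance, psi_true = psi_true, expression = expression)
}
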