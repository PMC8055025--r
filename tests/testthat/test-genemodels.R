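test_that("GTF coordinates convert to 0-based half-open and strands are honored", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";',
    'chr2\tsrc\texon\t101\t200\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";',
    'chr2\tsrc\texon\t301\t400\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";'
  ), gtf)
  gms <- parse_annotation(gtf)
  t1 <- gms$genes$g1[[1L]]
  expect_equal(t1$exons$start, c(100L, 300L))
  expect_equal(t1$exons$end, c(200L, 400L))
  # two transcripts sharing gene_id -> one gene with two transcripts
  expect_length(gms$genes$g1, 2L)
  # minus strand: exons reported 5'->3' in transcript orientation
  t2 <- gms$genes$g2[[1L]]
  expect_equal(t2$exons$start, c(300L, 100L))
})

test_that("malformed GTF lines are rejected with their line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tsrc\texon\t301"
  ), gtf)
  expect_error(parse_annotation(gtf), "line 2")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1";'
  ), gtf)
  expect_error(parse_annotation(gtf), "transcript_id")
})

test_that("GTF writing and re-parsing round-trips intervals and strands", {
  gms <- structure(list(
    genes = list(gA = toy_ale_gene("+"), gB = toy_ale_gene("-", "gB"),
                 gT = toy_tutr_gene()),
    structure = c(gA = "ALE", gB = "ALE", gT = "TUTR"), genome = NULL),
    class = "gene_model_set")
  path <- tempfile(fileext = ".gtf")
  write_gtf(gms, path)
  back <- parse_annotation(path)
  for (g in names(gms$genes)) {
    for (i in seq_along(gms$genes[[g]])) {
      orig <- gms$genes[[g]][[i]]
      rt <- Filter(function(t) t$id == orig$id, back$genes[[g]])[[1L]]
      expect_equal(rt$exons, orig$exons, info = orig$id)
      expect_identical(rt$strand, orig$strand)
    }
  }
  # the re-parse agrees with rtracklayer's reading of the same file
  skip_if_not_installed("rtracklayer")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ours <- do.call(rbind, lapply(unlist(back$genes, recursive = FALSE), function(t) {
    data.frame(tx = t$id, start = sort(t$exons$start), end = sort(t$exons$end))
  }))
  ours <- ours[order(ours$tx, ours$start), ]
  theirs <- data.frame(tx = gr$transcript_id,
                       start = BiocGenerics::start(gr) - 1L,
                       end = BiocGenerics::end(gr))
  theirs <- theirs[order(theirs$tx, theirs$start), ]
  expect_equal(ours$start, theirs$start)
  expect_equal(ours$end, theirs$end)
})

test_that("3'-end structure classification covers all definition cases", {
  expect_identical(classify_apa_structure(toy_ale_gene()[1L]), "SINGLE")
  # last exons share the same start but different ends -> tandem UTR
  expect_identical(classify_apa_structure(toy_tutr_gene()), "TUTR")
  expect_identical(classify_apa_structure(toy_ale_gene()), "ALE")
  expect_identical(classify_apa_structure(toy_ale_gene("-")), "ALE")
  # three termini, two sharing a last exon, one separate -> MIXED
  expect_identical(classify_apa_structure(toy_mixed_gene()), "MIXED")
  # invariant under transcript ordering
  expect_identical(classify_apa_structure(rev(toy_mixed_gene())), "MIXED")
  expect_identical(classify_apa_structure(rev(toy_tutr_gene())), "TUTR")
})

test_that("termini within the merge window collapse before classification", {
  txs <- list(
    mk_tx("a", "g", "+", rbind(c(0, 100), c(200, 500))),
    mk_tx("b", "g", "+", rbind(c(0, 100), c(200, 510)))  # 10 nt apart
  )
  expect_identical(classify_apa_structure(txs), "SINGLE")
  txs2 <- list(
    mk_tx("a", "g", "+", rbind(c(0, 100), c(200, 500))),
    mk_tx("b", "g", "+", rbind(c(0, 100), c(200, 560)))  # 60 nt apart
  )
  expect_identical(classify_apa_structure(txs2), "TUTR")
})

test_that("pA site categories and ranks follow gene structure", {
  single <- extract_pa_sites(toy_ale_gene()[1L], "SINGLE")
  expect_identical(single$category, "SINGLE_END")

  ale <- extract_pa_sites(toy_ale_gene(), "ALE")
  expect_identical(ale$category, c("PROX_ALE_END", "DIST_ALE_END"))
  expect_identical(ale$rank, 1:2)
  expect_identical(ale$pos, c(699L, 1599L))

  # TUTR gene with 3 termini -> two internal + one distal
  tutr3 <- list(
    mk_tx("a", "g", "+", rbind(c(0, 100), c(200, 400))),
    mk_tx("b", "g", "+", rbind(c(0, 100), c(200, 500))),
    mk_tx("c", "g", "+", rbind(c(0, 100), c(200, 620)))
  )
  p3 <- extract_pa_sites(tutr3, "TUTR")
  expect_identical(p3$category, c("TUTR_INTERNAL", "TUTR_INTERNAL", "TUTR_DISTAL"))

  mx <- extract_pa_sites(toy_mixed_gene(), "MIXED")
  expect_identical(mx$category, c("TUTR_INTERNAL", "TUTR_INTERNAL", "DIST_ALE_END"))

  # duplicate termini merge into a single pA site
  dup <- list(
    mk_tx("a", "g", "+", rbind(c(0, 100), c(200, 500))),
    mk_tx("b", "g", "+", rbind(c(0, 150), c(200, 500)))
  )
  expect_identical(nrow(extract_pa_sites(dup, "SINGLE")), 1L)
})

test_that("minus-strand pA ranks reverse genomic order", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:4, 1L)
    ends <- sort(sample(seq(500L, 5000L, by = 100L), n))
    txs <- lapply(seq_len(n), function(i) {
      mk_tx(paste0("t", i), "g", "-", rbind(c(ends[i], ends[i] + 90L),
                                            c(6000L, 6100L)))
    })
    pa <- extract_pa_sites(txs)
    # brute-force oracle: sort by strand-projected coordinate
    oracle <- order(-pa$pos)
    expect_identical(pa$rank, seq_len(n))
    expect_identical(order(pa$pos, decreasing = TRUE), oracle)
    expect_true(all(diff(pa$pos) < 0))
  }
})

test_that("every random gene receives exactly one of the four structure labels", {
  set.seed(11)
  cfg <- sim_config(seed = 11, n_single = 4, n_tutr = 4, n_ale = 6, n_mixed = 3)
  ref <- generate_reference(cfg)
  labs <- ref$gms$structure
  expect_true(all(labs %in% c("SINGLE", "TUTR", "ALE", "MIXED")))
  expect_identical(unname(labs[ref$truth$gene_id]), ref$truth$structure)
})

test_that("unique 3'UTR derivation keeps the longest per start and drops nested UTRs", {
  # same UTR start, lengths 300 and 500 -> the longer kept
  txs <- list(
    mk_tx("short", "g", "+", rbind(c(0, 100), c(400, 700))),
    mk_tx("long", "g", "+", rbind(c(0, 100), c(400, 900))),
    mk_tx("dist", "g", "+", rbind(c(0, 100), c(1200, 1500)))
  )
  utrs <- extract_unique_3utrs(txs, "MIXED")
  first <- utrs[utrs$start == 400L, ]
  expect_identical(nrow(first), 1L)
  expect_identical(first$end, 900L)

  # a 3'UTR lying entirely within exonic sequence of every other isoform
  # (3-transcript toy gene) is excluded
  txs2 <- list(
    mk_tx("inner", "g", "+", rbind(c(0, 100), c(380, 600))),
    mk_tx("host1", "g", "+", rbind(c(0, 100), c(300, 700))),
    mk_tx("host2", "g", "+", rbind(c(0, 100), c(350, 900)))
  )
  utrs2 <- extract_unique_3utrs(txs2, "MIXED")
  expect_false(any(utrs2$start == 380L & utrs2$end == 600L))

  # a two-ALE gene yields exactly two unique 3'UTRs with assignable roles
  u <- extract_unique_3utrs(toy_ale_gene(), "ALE")
  expect_identical(nrow(u), 2L)
  u <- assign_utr_roles(u, dominant_rank = 1L)
  expect_identical(u$role, c("UNIVERSAL", "DISTAL"))
  u2 <- assign_utr_roles(u, dominant_rank = 2L)
  expect_identical(u2$role, c("PROXIMAL", "UNIVERSAL"))

  # minus strand mirror
  um <- extract_unique_3utrs(toy_ale_gene("-"), "ALE")
  expect_identical(nrow(um), 2L)
  expect_identical(um$source_pa, 1:2)
  expect_true(um$start[1L] > um$start[2L])  # proximal UTR is genomically right
})

test_that("3'UTRs start at the annotated CDS end when present", {
  txs <- list(
    mk_tx("p", "g", "+", rbind(c(0, 100), c(400, 700)), cds_end = 450L),
    mk_tx("d", "g", "+", rbind(c(0, 100), c(1200, 1600)), cds_end = 1250L)
  )
  u <- extract_unique_3utrs(txs, "ALE", use_cds = TRUE)
  expect_identical(u$start[u$source_pa == 1L], 450L)
  expect_identical(u$start[u$source_pa == 2L], 1250L)
  u_nocds <- extract_unique_3utrs(txs, "ALE", use_cds = FALSE)
  expect_identical(u_nocds$start[u_nocds$source_pa == 1L], 400L)
})

test_that("unquantifiable ALE-like genes are flagged", {
  txs <- list(mk_tx("a", "g", "+", rbind(c(0, 100), c(380, 600))),
              mk_tx("b", "g", "+", rbind(c(0, 100), c(300, 700))))
  # the inner UTR is nested in the other isoform's last exon
  expect_warning(res <- extract_unique_3utrs(txs, "MIXED"), "unquantifiable")
  expect_true(isTRUE(attr(res, "unquantifiable")))
  expect_error(extract_unique_3utrs(toy_tutr_gene(), "TUTR"), "ALE or MIXED")
})

test_that("BED6 output is 0-based half-open with gene|role names", {
  u <- assign_utr_roles(extract_unique_3utrs(toy_ale_gene(), "ALE"), 1L)
  path <- tempfile(fileext = ".bed")
  write_utr_bed(u, path)
  bed <- read.delim(path, header = FALSE)
  expect_identical(bed$V2, u$start)
  expect_identical(bed$V3, u$end)
  expect_identical(bed$V4, paste0("gA|", u$role))
})
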