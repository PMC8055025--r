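test_that("PAS hexamer classification uses priority order, T/U and case-insensitively", {
  expect_identical(classify_pas_hexamer("CCCCAAUAAACCCC"), "AAUAAA")
  expect_identical(classify_pas_hexamer("CCCCAATAAACCCC"), "AAUAAA")  # DNA input
  expect_identical(classify_pas_hexamer("ccccaauaaacccc"), "AAUAAA")  # lowercase
  # both canonical and variant present -> canonical wins
  expect_identical(classify_pas_hexamer("AUUAAACCAAUAAA"), "AAUAAA")
  expect_identical(classify_pas_hexamer("CCAUUAAACC"), "AUUAAA")
  expect_identical(classify_pas_hexamer("CCAAUAUACC"), "AAUAUA")
  expect_identical(classify_pas_hexamer("CCCCCCCCCC"), "OTHER")
  expect_error(classify_pas_hexamer("AAUA"), "shorter")
  # deterministic on repeated calls
  w <- "GGAUUAAAGGAAUAUAGG"
  expect_identical(classify_pas_hexamer(w), classify_pas_hexamer(w))
})

test_that("PWM construction validates rows and parses MEME minimal format", {
  p <- synthetic_elav_pwm()
  expect_s3_class(p, "pwm")
  expect_identical(nchar(pwm_consensus(p)), nrow(p$matrix))
  expect_error(pwm("bad", matrix(0.3, 4, 4)), "sum to 1")
  expect_error(pwm("short", matrix(0.25, 3, 4)), "length")

  path <- tempfile(fileext = ".meme")
  write_meme_pwm(list(p), path)
  back <- read_meme_pwm(path)
  expect_identical(names(back), "ELAVlike_synth")
  expect_equal(back[[1]]$matrix, p$matrix, tolerance = 1e-5,
               ignore_attr = TRUE)

  # the packaged synthetic PWM file parses to the same matrix
  shipped <- read_meme_pwm(system.file("extdata", "elavlike_synth.meme",
                                       package = "apabypass"))
  expect_equal(shipped[[1]]$matrix, p$matrix, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("PWM scanning matches the exhaustive oracle and the consensus scores 1", {
  p <- synthetic_elav_pwm()
  cons <- pwm_consensus(p)
  hit <- scan_pwm(cons, p)
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$score_fraction, 1)
  expect_identical(hit$center_pos, 1L + (nchar(cons) - 1L) %/% 2L)

  # scanning is single-strand: the reverse complement does not match
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", cons))))
  expect_identical(nrow(scan_pwm(rc, p)), 0L)

  # sequence shorter than the PWM -> empty result
  expect_identical(nrow(scan_pwm("ACG", p)), 0L)

  # random sequences: exact equality with the brute-force enumeration
  set.seed(55)
  for (i in 1:12) {
    s <- rand_dna(1000)
    got <- scan_pwm(s, p, threshold = 0.6)
    want <- brute_scan(s, p, 0.6)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$center_pos, want$center_pos)
      expect_equal(got$score_fraction, want$score_fraction)
    }
  }

  # threshold is inclusive at the boundary
  lo <- apabypass:::.pwm_logodds(p)
  smin <- sum(apply(lo, 1, min)); smax <- sum(apply(lo, 1, max))
  frac <- scan_pwm("UUUGUUUU", p, threshold = 1)$score_fraction
  expect_equal(frac, 1)

  # ambiguous bases mask the window
  expect_identical(nrow(scan_pwm("UUUNUUUU", p, threshold = 0.1)), 0L)
})

test_that("motif counting collapses only exact-center duplicates", {
  m <- data.frame(seq_id = c("s1", "s1", "s1", "s2"),
                  center_pos = c(57L, 57L, 59L, 57L),
                  pwm_name = c("a", "b", "a", "a"))
  expect_identical(count_motifs_dedup(m), 3L)
  expect_identical(count_motifs_dedup(m[m$seq_id == "s1", ][1:2, ]), 1L)
  expect_identical(count_motifs_dedup(m[0, ]), 0L)
  expect_identical(count_motifs_dedup(NULL), 0L)
  # near-identical offsets (+/-1) are NOT collapsed
  m2 <- data.frame(seq_id = "s", center_pos = c(10L, 11L), pwm_name = c("a", "b"))
  expect_identical(count_motifs_dedup(m2), 2L)
  # dedup count never exceeds the raw count; equals it when centers distinct
  expect_lte(count_motifs_dedup(m), nrow(m))
  distinct <- data.frame(seq_id = "s", center_pos = c(1L, 5L, 9L), pwm_name = "a")
  expect_identical(count_motifs_dedup(distinct), nrow(distinct))
})

test_that("nucleotide metaprofiles match direct counting", {
  # all-U sequences -> U frequency 1 everywhere covered
  seqs <- rep(paste(rep("T", 21), collapse = ""), 4)
  prof <- nt_frequency_profile(seqs, anchors = rep(11L, 4), window = 10)
  expect_true(all(prof$U == 1))
  expect_true(all(abs(rowSums(prof[, c("A", "C", "G", "U")]) - 1) < 1e-12))

  # planted downstream U-block in half the sequences elevates U only there
  set.seed(8)
  n <- 40
  mk <- function(planted) {
    s <- strsplit(rand_dna(120), "")[[1]]
    if (planted) s[66:91] <- "T"   # +5..+30 relative to anchor 61
    paste(s, collapse = "")
  }
  seqs2 <- c(vapply(1:(n / 2), function(i) mk(TRUE), ""),
             vapply(1:(n / 2), function(i) mk(FALSE), ""))
  prof2 <- nt_frequency_profile(seqs2, anchors = rep(61L, n), window = 50)
  inside <- prof2$position >= 5 & prof2$position <= 30
  expect_gt(mean(prof2$U[inside]), mean(prof2$U[!inside]) + 0.3)
  # direct counting oracle at one position (+10)
  ch <- substr(seqs2, 71, 71)
  expect_equal(prof2$U[prof2$position == 10],
               mean(chartr("T", "U", ch) == "U"))

  # edge truncation reduces per-position coverage, not correctness
  prof3 <- nt_frequency_profile(c("ACGT", "ACGTACGT"), anchors = c(2L, 2L),
                                window = 5)
  expect_equal(prof3$n[prof3$position == 5], 1L)
  expect_error(nt_frequency_profile(character(0), integer(0)), "no sequences")
})

test_that("positional motif density localizes planted motifs", {
  p <- synthetic_elav_pwm()
  cons_dna <- chartr("U", "T", pwm_consensus(p))
  set.seed(9)
  n <- 30
  seqs <- vapply(1:n, function(i) {
    s <- strsplit(rand_dna(200), "")[[1]]
    s[121:128] <- strsplit(cons_dna, "")[[1]]  # center lands at +23 from anchor 101
    paste(s, collapse = "")
  }, "")
  dens <- positional_motif_density(seqs, anchors = rep(101L, n), p,
                                   threshold = 0.9, window = 60)
  center_rel <- (121 + 3) - 101  # window start 121, center offset (8-1)%/%2 = 3
  expect_equal(dens$density[dens$position == center_rel], 1)
  expect_true(all(dens$density >= 0 & dens$density <= 1))
  expect_lt(mean(dens$density[dens$position != center_rel]), 0.1)

  # no motifs -> all-zero profile
  none <- positional_motif_density(rep("ACACACACACAC", 3), rep(6L, 3), p)
  expect_true(all(none$density == 0))
})

test_that("group comparison and bypass correlation wrap the intended tests", {
  set.seed(10)
  a <- rnorm(100, 0.3, 0.1)
  b <- rnorm(100, 0.5, 0.1)
  res <- compare_groups(a, b)
  expect_lt(res["p"], 0.05)
  # identical groups -> p = 1 under the continuity-corrected approximation
  same <- rep(c(0.1, 0.2, 0.3), 5)
  expect_equal(unname(compare_groups(same, same)["p"]), 1)
  # invariant to within-group ordering
  expect_equal(compare_groups(a, b), compare_groups(sample(a), sample(b)))
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")

  # perfectly monotone relation -> rho 1
  mc <- setNames(1:20, paste0("g", 1:20))
  bc <- setNames((1:20)^2, paste0("g", 1:20))
  expect_equal(unname(correlate_motif_with_bypass(mc, bc)["rho"]), 1)
  # permuted pairing -> small rho, p > 0.05
  set.seed(123)
  bc_perm <- setNames(sample(as.numeric(bc)), names(bc))
  mc200 <- setNames(rnorm(200), paste0("h", 1:200))
  bc200 <- setNames(sample(rnorm(200)), paste0("h", 1:200))
  perm <- correlate_motif_with_bypass(mc200, bc200)
  expect_lt(abs(perm["rho"]), 0.2)
  expect_gt(perm["p"], 0.05)
  # degenerate ranks flagged
  expect_warning(
    flat <- correlate_motif_with_bypass(setNames(rep(1, 6), paste0("g", 1:6)),
                                        setNames(1:6, paste0("g", 1:6))),
    "degenerate")
  expect_true(is.na(flat["rho"]))
  expect_error(correlate_motif_with_bypass(mc[1:3], bc), "5 shared")
})
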