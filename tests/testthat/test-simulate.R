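test_that("tandem arrays have exact planted geometry and complete truth", {
  spec <- genome_spec(list(repeat_family("pBVlike", "satellite", 327, 100, 0)),
                      background_length = 5000, seed = 42)
  g <- build_synthetic_genome(spec)
  seg <- g$truth$segments
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$end - seg$start, 327 * 100)
  expect_equal(g$length, 327 * 100 + 5000)
  iv <- g$truth$intervals
  expect_equal(nrow(iv), 100L)
  expect_true(all(iv$end - iv$start == 327))
  # intervals are non-overlapping, 0-based half-open, inside the genome
  iv <- iv[order(iv$start), ]
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  expect_true(all(iv$start >= 0 & iv$end <= g$length))
  # divergence 0: every monomer equals the consensus
  mono <- substring(g$sequence, iv$start + 1, iv$end)
  expect_true(all(mono == g$truth$consensus$pBVlike))
})

test_that("a spec with no families yields pure background and empty truth", {
  g <- build_synthetic_genome(genome_spec(list(), background_length = 10000,
                                          seed = 1))
  expect_equal(g$length, 10000L)
  expect_equal(nrow(g$truth$intervals), 0L)
  expect_equal(g$truth$proportions$proportion, 1)
})

test_that("planted proportions sum to one and sizing errors name the family", {
  spec <- genome_spec(list(
    repeat_family("s1", "satellite", 50, 40, 0.02),
    repeat_family("d1", "dna_transposon", 300, 5, 0.05)),
    background_length = 7000, seed = 9)
  g <- build_synthetic_genome(spec)
  expect_equal(sum(g$truth$proportions$proportion), 1, tolerance = 1e-9)
  expect_error(
    genome_spec(list(repeat_family("huge", "satellite", 1000, 100, 0)),
                genome_length = 50000),
    "huge")
  expect_error(repeat_family("x", "satellite", 10, 5), "length")
  expect_error(repeat_family("x", "satellite", 50, 0), "copies")
  expect_error(repeat_family("x", "satellite", 50, 5, divergence = 0.5),
               "divergence")
})

test_that("per-copy divergence hits the requested identity", {
  spec <- genome_spec(list(repeat_family("s", "satellite", 100, 1000, 0.05)),
                      background_length = 0, seed = 11)
  g <- build_synthetic_genome(spec)
  iv <- g$truth$intervals
  cons <- strsplit(g$truth$consensus$s, "")[[1]]
  # oracle: direct mismatch count of every monomer against the consensus
  mism <- vapply(seq_len(nrow(iv)), function(k) {
    m <- strsplit(substring(g$sequence, iv$start[k] + 1, iv$end[k]), "")[[1]]
    sum(m != cons)
  }, numeric(1))
  identity <- 100 * (1 - mean(mism) / 100)
  expect_gt(identity, 94)
  expect_lt(identity, 96)
})

test_that("LTR families share an internal domain but not their LTRs", {
  spec <- genome_spec(list(
    repeat_family("ltr1", "ltr_retrotransposon", 1000, 2, 0),
    repeat_family("ltr2", "ltr_retrotransposon", 1000, 2, 0)),
    background_length = 4000, seed = 13)
  g <- build_synthetic_genome(spec)
  c1 <- g$truth$consensus$ltr1
  c2 <- g$truth$consensus$ltr2
  ltr_len <- 150  # 0.15 * 1000
  # identical terminal repeats within an element
  expect_equal(substr(c1, 1, ltr_len), substr(c1, 1001 - ltr_len, 1000))
  # internal domains nearly identical across families (1% divergence each)
  i1 <- strsplit(substr(c1, ltr_len + 1, 1000 - ltr_len), "")[[1]]
  i2 <- strsplit(substr(c2, ltr_len + 1, 1000 - ltr_len), "")[[1]]
  expect_lt(mean(i1 != i2), 0.05)
  # family-specific LTRs are unrelated
  l1 <- strsplit(substr(c1, 1, ltr_len), "")[[1]]
  l2 <- strsplit(substr(c2, 1, ltr_len), "")[[1]]
  expect_gt(mean(l1 != l2), 0.5)
})

test_that("shotgun pair count, mate geometry and determinism are exact", {
  g <- build_synthetic_genome(genome_spec(list(), background_length = 100000,
                                          seed = 3))
  rd <- simulate_shotgun_pairs(g, coverage = 1, read_length = 100,
                               insert_size = 300, seed = 5)
  expect_equal(nrow(rd), 2 * round(1 * 100000 / (2 * 100)))
  expect_true(all(nchar(rd$seq) == 100))
  # mates are on opposite strands and their ids cross-reference
  expect_equal(rd$strand, rep(c("+", "-"), nrow(rd) / 2))
  expect_equal(rd$mate_id[seq(1, nrow(rd), 2)], rd$id[seq(2, nrow(rd), 2)])
  # the reverse mate is the reverse complement of the genome interval
  k <- 7L
  rev_row <- rd[2 * k, ]
  expect_equal(rev_row$seq,
               revcomp(substring(g$sequence, rev_row$start + 1,
                                 rev_row$start + 100)))
  # byte-identical FASTQ under the same seed
  rd2 <- simulate_shotgun_pairs(g, coverage = 1, read_length = 100,
                                insert_size = 300, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rd, f1); write_fastq(rd2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_shotgun_pairs(g, 1, 100, 200000, 1), "shorter")
})

test_that("reads originate from families in proportion to planted content", {
  spec <- genome_spec(list(repeat_family("sat", "satellite", 80, 625, 0.02)),
                      background_length = 50000, seed = 21)
  g <- build_synthetic_genome(spec)   # satellite is 50% of 100 kb
  rd <- simulate_shotgun_pairs(g, coverage = 0.2, read_length = 100,
                               insert_size = 300, seed = 22)
  frac <- mean(rd$family == "sat")
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("recorded family of origin matches interval lookup of the start", {
  spec <- genome_spec(list(
    repeat_family("sat", "satellite", 60, 100, 0.02),
    repeat_family("dta", "dna_transposon", 400, 4, 0.02)),
    background_length = 20000, seed = 31)
  g <- build_synthetic_genome(spec)
  rd <- simulate_shotgun_pairs(g, 1, 100, 300, 32)
  seg <- g$truth$segments
  lookup <- function(pos) {
    hit <- which(seg$start <= pos & pos < seg$end)
    if (length(hit)) seg$family[hit] else "background"
  }
  fam_at_start <- vapply(rd$start, lookup, character(1))
  not_junction <- rd$family != "junction"
  expect_identical(rd$family[not_junction], fam_at_start[not_junction])
  # junction reads really do cross a segment boundary
  jn <- which(rd$family == "junction")
  crosses <- vapply(jn, function(k) {
    a <- rd$start[k]; b <- a + 100
    any((seg$start > a & seg$start < b) | (seg$end > a & seg$end < b))
  }, logical(1))
  expect_true(all(crosses))
})

test_that("ChIP weighting follows the closed-form renormalisation", {
  # family at ~10% with factor 5: expected chip fraction 5p / (5p + (1-p))
  spec <- genome_spec(list(repeat_family("sat", "satellite", 50, 200, 0.01)),
                      background_length = 90000, seed = 41)
  g <- build_synthetic_genome(spec)
  sim <- simulate_chip_reads(g, chip_profile(sat = 5), n_reads = 1e5,
                             read_length = 50, seed = 42, sequences = FALSE)
  exp_row <- sim$expected[sim$expected$family == "sat", ]
  p <- exp_row$input_fraction
  expect_equal(exp_row$chip_fraction, 5 * p / (5 * p + (1 - p)),
               tolerance = 1e-12)
  obs <- mean(sim$chip$family == "sat")
  sigma <- sqrt(exp_row$chip_fraction * (1 - exp_row$chip_fraction) / 1e5)
  expect_lt(abs(obs - exp_row$chip_fraction), 3 * sigma)
  # null profile: chip and input fractions agree within binomial error
  null <- simulate_chip_reads(g, chip_profile(), n_reads = 2e4, seed = 43,
                              sequences = FALSE)
  s0 <- sqrt(p * (1 - p) / 2e4)
  expect_lt(abs(mean(null$chip$family == "sat") -
                mean(null$input$family == "sat")), 4 * s0)
  expect_error(simulate_chip_reads(g, chip_profile(), 0), "n_reads")
  g0 <- build_synthetic_genome(genome_spec(
    list(repeat_family("only", "satellite", 60, 100, 0)),
    background_length = 0, seed = 44))
  expect_error(simulate_chip_reads(g0, chip_profile(only = 0), 10,
                                   read_length = 50), "zero")
})

test_that("chip read sets are exactly sized and deterministic per seed", {
  g <- build_synthetic_genome(genome_spec(
    list(repeat_family("s", "satellite", 60, 50, 0.02)),
    background_length = 10000, seed = 51))
  a <- simulate_chip_reads(g, chip_profile(s = 3), 500, seed = 52)
  b <- simulate_chip_reads(g, chip_profile(s = 3), 500, seed = 52)
  expect_equal(nrow(a$chip), 500)
  expect_equal(nrow(a$input), 500)
  expect_identical(a$chip, b$chip)
  expect_identical(a$input, b$input)
  expect_true(all(nchar(a$chip$seq) == 50))
})

test_that("under a null profile chip-vs-input composition p-values are uniform", {
  g <- make_calibration_genome(61, n_families = 10)
  pvals <- vapply(seq_len(200), function(i) {
    sim <- simulate_chip_reads(g, chip_profile(), n_reads = 2000,
                               seed = 61000L + i, sequences = FALSE)
    lv <- unique(g$truth$proportions$family)
    tab <- rbind(table(factor(sim$chip$family, levels = lv)),
                 table(factor(sim$input$family, levels = lv)))
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
})
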