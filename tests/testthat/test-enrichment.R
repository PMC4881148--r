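test_that("trimming and subsampling follow the sampling contract", {
  set.seed(5)
  rd <- data.frame(id = c("long", "short", sprintf("r%02d", 1:8)),
                   seq = c(random_dna(138), random_dna(40),
                           vapply(1:8, function(i) random_dna(60),
                                  character(1))),
                   stringsAsFactors = FALSE)
  rd$qual <- strrep("I", nchar(rd$seq))
  full <- prepare_chip_reads(rd, trim_length = 50, n_sample = 9, seed = 1)
  # a 138 nt read keeps its first 50 nt; the 40 nt read is discarded
  expect_equal(full$seq[full$id == "long"], substr(rd$seq[1], 1, 50))
  expect_false("short" %in% full$id)
  expect_true(all(nchar(full$seq) == 50))
  # sampling the whole pool returns it unchanged (identity permutation)
  expect_equal(full$id, rd$id[-2])
  # deterministic subsample, original order preserved
  s1 <- prepare_chip_reads(rd, 50, 4, seed = 9)
  s2 <- prepare_chip_reads(rd, 50, 4, seed = 9)
  expect_identical(s1, s2)
  expect_false(is.unsorted(match(s1$id, rd$id)))
  expect_error(prepare_chip_reads(rd, 50, 100, seed = 1), "short by 91")
})

test_that("reads map to the contig containing them and junk stays unmapped", {
  set.seed(11)
  contigs <- data.frame(
    contig_id = c("CL1_C1", "CL2_C1"),
    cluster_id = c("CL1", "CL2"),
    seq = c(random_dna(500), random_dna(500)), stringsAsFactors = FALSE)
  rd <- data.frame(
    id = c("hit1", "hit2rc", "junk"),
    seq = c(substr(contigs$seq[1], 101, 150),
            revcomp(substr(contigs$seq[2], 201, 250)),
            random_dna(50)),
    stringsAsFactors = FALSE)
  m <- map_reads_to_clusters(rd, contigs)
  expect_equal(m$cluster_id, c("CL1", "CL2", NA))
  expect_equal(m$identity[1:2], c(100, 100))
  expect_equal(m$aligned_length[1:2], c(50L, 50L))
  expect_equal(m$score[1:2], c(100, 100))
  expect_true(all(m$evalue[1:2] <= 1e-12))
  # optional word-size prefilter changes nothing on clean reads
  m9 <- map_reads_to_clusters(rd, contigs, word_size = 9)
  expect_equal(m9$cluster_id, m$cluster_id)
  expect_error(map_reads_to_clusters(rd, contigs[0, ]), "empty contig")
})

test_that("best-hit mapping equals an exhaustive Biostrings oracle", {
  library(Biostrings)
  set.seed(21)
  spec <- genome_spec(list(
    repeat_family("fa", "dna_transposon", 500, 3, 0.02),
    repeat_family("fb", "dna_transposon", 600, 3, 0.02),
    repeat_family("fc", "plastid_like", 550, 3, 0.01)),
    background_length = 8000, seed = 22)
  g <- build_synthetic_genome(spec)
  sim <- simulate_chip_reads(g, chip_profile(), 80, read_length = 50,
                             seed = 23)
  contigs <- data.frame(contig_id = paste0("CL", 1:3, "_C1"),
                        cluster_id = paste0("CL", 1:3),
                        seq = unlist(g$truth$consensus, use.names = FALSE),
                        stringsAsFactors = FALSE)
  mine <- map_reads_to_clusters(sim$chip, contigs)
  oracle <- biostrings_map_oracle(sim$chip, contigs)
  expect_identical(mine$cluster_id, oracle$cluster_id)
  expect_true(any(!is.na(mine$cluster_id)))
  expect_true(any(is.na(mine$cluster_id)))
})

test_that("enrichment ratios, the indeterminate floor and the call boundary", {
  mk_maps <- function(counts, n_total) {
    cl <- rep(names(counts), counts)
    data.frame(read_id = sprintf("r%05d", seq_len(n_total)),
               cluster_id = c(cl, rep(NA, n_total - length(cl))),
               stringsAsFactors = FALSE)
  }
  chip <- mk_maps(c(CL1 = 150, CL2 = 0, CL3 = 30), 1000)
  input <- mk_maps(c(CL1 = 100, CL2 = 200, CL3 = 10), 1000)
  rec <- compute_enrichment(chip, input,
                            reference_clusters = c("CL1", "CL2", "CL3"))
  expect_equal(rec$ratio[rec$cluster_id == "CL1"], 1.5)
  expect_equal(rec$ratio[rec$cluster_id == "CL2"], 0)
  # 10 input reads < min_input 20: indeterminate, no ratio
  expect_true(rec$indeterminate[rec$cluster_id == "CL3"])
  expect_true(is.na(rec$ratio[rec$cluster_id == "CL3"]))
  called <- call_enriched(rec, threshold = 1.5)
  expect_true(called$enriched[called$cluster_id == "CL1"])    # 1.50 inclusive
  expect_false(called$enriched[called$cluster_id == "CL3"])   # indeterminate
  chip149 <- mk_maps(c(CL1 = 149, CL2 = 0, CL3 = 30), 1000)
  rec149 <- call_enriched(compute_enrichment(chip149, input), 1.5)
  expect_false(rec149$enriched[rec149$cluster_id == "CL1"])   # 1.49 < 1.5
  expect_error(compute_enrichment(chip, input[1:999, ]), "different sizes")
})

test_that("swapping chip and input inverts every determinate ratio", {
  g <- make_calibration_genome(31, n_families = 10)
  f2c <- stats::setNames(sprintf("CL%02d", 1:10), sprintf("fam%02d", 1:10))
  sim <- simulate_chip_reads(g, chip_profile(fam03 = 4), 20000, seed = 32,
                             sequences = FALSE)
  a <- compute_enrichment(maps_from_truth(sim$chip, f2c),
                          maps_from_truth(sim$input, f2c),
                          reference_clusters = unname(f2c))
  b <- compute_enrichment(maps_from_truth(sim$input, f2c),
                          maps_from_truth(sim$chip, f2c),
                          reference_clusters = unname(f2c), min_input = 20)
  det <- !a$indeterminate & !b$indeterminate & a$ratio > 0
  expect_equal(b$ratio[det], 1 / a$ratio[det], tolerance = 1e-12)
})

test_that("expected ratios are invariant to the sampling depth", {
  g <- make_calibration_genome(41, n_families = 10)
  f2c <- stats::setNames(sprintf("CL%02d", 1:10), sprintf("fam%02d", 1:10))
  ratio_at <- function(n, seed) {
    sim <- simulate_chip_reads(g, chip_profile(fam05 = 5), n, seed = seed,
                               sequences = FALSE)
    rec <- compute_enrichment(maps_from_truth(sim$chip, f2c),
                              maps_from_truth(sim$input, f2c),
                              reference_clusters = unname(f2c))
    rec$ratio[rec$cluster_id == "CL05"]
  }
  r1 <- mean(vapply(1:8, function(i) ratio_at(25000, 4100 + i), numeric(1)))
  r2 <- mean(vapply(1:8, function(i) ratio_at(50000, 4200 + i), numeric(1)))
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("unenriched families behave like negative controls", {
  g <- make_calibration_genome(51)
  below <- 0L
  runs <- 50L
  for (i in seq_len(runs)) {
    out <- calibration_ratios(g, chip_profile(fam07 = 6), 20000, 5100L + i)
    r <- out$records$ratio[out$records$cluster_id == "CL33"]  # factor 1
    if (!is.na(r) && r < 1.5) below <- below + 1L
  }
  expect_gte(below / runs, 0.95)
})

test_that("planted enrichment factors are recovered in rank order", {
  g <- make_calibration_genome(61)
  prof <- chip_profile(fam10 = 2, fam20 = 5, fam30 = 10)
  ok <- 0L
  runs <- 50L
  for (i in seq_len(runs)) {
    out <- calibration_ratios(g, prof, 30000, 6100L + i)
    rec <- out$records
    r <- rec$ratio[match(c("CL10", "CL20", "CL30"), rec$cluster_id)]
    if (!anyNA(r) && r[1] > 1.5 && r[1] < r[2] && r[2] < r[3]) ok <- ok + 1L
  }
  expect_gte(ok / runs, 0.95)
})

test_that("composition summaries are normalised within the enriched set", {
  ann <- data.frame(cluster_id = c("CL1", "CL2", "CL3"),
                    group = c("satellite", "Ty3-gypsy", "unknown"),
                    clade = c("pEV-like", "chromovirus", NA),
                    family = c("pEV", "Beetle7", NA),
                    stringsAsFactors = FALSE)
  rec <- data.frame(cluster_id = c("CL1", "CL2", "CL3"),
                    chip_count = c(70L, 30L, 10L),
                    input_count = c(40L, 20L, 30L),
                    ratio = c(1.75, 1.5, 0.33),
                    indeterminate = FALSE, stringsAsFactors = FALSE)
  rec <- call_enriched(rec)
  cs <- composition_summary(rec, ann, "group")
  expect_equal(cs$pct_of_enriched[cs$label == "satellite"], 70)
  expect_equal(cs$pct_of_enriched[cs$label == "Ty3-gypsy"], 30)
  expect_equal(sum(cs$pct_of_enriched), 100)
  # secondary normalisation against the overall read amount
  cs2 <- composition_summary(rec, ann, "group", total_reads = 1000)
  expect_equal(cs2$pct_of_total[cs2$label == "satellite"], 7)
  # single enriched cluster: that label is 100%
  rec1 <- rec; rec1$enriched <- c(TRUE, FALSE, FALSE)
  expect_equal(composition_summary(rec1, ann, "family")$pct_of_enriched, 100)
  # no enriched clusters: an explicit empty summary, not an exception
  rec0 <- rec; rec0$enriched <- FALSE
  expect_equal(nrow(composition_summary(rec0, ann, "group")), 0L)
  # uncharacterized bucket for unknown-annotated enriched clusters
  rec$enriched <- TRUE
  expect_true("uncharacterized" %in% composition_summary(rec, ann, "group")$label)
})

test_that("chip mass ordering of a planted centromeric profile is recovered", {
  # sized so both families keep an expected renormalised ratio above 1.5:
  # ratio_i = f_i / (1 + sum_j (f_j - 1) p_j)
  spec <- genome_spec(list(
    repeat_family("cen_sat", "satellite", 60, 150, 0.02),
    repeat_family("cen_ltr", "ltr_retrotransposon", 600, 6, 0.02)),
    background_length = 80000, seed = 71)
  g <- build_synthetic_genome(spec)
  f2c <- c(cen_sat = "CL1", cen_ltr = "CL2")
  sim <- simulate_chip_reads(g, chip_profile(cen_sat = 6, cen_ltr = 3),
                             40000, seed = 72, sequences = FALSE)
  rec <- call_enriched(compute_enrichment(
    maps_from_truth(sim$chip, f2c), maps_from_truth(sim$input, f2c),
    reference_clusters = c("CL1", "CL2")))
  expect_true(all(rec$enriched))
  ann <- data.frame(cluster_id = c("CL1", "CL2"),
                    group = c("satellite", "Ty3-gypsy"),
                    clade = NA, family = NA, stringsAsFactors = FALSE)
  cs <- composition_summary(rec, ann, "group")
  expect_equal(cs$label[1], "satellite")  # larger planted chip mass first
})
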