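# Independent oracles and small fixture builders used across the suite.

# plain union-find, kept deliberately simple and separate from the package's
# clustering path
uf_partition <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) i <- parent[[i]]
    i
  }
  for (k in seq_along(edges_a)) {
    ra <- find(match(edges_a[k], ids))
    rb <- find(match(edges_b[k], ids))
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  split(ids, roots)
}

# canonical form of a read partition: sorted member lists of clusters with
# >= 2 reads, plus the singleton set, both sorted
partition_key <- function(members, singletons) {
  cl <- unname(sort(vapply(members, function(m) paste(sort(m), collapse = ","),
                           character(1))))
  list(clusters = cl, singletons = sort(singletons))
}

clusters_key <- function(x) {
  partition_key(x$clusters, x$singletons)
}

# single-linkage partition from a brute-force (exhaustive, unseeded) edge
# scan: the clustering oracle
brute_partition <- function(reads, min_identity = 90, min_coverage = 0.55) {
  ex <- repeatchip:::cpp_edges_exhaustive(reads$seq, min_identity, min_coverage)
  parts <- uf_partition(reads$id, reads$id[ex$a], reads$id[ex$b])
  members <- unname(parts[lengths(parts) >= 2L])
  singletons <- unlist(parts[lengths(parts) == 1L], use.names = FALSE)
  partition_key(members, singletons)
}

# two-satellite test genome yielding ~200 shotgun reads at 1x
make_two_satellite_reads <- function(seed) {
  spec <- genome_spec(list(
    repeat_family("satA", "satellite", 60, 84, 0.02),
    repeat_family("satB", "satellite", 80, 37, 0.05)),
    background_length = 12000, seed = seed)
  g <- build_synthetic_genome(spec)
  simulate_shotgun_pairs(g, coverage = 1, read_length = 100,
                         insert_size = 300, seed = seed + 1000L)
}

# recovery genome: four satellite families planted at 10 / 5 / 2 / 0.5 %
make_recovery_genome <- function(seed) {
  build_synthetic_genome(genome_spec(list(
    repeat_family("f10", "satellite", 80, 500, 0.05),
    repeat_family("f5", "satellite", 60, 333, 0.03),
    repeat_family("f2", "satellite", 70, 114, 0.02),
    repeat_family("f05", "satellite", 50, 40, 0.01)),
    background_length = 330040, seed = seed))
}

# per-family summed proportion of clusters whose majority read origin is
# that family (matched-cluster recovery estimate)
recovered_proportions <- function(clusters, reads, families) {
  fam_of <- stats::setNames(reads$family, reads$id)
  est <- stats::setNames(numeric(length(families)), families)
  n_clusters <- stats::setNames(integer(length(families)), families)
  for (i in seq_along(clusters$clusters)) {
    labs <- fam_of[clusters$clusters[[i]]]
    top <- names(sort(table(labs), decreasing = TRUE))[1]
    if (top %in% families) {
      est[top] <- est[top] + clusters$table$proportion_pct[i]
      n_clusters[top] <- n_clusters[top] + 1L
    }
  }
  list(proportion_pct = est, n_clusters = n_clusters)
}

# 50-family calibration genome for enrichment ratio studies
make_calibration_genome <- function(seed, n_families = 50) {
  fams <- lapply(seq_len(n_families), function(i)
    repeat_family(sprintf("fam%02d", i), "satellite", 60, 30, 0.01))
  build_synthetic_genome(genome_spec(fams, background_length = 30000,
                                     seed = seed))
}

calibration_cluster_map <- function(n_families = 50) {
  stats::setNames(sprintf("CL%02d", seq_len(n_families)),
                  sprintf("fam%02d", seq_len(n_families)))
}

# one enrichment-ratio realisation on the calibration genome, using truth
# labels as the (perfect) read-cluster assignment
calibration_ratios <- function(genome, profile, n_reads, seed,
                               min_input = 20) {
  sim <- simulate_chip_reads(genome, profile, n_reads, read_length = 50,
                             seed = seed, sequences = FALSE)
  f2c <- calibration_cluster_map()
  rec <- compute_enrichment(maps_from_truth(sim$chip, f2c),
                            maps_from_truth(sim$input, f2c),
                            reference_clusters = unname(f2c),
                            min_input = min_input)
  list(records = rec, expected = sim$expected)
}

# exhaustive best-hit mapping oracle built on Biostrings::pairwiseAlignment
# (independent alignment engine; same scoring scheme and e-value rule)
biostrings_map_oracle <- function(reads, contigs, max_evalue = 1e-12) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  total_ref <- sum(nchar(contigs$seq))
  nr <- nrow(reads)
  queries <- Biostrings::DNAStringSet(c(reads$seq, revcomp(reads$seq)))
  score_mat <- matrix(NA_real_, 2L * nr, nrow(contigs))
  for (j in seq_len(nrow(contigs))) {
    pa <- Biostrings::pairwiseAlignment(
      queries, Biostrings::DNAString(contigs$seq[j]), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
      scoreOnly = TRUE)
    score_mat[, j] <- pa
  }
  out <- data.frame(read_id = reads$id, cluster_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nr)) {
    sc <- rbind(score_mat[r, ], score_mat[nr + r, ])  # strand x contig
    best <- max(sc)
    ev <- alignment_evalue(best, nchar(reads$seq[r]), total_ref)
    if (ev <= max_evalue) {
      cand <- which(sc == best, arr.ind = TRUE)
      ord <- order(contigs$cluster_id[cand[, 2]],
                   contigs$contig_id[cand[, 2]], cand[, 1])
      out$cluster_id[r] <- contigs$cluster_id[cand[ord[1], 2]]
    }
  }
  out
}

expect_same_partition <- function(a, b) {
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$singletons, b$singletons)
}
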