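#' Trim and subsample ChIP/input reads
#'
#' Each read is truncated to its first `trim_length` bases; shorter reads
#' are discarded. From the surviving pool, exactly `n_sample` reads are
#' drawn uniformly without replacement (deterministic per seed, output in
#' original pool order, so sampling the whole pool returns it unchanged).
#' ChIP and input samples must be drawn to the same `n_sample` so their
#' mapped counts are directly comparable.
#'
#' @param reads data frame with columns `id`, `seq` and optionally `qual`.
#' @param trim_length target read length in nt (default 50).
#' @param n_sample reads to retain.
#' @param seed integer seed for the subsampling.
#' @return the trimmed, sampled reads.
#' @export
prepare_chip_reads <- function(reads, trim_length = 50, n_sample, seed = 1L) {
  keep <- nchar(reads$seq) >= trim_length
  pool <- reads[keep, , drop = FALSE]
  pool$seq <- substr(pool$seq, 1L, trim_length)
  if (!is.null(pool$qual)) pool$qual <- substr(pool$qual, 1L, trim_length)
  if (n_sample > nrow(pool)) {
    stop("cannot sample ", n_sample, " reads: only ", nrow(pool),
         " available after trimming (short by ", n_sample - nrow(pool), ")")
  }
  if (n_sample < nrow(pool)) {
    set.seed(seed)
    idx <- sort(sample.int(nrow(pool), n_sample))
    pool <- pool[idx, , drop = FALSE]
  }
  rownames(pool) <- NULL
  pool
}

# Karlin-Altschul lambda for an ungapped match/mismatch scheme over uniform
# base composition: the unique positive root of
#   0.25 exp(lambda * match) + 0.75 exp(lambda * mismatch) = 1
ka_lambda <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 5), tol = 1e-12)$root
}

#' E-value of a local alignment score
#'
#' Karlin-Altschul statistics `E = K m n exp(-lambda S)` with lambda solved
#' for the match/mismatch scheme over uniform base composition and a fixed
#' `K` (default 0.41, the tabulated value for the +2/-3 scheme with gap
#' costs 5/2). `m` is the query length and `n` the total reference length.
#'
#' @param score alignment score(s).
#' @param m query length in nt.
#' @param n total reference (database) length in nt.
#' @param match,mismatch the scoring scheme (defaults +2/-3).
#' @param K Karlin-Altschul K (default 0.41).
#' @return e-value(s).
#' @export
alignment_evalue <- function(score, m, n, match = 2, mismatch = -3, K = 0.41) {
  lambda <- ka_lambda(match, mismatch)
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

#' Map reads to cluster contigs by best local alignment
#'
#' Smith-Waterman local alignment on both strands with BLASTN-style scoring
#' (defaults: match +2, mismatch -3, gap open 5, gap extend 2, no masking).
#' A read maps if and only if its best hit has an e-value at or below
#' `max_evalue`; the best hit is the lowest e-value (equivalently highest
#' score), with ties broken by lowest cluster id then contig id. Each read
#' maps to at most one cluster.
#'
#' By default every read/contig/strand combination is scored exactly, so
#' best-hit assignment matches an exhaustive dynamic-programming oracle.
#' Setting `word_size` (e.g. 9) restricts scoring to combinations sharing an
#' exact word of that length — much faster and lossless in practice for
#' reads drawn from the contigs' families, though a sufficiently degenerate
#' borderline hit with no exact word could be skipped.
#'
#' @param reads data frame with columns `id`, `seq`.
#' @param contigs data frame with columns `contig_id`, `cluster_id`, `seq`.
#' @param max_evalue mapping threshold (default 1e-12).
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @param word_size optional integer k-mer prefilter; `NULL` = exact.
#' @param details if `TRUE` (default) the best hit of every mapped read is
#'   tracebacked to report identity and aligned length.
#' @return data frame with one row per read: `read_id`, `cluster_id` (NA if
#'   unmapped), `contig_id`, `score`, `evalue`, and with `details` also
#'   `identity`, `aligned_length`.
#' @export
map_reads_to_clusters <- function(reads, contigs, max_evalue = 1e-12,
                                  match = 2, mismatch = -3, gap_open = 5,
                                  gap_extend = 2, word_size = NULL,
                                  details = TRUE) {
  if (is.null(contigs) || nrow(contigs) == 0L) stop("empty contig set")
  nr <- nrow(reads)
  nc <- nrow(contigs)
  total_ref <- sum(nchar(contigs$seq))
  queries <- c(reads$seq, revcomp(reads$seq))

  if (is.null(word_size)) {
    qi <- rep(seq_len(2L * nr), each = nc)
    si <- rep(seq_len(nc), times = 2L * nr)
  } else {
    cand <- cpp_kmer_candidates(reads$seq, contigs$seq,
                                as.integer(word_size))
    if (nrow(cand) == 0L) {
      qi <- integer(0); si <- integer(0)
    } else {
      qi <- cand$query + cand$strand * nr
      si <- cand$subject
    }
  }

  out <- data.frame(read_id = reads$id, cluster_id = NA_character_,
                    contig_id = NA_character_, score = NA_real_,
                    evalue = NA_real_, stringsAsFactors = FALSE)
  if (details) {
    out$identity <- NA_real_
    out$aligned_length <- NA_integer_
  }
  if (length(qi)) {
    sc <- cpp_sw_score_pairs(queries, contigs$seq, qi, si,
                             match, mismatch, gap_open, gap_extend)
    ridx <- ((qi - 1L) %% nr) + 1L
    # per read: highest score, ties by lowest cluster then contig id, then
    # + strand
    ord <- order(ridx, -sc, contigs$cluster_id[si], contigs$contig_id[si],
                 qi > nr)
    first <- ord[!duplicated(ridx[ord])]
    ev <- alignment_evalue(sc[first], nchar(reads$seq[ridx[first]]),
                           total_ref, match, mismatch)
    mapped <- ev <= max_evalue
    rows <- ridx[first][mapped]
    out$cluster_id[rows] <- contigs$cluster_id[si[first][mapped]]
    out$contig_id[rows] <- contigs$contig_id[si[first][mapped]]
    out$score[rows] <- sc[first][mapped]
    out$evalue[rows] <- ev[mapped]
    if (details && any(mapped)) {
      sel <- first[mapped]
      for (t in seq_along(sel)) {
        tb <- cpp_sw_traceback(queries[qi[sel[t]]], contigs$seq[si[sel[t]]],
                               match, mismatch, gap_open, gap_extend)
        r <- ridx[sel[t]]
        out$identity[r] <- if (tb$length > 0) 100 * tb$matches / tb$length else 0
        out$aligned_length[r] <- tb$length
      }
    }
  }
  out
}

#' Per-cluster ChIP/input enrichment records
#'
#' Counts ChIP and input reads assigned to each reference cluster and forms
#' the plain ratio `chip_count / input_count`. Clusters with fewer than
#' `min_input` input reads get no ratio and are flagged indeterminate
#' (reported, never silently dropped). A per-mapped-sample normalised ratio
#' is reported alongside. Both map sets must contain the same total number
#' of reads, otherwise the ratio would be biased.
#'
#' @param chip_maps,input_maps mapping tables with columns `read_id`,
#'   `cluster_id` (NA = unmapped), e.g. from [map_reads_to_clusters()].
#' @param reference_clusters cluster ids to report; defaults to every
#'   cluster seen in either map set.
#' @param min_input minimum input count for a determinate ratio
#'   (default 20).
#' @return data frame of class `enrichment_records`: `cluster_id`,
#'   `chip_count`, `input_count`, `ratio`, `ratio_normalized`,
#'   `indeterminate`.
#' @export
compute_enrichment <- function(chip_maps, input_maps,
                               reference_clusters = NULL, min_input = 20) {
  if (nrow(chip_maps) != nrow(input_maps)) {
    stop("ChIP and input were sampled to different sizes (",
         nrow(chip_maps), " vs ", nrow(input_maps),
         "); ratios would be biased")
  }
  if (is.null(reference_clusters)) {
    reference_clusters <- sort(unique(c(chip_maps$cluster_id,
                                        input_maps$cluster_id)))
    reference_clusters <- reference_clusters[!is.na(reference_clusters)]
  }
  cc <- table(factor(chip_maps$cluster_id, levels = reference_clusters))
  ic <- table(factor(input_maps$cluster_id, levels = reference_clusters))
  chip_count <- as.integer(cc)
  input_count <- as.integer(ic)
  indeterminate <- input_count < min_input
  ratio <- ifelse(indeterminate, NA_real_, chip_count / input_count)
  chip_mapped <- sum(!is.na(chip_maps$cluster_id))
  input_mapped <- sum(!is.na(input_maps$cluster_id))
  ratio_norm <- if (chip_mapped > 0 && input_mapped > 0) {
    ifelse(indeterminate, NA_real_,
           (chip_count / chip_mapped) / (input_count / input_mapped))
  } else NA_real_
  out <- data.frame(cluster_id = reference_clusters,
                    chip_count = chip_count, input_count = input_count,
                    ratio = ratio, ratio_normalized = ratio_norm,
                    indeterminate = indeterminate,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_records", "data.frame")
  out
}

#' Call enriched clusters at a ChIP/input ratio threshold
#'
#' A cluster is enriched when its ratio reaches the threshold (inclusive;
#' the conventional cutoff is 1.5). Indeterminate clusters are never
#' enriched.
#'
#' @param records an `enrichment_records` table.
#' @param threshold minimum ChIP/input ratio (default 1.5).
#' @return the records with a logical `enriched` column.
#' @export
call_enriched <- function(records, threshold = 1.5) {
  records$enriched <- !records$indeterminate & !is.na(records$ratio) &
    records$ratio >= threshold
  records
}

#' Repeat composition of the enriched fraction
#'
#' Sums ChIP read counts of enriched clusters per annotation label and
#' expresses each label's share in percent. The primary denominator is the
#' total ChIP count over enriched clusters (shares sum to 100 within each
#' hierarchy level); when `total_reads` is given, a secondary column
#' normalised to that overall read amount is added. Enriched clusters with
#' group `unknown` appear as `"uncharacterized"`.
#'
#' @param records an `enrichment_records` table with an `enriched` column
#'   (see [call_enriched()]).
#' @param annotations per-cluster annotation table (see
#'   [annotate_clusters()]).
#' @param level hierarchy level: `"group"`, `"clade"` or `"family"`.
#' @param total_reads optional overall read amount for the secondary
#'   normalisation.
#' @return data frame with columns `label`, `chip_count`,
#'   `pct_of_enriched` and optionally `pct_of_total`; empty (not an error)
#'   when nothing is enriched.
#' @export
composition_summary <- function(records, annotations,
                                level = c("group", "clade", "family"),
                                total_reads = NULL) {
  level <- match.arg(level)
  if (is.null(records$enriched)) stop("run call_enriched() first")
  enr <- records[records$enriched, , drop = FALSE]
  empty <- data.frame(label = character(0), chip_count = integer(0),
                      pct_of_enriched = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(total_reads)) empty$pct_of_total <- numeric(0)
  if (nrow(enr) == 0L) return(empty)
  lab <- annotations[[level]][match(enr$cluster_id, annotations$cluster_id)]
  lab[is.na(lab) | lab == "unknown"] <- "uncharacterized"
  tot <- sum(enr$chip_count)
  agg <- tapply(enr$chip_count, lab, sum)
  out <- data.frame(label = names(agg), chip_count = as.integer(agg),
                    pct_of_enriched = if (tot > 0) 100 * as.integer(agg) / tot
                                      else 0,
                    stringsAsFactors = FALSE)
  if (!is.null(total_reads)) {
    out$pct_of_total <- 100 * out$chip_count / total_reads
  }
  out <- out[order(-out$chip_count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Turn simulator truth labels into a mapping table
#'
#' For reads simulated with known family of origin, assigns each read the
#' cluster standing for its family (perfect-mapping regime, useful for
#' calibration studies of the ratio statistic itself); junction and
#' background reads stay unmapped.
#'
#' @param reads read data frame with a `family` column.
#' @param family_to_cluster named character vector mapping family name to
#'   cluster id.
#' @return data frame with `read_id`, `cluster_id`.
#' @export
maps_from_truth <- function(reads, family_to_cluster) {
  cl <- unname(family_to_cluster[reads$family])
  data.frame(read_id = reads$id, cluster_id = cl, stringsAsFactors = FALSE)
}
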