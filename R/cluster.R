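#' Quality-filter a read set
#'
#' Keeps reads whose mean Phred quality reaches `min_mean_quality` and whose
#' fraction of ambiguous bases (N) does not exceed `max_n_fraction`. Reads
#' without quality strings pass the quality criterion. The returned subset
#' preserves input order and carries a filter report as attribute
#' `"filter_report"` (kept, dropped by each reason).
#'
#' @param reads data frame with columns `id`, `seq` and optionally `qual`
#'   (Phred+33).
#' @param min_mean_quality minimum per-read mean Phred score (default 20).
#' @param max_n_fraction maximum tolerated N fraction (default 0.05).
#' @return the retained reads.
#' @export
quality_filter <- function(reads, min_mean_quality = 20, max_n_fraction = 0.05) {
  if (is.null(reads) || nrow(reads) == 0L) stop("no reads to filter")
  n <- nchar(reads$seq)
  n_frac <- (n - nchar(gsub("N", "", reads$seq, fixed = TRUE))) / pmax(n, 1L)
  if (!is.null(reads$qual)) {
    mq <- vapply(reads$qual, function(q) mean(utf8ToInt(q)) - 33,
                 numeric(1), USE.NAMES = FALSE)
  } else {
    mq <- rep(Inf, nrow(reads))
  }
  low_q <- mq < min_mean_quality
  many_n <- n_frac > max_n_fraction
  keep <- !low_q & !many_n
  if (!any(keep)) stop("all ", nrow(reads), " reads removed by filtering")
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- data.frame(
    kept = sum(keep),
    dropped_low_quality = sum(low_q),
    dropped_n_fraction = sum(many_n & !low_q))
  out
}

#' All-vs-all read similarity edges
#'
#' An (undirected) edge joins two reads when a gapless local alignment, on
#' either strand, reaches at least `min_identity` percent identity over at
#' least `min_coverage` of the shorter read. Candidate read pairs and
#' diagonals come from shared k-mers; with the default `kmer_seed_length = 8`
#' the seeding provably loses no qualifying pair on substitution-only data
#' at the default thresholds (see the vignette).
#'
#' @param reads data frame with columns `id` and `seq` (at least 2 rows).
#' @param min_identity minimum percent identity of the aligned window
#'   (default 90).
#' @param min_coverage minimum aligned fraction of the shorter read
#'   (default 0.55).
#' @param kmer_seed_length k-mer length of the candidate prefilter
#'   (default 8).
#' @return data frame with columns `read_a`, `read_b` (with
#'   `read_a < read_b`), `identity`, `coverage`, `length`, `strand`
#'   (0 = same strand, 1 = opposite).
#' @export
pairwise_similarities <- function(reads, min_identity = 90, min_coverage = 0.55,
                                  kmer_seed_length = 8) {
  if (nrow(reads) < 2L) stop("need at least 2 reads")
  res <- cpp_edges_seeded(reads$seq, as.integer(kmer_seed_length),
                          min_identity, min_coverage, FALSE)
  ids_a <- reads$id[res$a]
  ids_b <- reads$id[res$b]
  swap <- ids_a > ids_b
  tmp <- ids_a[swap]; ids_a[swap] <- ids_b[swap]; ids_b[swap] <- tmp
  out <- data.frame(read_a = ids_a, read_b = ids_b,
                    identity = res$identity, coverage = res$coverage,
                    length = res$length, strand = res$strand,
                    stringsAsFactors = FALSE)
  out[order(out$read_a, out$read_b), , drop = FALSE]
}

new_repeat_clusters <- function(members, singletons, n_total) {
  sizes <- lengths(members)
  ord <- order(-sizes, vapply(members, min, character(1)))
  members <- members[ord]
  names(members) <- if (length(members))
    paste0("CL", seq_along(members)) else character(0)
  tab <- data.frame(cluster_id = character(length(members)),
                    n_reads = lengths(members),
                    stringsAsFactors = FALSE)
  tab$cluster_id <- names(members)
  structure(list(clusters = members, singletons = singletons,
                 table = tab, n_total = n_total),
            class = "repeat_clusters")
}

#' Partition reads into repeat clusters from a similarity edge list
#'
#' Clusters are the connected components (>= 2 reads) of the similarity
#' graph, ranked by descending read count with ties broken by the smallest
#' member id; reads in no edge are singletons. The partition is exhaustive
#' and disjoint over `all_read_ids`.
#'
#' @param edges edge data frame from [pairwise_similarities()].
#' @param all_read_ids ids of every analysed read.
#' @return a `repeat_clusters` object: list with `clusters` (named list of
#'   read-id vectors, ranked), `singletons`, `table` (cluster_id, n_reads)
#'   and `n_total`.
#' @export
detect_clusters <- function(edges, all_read_ids) {
  all_read_ids <- as.character(all_read_ids)
  if (nrow(edges)) {
    bad <- setdiff(unique(c(edges$read_a, edges$read_b)), all_read_ids)
    if (length(bad)) stop("edges reference unknown read ids: ",
                          paste(head(bad, 3), collapse = ", "))
    g <- igraph::graph_from_data_frame(edges[, c("read_a", "read_b")],
                                       directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    members <- unname(members[lengths(members) >= 2L])
  } else {
    members <- list()
  }
  clustered <- unlist(members, use.names = FALSE)
  singletons <- setdiff(all_read_ids, clustered)
  new_repeat_clusters(members, singletons, length(all_read_ids))
}

#' Cluster reads in one pass (seeded graph + incremental merging)
#'
#' Produces the same partition as
#' `detect_clusters(pairwise_similarities(reads), reads$id)` without
#' materialising the full edge list: candidate pairs whose endpoints are
#' already connected are skipped, which cannot change the connected
#' components.
#'
#' @inheritParams pairwise_similarities
#' @return a `repeat_clusters` object (see [detect_clusters()]).
#' @export
cluster_reads <- function(reads, min_identity = 90, min_coverage = 0.55,
                          kmer_seed_length = 8) {
  if (nrow(reads) < 2L) stop("need at least 2 reads")
  res <- cpp_edges_seeded(reads$seq, as.integer(kmer_seed_length),
                          min_identity, min_coverage, TRUE)
  parent <- res$parent
  grp <- split(reads$id, parent)
  members <- unname(grp[lengths(grp) >= 2L])
  singles <- unlist(grp[lengths(grp) == 1L], use.names = FALSE)
  new_repeat_clusters(members, singles, nrow(reads))
}

#' @export
print.repeat_clusters <- function(x, ...) {
  cat("Repeat clustering:", length(x$clusters), "clusters,",
      length(x$singletons), "singletons,", x$n_total, "reads\n")
  tab <- x$table
  if (!is.null(tab$proportion_pct)) {
    tab$proportion_pct <- sprintf("%.4f", tab$proportion_pct)
  }
  print(head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("...", nrow(tab) - 10, "more clusters\n")
  invisible(x)
}

#' @export
summary.repeat_clusters <- function(object, ...) {
  in_clusters <- sum(lengths(object$clusters))
  cat("Reads analysed:   ", object$n_total, "\n")
  cat("Reads in clusters:", in_clusters,
      sprintf("(%.1f%%)", 100 * in_clusters / object$n_total), "\n")
  cat("Singletons:       ", length(object$singletons), "\n")
  cat("Clusters:         ", length(object$clusters), "\n")
  invisible(object)
}

#' Genome proportion of a cluster from read counts
#'
#' The share of the genome attributed to a repeat cluster is the share of
#' analysed reads it contains, expressed in percent:
#' `100 * n_reads / total_analyzed_reads`.
#'
#' @param n_reads read count(s) of the cluster(s).
#' @param total_analyzed_reads clustered + singleton reads after filtering.
#' @return percentage(s).
#' @export
genome_proportion <- function(n_reads, total_analyzed_reads) {
  if (total_analyzed_reads <= 0) stop("total_analyzed_reads must be > 0")
  100 * n_reads / total_analyzed_reads
}

#' Attach genome proportions to a clustering
#'
#' @param clusters a `repeat_clusters` object.
#' @param total_analyzed_reads denominator; defaults to the number of reads
#'   that entered the clustering (clustered + singletons).
#' @return the clustering with a `proportion_pct` column in its `table`.
#' @export
add_proportions <- function(clusters, total_analyzed_reads = clusters$n_total) {
  clusters$table$proportion_pct <-
    genome_proportion(clusters$table$n_reads, total_analyzed_reads)
  clusters
}

#' Select clusters abundant enough to annotate
#'
#' Retains clusters whose genome proportion is at least `threshold` percent
#' (boundary inclusive), preserving rank order. The retained set is the
#' reference against which ChIP and input reads are mapped.
#'
#' @param clusters a `repeat_clusters` object with proportions (see
#'   [add_proportions()]).
#' @param threshold minimum genome proportion in percent (default 0.01).
#' @return the clustering restricted to the selected clusters.
#' @export
select_annotatable_clusters <- function(clusters, threshold = 0.01) {
  if (is.null(clusters$table$proportion_pct))
    stop("proportions not computed; run add_proportions() first")
  keep <- clusters$table$proportion_pct >= threshold
  out <- clusters
  out$clusters <- clusters$clusters[keep]
  out$table <- clusters$table[keep, , drop = FALSE]
  rownames(out$table) <- NULL
  out
}

#' Inter-cluster links through mate pairs
#'
#' Counts read pairs whose two mates fall into two distinct clusters; pairs
#' of clusters joined by at least `min_links` such mate pairs are reported.
#' Links indicate repeats split between clusters (e.g. the LTRs and the
#' internal domain of one retrotransposon family) and serve as annotation
#' hints only.
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads read data frame with `id` and `mate_id` columns.
#' @param min_links minimum number of spanning mate pairs (default 5).
#' @return data frame with columns `cluster_a`, `cluster_b`, `n_pairs`.
#' @export
link_clusters_by_pairs <- function(clusters, reads, min_links = 5) {
  empty <- data.frame(cluster_a = character(0), cluster_b = character(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
  if (is.null(reads$mate_id) || length(clusters$clusters) < 2L) return(empty)
  member <- rep(names(clusters$clusters), lengths(clusters$clusters))
  names(member) <- unlist(clusters$clusters, use.names = FALSE)
  c1 <- unname(member[reads$id])
  c2 <- unname(member[reads$mate_id])
  ok <- !is.na(c1) & !is.na(c2) & c1 != c2 & reads$id < reads$mate_id
  if (!any(ok)) return(empty)
  a <- pmin(c1[ok], c2[ok]); b <- pmax(c1[ok], c2[ok])
  tab <- table(paste(a, b, sep = "\t"))
  tab <- tab[tab >= min_links]
  if (!length(tab)) return(empty)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(cluster_a = vapply(parts, `[`, character(1), 1),
                    cluster_b = vapply(parts, `[`, character(1), 2),
                    n_pairs = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_pairs, out$cluster_a), , drop = FALSE]
}
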