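#' Assemble cluster reads into consensus contigs by greedy exact overlap
#'
#' Repeatedly merges the pair of contigs with the longest exact
#' suffix-prefix overlap of at least `min_overlap` nucleotides, trying both
#' orientations of each partner (strand-aware). Because only exact overlaps
#' are merged, the merged columns agree by construction, so the
#' majority-vote consensus over a merged column is the shared base itself.
#' Reads that never merge remain single-read contigs; the contig set covers
#' every read. Overlaps are maintained incrementally, so a merge only
#' rescores the new contig against the surviving ones.
#'
#' @param reads data frame with columns `id` and `seq` (the members of one
#'   cluster; at least 1 row) or a named character vector of sequences.
#' @param min_overlap minimum exact overlap in nt (default 31).
#' @return data frame with columns `contig_id`, `seq`, `n_reads`, plus a
#'   `reads` attribute (list of member read ids per contig).
#' @export
build_cluster_contigs <- function(reads, min_overlap = 31) {
  if (is.character(reads)) {
    if (length(reads) == 0L) stop("no reads to assemble")
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("r", seq_along(reads))
    reads <- data.frame(id = ids, seq = unname(reads), stringsAsFactors = FALSE)
  }
  n <- nrow(reads)
  if (n == 0L) stop("no reads to assemble")
  min_overlap <- as.integer(min_overlap)

  # contig slots: at most n + (n-1) contigs ever exist
  cap <- 2L * n
  seqf <- character(cap); seqr <- character(cap)
  members <- vector("list", cap)
  seqf[seq_len(n)] <- reads$seq
  seqr[seq_len(n)] <- revcomp(reads$seq)
  members[seq_len(n)] <- as.list(reads$id)
  alive <- c(rep(TRUE, n), rep(FALSE, cap - n))
  m <- n

  if (n > 1L) {
    # oriented entries: k in 1..cap is contig k forward, cap + k is its
    # reverse complement. O[i, j] = longest exact suffix(i)/prefix(j)
    # overlap. Same-contig pairs and rc-rc pairs (mirror images of
    # forward-forward joins) are kept at zero.
    oseq <- function(k) {
      out <- character(length(k))
      r <- k > cap
      out[!r] <- seqf[k[!r]]
      out[r] <- seqr[k[r] - cap]
      out
    }
    ocontig <- function(k) ifelse(k > cap, k - cap, k)
    O <- matrix(0L, 2L * cap, 2L * cap)
    init <- c(seq_len(n), cap + seq_len(n))
    ov <- cpp_overlap_matrix(oseq(init), oseq(init), min_overlap)
    ci <- ocontig(init)
    ov[outer(ci, ci, "==")] <- 0L
    ov[init > cap, init > cap] <- 0L
    O[init, init] <- ov

    repeat {
      best <- max(O)
      if (best < min_overlap) break
      hit <- which(O == best, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      i <- hit[1, 1]; j <- hit[1, 2]
      ci <- ocontig(i); cj <- ocontig(j)
      merged <- paste0(oseq(i), substr(oseq(j), best + 1L, nchar(oseq(j))))
      m <- m + 1L
      seqf[m] <- merged
      seqr[m] <- revcomp(merged)
      members[[m]] <- c(members[[ci]], members[[cj]])
      alive[c(ci, cj)] <- FALSE
      alive[m] <- TRUE
      gone <- c(ci, cj, cap + ci, cap + cj)
      O[gone, ] <- 0L
      O[, gone] <- 0L
      act <- which(alive[seq_len(m)])
      act <- act[act != m]
      if (length(act)) {
        others <- c(act, cap + act)
        new_or <- c(m, cap + m)
        row_ov <- cpp_overlap_matrix(oseq(new_or), oseq(others), min_overlap)
        col_ov <- cpp_overlap_matrix(oseq(others), oseq(new_or), min_overlap)
        # zero the rc-rc combinations
        row_ov[2L, others > cap] <- 0L
        col_ov[others > cap, 2L] <- 0L
        O[new_or, others] <- row_ov
        O[others, new_or] <- col_ov
      }
      if (sum(alive) < 2L) break
    }
  }

  keep <- which(alive[seq_len(m)])
  seqs <- seqf[keep]
  mem <- members[keep]
  ord <- order(-nchar(seqs), vapply(mem, min, character(1)))
  seqs <- seqs[ord]; mem <- mem[ord]
  out <- data.frame(contig_id = paste0("C", seq_along(seqs)),
                    seq = seqs, n_reads = lengths(mem),
                    stringsAsFactors = FALSE)
  attr(out, "reads") <- stats::setNames(mem, out$contig_id)
  out
}

#' Assemble contigs for every cluster of a clustering
#'
#' @param clusters a `repeat_clusters` object.
#' @param reads the read data frame the clustering was built from.
#' @param min_overlap minimum exact overlap in nt (default 31).
#' @return data frame with columns `cluster_id`, `contig_id`, `seq`,
#'   `n_reads`; contig ids are `<cluster>_<contig>`.
#' @export
assemble_clusters <- function(clusters, reads, min_overlap = 31) {
  seq_of <- stats::setNames(reads$seq, reads$id)
  pieces <- lapply(names(clusters$clusters), function(cl) {
    ids <- clusters$clusters[[cl]]
    ctg <- build_cluster_contigs(
      data.frame(id = ids, seq = unname(seq_of[ids]), stringsAsFactors = FALSE),
      min_overlap = min_overlap)
    data.frame(cluster_id = cl,
               contig_id = paste0(cl, "_", ctg$contig_id),
               seq = ctg$seq, n_reads = ctg$n_reads,
               stringsAsFactors = FALSE)
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(cluster_id = character(0), contig_id = character(0),
               seq = character(0), n_reads = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
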