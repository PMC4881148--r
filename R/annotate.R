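#' Read a hierarchical repeat reference database from FASTA
#'
#' Header convention: `>id group|clade|family`; clade and family may be
#' empty. Groups follow the usual repeat taxonomy (satellite, Ty3-gypsy,
#' Ty1-copia, ENV-like, LINE, SINE, DNA-transposon, rDNA, pararetrovirus,
#' plastid, telomeric, unknown).
#'
#' @param path FASTA file.
#' @return data frame with columns `id`, `seq`, `group`, `clade`, `family`.
#' @export
read_repeat_db <- function(path) {
  fa <- read_sequences(path)
  lab <- sub("^\\S+\\s*", "", fa$desc)
  parts <- strsplit(lab, "|", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i && nzchar(trimws(p[i]))) trimws(p[i]) else NA_character_
  }, character(1))
  db <- data.frame(id = fa$id, seq = fa$seq, group = get(1), clade = get(2),
                   family = get(3), stringsAsFactors = FALSE)
  if (anyNA(db$group)) stop("repeat db records must carry a group label")
  db
}

#' Write a repeat reference database as FASTA
#'
#' @param db data frame with columns `id`, `seq`, `group`, `clade`, `family`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeat_db <- function(db, path) {
  blank <- function(x) ifelse(is.na(x), "", x)
  hdr <- paste0(db$id, " ", blank(db$group), "|", blank(db$clade), "|",
                blank(db$family))
  write_fasta(stats::setNames(db$seq, hdr), path)
}

# best database hit of one contig: highest local-alignment score over all
# records and both strands; ties broken by lower record index, + strand first
best_db_hit <- function(contig_seq, db, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2) {
  queries <- c(contig_seq, revcomp(contig_seq))
  nrec <- nrow(db)
  qi <- rep(c(1L, 2L), each = nrec)
  si <- rep(seq_len(nrec), 2L)
  sc <- cpp_sw_score_pairs(queries, db$seq, qi, si, match, mismatch,
                           gap_open, gap_extend)
  # ties broken by record id (not record position, so permuting the
  # database never changes the result), then + strand first
  best_at <- order(-sc, db$id[si], qi)[1]
  tb <- cpp_sw_traceback(queries[qi[best_at]], db$seq[si[best_at]],
                         match, mismatch, gap_open, gap_extend)
  list(record = si[best_at], score = tb$score,
       identity = if (tb$length > 0) 100 * tb$matches / tb$length else 0,
       aligned_length = tb$length)
}

#' Annotate one cluster by majority vote over its contigs' database hits
#'
#' Each contig's best database hit (local alignment, both strands) votes
#' with weight equal to the number of reads in the contig, provided the hit
#' reaches `min_identity` percent identity over at least `min_hit_length`
#' aligned nucleotides. The cluster label is assigned at the deepest
#' hierarchy level (family > clade > group) where a strict majority (> 50%)
#' of the voting weight agrees; clusters with no qualifying hit are labelled
#' group `"unknown"`. The result does not depend on database record order.
#'
#' @param contigs data frame with columns `seq` and `n_reads` (one cluster's
#'   contigs, e.g. from [build_cluster_contigs()]).
#' @param db reference database (see [read_repeat_db()]).
#' @param min_identity minimum hit identity in percent (default 80).
#' @param min_hit_length minimum aligned length in nt (default 50).
#' @return list of class `repeat_annotation`: `group`, `clade`, `family`
#'   (NA below the assigned level), `support` (fraction of voting weight
#'   agreeing at the assigned level) and `n_hits` (number of voting
#'   contigs).
#' @export
annotate_cluster <- function(contigs, db, min_identity = 80,
                             min_hit_length = 50) {
  if (nrow(db) == 0L) stop("empty reference database")
  votes <- list()
  n_hits <- 0L
  for (i in seq_len(nrow(contigs))) {
    hit <- best_db_hit(contigs$seq[i], db)
    if (hit$identity >= min_identity && hit$aligned_length >= min_hit_length) {
      n_hits <- n_hits + 1L
      votes[[length(votes) + 1L]] <- data.frame(
        weight = contigs$n_reads[i],
        group = db$group[hit$record], clade = db$clade[hit$record],
        family = db$family[hit$record], stringsAsFactors = FALSE)
    }
  }
  unknown <- structure(list(group = "unknown", clade = NA_character_,
                            family = NA_character_, support = NA_real_,
                            n_hits = 0L), class = "repeat_annotation")
  if (!length(votes)) return(unknown)
  v <- do.call(rbind, votes)
  W <- sum(v$weight)
  majority <- function(labels) {
    ok <- !is.na(labels)
    if (!any(ok)) return(NULL)
    w <- tapply(v$weight[ok], labels[ok], sum)
    top <- which.max(w)
    if (w[top] > W / 2) list(label = names(w)[top], support = unname(w[top]) / W)
    else NULL
  }
  fam <- majority(ifelse(is.na(v$family), NA,
                         paste(v$group, v$clade, v$family, sep = "\r")))
  if (!is.null(fam)) {
    p <- strsplit(fam$label, "\r", fixed = TRUE)[[1]]
    return(structure(list(group = p[1], clade = p[2], family = p[3],
                          support = fam$support, n_hits = n_hits),
                     class = "repeat_annotation"))
  }
  cl <- majority(ifelse(is.na(v$clade), NA, paste(v$group, v$clade, sep = "\r")))
  if (!is.null(cl)) {
    p <- strsplit(cl$label, "\r", fixed = TRUE)[[1]]
    return(structure(list(group = p[1], clade = p[2], family = NA_character_,
                          support = cl$support, n_hits = n_hits),
                     class = "repeat_annotation"))
  }
  gr <- majority(v$group)
  if (!is.null(gr)) {
    return(structure(list(group = gr$label, clade = NA_character_,
                          family = NA_character_, support = gr$support,
                          n_hits = n_hits), class = "repeat_annotation"))
  }
  unknown$n_hits <- n_hits
  unknown
}

#' @export
print.repeat_annotation <- function(x, ...) {
  lab <- paste(Filter(function(z) !is.na(z), c(x$group, x$clade, x$family)),
               collapse = " / ")
  cat("Repeat annotation:", lab,
      if (!is.na(x$support)) sprintf("(support %.2f, %d voting contigs)",
                                     x$support, x$n_hits) else "", "\n")
  invisible(x)
}

#' Annotate every cluster of a clustering
#'
#' @param contig_table contigs of all clusters (see [assemble_clusters()]).
#' @param db reference database.
#' @param clusters optional `repeat_clusters` object with proportions; when
#'   given, proportions are carried into the output.
#' @inheritParams annotate_cluster
#' @return data frame with one row per cluster: `cluster_id`, `group`,
#'   `clade`, `family`, `support`, `n_hits` (+ `n_reads`, `proportion_pct`
#'   when available).
#' @export
annotate_clusters <- function(contig_table, db, clusters = NULL,
                              min_identity = 80, min_hit_length = 50) {
  ids <- unique(contig_table$cluster_id)
  rows <- lapply(ids, function(cl) {
    ann <- annotate_cluster(contig_table[contig_table$cluster_id == cl, ,
                                         drop = FALSE],
                            db, min_identity, min_hit_length)
    data.frame(cluster_id = cl, group = ann$group, clade = ann$clade,
               family = ann$family, support = ann$support,
               n_hits = ann$n_hits, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), group = character(0),
               clade = character(0), family = character(0),
               support = numeric(0), n_hits = integer(0),
               stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    out <- merge(clusters$table, out, by = "cluster_id", sort = FALSE)
    out <- out[match(clusters$table$cluster_id, out$cluster_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate annotated clusters into a repeat-group composition table
#'
#' Sums genome proportions per repeat group; clusters annotated `unknown`
#' are reported under `"Unknown"`.
#'
#' @param annotated data frame with columns `group` and `proportion_pct`
#'   (see [annotate_clusters()]).
#' @return data frame with columns `group`, `n_clusters`, `proportion_pct`,
#'   sorted by descending proportion.
#' @export
aggregate_repeat_groups <- function(annotated) {
  if (nrow(annotated) == 0L) {
    return(data.frame(group = character(0), n_clusters = integer(0),
                      proportion_pct = numeric(0), stringsAsFactors = FALSE))
  }
  grp <- ifelse(annotated$group == "unknown", "Unknown", annotated$group)
  agg <- aggregate(annotated$proportion_pct, by = list(group = grp), FUN = sum)
  cnt <- aggregate(rep(1L, nrow(annotated)), by = list(group = grp), FUN = sum)
  out <- data.frame(group = agg$group, n_clusters = cnt$x,
                    proportion_pct = agg$x, stringsAsFactors = FALSE)
  out[order(-out$proportion_pct, out$group), , drop = FALSE]
}
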