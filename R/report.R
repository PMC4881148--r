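#' Genome sizes used to convert proportions into physical sizes
#'
#' Defaults are the sugar beet convention: a 758 Mb estimated genome for
#' read-clustering proportions and the 567 Mb assembly for assembly-based
#' proportions.
#'
#' @param estimated_genome_mb estimated genome size in Mb.
#' @param assembly_mb assembly size in Mb.
#' @return list with the two sizes.
#' @export
genome_sizes <- function(estimated_genome_mb = 758, assembly_mb = 567) {
  if (estimated_genome_mb <= 0 || assembly_mb <= 0)
    stop("genome sizes must be > 0")
  list(estimated_genome_mb = estimated_genome_mb, assembly_mb = assembly_mb)
}

#' Convert a genome proportion to megabases
#'
#' `pct/100 * genome_mb`, rounded half-up to 2 decimals — the arithmetic of
#' repeat-content comparison tables, where size deltas are consistent with
#' differencing the printed (rounded) sizes.
#'
#' @param pct genome proportion in percent (>= 0).
#' @param genome_mb genome size in megabases (> 0).
#' @return size in Mb, rounded to 2 decimals.
#' @export
proportion_to_megabases <- function(pct, genome_mb) {
  if (any(pct < 0)) stop("pct must be >= 0")
  if (any(genome_mb <= 0)) stop("genome_mb must be > 0")
  round_half_up(pct / 100 * genome_mb, 2)
}

#' Compare cluster-based with assembly-based repeat content
#'
#' Joins the two tables by repeat label (case-insensitive exact match);
#' repeats absent from one side carry proportion 0 there. Sizes are
#' computed with [proportion_to_megabases()] against the respective genome
#' size and `delta_mb` is the difference of the rounded sizes
#' (cluster - assembly).
#'
#' @param cluster_rows data frame with columns `repeat` (label) and `pct`
#'   (cluster-based genome proportion in percent).
#' @param assembly_rows data frame with the same columns for the
#'   assembly-based annotation.
#' @param sizes a [genome_sizes()] list.
#' @return data frame with columns `repeat`, `assembly_pct`, `assembly_mb`,
#'   `cluster_pct`, `cluster_mb`, `delta_mb`.
#' @export
compare_to_assembly <- function(cluster_rows, assembly_rows,
                                sizes = genome_sizes()) {
  chk <- function(df, side) {
    if (!all(c("repeat", "pct") %in% colnames(df)))
      stop(side, " table needs columns 'repeat' and 'pct'")
    key <- tolower(trimws(df[["repeat"]]))
    if (anyDuplicated(key))
      stop("duplicate repeat labels in ", side, " table: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    key
  }
  ck <- chk(cluster_rows, "cluster")
  ak <- chk(assembly_rows, "assembly")
  keys <- union(ck, ak)
  label <- ifelse(keys %in% ck,
                  cluster_rows[["repeat"]][match(keys, ck)],
                  assembly_rows[["repeat"]][match(keys, ak)])
  cpct <- ifelse(keys %in% ck, cluster_rows$pct[match(keys, ck)], 0)
  apct <- ifelse(keys %in% ak, assembly_rows$pct[match(keys, ak)], 0)
  amb <- proportion_to_megabases(apct, sizes$assembly_mb)
  cmb <- proportion_to_megabases(cpct, sizes$estimated_genome_mb)
  out <- data.frame(label, assembly_pct = apct, assembly_mb = amb,
                    cluster_pct = cpct, cluster_mb = cmb,
                    delta_mb = round_half_up(cmb - amb, 2),
                    stringsAsFactors = FALSE)
  colnames(out)[1] <- "repeat"
  out
}
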