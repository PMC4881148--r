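#' Describe one repeat family to plant in a synthetic genome
#'
#' A family is either a tandem satellite (contiguous array of mutated
#' monomers), a dispersed LTR retrotransposon (family-specific long terminal
#' repeats flanking an internal domain that is conserved across the LTR
#' families of the genome), a dispersed DNA-transposon-like element, or a
#' dispersed plastid-like segment.
#'
#' @param name family label.
#' @param kind one of `"satellite"`, `"ltr_retrotransposon"`,
#'   `"dna_transposon"`, `"plastid_like"`.
#' @param length monomer length (satellites) or full element length
#'   (dispersed kinds), in nucleotides; at least 20.
#' @param copies number of monomers (satellites) or element copies; at
#'   least 1.
#' @param divergence per-base substitution probability applied independently
#'   to every copy, in \[0, 0.3\].
#' @param ltr_fraction for LTR retrotransposons, the fraction of the element
#'   length taken by each terminal repeat (default 0.15).
#' @return a `repeat_family` object (list).
#' @export
repeat_family <- function(name, kind = c("satellite", "ltr_retrotransposon",
                                         "dna_transposon", "plastid_like"),
                          length, copies, divergence = 0,
                          ltr_fraction = 0.15) {
  kind <- match.arg(kind)
  if (length < 20) stop("family '", name, "': element/monomer length must be >= 20 nt")
  if (copies < 1) stop("family '", name, "': copies must be >= 1")
  if (divergence < 0 || divergence > 0.3)
    stop("family '", name, "': divergence must be in [0, 0.3]")
  structure(list(name = as.character(name), kind = kind,
                 length = as.integer(length), copies = as.integer(copies),
                 divergence = divergence,
                 arrangement = if (kind == "satellite") "tandem" else "dispersed",
                 ltr_fraction = ltr_fraction),
            class = "repeat_family")
}

#' Specify a synthetic genome
#'
#' Either `background_length` (unique single-copy sequence added around the
#' planted repeats) or a total `genome_length` must be given; in the latter
#' case the background is whatever the planted repeats leave free, and a
#' sizing error naming the offending family is raised if the planted repeats
#' exceed the genome length.
#'
#' @param families list of [repeat_family()] objects.
#' @param background_length nucleotides of unique background sequence.
#' @param genome_length optional total genome length in nucleotides.
#' @param seed integer seed; all randomness of genome construction flows
#'   from it.
#' @return a `genome_spec` object.
#' @export
genome_spec <- function(families, background_length = NULL,
                        genome_length = NULL, seed = 1L) {
  stopifnot(is.list(families))
  for (f in families) {
    if (!inherits(f, "repeat_family")) stop("families must be repeat_family objects")
  }
  nm <- vapply(families, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate family names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  planted <- vapply(families, function(f) as.numeric(f$length) * f$copies, numeric(1))
  if (is.null(background_length)) {
    if (is.null(genome_length)) stop("give background_length or genome_length")
    cum <- cumsum(planted)
    over <- which(cum > genome_length)
    if (length(over)) {
      stop("planted repeats exceed genome length of ", genome_length,
           " nt at family '", nm[over[1]], "'")
    }
    background_length <- genome_length - sum(planted)
  }
  if (background_length < 0) stop("background_length must be >= 0")
  structure(list(families = families,
                 background_length = as.numeric(background_length),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Build a synthetic repeat-rich genome with recorded ground truth
#'
#' Tandem satellite families are emitted as one contiguous array of
#' independently mutated monomers; dispersed families as mutated copies (on
#' random strands) inserted at random, non-overlapping positions between
#' background chunks. Every planted copy's interval is recorded, 0-based
#' half-open; contiguous single-family blocks ("segments") are recorded
#' separately and are the unit used to label simulated reads.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `synthetic_genome`: list with elements
#'   `sequence` (DNA string), `length`, and `truth` (list with `intervals`,
#'   `segments`, `proportions` data frames and `consensus`, a named list of
#'   unmutated family consensus sequences).
#' @export
build_synthetic_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  fams <- spec$families
  nm <- vapply(fams, `[[`, character(1), "name")

  # consensus sequences; LTR families share one conserved internal domain
  consensus <- vector("list", length(fams))
  names(consensus) <- nm
  is_ltr <- vapply(fams, function(f) f$kind == "ltr_retrotransposon", logical(1))
  internal_master <- NULL
  if (any(is_ltr)) {
    max_int <- max(vapply(fams[is_ltr], function(f) {
      f$length - 2L * as.integer(round(f$ltr_fraction * f$length))
    }, numeric(1)))
    internal_master <- random_dna(max(max_int, 20))
  }
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    if (f$kind == "ltr_retrotransposon") {
      ltr_len <- as.integer(round(f$ltr_fraction * f$length))
      int_len <- f$length - 2L * ltr_len
      ltr <- random_dna(ltr_len)
      # per-family light divergence of the shared internal domain
      internal <- mutate_seq(substr(internal_master, 1L, int_len), 0.01)
      consensus[[i]] <- paste0(ltr, internal, ltr)
    } else {
      consensus[[i]] <- random_dna(f$length)
    }
  }

  # planted segments: one array per satellite, one per dispersed copy
  seg_fam <- character(0); seg_seq <- character(0); seg_strand <- character(0)
  seg_copies <- list()
  for (i in seq_along(fams)) {
    f <- fams[[i]]
    if (f$arrangement == "tandem") {
      monomers <- vapply(seq_len(f$copies),
                         function(k) mutate_seq(consensus[[i]], f$divergence),
                         character(1))
      seg_fam <- c(seg_fam, f$name)
      seg_seq <- c(seg_seq, paste(monomers, collapse = ""))
      seg_strand <- c(seg_strand, "+")
      seg_copies[[length(seg_copies) + 1L]] <- nchar(monomers)
    } else {
      for (k in seq_len(f$copies)) {
        cp <- mutate_seq(consensus[[i]], f$divergence)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") cp <- revcomp(cp)
        seg_fam <- c(seg_fam, f$name)
        seg_seq <- c(seg_seq, cp)
        seg_strand <- c(seg_strand, strand)
        seg_copies[[length(seg_copies) + 1L]] <- nchar(cp)
      }
    }
  }
  nseg <- length(seg_fam)
  if (nseg > 0) {
    ord <- sample.int(nseg)
    seg_fam <- seg_fam[ord]; seg_seq <- seg_seq[ord]
    seg_strand <- seg_strand[ord]; seg_copies <- seg_copies[ord]
  }

  bg_len <- spec$background_length
  if (nseg == 0 && bg_len == 0) stop("empty genome: no families and no background")
  # split the background into nseg + 1 chunks at random cut points
  if (bg_len > 0) {
    cuts <- sort(sample(0:bg_len, nseg, replace = TRUE))
    chunk_len <- diff(c(0, cuts, bg_len))
  } else {
    chunk_len <- rep(0, nseg + 1L)
  }
  background <- random_dna(bg_len)

  pieces <- character(0)
  seg_df <- data.frame(family = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0),
                       stringsAsFactors = FALSE)
  int_df <- list()
  pos <- 0
  bg_off <- 0
  for (s in seq_len(nseg + 1L)) {
    if (chunk_len[s] > 0) {
      pieces <- c(pieces, substr(background, bg_off + 1, bg_off + chunk_len[s]))
      bg_off <- bg_off + chunk_len[s]
      pos <- pos + chunk_len[s]
    }
    if (s <= nseg) {
      seg_len <- nchar(seg_seq[s])
      pieces <- c(pieces, seg_seq[s])
      seg_df <- rbind(seg_df, data.frame(
        family = seg_fam[s], start = pos, end = pos + seg_len,
        strand = seg_strand[s], stringsAsFactors = FALSE))
      cl <- seg_copies[[s]]
      st <- pos + cumsum(c(0, cl[-length(cl)]))
      int_df[[length(int_df) + 1L]] <- data.frame(
        family = seg_fam[s], copy = seq_along(cl),
        start = st, end = st + cl, strand = seg_strand[s],
        stringsAsFactors = FALSE)
      pos <- pos + seg_len
    }
  }
  sequence <- paste(pieces, collapse = "")
  glen <- nchar(sequence)
  intervals <- if (length(int_df)) do.call(rbind, int_df) else
    data.frame(family = character(0), copy = integer(0), start = numeric(0),
               end = numeric(0), strand = character(0), stringsAsFactors = FALSE)
  rownames(intervals) <- NULL

  planted <- vapply(nm, function(f) sum(intervals$end[intervals$family == f] -
                                          intervals$start[intervals$family == f]),
                    numeric(1))
  proportions <- data.frame(
    family = c(nm, "background"),
    kind = c(vapply(fams, `[[`, character(1), "kind"), "background"),
    proportion = c(planted / glen, bg_len / glen),
    stringsAsFactors = FALSE)

  structure(list(sequence = sequence, length = glen,
                 truth = list(intervals = intervals, segments = seg_df,
                              proportions = proportions,
                              consensus = consensus),
                 spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", x$length, "nt;",
      nrow(x$truth$segments), "planted segments from",
      sum(x$truth$proportions$family != "background"), "families\n")
  pr <- x$truth$proportions
  pr$proportion <- sprintf("%.4f", pr$proportion)
  print(pr, row.names = FALSE)
  invisible(x)
}

# label the read interval [start, start+len): wholly inside one planted
# segment -> family; overlapping a segment boundary -> "junction";
# otherwise background
label_reads <- function(genome, start, len) {
  seg <- genome$truth$segments
  out <- rep("background", length(start))
  if (nrow(seg) == 0L) return(out)
  seg <- seg[order(seg$start), , drop = FALSE]
  idx <- findInterval(start, seg$start)
  end <- start + len
  inside <- idx >= 1L & start >= seg$start[pmax(idx, 1L)] & start < seg$end[pmax(idx, 1L)]
  wholly <- inside & end <= seg$end[pmax(idx, 1L)]
  out[wholly] <- seg$family[idx[wholly]]
  out[inside & !wholly] <- "junction"
  # reads starting in background but running into the next segment
  nxt <- pmin(idx + 1L, nrow(seg))
  runs_in <- !inside & idx < nrow(seg) & end > seg$start[nxt]
  out[runs_in] <- "junction"
  out
}

#' Simulate paired-end shotgun reads from a synthetic genome
#'
#' Fragment start positions are uniform; the two mates of each pair sit on
#' opposite strands at a fixed insert size. Reads are error-free by default
#' (constant quality "I"); an optional uniform substitution error rate can
#' be applied. Each read records its true family of origin: wholly inside a
#' planted segment inherits the family label, boundary-spanning reads are
#' labelled `"junction"`, the rest `"background"`.
#'
#' @param genome a [build_synthetic_genome()] result.
#' @param coverage fold sequence coverage (> 0).
#' @param read_length read length in nt.
#' @param insert_size outer fragment size in nt (`read_length <= insert_size
#'   <= genome length`).
#' @param seed integer seed.
#' @param error_rate uniform per-base sequencing error probability
#'   (default 0).
#' @return data frame with columns `id`, `seq`, `qual`, `mate_id`, `family`,
#'   `start` (0-based), `strand`; number of rows is twice
#'   `round(coverage * genome_length / (2 * read_length))`.
#' @export
simulate_shotgun_pairs <- function(genome, coverage, read_length = 100,
                                   insert_size = 300, seed = 1L,
                                   error_rate = 0) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_length > insert_size) stop("read_length must be <= insert_size")
  if (insert_size > genome$length)
    stop("genome (", genome$length, " nt) is shorter than insert_size (",
         insert_size, " nt)")
  set.seed(seed)
  n_pairs <- round(coverage * genome$length / (2 * read_length))
  if (n_pairs < 1) stop("coverage too low: zero pairs requested")
  s <- sample(0:(genome$length - insert_size), n_pairs, replace = TRUE)
  fwd_start <- s
  rev_start <- s + insert_size - read_length
  seq1 <- substring(genome$sequence, fwd_start + 1, fwd_start + read_length)
  seq2 <- revcomp(substring(genome$sequence, rev_start + 1,
                            rev_start + read_length))
  if (error_rate > 0) {
    seq1 <- vapply(seq1, mutate_seq, character(1), divergence = error_rate,
                   USE.NAMES = FALSE)
    seq2 <- vapply(seq2, mutate_seq, character(1), divergence = error_rate,
                   USE.NAMES = FALSE)
  }
  id1 <- sprintf("read%06d/1", seq_len(n_pairs))
  id2 <- sprintf("read%06d/2", seq_len(n_pairs))
  qual <- strrep("I", read_length)
  fam1 <- label_reads(genome, fwd_start, read_length)
  fam2 <- label_reads(genome, rev_start, read_length)
  out <- data.frame(
    id = c(rbind(id1, id2)),
    seq = c(rbind(seq1, seq2)),
    qual = qual,
    mate_id = c(rbind(id2, id1)),
    family = c(rbind(fam1, fam2)),
    start = c(rbind(fwd_start, rev_start)),
    strand = rep(c("+", "-"), n_pairs),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-family ChIP enrichment profile
#'
#' Enrichment factors weight the probability that a ChIP read starts inside
#' a family's planted sequence. Background and all unlisted families have
#' factor 1; with all factors 1 the ChIP read distribution is statistically
#' identical to the input.
#'
#' @param ... named enrichment factors (dimensionless, >= 0), e.g.
#'   `chip_profile(satA = 5)`.
#' @param factors alternatively, a named numeric vector.
#' @return a named numeric vector of class `chip_profile`.
#' @export
chip_profile <- function(..., factors = NULL) {
  f <- if (is.null(factors)) unlist(list(...)) else factors
  if (length(f) == 0L) f <- numeric(0)
  if (length(f) && (is.null(names(f)) || any(!nzchar(names(f)))))
    stop("enrichment factors must be named by family")
  if (any(f < 0)) stop("enrichment factors must be >= 0")
  structure(as.numeric(f), names = names(f), class = "chip_profile")
}

#' Simulate single-end ChIP and input read sets
#'
#' Input reads start uniformly over the genome; ChIP read start positions
#' are weighted by the enrichment factor of the planted segment covering the
#' start coordinate (background weight 1), with weights renormalised. Both
#' sets have exactly `n_reads` reads. The closed-form per-family
#' expectations implied by the weights are returned alongside, so recovery
#' tests can compare observation with expectation.
#'
#' @param genome a [build_synthetic_genome()] result.
#' @param profile a [chip_profile()].
#' @param n_reads reads per sample (> 0).
#' @param read_length read length in nt.
#' @param seed integer seed.
#' @param sequences if `FALSE`, skip sequence extraction and return only
#'   start coordinates and family labels (fast path for calibration runs).
#' @return list with `chip` and `input` read data frames (columns `id`,
#'   `family`, `start`, and when `sequences = TRUE` also `seq`, `qual`,
#'   `strand`) and `expected`, a per-family table of input/ChIP start-weight
#'   fractions and the expected ChIP/input ratio.
#' @export
simulate_chip_reads <- function(genome, profile, n_reads, read_length = 50,
                                seed = 1L, sequences = TRUE) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (read_length > genome$length) stop("read_length exceeds genome length")

  # decompose valid start coordinates [0, L - read_length] into regions of
  # constant family
  max_start <- genome$length - read_length
  seg <- genome$truth$segments
  seg <- seg[order(seg$start), , drop = FALSE]
  bounds <- sort(unique(c(0, seg$start, seg$end, max_start + 1)))
  bounds <- bounds[bounds >= 0 & bounds <= max_start + 1]
  if (bounds[length(bounds)] != max_start + 1) bounds <- c(bounds, max_start + 1)
  reg_start <- bounds[-length(bounds)]
  reg_end <- bounds[-1]
  keep <- reg_end > reg_start
  reg_start <- reg_start[keep]; reg_end <- reg_end[keep]
  reg_fam <- rep("background", length(reg_start))
  if (nrow(seg)) {
    idx <- findInterval(reg_start, seg$start)
    cov <- idx >= 1L & reg_start < seg$end[pmax(idx, 1L)]
    reg_fam[cov] <- seg$family[idx[cov]]
  }
  reg_n <- reg_end - reg_start
  fac <- rep(1, length(reg_fam))
  hit <- reg_fam %in% names(profile)
  fac[hit] <- as.numeric(profile[reg_fam[hit]])
  w_input <- reg_n
  w_chip <- fac * reg_n
  if (sum(w_chip) <= 0) stop("all ChIP sampling weights are zero")

  set.seed(seed)
  draw <- function(w) {
    ri <- sample.int(length(w), n_reads, replace = TRUE, prob = w)
    off <- pmin(floor(runif(n_reads) * reg_n[ri]), reg_n[ri] - 1)
    list(start = reg_start[ri] + off, family = reg_fam[ri])
  }
  chip <- draw(w_chip)
  input <- draw(w_input)

  mk <- function(x, tag) {
    df <- data.frame(id = sprintf("%s%06d", tag, seq_len(n_reads)),
                     family = x$family, start = x$start,
                     stringsAsFactors = FALSE)
    if (sequences) {
      sq <- substring(genome$sequence, x$start + 1, x$start + read_length)
      strand <- sample(c("+", "-"), n_reads, replace = TRUE)
      sq[strand == "-"] <- revcomp(sq[strand == "-"])
      df$seq <- sq
      df$qual <- strrep("I", nchar(sq))
      df$strand <- strand
    }
    df
  }
  chip_df <- mk(chip, "chip")
  input_df <- mk(input, "input")

  fams <- unique(c(reg_fam))
  q <- vapply(fams, function(f) sum(w_input[reg_fam == f]) / sum(w_input),
              numeric(1))
  cfrac <- vapply(fams, function(f) sum(w_chip[reg_fam == f]) / sum(w_chip),
                  numeric(1))
  expected <- data.frame(family = fams, input_fraction = q,
                         chip_fraction = cfrac,
                         expected_ratio = cfrac / q,
                         stringsAsFactors = FALSE)
  rownames(expected) <- NULL
  list(chip = chip_df, input = input_df, expected = expected)
}

#' Export a synthetic genome's ground truth as TSV tables
#'
#' Writes the per-family proportions/enrichment-factor table and a BED-like
#' table of planted copy intervals (0-based half-open).
#'
#' @param genome a [build_synthetic_genome()] result.
#' @param profile optional [chip_profile()] whose factors are recorded.
#' @param truth_path,intervals_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(genome, truth_path, intervals_path,
                               profile = NULL) {
  pr <- genome$truth$proportions
  fac <- rep(1, nrow(pr))
  if (!is.null(profile)) {
    hit <- pr$family %in% names(profile)
    fac[hit] <- as.numeric(profile[pr$family[hit]])
  }
  pr$enrichment_factor <- fac
  write_tsv(pr, truth_path)
  iv <- genome$truth$intervals
  write_tsv(iv[, c("family", "start", "end", "strand", "copy")], intervals_path)
  invisible(c(truth_path, intervals_path))
}

#' Build a repeat reference database from planted family consensi
#'
#' Turns a synthetic genome's unmutated family consensus sequences into a
#' hierarchical reference database suitable for [annotate_cluster()]: one
#' record per family, with the group taken from the family kind
#' (`satellite`, `Ty1-copia`/`Ty3-gypsy` for LTR retrotransposons,
#' `DNA-transposon`, `plastid`) and a family-specific clade label.
#'
#' @param genome a [build_synthetic_genome()] result.
#' @param ltr_groups optional named character vector assigning LTR families
#'   to `"Ty3-gypsy"` or `"Ty1-copia"` (default: all `"Ty3-gypsy"`).
#' @return data frame with columns `id`, `seq`, `group`, `clade`, `family`.
#' @export
reference_db_from_truth <- function(genome, ltr_groups = NULL) {
  pr <- genome$truth$proportions
  pr <- pr[pr$family != "background", , drop = FALSE]
  grp <- c(satellite = "satellite", ltr_retrotransposon = "Ty3-gypsy",
           dna_transposon = "DNA-transposon", plastid_like = "plastid")
  group <- unname(grp[pr$kind])
  if (!is.null(ltr_groups)) {
    hit <- pr$family %in% names(ltr_groups)
    group[hit] <- unname(ltr_groups[pr$family[hit]])
  }
  data.frame(id = paste0("ref_", pr$family),
             seq = unlist(genome$truth$consensus[pr$family], use.names = FALSE),
             group = group,
             clade = paste0(pr$family, "-like"),
             family = pr$family,
             stringsAsFactors = FALSE)
}
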