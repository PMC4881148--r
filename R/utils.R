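#' Reverse complement
#'
#' Vectorised reverse complement of DNA strings. Non-ACGT characters are
#' passed through unchanged (so `N` stays `N`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  cpp_revcomp(as.character(x))
}

#' Random DNA sequence
#'
#' @param n sequence length in nucleotides.
#' @return a single DNA string drawn uniformly over A/C/G/T using the current
#'   RNG state.
#' @export
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a DNA sequence
#'
#' Substitution-only mutation: each base is replaced, with probability
#' `divergence`, by one of the three other bases. Substitutions keep sequence
#' coordinates exact, which is what downstream identity arithmetic relies on.
#' An optional indel mode (equal rates of single-base insertion and deletion)
#' is available but off by default.
#'
#' @param seq DNA string.
#' @param divergence per-base substitution probability in \[0, 0.3\].
#' @param indel_rate per-base probability of a single-base indel (default 0).
#' @return mutated DNA string.
#' @export
mutate_seq <- function(seq, divergence, indel_rate = 0) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  n <- nchar(seq)
  if (n == 0L || (divergence == 0 && indel_rate == 0)) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(n) < divergence
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    # draw uniformly among the three non-identical bases
    cur <- match(v[hit], bases)
    off <- sample.int(3L, sum(hit), replace = TRUE)
    v[hit] <- bases[((cur - 1L + off) %% 4L) + 1L]
  }
  if (indel_rate > 0) {
    ind <- runif(length(v)) < indel_rate
    if (any(ind)) {
      del <- runif(sum(ind)) < 0.5
      keep <- rep(TRUE, length(v))
      ins <- character(length(v))
      idx <- which(ind)
      keep[idx[del]] <- FALSE
      ins[idx[!del]] <- sample(c("A", "C", "G", "T"), sum(!del), replace = TRUE)
      v <- paste0(ifelse(keep, v, ""), ins)
    }
  }
  paste(v, collapse = "")
}

# round half away from zero at `digits` decimals (Table-style arithmetic;
# base round() would round half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0(">", ids, "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Write a read set as FASTQ
#'
#' @param reads data frame with columns `id`, `seq` and optionally `qual`
#'   (constant quality "I", Phred 40, is used when absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is taken from the first non-empty character (`>` or `@`).
#'
#' @param path input file.
#' @return data frame with columns `id`, `seq` and, for FASTQ, `qual`.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in ", path)
  if (startsWith(lines[[1]], "@")) {
    if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
    ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
    ids <- sub("\\s.*$", "", ids)
    data.frame(id = ids,
               seq = lines[seq(2L, length(lines), by = 4L)],
               qual = lines[seq(4L, length(lines), by = 4L)],
               stringsAsFactors = FALSE)
  } else if (startsWith(lines[[1]], ">")) {
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    ids_short <- sub("\\s.*$", "", ids)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                   paste, character(1), collapse = "")
    data.frame(id = ids_short, desc = ids, seq = unname(seqs),
               stringsAsFactors = FALSE)
  } else {
    stop("unrecognised sequence format in ", path)
  }
}

# deterministic sub-seed derivation (stays below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 8191) %% 2147483647)
}

# write a TSV with an optional '#'-prefixed parameter comment line
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, trim = TRUE, scientific = FALSE, digits = 15))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
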