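config_to_spec <- function(sim) {
  fams <- lapply(sim$families, function(f) {
    repeat_family(name = f$name, kind = f$kind, length = f$length,
                  copies = f$copies,
                  divergence = if (is.null(f$divergence)) 0 else f$divergence)
  })
  genome_spec(fams, background_length = sim$background_length,
              genome_length = sim$genome_length,
              seed = if (is.null(sim$seed)) 1L else sim$seed)
}

default_config <- function() {
  list(
    cluster = list(min_identity = 90, min_coverage = 0.55,
                   kmer_seed_length = 8, min_links = 5,
                   proportion_threshold = 0.01,
                   min_mean_quality = 20, max_n_fraction = 0.05),
    assemble = list(min_overlap = 31),
    annotate = list(min_identity = 80, min_hit_length = 50),
    enrich = list(trim_length = 50, threshold = 1.5, min_input = 20,
                  max_evalue = 1e-12, word_size = 9, seed = 303),
    report = list(estimated_genome_mb = 758, assembly_mb = 567)
  )
}

pipe_log <- function(...) message("[repeatchip] ", ...)

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full repeat-chromatin pipeline
#'
#' Orchestrates simulate (optional) -> quality filter -> read clustering ->
#' contig assembly -> annotation -> ChIP/input enrichment -> reporting,
#' writing every result as a TSV/FASTA/FASTQ file plus a machine-readable
#' run manifest (parameters, seeds, output digests). Reruns with the same
#' configuration are byte-identical.
#'
#' @param config configuration list, or path to a YAML file with the same
#'   structure (see the bundled `demo_config.yaml` under `extdata`).
#' @param outdir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results (`clusters`,
#'   `annotations`, `enrichment`, `composition`, `manifest`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_config(), config)
  if (!quiet) pipe_log("writing to ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # --- simulate -------------------------------------------------------------
  if (is.null(cfg$simulate)) stop("config must contain a 'simulate' block")
  sim <- cfg$simulate
  genome <- run_stage("simulate", {
    build_synthetic_genome(config_to_spec(sim))
  })
  profile <- chip_profile(factors = unlist(sim$chip$factors))
  pairs <- run_stage("simulate", {
    simulate_shotgun_pairs(genome,
      coverage = sim$coverage,
      read_length = if (is.null(sim$read_length)) 100 else sim$read_length,
      insert_size = if (is.null(sim$insert_size)) 300 else sim$insert_size,
      seed = if (is.null(sim$reads_seed)) 11L else sim$reads_seed)
  })
  chip <- run_stage("simulate", {
    simulate_chip_reads(genome, profile,
      n_reads = sim$chip$n_reads,
      read_length = if (is.null(sim$chip$read_length)) 50 else sim$chip$read_length,
      seed = if (is.null(sim$chip$seed)) 22L else sim$chip$seed)
  })
  db <- reference_db_from_truth(genome)
  if (!quiet) pipe_log("simulated ", genome$length, " nt genome, ",
                       nrow(pairs), " genomic reads, 2 x ",
                       nrow(chip$chip), " ChIP/input reads")
  emit("genome.fasta", function(p)
    write_fasta(c(genome = genome$sequence), p))
  emit("reads_1.fastq", function(p)
    write_fastq(pairs[pairs$strand == "+", ], p))
  emit("reads_2.fastq", function(p)
    write_fastq(pairs[pairs$strand == "-", ], p))
  emit("chip.fastq", function(p) write_fastq(chip$chip, p))
  emit("input.fastq", function(p) write_fastq(chip$input, p))
  emit("reference_db.fasta", function(p) write_repeat_db(db, p))
  run_stage("simulate", {
    write_ground_truth(genome, file.path(outdir, "truth_families.tsv"),
                       file.path(outdir, "truth_intervals.tsv"), profile)
  })
  paths <- c(paths, file.path(outdir, c("truth_families.tsv",
                                        "truth_intervals.tsv")))

  # --- filter + cluster -----------------------------------------------------
  cl <- cfg$cluster
  filtered <- run_stage("filter", {
    quality_filter(pairs, cl$min_mean_quality, cl$max_n_fraction)
  })
  clusters <- run_stage("cluster", {
    add_proportions(cluster_reads(filtered, cl$min_identity, cl$min_coverage,
                                  cl$kmer_seed_length))
  })
  if (!quiet) pipe_log(length(clusters$clusters), " clusters, ",
                       length(clusters$singletons), " singletons")
  reference <- run_stage("cluster", {
    select_annotatable_clusters(clusters, cl$proportion_threshold)
  })
  links <- run_stage("cluster", {
    link_clusters_by_pairs(clusters, filtered, cl$min_links)
  })
  emit("clusters.tsv", function(p)
    write_tsv(clusters$table, p,
              comment = sprintf("min_identity=%g min_coverage=%g k=%d",
                                cl$min_identity, cl$min_coverage,
                                as.integer(cl$kmer_seed_length))))
  emit("membership.tsv", function(p) {
    member <- rep(names(clusters$clusters), lengths(clusters$clusters))
    names(member) <- unlist(clusters$clusters, use.names = FALSE)
    mm <- member[filtered$id]
    write_tsv(data.frame(read_id = filtered$id,
                         cluster_id = ifelse(is.na(mm), "singleton", mm),
                         stringsAsFactors = FALSE), p)
  })
  emit("links.tsv", function(p)
    write_tsv(links, p, comment = sprintf("min_links=%d",
                                          as.integer(cl$min_links))))

  # --- assemble + annotate --------------------------------------------------
  contigs <- run_stage("assemble", {
    assemble_clusters(reference, filtered, cfg$assemble$min_overlap)
  })
  emit("contigs.fasta", function(p)
    write_fasta(stats::setNames(contigs$seq, contigs$contig_id), p))
  annotations <- run_stage("annotate", {
    annotate_clusters(contigs, db, clusters = reference,
                      min_identity = cfg$annotate$min_identity,
                      min_hit_length = cfg$annotate$min_hit_length)
  })
  emit("annotations.tsv", function(p) write_tsv(annotations, p))
  emit("repeat_groups.tsv", function(p)
    write_tsv(aggregate_repeat_groups(annotations), p))

  # --- enrichment -----------------------------------------------------------
  en <- cfg$enrich
  n_sample <- if (is.null(en$n_sample))
    min(nrow(chip$chip), nrow(chip$input)) else en$n_sample
  chip_s <- run_stage("enrich", {
    prepare_chip_reads(chip$chip, en$trim_length, n_sample, en$seed)
  })
  input_s <- run_stage("enrich", {
    prepare_chip_reads(chip$input, en$trim_length, n_sample,
                       en$seed + 1L)
  })
  chip_maps <- run_stage("enrich", {
    map_reads_to_clusters(chip_s, contigs, max_evalue = en$max_evalue,
                          word_size = en$word_size, details = FALSE)
  })
  input_maps <- run_stage("enrich", {
    map_reads_to_clusters(input_s, contigs, max_evalue = en$max_evalue,
                          word_size = en$word_size, details = FALSE)
  })
  records <- run_stage("enrich", {
    call_enriched(compute_enrichment(chip_maps, input_maps,
                                     reference_clusters = reference$table$cluster_id,
                                     min_input = en$min_input),
                  en$threshold)
  })
  if (!quiet) pipe_log(sum(records$enriched), " of ", nrow(records),
                       " reference clusters enriched at ratio >= ",
                       en$threshold)
  emit("mapping_chip.tsv", function(p) write_tsv(chip_maps, p))
  emit("mapping_input.tsv", function(p) write_tsv(input_maps, p))
  emit("enrichment.tsv", function(p)
    write_tsv(as.data.frame(records), p,
              comment = sprintf("threshold=%g min_input=%d n_sample=%d",
                                en$threshold, as.integer(en$min_input),
                                as.integer(n_sample))))
  composition <- list()
  for (lev in c("group", "clade", "family")) {
    composition[[lev]] <- composition_summary(records, annotations, lev,
                                              total_reads = n_sample)
    emit(paste0("composition_", lev, ".tsv"),
         local({
           lev0 <- lev
           function(p) write_tsv(composition[[lev0]], p)
         }))
  }

  # --- report ---------------------------------------------------------------
  sizes <- genome_sizes(cfg$report$estimated_genome_mb, cfg$report$assembly_mb)
  truth_rows <- data.frame(
    "repeat" = genome$truth$proportions$family,
    pct = 100 * genome$truth$proportions$proportion,
    check.names = FALSE, stringsAsFactors = FALSE)
  truth_rows <- truth_rows[truth_rows[["repeat"]] != "background", ,
                           drop = FALSE]
  fam_est <- annotations[!is.na(annotations$family), , drop = FALSE]
  cluster_rows <- if (nrow(fam_est)) {
    agg <- tapply(fam_est$proportion_pct, fam_est$family, sum)
    data.frame("repeat" = names(agg), pct = as.numeric(agg),
               check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame("repeat" = character(0), pct = numeric(0),
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  comparison <- run_stage("report", {
    compare_to_assembly(cluster_rows, truth_rows, sizes)
  })
  emit("comparison.tsv", function(p)
    write_tsv(comparison, p,
              comment = sprintf("cluster_side_mb=%g assembly_side_mb=%g",
                                sizes$estimated_genome_mb, sizes$assembly_mb)))

  # --- manifest -------------------------------------------------------------
  digests <- tools::md5sum(sort(unlist(paths)))
  manifest <- list(
    package = "repeatchip",
    version = as.character(utils::packageVersion("repeatchip")),
    parameters = cfg,
    outputs = as.list(digests))
  names(manifest$outputs) <- basename(names(digests))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!quiet) pipe_log("done; manifest at ", manifest_path)

  invisible(list(genome = genome, clusters = clusters, reference = reference,
                 contigs = contigs, annotations = annotations,
                 enrichment = records, composition = composition,
                 comparison = comparison, manifest = manifest))
}

#' Path of the bundled demo configuration
#'
#' A small five-family genome (two satellites, one LTR retrotransposon, one
#' DNA transposon, one plastid-like segment; 50 kb total) with one strongly
#' ChIP-enriched satellite, sized so the whole pipeline runs in seconds.
#'
#' @return file path of the YAML config.
#' @export
demo_config <- function() {
  system.file("extdata", "demo_config.yaml", package = "repeatchip",
              mustWork = TRUE)
}
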