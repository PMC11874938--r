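# End-to-end pipeline: binds the synthetic generator, translated search,
# coverage-based calling, pseudogene analysis and Dollo loss mapping, with
# a machine-readable configuration echo so every run is reproducible.

#' Default pipeline thresholds
#'
#' @return Named list of every tunable the pipeline uses, with its
#'   default: the search scoring and thresholds, the presence-call rules
#'   and the coverage-model overlap.
#' @export
pipeline_defaults <- function() {
  sc <- search_scoring()
  cr <- call_rules()
  list(matrix = sc$matrix, gap_opening = sc$gap_opening,
       gap_extension = sc$gap_extension,
       min_score_contig = sc$min_score_contig,
       min_score_read = sc$min_score_read,
       alpha = cr$alpha, min_identity = cr$min_identity,
       min_exons = cr$min_exons,
       require_pcr_free = cr$require_pcr_free,
       min_overlap = 45L, fs_penalty = 15,
       read_length = 150L, detection_prob_per_read = 1)
}

#' Configure a synthetic end-to-end run
#'
#' Describes a multi-species scenario: one neuropeptide gene family, a
#' rooted species tree, and per-species genome/archive settings stating
#' whether the gene is planted intact, planted with pseudogenizing
#' lesions, or not planted at all.
#'
#' @param species Tibble with columns `species`, `gene_state`
#'   (`"present"`, `"pseudogene"` or `"absent"`), and optionally
#'   `coverage`, `genome_size`, `pcr_free`.
#' @param tree Newick string for the species tree (tips must match
#'   `species$species`).
#' @param gene Name of the gene (used in reports).
#' @param family,n_paracopies,core_peptide,spacer_len Precursor layout
#'   passed to [plant_precursor_spec()].
#' @param coverage,genome_size Defaults applied where the species table
#'   has no explicit value.
#' @param n_lesions Frameshifts injected into `pseudogene` species
#'   (default 5, plus one premature stop).
#' @param seed Integer master seed.
#' @param out_dir Output directory (created; every intermediate table is
#'   written there).
#' @param thresholds Overrides of [pipeline_defaults()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(species, tree, gene = "tryptopyrokinin",
                       family = "tryptopyrokinin",
                       n_paracopies = 3L, core_peptide = "WFGPRL",
                       spacer_len = 2L, coverage = 50,
                       genome_size = 4000L, n_lesions = 5L,
                       seed = 1L, out_dir = tempfile("peptidetect_run_"),
                       thresholds = list()) {
  stopifnot(is.data.frame(species),
            all(c("species", "gene_state") %in% names(species)),
            all(species$gene_state %in%
                  c("present", "pseudogene", "absent")))
  th <- utils::modifyList(pipeline_defaults(), thresholds)
  if (!"coverage" %in% names(species)) species$coverage <- coverage
  if (!"genome_size" %in% names(species)) {
    species$genome_size <- genome_size
  }
  if (!"pcr_free" %in% names(species)) species$pcr_free <- TRUE
  structure(list(species = species, tree = tree, gene = gene,
                 family = family, n_paracopies = as.integer(n_paracopies),
                 core_peptide = core_peptide,
                 spacer_len = as.integer(spacer_len),
                 n_lesions = as.integer(n_lesions),
                 seed = as.integer(seed), out_dir = out_dir,
                 thresholds = th),
            class = "run_config")
}

pipeline_log <- function(con, stage, seed, msg) {
  line <- sprintf("[%s] seed=%d %s", stage, seed, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full inference pipeline on a synthetic scenario
#'
#' For every species: builds a genome (planting the gene per the
#' configured state and injecting lesions for pseudogene species),
#' simulates a PCR-free read archive at the configured coverage, searches
#' it with the reference precursor query, fits the coverage model, and
#' calls the gene present / pseudogene / absent / indeterminate.  Calls
#' are then mapped on the species tree under Dollo parsimony, with
#' pseudogenes counted both as persisting DNA and as functional losses.
#' Every intermediate table, a config echo and a log are written to
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A list of class `"pipeline_result"`: `calls` (presence-call
#'   tibble), `spot_counts`, `losses_dna` and `losses_functional`
#'   (`loss_report`s), `reference` (precursor string), `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  th <- config$thresholds
  scoring <- search_scoring(th$matrix, th$gap_opening, th$gap_extension,
                            th$min_score_contig, th$min_score_read)
  rules <- call_rules(th$alpha, th$min_identity, th$min_exons,
                      th$require_pcr_free)

  # config echo for reproducibility
  echo <- config
  echo$species <- as.data.frame(config$species)
  class(echo) <- NULL
  yaml::write_yaml(echo, file.path(config$out_dir, "config_echo.yaml"))
  pipeline_log(log_con, "config", config$seed,
               paste("echo written;", nrow(config$species), "species"))

  reference <- plant_precursor_spec(config$family, config$n_paracopies,
                                    config$core_peptide,
                                    config$spacer_len,
                                    seed = config$seed)
  m <- nchar(reference)
  # the query's own coding exons: planted genes carry two, so exon
  # support is informative the way it is for real receptor queries
  query <- protein_query(config$gene, as.character(reference),
                         family = config$family,
                         exon_segments = list(c(1L, m %/% 2L),
                                              c(m %/% 2L + 1L, m)))

  calls <- list()
  spot_counts <- list()
  for (i in seq_len(nrow(config$species))) {
    sp <- config$species[i, ]
    sp_seed <- config$seed + 1000L * i
    stage <- paste0("species:", sp$species)
    result <- tryCatch({
      # every species carries the same ortholog protein (codon usage
      # still differs per species through the genome seed)
      specs <- if (sp$gene_state != "absent") {
        list(gene_spec(config$gene, config$family,
                       precursor = as.character(reference),
                       n_exons = 2L, intron_len = 301L))
      } else {
        list()
      }
      genome <- build_genome(sp$genome_size, specs, seed = sp_seed)
      lesion_report <- NULL
      if (sp$gene_state == "pseudogene") {
        genome <- inject_lesions(genome, config$gene,
                                 n_frameshifts = config$n_lesions,
                                 n_stops = 1L, seed = sp_seed + 1L)
        aln <- align_locus_to_reference(
          spliced_cds(genome, config$gene), as.character(reference),
          scoring, fs_penalty = th$fs_penalty)
        lesion_report <- call_gene_status(aln, family = config$family)
      }
      archive <- simulate_reads(genome, coverage = sp$coverage,
                                read_length = th$read_length,
                                pcr_free = sp$pcr_free,
                                prefix = sp$species, seed = sp_seed + 2L)
      spots <- search_archive(query, archive, scoring)
      model <- coverage_model(genome$size_bp, nrow(archive$reads),
                              th$read_length,
                              target_length = 3L * nchar(reference),
                              min_overlap = th$min_overlap)
      hits <- NULL
      if (spots$n_spots[1] > 0 && sp$gene_state != "pseudogene") {
        hits <- search_sequence(query, genome$sequence, scoring,
                                min_score = th$min_score_contig,
                                subject_id = sp$species)
      }
      if (spots$n_spots[1] == 0) lesion_report <- NULL
      call <- call_presence(sp$species, config$gene, spots, hits = hits,
                            lesions = lesion_report, model = model,
                            rules = rules, pcr_free = sp$pcr_free,
                            detection_prob_per_read =
                              th$detection_prob_per_read,
                            queries = query)
      pipeline_log(log_con, stage, sp_seed,
                   sprintf("state=%s spots=%d call=%s", sp$gene_state,
                           spots$n_spots[1], call$status))
      list(call = call, spots = spots)
    }, error = function(e) {
      pipeline_log(log_con, stage, sp_seed, paste("FAILED:",
                                                  conditionMessage(e)))
      stop("stage ", stage, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    calls[[i]] <- result$call
    spot_counts[[i]] <- tibble::tibble(species = sp$species,
                                       gene = config$gene,
                                       n_spots = result$spots$n_spots[1])
  }
  calls <- dplyr::bind_rows(calls)
  spot_counts <- dplyr::bind_rows(spot_counts)

  tree <- parse_newick(config$tree)
  states <- stats::setNames(
    ifelse(calls$status == "indeterminate", "unknown", calls$status),
    calls$species)
  losses_dna <- dollo_min_losses(tree, states, gene = config$gene,
                                 pseudogene_as = "present")
  losses_fun <- dollo_min_losses(tree, states, gene = config$gene,
                                 pseudogene_as = "absent")
  pipeline_log(log_con, "losses", config$seed,
               sprintf("dna=%d functional=%d", losses_dna$min_losses,
                       losses_fun$min_losses))

  write_tsv_result(calls, file.path(config$out_dir,
                                    "presence_calls.tsv"))
  write_tsv_result(spot_counts, file.path(config$out_dir,
                                          "spot_counts.tsv"))
  write_tsv_result(tidy(losses_dna),
                   file.path(config$out_dir, "losses_dna.tsv"))
  write_tsv_result(tidy(losses_fun),
                   file.path(config$out_dir, "losses_functional.tsv"))
  write_loss_newick(losses_dna,
                    file.path(config$out_dir, "losses_dna.nwk"))

  structure(list(calls = calls, spot_counts = spot_counts,
                 losses_dna = losses_dna,
                 losses_functional = losses_fun,
                 reference = as.character(reference),
                 out_dir = config$out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$calls[, c("species", "gene", "status", "n_spots", "p_abs")])
  cat(sprintf("minimum losses: %d (DNA), %d (functional)\n",
              x$losses_dna$min_losses, x$losses_functional$min_losses))
  cat("outputs in:", x$out_dir, "\n")
  invisible(x)
}
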