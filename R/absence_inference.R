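# Coverage-calibrated absence inference: converts spot counts and archive
# coverage into presence / pseudogene / absent / indeterminate calls with
# an explicit absence-probability bound, and builds tissue expression
# tables.
#
# The model: a PCR-free archive of N reads of length L_r from a genome of
# size G samples read start positions approximately uniformly, so the
# number of reads overlapping a detectable target of length L_t by at
# least o_min bases is Poisson with mean
#   lambda = N * (L_r + L_t - 2*o_min + 1) / G,
# and the probability that not a single read supports the target is
# exp(-lambda) (times a per-read detection probability when conserved
# blocks cover only part of the target).  With full-length detection and
# o_min matching the read length this collapses to exp(-c) with
# c = N * L_r / G the genome coverage: at 50x the absence probability is
# below 1e-6 by many orders of magnitude.

#' Coverage model for a detection target
#'
#' @param genome_size Genome size G in bp.
#' @param read_count Number of reads N in the archive.
#' @param read_length Read length L_r in bp.
#' @param target_length Detectable target length L_t in bp (default: one
#'   read length, giving `lambda` close to the coverage).
#' @param min_overlap Minimum read/target overlap o_min in bp for a read
#'   to be detectable (default 45 nt = 15 residues of translated
#'   sequence).
#' @return A list of class `"coverage_model"` with fields `G`, `N`,
#'   `L_r`, `L_t`, `o_min`, `coverage` (`N*L_r/G`) and `lambda`.
#' @export
coverage_model <- function(genome_size, read_count, read_length,
                           target_length = read_length,
                           min_overlap = 45L) {
  stopifnot(genome_size > 0, read_count >= 0, read_length > 0,
            target_length > 0, min_overlap > 0,
            min_overlap <= read_length, min_overlap <= target_length)
  cov <- read_count * read_length / genome_size
  lambda <- read_count *
    (read_length + target_length - 2 * min_overlap + 1) / genome_size
  structure(list(G = genome_size, N = read_count, L_r = read_length,
                 L_t = target_length, o_min = min_overlap,
                 coverage = cov, lambda = lambda),
            class = "coverage_model")
}

#' @export
print.coverage_model <- function(x, ...) {
  cat(sprintf(
    "<coverage_model> G=%s bp, N=%s reads x %d bp -> coverage %.2fx\n",
    format(x$G, big.mark = ","), format(x$N, big.mark = ","), x$L_r,
    x$coverage))
  cat(sprintf("  target %d bp, min overlap %d bp -> lambda = %.3f\n",
              x$L_t, x$o_min, x$lambda))
  invisible(x)
}

#' @rdname coverage_model
#' @param x A `coverage_model`.
#' @param ... Unused.
#' @export
tidy.coverage_model <- function(x, ...) {
  tibble::tibble(genome_size = x$G, read_count = x$N,
                 read_length = x$L_r, target_length = x$L_t,
                 min_overlap = x$o_min, coverage = x$coverage,
                 lambda = x$lambda)
}

#' Probability that a present target is entirely missed
#'
#' `p_abs = exp(-lambda * detection_prob_per_read)`.  Passing a bare
#' number instead of a model treats it as the coverage `c` with the
#' simplification `lambda = c` (every read overlapping the target at all
#' is detectable), recovering the textbook `exp(-c)` bound: at 50x
#' coverage the chance that a genuinely present sequence leaves no trace
#' in a PCR-free archive is below 1e-6 by sixteen orders of magnitude.
#'
#' @param model A [coverage_model()], or a non-negative number interpreted
#'   as the coverage.
#' @param detection_prob_per_read Probability that a read overlapping the
#'   target is recognized (in (0, 1]; below 1 models targets whose
#'   conserved blocks cover only part of their length).
#' @return The absence probability bound, a number in (0, 1].
#' @export
#' @examples
#' absence_probability(50)            # exp(-50), far below 1e-6
#' absence_probability(log(2))        # exactly 0.5
absence_probability <- function(model, detection_prob_per_read = 1) {
  stopifnot(detection_prob_per_read > 0, detection_prob_per_read <= 1)
  lambda <- if (inherits(model, "coverage_model")) {
    model$lambda
  } else {
    stopifnot(is.numeric(model), model >= 0)
    as.numeric(model)
  }
  exp(-lambda * detection_prob_per_read)
}

#' Calibrate the absence bound by simulation
#'
#' For each coverage level, simulates read archives over a genome
#' carrying one single-copy target and records the fraction of replicates
#' in which no read overlaps the target by at least `min_overlap` bases,
#' next to the closed-form prediction `exp(-lambda)` and a binomial 95%
#' interval around it.
#'
#' @param coverages Coverage levels to test.
#' @param replicates Replicates per level (>= 100).
#' @param genome_size,read_length,target_length,min_overlap Model
#'   parameters (defaults: 20 kb genome, 150 bp reads, 300 bp target,
#'   45 bp overlap).
#' @param seed Integer seed.
#' @return Tibble of class `"absence_calibration"`: `coverage`, `lambda`,
#'   `predicted` (`exp(-lambda)`), `observed` miss fraction,
#'   `ci_lo`/`ci_hi` (binomial 95% interval of the observed fraction
#'   under the predicted miss probability), `replicates`.
#' @export
calibrate_by_simulation <- function(coverages, replicates = 1000L,
                                    genome_size = 20000L,
                                    read_length = 150L,
                                    target_length = 300L,
                                    min_overlap = 45L, seed = 1L) {
  stopifnot(replicates >= 100)
  target_start <- genome_size %/% 2
  rows <- with_seed(seed, {
    lapply(coverages, function(cv) {
      n_reads <- round(cv * genome_size / read_length)
      model <- coverage_model(genome_size, n_reads, read_length,
                              target_length, min_overlap)
      # a read supports the target iff its start falls in a window of
      # width L_r + L_t - 2*o_min + 1
      win_lo <- target_start - read_length + min_overlap
      win_hi <- target_start + target_length - min_overlap
      n_start <- genome_size - read_length + 1L
      miss <- vapply(seq_len(replicates), function(r) {
        if (n_reads == 0L) return(TRUE)
        starts <- sample.int(n_start, n_reads, replace = TRUE)
        !any(starts >= win_lo & starts <= win_hi)
      }, logical(1))
      pred <- exp(-model$lambda)
      tibble::tibble(coverage = cv, lambda = model$lambda,
                     predicted = pred, observed = mean(miss),
                     ci_lo = stats::qbinom(0.025, replicates, pred) /
                       replicates,
                     ci_hi = stats::qbinom(0.975, replicates, pred) /
                       replicates,
                     replicates = as.integer(replicates))
    })
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("absence_calibration", class(res))
  res
}

#' Presence-call rule configuration
#'
#' @param alpha Absence significance: zero spots are called `absent` only
#'   when the absence probability bound is at or below `alpha`
#'   (default 1e-6, the coverage-argument bound at 50x).
#' @param min_identity Minimum identity fraction of supporting hits for a
#'   `present` call (default 0.8).
#' @param min_exons Minimum number of distinct query coding exons that
#'   must be represented among the hits (default 2).
#' @param require_pcr_free Absence calls require a PCR-free archive;
#'   amplified archives downgrade `absent` to `indeterminate`
#'   (default `TRUE`).
#' @return A list of class `"call_rules"`.
#' @export
call_rules <- function(alpha = 1e-6, min_identity = 0.8, min_exons = 2L,
                       require_pcr_free = TRUE) {
  stopifnot(alpha > 0, alpha < 1, min_identity > 0, min_identity <= 1,
            min_exons >= 1)
  structure(list(alpha = alpha, min_identity = min_identity,
                 min_exons = as.integer(min_exons),
                 require_pcr_free = require_pcr_free),
            class = "call_rules")
}

#' Call a gene present, pseudogene, absent or indeterminate
#'
#' Applies the receptor-evidence rule: `present` when supporting hits
#' carry no frameshift indels, their identity is at least
#' `min_identity`, and at least `min_exons` distinct query coding exons
#' are represented; `pseudogene` when a lesion report says so; `absent`
#' when there are zero supporting spots in a PCR-free archive and the
#' coverage model puts the probability of missing a present gene at or
#' below `alpha`; otherwise `indeterminate`.
#'
#' @param species,gene Labels for the call.
#' @param spots A `spot_hit_table` row set from [search_archive()] for
#'   this gene's queries, or an integer spot count.
#' @param hits Optional hit tibble (from [search_sequence()] on an
#'   assembly, or per-read realignments) supplying identity and indel
#'   evidence.
#' @param exon_support Integer vector of distinct query exon indices
#'   supported (default: computed from `hits` and `queries` when
#'   available).
#' @param lesions Optional `lesion_report` from [call_gene_status()].
#' @param model A [coverage_model()] for the archive.
#' @param rules A [call_rules()] object.
#' @param pcr_free Whether the archive is PCR-free (default `TRUE`).
#' @param detection_prob_per_read Passed to [absence_probability()].
#' @param queries Optional query tibble for exon-support computation.
#' @return One-row tibble of class `"presence_call"`: `species`, `gene`,
#'   `status`, `n_spots`, `n_exons_supported`, `indel_free`,
#'   `max_identity`, `p_abs`, `notes`.
#' @export
call_presence <- function(species, gene, spots, hits = NULL,
                          exon_support = NULL, lesions = NULL,
                          model = NULL, rules = call_rules(),
                          pcr_free = TRUE,
                          detection_prob_per_read = 1,
                          queries = NULL) {
  n_spots <- if (inherits(spots, "spot_hit_table") ||
                 is.data.frame(spots)) {
    sum(spots$n_spots)
  } else {
    as.integer(spots)
  }
  p_abs <- if (!is.null(model)) {
    absence_probability(model, detection_prob_per_read)
  } else {
    NA_real_
  }
  indel_free <- NA
  max_identity <- NA_real_
  n_exons <- NA_integer_
  if (!is.null(hits) && nrow(hits) > 0) {
    max_identity <- max(hits$identity)
    # the evidence rule is applied to the supporting hits: those at or
    # above the identity threshold
    supporting <- hits[hits$identity >= rules$min_identity, ]
    if (nrow(supporting) > 0) {
      indel_free <- all(supporting$n_indels == 0)
      if (is.null(exon_support) && !is.null(queries)) {
        loci <- merge_hits_to_loci(supporting, queries = queries)
        exon_support <- sort(unique(unlist(loci$exon_support)))
      }
    } else {
      indel_free <- FALSE
    }
  }
  if (!is.null(exon_support)) n_exons <- length(exon_support)

  notes <- character()
  status <- "indeterminate"
  if (!is.null(lesions) && n_spots == 0) {
    status <- "indeterminate"
    notes <- c(notes, "conflicting inputs: lesion report present but zero supporting spots")
    warning("lesion report supplied with zero spots; returning indeterminate")
  } else if (!is.null(lesions) && lesions$verdict == "pseudogene") {
    status <- "pseudogene"
  } else if (!is.null(hits) && nrow(hits) > 0 && isTRUE(indel_free) &&
             !is.na(max_identity) &&
             max_identity >= rules$min_identity &&
             !is.na(n_exons) && n_exons >= rules$min_exons) {
    status <- "present"
  } else if (n_spots == 0) {
    if (!is.na(p_abs) && p_abs <= rules$alpha &&
        (pcr_free || !rules$require_pcr_free)) {
      status <- "absent"
    } else {
      status <- "indeterminate"
      if (!pcr_free && !is.na(p_abs) && p_abs <= rules$alpha) {
        notes <- c(notes,
                   "zero spots but archive is PCR-amplified; absence not callable")
      } else if (!is.na(p_abs) && p_abs > rules$alpha) {
        notes <- c(notes, sprintf(
          "zero spots but p_abs = %.3g > alpha; gene may have escaped detection",
          p_abs))
      }
    }
  } else {
    notes <- c(notes, "spots found but presence criteria not all met")
  }
  res <- tibble::tibble(species = species, gene = gene, status = status,
                        n_spots = n_spots,
                        n_exons_supported = n_exons,
                        indel_free = indel_free,
                        max_identity = max_identity,
                        p_abs = p_abs,
                        notes = paste(notes, collapse = "; "))
  class(res) <- c("presence_call", class(res))
  res
}

#' Quantify expression across tissue archives
#'
#' Counts supporting spots per query in each archive, mirroring the
#' spot-count tables used to localize neuropeptide expression across
#' body parts.
#'
#' @param queries Query tibble ([protein_query()] rows).
#' @param archives Named list of `read_archive` objects (names are
#'   archive ids; tissue labels are taken from the archives).
#' @param scoring,min_score Passed to [search_archive()].
#' @param per_million Add `<query>_per_million` columns normalized by the
#'   archive total (default `FALSE`).
#' @return Tibble of class `"expression_table"`: one row per archive with
#'   `archive`, `tissue`, `total_spots`, then one count column per query.
#' @export
quantify_expression <- function(queries, archives,
                                scoring = search_scoring(),
                                min_score = scoring$min_score_read,
                                per_million = FALSE) {
  if (is.null(names(archives))) {
    names(archives) <- sprintf("archive_%d", seq_along(archives))
  }
  rows <- lapply(names(archives), function(id) {
    arch <- archives[[id]]
    tab <- search_archive(queries, arch, scoring, min_score)
    counts <- stats::setNames(as.list(tab$n_spots), tab$query_id)
    out <- tibble::tibble(archive = id,
                          tissue = arch$tissue %||% NA_character_,
                          total_spots = arch$n_spots)
    dplyr::bind_cols(out, tibble::as_tibble(counts))
  })
  res <- dplyr::bind_rows(rows)
  if (per_million) {
    for (q in queries$query_id) {
      res[[paste0(q, "_per_million")]] <-
        ifelse(res$total_spots > 0, res[[q]] / res$total_spots * 1e6, 0)
    }
  }
  class(res) <- c("expression_table", class(res))
  res
}

#' @rdname quantify_expression
#' @param x An `expression_table`.
#' @param ... Unused.
#' @export
tidy.expression_table <- function(x, ...) {
  id_cols <- c("archive", "tissue", "total_spots")
  count_cols <- setdiff(names(x), c(id_cols, grep("_per_million",
                                                  names(x), value = TRUE)))
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(dplyr::all_of(count_cols), names_to = "query",
                        values_to = "n_spots")
}
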