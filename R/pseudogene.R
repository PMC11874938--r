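# Pseudogene analysis: frame-aware comparison of a candidate locus
# against an intact ortholog precursor, recovering frameshifts and
# premature stops, and calling the locus intact or pseudogenized.

#' Align a locus to a reference precursor, tolerating frameshifts
#'
#' Three-frame dynamic programming aligns the reference protein to the
#' locus nucleotide sequence; a residue may consume 3 nt (in-frame), 2 nt
#' (a single-base deletion in the locus) or 4 nt (a single-base
#' insertion), the non-3 widths paying a frame-jump penalty.  Frame jumps
#' and aligned stop codons are recorded as lesions.  When the locus shows
#' no detectable homology to the reference (no translated-search hit at
#' `min_anchor_score`), an explicit no-alignment result is returned
#' rather than any verdict.
#'
#' @param locus_nt Nucleotide string of the candidate locus (spliced
#'   coding sequence, either orientation).
#' @param reference Intact ortholog precursor (residue string).
#' @param scoring A [search_scoring()] object (substitution matrix shared
#'   with the translated search).
#' @param fs_penalty Frame-jump penalty, raw score units (default 15).
#' @param gap_aa,gap_codon Penalty for deleting a residue / inserting a
#'   full codon (default 13 each, one affine open+extend step).
#' @param min_anchor_score Translated-search raw score required to accept
#'   that the locus is homologous at all (default 45).
#' @return A list of class `"frameshift_alignment"`: `aligned` (logical),
#'   `strand`, `score`, `nt_start`, `nt_end` (aligned region of the locus
#'   in the orientation given by `strand`), `lesions` (tibble: `type`,
#'   `coding_pos`, `ref_pos`), `qaln`, `saln` (`!` marks a 2-nt
#'   frameshift column, `*` an aligned stop), `reference`, `locus_nt`.
#' @export
align_locus_to_reference <- function(locus_nt, reference,
                                     scoring = search_scoring(),
                                     fs_penalty = 15, gap_aa = 13,
                                     gap_codon = 13,
                                     min_anchor_score = 45) {
  locus_nt <- toupper(locus_nt)
  anchor <- search_sequence(protein_query("ref", reference), locus_nt,
                            scoring, min_score = min_anchor_score)
  if (nrow(anchor) == 0) {
    return(structure(list(aligned = FALSE, strand = NA_character_,
                          score = NA_real_, lesions = NULL,
                          reference = reference, locus_nt = locus_nt),
                     class = "frameshift_alignment"))
  }
  strand <- if (anchor$frame[1] > 0) "+" else "-"
  nt <- if (strand == "+") locus_nt else revcomp(locus_nt)
  nt <- gsub("[^ACGT]", "N", nt)
  mat <- scoring_matrix(scoring)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # index order must be 16*a + 4*b + c with A,C,G,T = 0..3
  codons <- sapply(0:63, function(k) {
    paste0(bases[k %/% 16 + 1], bases[(k %/% 4) %% 4 + 1],
           bases[k %% 4 + 1])
  })
  codon_aa <- paste(unname(gc[codons]), collapse = "")
  res <- .frameshift_align_cpp(reference, nt, mat,
                               paste(rownames(mat), collapse = ""),
                               codon_aa, fs_penalty, gap_aa, gap_codon)
  les <- tibble::tibble(type = character(), coding_pos = integer(),
                        ref_pos = integer())
  fs <- res$moves %in% c(2L, 3L)
  if (any(fs)) {
    les <- dplyr::bind_rows(les, tibble::tibble(
      type = ifelse(res$moves[fs] == 2L, "frameshift_del",
                    "frameshift_ins"),
      coding_pos = res$nt_pos[fs],
      ref_pos = res$ref_pos[fs]))
  }
  if (length(res$stop_nt) > 0) {
    les <- dplyr::bind_rows(les, tibble::tibble(
      type = "premature_stop",
      coding_pos = res$stop_nt,
      ref_pos = res$stop_ref))
  }
  les <- dplyr::arrange(les, .data$coding_pos)
  structure(list(aligned = TRUE, strand = strand, score = res$score,
                 nt_start = res$nt_start, nt_end = res$nt_end,
                 lesions = les, moves = res$moves,
                 ref_pos = res$ref_pos, nt_pos = res$nt_pos,
                 qaln = res$qaln, saln = res$saln,
                 reference = reference, locus_nt = locus_nt),
            class = "frameshift_alignment")
}

#' @export
print.frameshift_alignment <- function(x, ...) {
  if (!x$aligned) {
    cat("<frameshift_alignment> no detectable homology\n")
    return(invisible(x))
  }
  cat(sprintf("<frameshift_alignment> strand %s, score %.0f, locus %d-%d\n",
              x$strand, x$score, x$nt_start, x$nt_end))
  cat(sprintf("  lesions: %d (%s)\n", nrow(x$lesions),
              paste(x$lesions$type, collapse = ", ")))
  invisible(x)
}

# per-reference-residue subject characters of an alignment
aligned_subject_by_ref <- function(aln) {
  out <- rep("-", nchar(aln$reference))
  qa <- strsplit(aln$qaln, "")[[1]]
  sa <- strsplit(aln$saln, "")[[1]]
  i <- 0L
  for (k in seq_along(qa)) {
    if (qa[k] != "-") {
      i <- i + 1L
      out[i] <- sa[k]
    }
  }
  out
}

#' Call a candidate locus intact or pseudogene
#'
#' A locus is a pseudogene when at least one frameshift or premature stop
#' lies at or before the end of the reference's last paracopy cassette;
#' core mutations (paracopies whose C-terminal family pattern fails in
#' the locus without any frameshift inside the cassette) never
#' pseudogenize on their own - they only reduce the paracopy count.
#' Frameshifts strictly downstream of all paracopies leave the verdict
#' intact and are flagged in the notes.
#'
#' @param aln A `frameshift_alignment` from [align_locus_to_reference()]
#'   (must have `aligned = TRUE`).
#' @param family Family whose paracopies delimit the region in which
#'   lesions pseudogenize; default: the most frequent family among the
#'   reference's classified peptides.
#' @param motifs Motif table used to annotate the reference and to test
#'   core integrity.
#' @return A list of class `"lesion_report"`: `verdict`
#'   (`"intact"`/`"pseudogene"`), `lesions` (tibble: `type`,
#'   `coding_pos`, `ref_pos`, including any `core_mutation` rows),
#'   `n_paracopies_intact`, `n_paracopies_reference`,
#'   `first_lesion_vs_first_paracopy` (`"no_lesions"`, `"upstream"`,
#'   `"within"` or `"downstream"`), `notes`.
#' @export
call_gene_status <- function(aln, family = NULL,
                             motifs = default_motif_table()) {
  stopifnot(inherits(aln, "frameshift_alignment"))
  if (!aln$aligned) {
    stop("no alignment available; cannot call gene status")
  }
  ann <- annotate_precursor(aln$reference, motifs)
  peps <- ann$peptides[!is.na(ann$peptides$family), ]
  if (is.null(family)) {
    if (nrow(peps) == 0) stop("reference has no classified paracopies")
    family <- names(sort(table(peps$family), decreasing = TRUE))[1]
  }
  para <- peps[peps$family == family, ]
  if (nrow(para) == 0) stop("reference has no paracopies of family ",
                            family)
  # cassette of a paracopy extends through its amidation G + cleavage site
  cass_end <- vapply(para$end, function(e) {
    nxt <- ann$sites$position[ann$sites$position > e]
    if (length(nxt) > 0) min(nxt) else e
  }, numeric(1))
  first_start <- min(para$start)
  last_end <- max(cass_end)

  lesions <- aln$lesions
  disruptive <- lesions[lesions$type %in%
                          c("frameshift_del", "frameshift_ins",
                            "premature_stop"), ]
  # core integrity: a paracopy is intact when its reference interval is
  # aligned without frameshift and its C-terminal pattern still matches
  sub_by_ref <- aligned_subject_by_ref(aln)
  pattern <- motifs$pattern[motifs$family == family][1]
  core_rows <- list()
  n_intact <- 0L
  for (p in seq_len(nrow(para))) {
    span <- para$start[p]:para$end[p]
    seg <- paste(sub_by_ref[span], collapse = "")
    fs_inside <- any(disruptive$ref_pos >= para$start[p] &
                       disruptive$ref_pos <= cass_end[p])
    if (!fs_inside && grepl(pattern, seg)) {
      n_intact <- n_intact + 1L
    } else if (!fs_inside) {
      core_rows[[length(core_rows) + 1L]] <- tibble::tibble(
        type = "core_mutation",
        coding_pos = NA_integer_,
        ref_pos = as.integer(para$end[p]))
    }
  }
  all_lesions <- dplyr::arrange(
    dplyr::bind_rows(lesions, dplyr::bind_rows(core_rows)),
    .data$ref_pos)

  pseudo <- any(disruptive$ref_pos <= last_end)
  notes <- character()
  if (!pseudo && nrow(disruptive) > 0) {
    notes <- c(notes, paste0(
      "frameshift/stop lesions occur only downstream of the last ",
      "paracopy cassette; verdict kept intact"))
  }
  ordering <- if (nrow(disruptive) == 0) {
    "no_lesions"
  } else if (min(disruptive$ref_pos) < first_start) {
    "upstream"
  } else if (min(disruptive$ref_pos) <= last_end) {
    "within"
  } else {
    "downstream"
  }
  structure(list(verdict = if (pseudo) "pseudogene" else "intact",
                 lesions = all_lesions,
                 n_paracopies_intact = n_intact,
                 n_paracopies_reference = nrow(para),
                 family = family,
                 first_lesion_vs_first_paracopy = ordering,
                 notes = notes),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat(sprintf("<lesion_report> verdict: %s (%s)\n", x$verdict, x$family))
  cat(sprintf("  %d lesion(s); intact paracopies %d/%d; first lesion %s\n",
              nrow(x$lesions), x$n_paracopies_intact,
              x$n_paracopies_reference, x$first_lesion_vs_first_paracopy))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @rdname call_gene_status
#' @param x A `lesion_report`.
#' @param ... Unused.
#' @export
tidy.lesion_report <- function(x, ...) {
  les <- x$lesions
  les$verdict <- x$verdict
  les$family <- x$family
  les
}
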