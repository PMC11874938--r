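# Rule-based annotation of neuropeptide precursor proteins: signal
# peptide, prohormone-convertase cleavage sites, mature peptides with
# C-terminal amidation, family motif classification and paracopy counting.

#' Default neuropeptide family motif table
#'
#' C-terminal core patterns per family, anchored at the mature peptide's
#' C-terminus.  The patterns are literature-informed configuration, not
#' fixed biology: the consensus cores of the PRXamide families
#' (pyrokinin FXPRL-amide, tryptopyrokinin WFGPRL-type with the diagnostic
#' tryptophan, periviscerokinin PRV-amide), the RYamides, the mantis
#' ELLamide variant of EFLamide, SMYamide, leucokinins and inotocin.
#' Override or extend freely.
#'
#' @return Tibble with columns `family`, `pattern` (regular expression over
#'   residues, `$`-anchored), `amidation_required`, `min_core_length`.
#' @export
default_motif_table <- function() {
  tibble::tribble(
    ~family,             ~pattern,            ~amidation_required, ~min_core_length,
    "tryptopyrokinin",   "[WY].{2}PR[LIV]$",  TRUE,                6L,
    "pyrokinin",         "[FY].PR[LIV]$",     TRUE,                5L,
    "periviscerokinin",  "PRV$",              TRUE,                5L,
    "RYamide",           "R[YF]$",            TRUE,                4L,
    "EFLamide",          "E[FL]L$",           TRUE,                5L,
    "SMYamide",          "SMY$",              TRUE,                4L,
    "leucokinin",        "F.[SA]WG$",         TRUE,                6L,
    "inotocin",          "C..[GST].C.{2,4}PRG$", TRUE,             9L
  )
}

#' Predict a signal peptide
#'
#' Rule-based stand-in for a dedicated signal-peptide predictor, so the
#' package stays self-contained: a signal peptide is a span starting at
#' residue 1, of length 15 to 35, containing a hydrophobic core of at
#' least `min_hydrophobic` consecutive residues from
#' \{A,I,L,M,F,V,W,C\}, and ending where the (-3, -1) small-residue rule
#' of signal peptidase first fires (both positions in \{A,G,S,C,T\})
#' after the hydrophobic core.  Approximate by design.
#'
#' @param precursor Residue string (length >= 25).
#' @param min_len,max_len Allowed signal length range.
#' @param min_hydrophobic Minimum length of the hydrophobic core.
#' @return `c(start = 1, end = p)` or `NULL` when no span qualifies.
#' @export
predict_signal_peptide <- function(precursor, min_len = 15L, max_len = 35L,
                                   min_hydrophobic = 6L) {
  stopifnot(nchar(precursor) >= 25)
  chars <- strsplit(precursor, "")[[1]]
  hydro <- chars %in% AA_HYDROPHOBIC
  # longest hydrophobic run ending at or before each position
  run <- integer(length(chars))
  for (i in seq_along(chars)) {
    run[i] <- if (hydro[i]) (if (i > 1) run[i - 1] else 0L) + 1L else 0L
  }
  upper <- min(max_len, nchar(precursor) - 1L)
  for (p in min_len:upper) {
    core_ok <- any(run[seq_len(p)] >= min_hydrophobic)
    small_ok <- chars[p] %in% AA_SMALL && chars[p - 2L] %in% AA_SMALL
    if (core_ok && small_ok) return(c(start = 1L, end = p))
  }
  NULL
}

#' Find prohormone-convertase cleavage sites
#'
#' Reports all KR, RR and KK basic doublets and, optionally, isolated
#' arginines.  Runs of more than two basic residues are treated as one
#' site whose kind is given by the last two residues.  An isolated R is
#' accepted only when (i) another basic residue lies 4, 6 or 8 positions
#' upstream (the classical monobasic processing context) and that residue
#' is not itself part of a cleavage site, (ii) the site is not flanked by
#' proline on either side (proline blocks convertase processing, which is
#' what protects the internal arginine of PRXamide-type cores), and
#' (iii) the upstream product would be at least `min_product` residues.
#' Positions are cut-points: the index of the last basic residue of the
#' site (cleavage occurs after it).
#'
#' @param precursor Residue string.
#' @param accept_single_r Consider isolated arginines (default `TRUE`).
#' @param min_product Minimum product length for a monobasic site
#'   (default 4).
#' @return Tibble: `position` (cut-point), `kind` in
#'   `"KR","RR","KK","RK","single-R"`, `site_start` (first basic residue
#'   of the site).
#' @export
find_cleavage_sites <- function(precursor, accept_single_r = TRUE,
                                min_product = 4L) {
  chars <- strsplit(precursor, "")[[1]]
  basic <- chars %in% c("K", "R")
  n <- length(chars)
  sites <- list()
  # maximal runs of basic residues; doublet sites first, so monobasic
  # context can exclude residues that already belong to a site
  r <- rle(basic)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  site_residue <- rep(FALSE, n)
  for (i in seq_along(r$values)) {
    if (r$values[i] && ends[i] - starts[i] + 1L >= 2L) {
      site_residue[starts[i]:ends[i]] <- TRUE
    }
  }
  prev_cut <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- starts[i]; e <- ends[i]
    if (e - s + 1L >= 2L) {
      kind <- paste0(chars[e - 1L], chars[e])
      sites[[length(sites) + 1L]] <-
        tibble::tibble(position = e, kind = kind, site_start = s)
      prev_cut <- e
    } else if (chars[s] == "R" && accept_single_r) {
      up <- s - c(4L, 6L, 8L)
      up <- up[up >= 1L]
      upstream_basic <- any(basic[up] & !site_residue[up])
      no_pro <- (s == n || chars[s + 1L] != "P") &&
        (s == 1L || chars[s - 1L] != "P")
      product_len <- s - 1L - prev_cut
      if (upstream_basic && no_pro && product_len >= min_product) {
        sites[[length(sites) + 1L]] <-
          tibble::tibble(position = s, kind = "single-R", site_start = s)
        prev_cut <- s
      }
    }
  }
  if (length(sites) == 0) {
    return(tibble::tibble(position = integer(), kind = character(),
                          site_start = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(sites), .data$position)
}

#' Extract mature peptides between cleavage sites
#'
#' Peptides are the inter-site segments after signal-peptide removal; a
#' trailing glycine immediately preceding a site is stripped and marks
#' the peptide as C-terminally amidated.
#'
#' @param precursor Residue string.
#' @param sites Cleavage-site tibble from [find_cleavage_sites()] (sorted).
#' @param signal Signal span from [predict_signal_peptide()] or `NULL`.
#' @return Tibble: `start`, `end` (coordinates of the mature peptide in
#'   the precursor, after G stripping), `sequence`, `amidated`.
#' @export
extract_peptides <- function(precursor, sites, signal = NULL) {
  n <- nchar(precursor)
  chars <- strsplit(precursor, "")[[1]]
  from <- if (is.null(signal)) 1L else signal[["end"]] + 1L
  bounds_start <- c(from, sites$position + 1L)
  bounds_end <- c(sites$site_start - 1L, n)
  out <- list()
  for (i in seq_along(bounds_start)) {
    s <- bounds_start[i]; e <- bounds_end[i]
    if (e < s) next
    amid <- FALSE
    # a G immediately before a cleavage site becomes the C-terminal amide
    if (i <= nrow(sites) && chars[e] == "G") {
      amid <- TRUE
      e <- e - 1L
      if (e < s) next
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      start = s, end = e,
      sequence = substr(precursor, s, e),
      amidated = amid)
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), amidated = logical()))
  }
  dplyr::bind_rows(out)
}

#' Classify peptides into neuropeptide families
#'
#' Each peptide is assigned to at most one family by matching the
#' family's C-terminal core pattern; when several families match, the
#' longest matched core wins and exact ties leave the peptide unassigned
#' with a warning.
#'
#' @param peptides Tibble from [extract_peptides()].
#' @param motifs Motif table (default [default_motif_table()]).
#' @return `peptides` with a `family` column added, plus attribute
#'   `"paracopy_counts"` (named integer vector per family).
#' @export
classify_peptides <- function(peptides, motifs = default_motif_table()) {
  stopifnot(nrow(motifs) > 0)
  fam <- rep(NA_character_, nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$sequence[i]
    best_len <- -1L
    best_fams <- character()
    for (j in seq_len(nrow(motifs))) {
      if (motifs$amidation_required[j] && !peptides$amidated[i]) next
      if (nchar(pep) < motifs$min_core_length[j]) next
      m <- regexpr(motifs$pattern[j], pep)
      if (m[1] == -1) next
      mlen <- attr(m, "match.length")
      if (mlen > best_len) {
        best_len <- mlen
        best_fams <- motifs$family[j]
      } else if (mlen == best_len) {
        best_fams <- c(best_fams, motifs$family[j])
      }
    }
    if (length(best_fams) == 1) {
      fam[i] <- best_fams
    } else if (length(best_fams) > 1) {
      warning("peptide ", pep, " matches several families equally (",
              paste(best_fams, collapse = ", "), "); left unassigned")
    }
  }
  peptides$family <- fam
  counts <- table(fam[!is.na(fam)])
  attr(peptides, "paracopy_counts") <-
    stats::setNames(as.integer(counts), names(counts))
  peptides
}

#' Count cysteine residues
#'
#' @param precursor Residue string.
#' @param interval Optional `c(start, end)` restricting the count
#'   (1-based closed).
#' @return Integer count of `C`.
#' @export
count_cysteines <- function(precursor, interval = NULL) {
  if (!is.null(interval)) {
    if (interval[2] < interval[1]) return(0L)
    precursor <- substr(precursor, interval[1], interval[2])
  }
  stringr::str_count(precursor, stringr::fixed("C"))
}

#' Annotate a neuropeptide precursor
#'
#' Full annotation: signal peptide, convertase cleavage sites, mature
#' peptides with amidation flags, family assignments with paracopy
#' counts, and cysteine count.
#'
#' @param precursor Residue string (or a `precursor_spec`).
#' @param motifs Motif table (default [default_motif_table()]).
#' @param accept_single_r,min_product Passed to [find_cleavage_sites()].
#' @return A list of class `"precursor_annotation"`: `signal`
#'   (`c(start, end)` or `NULL`), `sites` (tibble), `peptides` (tibble
#'   with `family`), `paracopy_counts` (named integer vector),
#'   `n_cysteines`, `precursor`.
#' @export
#' @examples
#' prec <- plant_precursor_spec("tryptopyrokinin", 3, "WFGPRL")
#' annotate_precursor(prec)
annotate_precursor <- function(precursor, motifs = default_motif_table(),
                               accept_single_r = TRUE, min_product = 4L) {
  precursor <- as.character(precursor)
  signal <- if (nchar(precursor) >= 25) {
    predict_signal_peptide(precursor)
  } else {
    NULL
  }
  sites <- find_cleavage_sites(precursor, accept_single_r, min_product)
  peptides <- extract_peptides(precursor, sites, signal)
  peptides <- classify_peptides(peptides, motifs)
  structure(list(signal = signal, sites = sites, peptides = peptides,
                 paracopy_counts = attr(peptides, "paracopy_counts"),
                 n_cysteines = count_cysteines(precursor),
                 precursor = precursor),
            class = "precursor_annotation")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat("<precursor_annotation>\n")
  if (!is.null(x$signal)) {
    cat(sprintf("  signal peptide: residues %d-%d\n",
                x$signal[["start"]], x$signal[["end"]]))
  } else {
    cat("  signal peptide: none detected\n")
  }
  cat(sprintf("  cleavage sites: %d (%s)\n", nrow(x$sites),
              paste(x$sites$kind, collapse = ", ")))
  cat(sprintf("  peptides: %d, amidated: %d\n", nrow(x$peptides),
              sum(x$peptides$amidated)))
  if (length(x$paracopy_counts) > 0) {
    cat("  paracopies:",
        paste(sprintf("%s=%d", names(x$paracopy_counts),
                      x$paracopy_counts), collapse = ", "), "\n")
  }
  cat(sprintf("  cysteines: %d\n", x$n_cysteines))
  invisible(x)
}

#' Tidy a precursor annotation
#'
#' @param x A `precursor_annotation`.
#' @param ... Unused.
#' @return Tibble of annotated segments: one row per feature (`signal`,
#'   `peptide`, `cleavage_site`) with coordinates, sequence, amidation
#'   and family.
#' @export
tidy.precursor_annotation <- function(x, ...) {
  rows <- list()
  if (!is.null(x$signal)) {
    rows[[1]] <- tibble::tibble(
      feature = "signal", start = x$signal[["start"]],
      end = x$signal[["end"]],
      sequence = substr(x$precursor, x$signal[["start"]],
                        x$signal[["end"]]),
      amidated = NA, family = NA_character_)
  }
  if (nrow(x$peptides) > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = "peptide", start = x$peptides$start,
      end = x$peptides$end, sequence = x$peptides$sequence,
      amidated = x$peptides$amidated, family = x$peptides$family)
  }
  if (nrow(x$sites) > 0) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = "cleavage_site", start = x$sites$site_start,
      end = x$sites$position,
      sequence = substr(rep(x$precursor, nrow(x$sites)),
                        x$sites$site_start, x$sites$position),
      amidated = NA, family = x$sites$kind)
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}
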