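# Synthetic genomes, planted precursor genes, read archives and lesions.
#
# The generator emulates the essential structure of the real inputs the
# inference chain is designed for: large genomes carrying sparse multi-exon
# neuropeptide genes whose coding parts contain strongly conserved cores
# (peptide paracopies, receptor transmembrane blocks), PCR-free uniformly
# sampled genomic reads at a stated coverage, tissue-specific transcript
# pools, and pseudogenizing indels.

# run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# codons per amino acid under the standard code (stops excluded)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# reverse-translate a protein, sampling synonymous codons from the RNG stream
reverse_translate <- function(protein) {
  tab <- codon_table()
  aas <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(aas), names(tab))
  if (length(bad) > 0) {
    stop("cannot reverse-translate residues: ", paste(bad, collapse = ", "))
  }
  paste(vapply(aas, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# residues used for random spacers: no basics (K/R), no G, no P
SPACER_ALPHABET <- c("S", "A", "N", "D", "E", "Q", "T", "Y", "H")

#' Build a synthetic neuropeptide precursor protein
#'
#' Constructs a precursor in the canonical layout of a multi-copy
#' neuropeptide prohormone: an N-terminal signal peptide followed by
#' `n_paracopies` cassettes, each `spacer + core peptide + G + KR`.  The
#' glycine is the amidation donor and the lysine-arginine doublet the
#' convertase cleavage site, so [annotate_precursor()] on the result
#' recovers exactly `n_paracopies` amidated, family-matching peptides.
#'
#' @param family Family tag (must be a family known to the motif table used
#'   downstream, e.g. `"tryptopyrokinin"`, `"RYamide"`).
#' @param n_paracopies Number of peptide paracopies (>= 1).
#' @param core_peptide Residue string of the conserved core, e.g. `"WFGPRL"`.
#'   Cores containing basic-residue doublets (KK/KR/RK/RR) are rejected
#'   because they would collide with the cleavage rules.
#' @param spacer_len Length of the N-terminal spacer within each cassette
#'   (default 0: the mature peptide is exactly the core).
#' @param signal_len Signal peptide length, 15 to 35 residues (default 15).
#' @param seed Integer seed controlling spacer composition.
#' @return A character scalar of class `"precursor_spec"` carrying the
#'   protein sequence, with attributes `family`, `n_paracopies`, `core`,
#'   `signal_end` (last residue of the signal peptide) and `cassettes`
#'   (a tibble of cassette and core coordinates, 1-based closed).
#' @export
#' @examples
#' plant_precursor_spec("tryptopyrokinin", 3, "WFGPRL")
plant_precursor_spec <- function(family, n_paracopies, core_peptide,
                                 spacer_len = 0L, signal_len = 15L,
                                 seed = 1L) {
  stopifnot(n_paracopies >= 1, nchar(core_peptide) >= 1)
  if (signal_len < 15L || signal_len > 35L) {
    stop("signal_len must be between 15 and 35")
  }
  if (grepl("[KR][KR]", core_peptide)) {
    stop("core peptide contains a basic-residue doublet that would collide ",
         "with the cleavage rules: ", core_peptide)
  }
  with_seed(seed, {
    # signal: Met + Lys, hydrophobic stretch, then S-Y-A so the (-3, -1)
    # small-residue rule fires exactly at the planted boundary
    hydro <- sample(c("L", "V", "I", "F", "M", "W"), signal_len - 5L,
                    replace = TRUE)
    signal <- paste0("MK", paste(hydro, collapse = ""), "SYA")
    cassettes <- vapply(seq_len(n_paracopies), function(i) {
      spacer <- if (spacer_len > 0) {
        paste(sample(SPACER_ALPHABET, spacer_len, replace = TRUE),
              collapse = "")
      } else {
        ""
      }
      paste0(spacer, core_peptide, "G", "KR")
    }, character(1))
    protein <- paste0(signal, paste(cassettes, collapse = ""))
    cass_len <- spacer_len + nchar(core_peptide) + 3L
    cass_start <- signal_len + (seq_len(n_paracopies) - 1L) * cass_len + 1L
    core_start <- cass_start + spacer_len
    info <- tibble::tibble(
      paracopy = seq_len(n_paracopies),
      cassette_start = cass_start,
      cassette_end = cass_start + cass_len - 1L,
      core_start = core_start,
      core_end = core_start + nchar(core_peptide) - 1L
    )
    structure(protein,
              class = "precursor_spec",
              family = family,
              n_paracopies = as.integer(n_paracopies),
              core = core_peptide,
              signal_end = as.integer(signal_len),
              cassettes = info)
  })
}

#' @export
print.precursor_spec <- function(x, ...) {
  cat(sprintf("<precursor_spec> %s, %d paracopies, core %s\n",
              attr(x, "family"), attr(x, "n_paracopies"), attr(x, "core")))
  cat(unclass(x), "\n")
  invisible(x)
}

#' Specify a gene to plant in a synthetic genome
#'
#' @param gene_id Gene identifier.
#' @param family Family tag passed to [plant_precursor_spec()], or
#'   free-form when `precursor` is supplied directly.
#' @param n_paracopies,core_peptide,spacer_len,signal_len Precursor layout,
#'   see [plant_precursor_spec()].  Ignored when `precursor` is given.
#' @param precursor Optional explicit precursor protein (residue string),
#'   e.g. a receptor exon construct.
#' @param n_exons Number of coding exons (1 to 5).
#' @param intron_len Length of each intron separating the coding exons.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `"gene_spec"`.
#' @export
gene_spec <- function(gene_id, family, n_paracopies = 3L,
                      core_peptide = "WFGPRL", spacer_len = 0L,
                      signal_len = 15L, precursor = NULL,
                      n_exons = 1L, intron_len = 200L, strand = "+") {
  stopifnot(n_exons >= 1, n_exons <= 5, strand %in% c("+", "-"))
  structure(list(gene_id = gene_id, family = family,
                 n_paracopies = as.integer(n_paracopies),
                 core_peptide = core_peptide,
                 spacer_len = as.integer(spacer_len),
                 signal_len = as.integer(signal_len),
                 precursor = precursor,
                 n_exons = as.integer(n_exons),
                 intron_len = as.integer(intron_len),
                 strand = strand),
            class = "gene_spec")
}

#' Build a synthetic genome with planted genes
#'
#' The background sequence is i.i.d. uniform over A/C/G/T.  Each gene's
#' precursor is reverse-translated (synonymous codons sampled uniformly),
#' split into the requested number of coding exons separated by introns,
#' and placed at a random non-overlapping position.  The concatenated
#' spliced exons of a lesion-free gene translate exactly (frame 0,
#' standard code) to its precursor.
#'
#' @param size_bp Genome size in base pairs.
#' @param gene_specs List of [gene_spec()] objects.
#' @param seed Integer seed; the whole construction is deterministic for a
#'   fixed seed.
#' @return A `genome_model`: list with `sequence` (character scalar),
#'   `features` (tibble: gene_id, family, strand, exons list-column of
#'   tibbles with 1-based closed start/end, precursor, lesions list-column)
#'   and `size_bp`.
#' @export
build_genome <- function(size_bp, gene_specs, seed) {
  stopifnot(size_bp >= 1)
  if (inherits(gene_specs, "gene_spec")) gene_specs <- list(gene_specs)
  with_seed(seed, {
    background <- random_nt(size_bp)
    feats <- vector("list", length(gene_specs))
    occupied <- tibble::tibble(start = integer(), end = integer())
    seq_chr <- background
    for (k in seq_along(gene_specs)) {
      gs <- gene_specs[[k]]
      protein <- gs$precursor
      prec_attr <- NULL
      if (is.null(protein)) {
        prec_attr <- plant_precursor_spec(gs$family, gs$n_paracopies,
                                          gs$core_peptide, gs$spacer_len,
                                          gs$signal_len,
                                          seed = sample.int(1e6, 1))
        protein <- unclass(prec_attr)
        attributes(protein) <- NULL
      }
      cds <- reverse_translate(protein)
      cds_len <- nchar(cds)
      # split the CDS into n_exons pieces at random interior points
      n_ex <- gs$n_exons
      if (cds_len < n_ex) stop("CDS too short for ", n_ex, " exons")
      cuts <- if (n_ex > 1) {
        sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
      } else {
        integer()
      }
      piece_start <- c(1L, cuts + 1L)
      piece_end <- c(cuts, cds_len)
      region_len <- cds_len + (n_ex - 1L) * gs$intron_len
      if (region_len > size_bp) {
        stop("exon/intron set of gene ", gs$gene_id,
             " exceeds the genome size")
      }
      # find a placement not overlapping previously placed genes
      placed <- FALSE
      for (try in seq_len(200L)) {
        start <- sample.int(size_bp - region_len + 1L, 1L)
        end <- start + region_len - 1L
        if (!any(start <= occupied$end & end >= occupied$start)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place gene ", gs$gene_id,
             " without overlap; genome too small or too crowded")
      }
      occupied <- dplyr::bind_rows(occupied,
                                   tibble::tibble(start = start, end = end))
      introns <- replicate(max(n_ex - 1L, 0L), random_nt(gs$intron_len))
      region <- paste0(
        paste0(substring(cds, piece_start, piece_end),
               c(introns, ""), collapse = ""))
      # exon coordinates within the region (gene on + orientation)
      ex_start_rel <- cumsum(c(1L, head(piece_end - piece_start + 1L, -1L) +
                                 gs$intron_len))
      ex_end_rel <- ex_start_rel + (piece_end - piece_start)
      if (gs$strand == "-") {
        region <- revcomp(region)
        # mirror exon coordinates within the region
        new_start <- region_len - ex_end_rel + 1L
        new_end <- region_len - ex_start_rel + 1L
        ord <- order(new_start)
        ex_start_rel <- new_start[ord]
        ex_end_rel <- new_end[ord]
      }
      substr(seq_chr, start, end) <- region
      exon_start <- start + ex_start_rel - 1L
      exon_end <- start + ex_end_rel - 1L
      feats[[k]] <- tibble::tibble(
        gene_id = gs$gene_id,
        family = gs$family,
        strand = gs$strand,
        exons = list(tibble::tibble(start = exon_start, end = exon_end)),
        precursor = protein,
        precursor_info = list(prec_attr),
        lesions = list(tibble::tibble(type = character(),
                                      coding_pos = integer(),
                                      coding_pos_mut = integer(),
                                      genome_pos = integer()))
      )
    }
    structure(list(sequence = seq_chr,
                   features = dplyr::bind_rows(feats),
                   size_bp = as.integer(size_bp)),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %s bp, %d planted gene(s)\n",
              format(x$size_bp, big.mark = ","), nrow(x$features)))
  if (nrow(x$features) > 0) {
    for (i in seq_len(nrow(x$features))) {
      ex <- x$features$exons[[i]]
      nles <- nrow(x$features$lesions[[i]])
      cat(sprintf("  %s (%s, %s): %d exon(s) [%d-%d]%s\n",
                  x$features$gene_id[i], x$features$family[i],
                  x$features$strand[i], nrow(ex), min(ex$start), max(ex$end),
                  if (nles > 0) sprintf(", %d lesion(s)", nles) else ""))
    }
  }
  invisible(x)
}

# genome positions of each coding base, 5' to 3' on the coding strand
coding_map <- function(genome, gene_id) {
  feat <- genome$features[genome$features$gene_id == gene_id, ]
  if (nrow(feat) == 0) stop("no such gene: ", gene_id)
  ex <- feat$exons[[1]]
  pos <- unlist(Map(seq, ex$start, ex$end))
  if (feat$strand[1] == "-") pos <- rev(pos)
  pos
}

#' Extract the spliced coding sequence of a planted gene
#'
#' Concatenates the gene's exons in coding orientation (reverse-complemented
#' for minus-strand genes).
#'
#' @param genome A `genome_model`.
#' @param gene_id Gene identifier.
#' @return Character scalar with the spliced CDS.
#' @export
spliced_cds <- function(genome, gene_id) {
  feat <- genome$features[genome$features$gene_id == gene_id, ]
  if (nrow(feat) == 0) stop("no such gene: ", gene_id)
  ex <- feat$exons[[1]]
  pieces <- substring(genome$sequence, ex$start, ex$end)
  cds <- paste(pieces, collapse = "")
  if (feat$strand[1] == "-") cds <- revcomp(cds)
  cds
}

#' Simulate a PCR-free short-read archive
#'
#' Reads are sampled uniformly over valid start positions with uniform
#' strand choice, emulating a PCR-free genomic sequencing run in which
#' reads are random sequences from the genome.  Sequencing errors are
#' uniform substitutions.
#'
#' @param source A `genome_model`, a plain nucleotide string, or a
#'   transcript pool (tibble with columns `transcript_id`, `sequence`,
#'   `abundance`).
#' @param coverage Target mean per-base depth; the number of reads is
#'   `round(coverage * source_length / read_length)`.  Ignored when
#'   `n_reads` is given.
#' @param n_reads Explicit number of reads (required for transcript pools
#'   unless `coverage` is supplied).
#' @param read_length Read length in bp (default 150).
#' @param paired Simulate read pairs from fragments of `insert_size`
#'   (a pair is one spot).
#' @param insert_size Outer fragment length for paired reads (default 350).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param pcr_free Archive metadata flag; absence calls downstream require
#'   PCR-free archives (default `TRUE`).
#' @param tissue Optional tissue label for transcriptome archives.
#' @param prefix Spot-id prefix (default `"SYN"`).
#' @param seed Integer seed; output is deterministic for fixed inputs.
#' @return A `read_archive`: list with `reads` (tibble: read_id, spot_id,
#'   mate, seq, source_id, start, strand), `read_length`, `paired`,
#'   `pcr_free`, `tissue`, `n_spots`.
#' @export
simulate_reads <- function(source, coverage = NULL, n_reads = NULL,
                           read_length = 150L, paired = FALSE,
                           insert_size = 350L, error_rate = 0,
                           pcr_free = TRUE, tissue = NA_character_,
                           prefix = "SYN", seed) {
  if (error_rate < 0) stop("error_rate must be non-negative")
  is_pool <- is.data.frame(source)
  if (is_pool) {
    stopifnot(all(c("transcript_id", "sequence", "abundance") %in%
                    names(source)))
    if (nrow(source) == 0 || any(nchar(source$sequence) == 0)) {
      stop("zero-length source sequence")
    }
    src_len <- sum(nchar(source$sequence))
  } else {
    src_seq <- if (inherits(source, "genome_model")) source$sequence
               else as.character(source)
    if (nchar(src_seq) == 0) stop("zero-length source sequence")
    src_len <- nchar(src_seq)
    if (read_length > src_len) {
      stop("read_length exceeds the source length")
    }
  }
  if (is.null(n_reads)) {
    if (is.null(coverage)) stop("supply either coverage or n_reads")
    if (coverage < 0) stop("coverage must be non-negative")
    n_reads <- round(coverage * src_len / read_length)
  }
  n_reads <- as.integer(n_reads)

  empty <- tibble::tibble(read_id = character(), spot_id = character(),
                          mate = integer(), seq = character(),
                          source_id = character(), start = integer(),
                          strand = character())
  reads <- with_seed(seed, {
    if (n_reads == 0L) {
      empty
    } else if (is_pool) {
      if (any(nchar(source$sequence) < read_length)) {
        stop("read_length exceeds a transcript length")
      }
      idx <- sample.int(nrow(source), n_reads, replace = TRUE,
                        prob = source$abundance)
      starts <- vapply(idx, function(i) {
        sample.int(nchar(source$sequence[i]) - read_length + 1L, 1L)
      }, integer(1))
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- substring(source$sequence[idx], starts,
                        starts + read_length - 1L)
      seqs <- ifelse(strands == "-",
                     vapply(seqs, revcomp, character(1), USE.NAMES = FALSE),
                     seqs)
      tibble::tibble(
        read_id = sprintf("%s.%d.1", prefix, seq_len(n_reads)),
        spot_id = sprintf("%s.%d", prefix, seq_len(n_reads)),
        mate = 1L, seq = seqs,
        source_id = source$transcript_id[idx],
        start = starts, strand = strands)
    } else if (!paired) {
      starts <- sample.int(src_len - read_length + 1L, n_reads,
                           replace = TRUE)
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      seqs <- substring(src_seq, starts, starts + read_length - 1L)
      seqs <- ifelse(strands == "-",
                     vapply(seqs, revcomp, character(1), USE.NAMES = FALSE),
                     seqs)
      tibble::tibble(
        read_id = sprintf("%s.%d.1", prefix, seq_len(n_reads)),
        spot_id = sprintf("%s.%d", prefix, seq_len(n_reads)),
        mate = 1L, seq = seqs,
        source_id = "genome", start = starts, strand = strands)
    } else {
      if (insert_size > src_len) stop("insert_size exceeds source length")
      if (insert_size < read_length) stop("insert_size < read_length")
      n_spots <- as.integer(ceiling(n_reads / 2))
      fstarts <- sample.int(src_len - insert_size + 1L, n_spots,
                            replace = TRUE)
      fstrands <- sample(c("+", "-"), n_spots, replace = TRUE)
      r1 <- substring(src_seq, fstarts, fstarts + read_length - 1L)
      r2_start <- fstarts + insert_size - read_length
      r2 <- vapply(substring(src_seq, r2_start,
                             fstarts + insert_size - 1L),
                   revcomp, character(1), USE.NAMES = FALSE)
      # on a minus fragment the roles of the mates swap
      m1 <- ifelse(fstrands == "+", r1, r2)
      m2 <- ifelse(fstrands == "+", r2, r1)
      tibble::tibble(
        read_id = c(sprintf("%s.%d.1", prefix, seq_len(n_spots)),
                    sprintf("%s.%d.2", prefix, seq_len(n_spots))),
        spot_id = rep(sprintf("%s.%d", prefix, seq_len(n_spots)), 2L),
        mate = rep(c(1L, 2L), each = n_spots),
        seq = c(m1, m2),
        source_id = "genome",
        start = c(ifelse(fstrands == "+", fstarts, r2_start),
                  ifelse(fstrands == "+", r2_start, fstarts)),
        strand = rep(fstrands, 2L))
    }
  })
  if (error_rate > 0 && nrow(reads) > 0) {
    reads$seq <- with_seed(seed + 1L, {
      inject_substitutions(reads$seq, error_rate)
    })
  }
  structure(list(reads = reads,
                 read_length = as.integer(read_length),
                 paired = paired,
                 pcr_free = pcr_free,
                 tissue = tissue,
                 n_spots = length(unique(reads$spot_id))),
            class = "read_archive")
}

inject_substitutions <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(s)
    chars <- strsplit(s, "")[[1]]
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.read_archive <- function(x, ...) {
  cat(sprintf(
    "<read_archive> %d spot(s), %d read(s) x %d bp, %s%s%s\n",
    x$n_spots, nrow(x$reads), x$read_length,
    if (x$paired) "paired" else "single-end",
    if (isTRUE(x$pcr_free)) ", PCR-free" else ", PCR-amplified",
    if (!is.na(x$tissue)) paste0(", tissue=", x$tissue) else ""))
  invisible(x)
}

#' Inject pseudogenizing lesions into a planted gene
#'
#' Introduces single-base frameshifts (insertions or deletions) and/or
#' premature stop codons into the coding sequence of one planted gene and
#' records each lesion (type and coding coordinate) in the gene's lesion
#' list.  After injection the spliced translation differs from the intact
#' precursor.  Lesion coordinates are strand-relative coding positions,
#' 1-based, in the intact CDS (`coding_pos`) and in the mutated CDS
#' (`coding_pos_mut`).
#'
#' @param genome A `genome_model`.
#' @param gene_id Gene to mutate.
#' @param n_frameshifts Number of single-base indels to inject.
#' @param n_stops Number of codons to replace by TAA.
#' @param seed Integer seed.
#' @param min_spacing Minimum spacing between lesions in coding bp
#'   (default 30).
#' @param region Optional coding interval `c(lo, hi)` to restrict lesion
#'   placement (1-based, in intact CDS coordinates).
#' @return The updated `genome_model` (sequence edited, coordinates of all
#'   downstream features shifted, lesion list filled).
#' @export
inject_lesions <- function(genome, gene_id, n_frameshifts = 0L,
                           n_stops = 0L, seed, min_spacing = 30L,
                           region = NULL) {
  n_lesions <- n_frameshifts + n_stops
  if (n_lesions == 0L) return(genome)
  feat_idx <- which(genome$features$gene_id == gene_id)
  if (length(feat_idx) == 0) stop("no such gene: ", gene_id)
  cmap <- coding_map(genome, gene_id)
  cds_len <- length(cmap)
  lo <- max(10L, if (is.null(region)) 10L else as.integer(region[1]))
  hi <- min(cds_len - 3L, if (is.null(region)) cds_len - 3L
                          else as.integer(region[2]))
  if (hi - lo + 1L < n_lesions * min_spacing) {
    stop("coding region too short to host ", n_lesions,
         " lesions at spacing ", min_spacing)
  }
  strand <- genome$features$strand[feat_idx]

  with_seed(seed, {
    # rejection-sample positions at the required spacing
    pos <- integer(0)
    for (try in seq_len(2000L)) {
      cand <- sort(sample(lo:hi, n_lesions))
      if (n_lesions == 1L || min(diff(cand)) >= min_spacing) {
        pos <- cand
        break
      }
    }
    if (length(pos) == 0) stop("could not place lesions at spacing ",
                               min_spacing)
    types <- sample(c(rep_len(c("frameshift_del", "frameshift_ins"),
                              n_frameshifts),
                      rep("premature_stop", n_stops)))
    lesions <- tibble::tibble(type = types, coding_pos = pos,
                              coding_pos_mut = NA_integer_,
                              genome_pos = cmap[pos])
    # mutated-CDS coordinate: shift by net indels introduced upstream
    shift <- cumsum(c(0L, head(ifelse(types == "frameshift_ins", 1L,
                               ifelse(types == "frameshift_del", -1L, 0L)),
                               -1L)))
    lesions$coding_pos_mut <- lesions$coding_pos + shift

    # apply edits in descending genome position so that coordinates of
    # not-yet-applied edits stay valid
    edits <- lesions
    edits$ord <- order(order(-edits$genome_pos))
    comp1 <- function(b) chartr("ACGT", "TGCA", b)
    for (i in order(-edits$genome_pos)) {
      g <- edits$genome_pos[i]
      type <- edits$type[i]
      if (type == "frameshift_del") {
        genome <- genome_delete(genome, g)
      } else if (type == "frameshift_ins") {
        base <- sample(c("A", "C", "G", "T"), 1L)
        # insert after g on + genes, before g on - genes, so the new base
        # lands just downstream of the chosen coding position
        at <- if (strand == "+") g else g - 1L
        genome <- genome_insert(genome, at, base)
      } else {
        cpos <- edits$coding_pos[i]
        codon_start <- cpos - ((cpos - 1L) %% 3L)
        gpos <- cmap[codon_start:(codon_start + 2L)]
        stop_bases <- c("T", "A", "A")
        chars <- strsplit(genome$sequence, "")[[1]]
        for (k in 1:3) {
          b <- stop_bases[k]
          chars[gpos[k]] <- if (strand == "+") b else comp1(b)
        }
        genome$sequence <- paste(chars, collapse = "")
      }
    }
    genome$features$lesions[[feat_idx]] <-
      dplyr::arrange(lesions, .data$coding_pos)
    genome
  })
}

# delete the base at genome position g, shifting downstream coordinates
genome_delete <- function(genome, g) {
  genome$sequence <- paste0(substr(genome$sequence, 1L, g - 1L),
                            substr(genome$sequence, g + 1L,
                                   nchar(genome$sequence)))
  genome$size_bp <- genome$size_bp - 1L
  genome$features$exons <- lapply(genome$features$exons, function(ex) {
    ex$end <- ifelse(ex$end >= g, ex$end - 1L, ex$end)
    ex$start <- ifelse(ex$start > g, ex$start - 1L, ex$start)
    ex
  })
  genome
}

# insert base(s) after genome position g (g = 0 prepends)
genome_insert <- function(genome, g, base) {
  genome$sequence <- paste0(substr(genome$sequence, 1L, g), base,
                            substr(genome$sequence, g + 1L,
                                   nchar(genome$sequence)))
  w <- nchar(base)
  genome$size_bp <- genome$size_bp + w
  genome$features$exons <- lapply(genome$features$exons, function(ex) {
    grow <- ex$start <= g & ex$end > g
    ex$end <- ifelse(ex$end > g | grow, ex$end + w, ex$end)
    ex$start <- ifelse(ex$start > g, ex$start + w, ex$start)
    ex
  })
  genome
}

#' Build a transcript pool from planted genes
#'
#' @param genome A `genome_model`.
#' @param gene_ids Genes to include (default: all).
#' @param abundances Relative abundances, recycled to the number of genes.
#' @return Tibble with columns `transcript_id`, `sequence`, `abundance`,
#'   usable as the `source` of [simulate_reads()].
#' @export
transcript_pool <- function(genome, gene_ids = genome$features$gene_id,
                            abundances = 1) {
  tibble::tibble(
    transcript_id = gene_ids,
    sequence = vapply(gene_ids, function(g) spliced_cds(genome, g),
                      character(1), USE.NAMES = FALSE),
    abundance = rep_len(abundances, length(gene_ids)))
}
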