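# Translated homology search: local alignment of protein queries against
# six-frame translations of contigs or individual short reads, with
# spot-level counting.  Plays the role tblastn / tblastn_vdb play against
# assemblies and read archives.
#
# Alignments never cross a stop codon in the subject frame: every frame
# translation is split at stops and each stop-free segment is aligned
# separately (full Smith-Waterman per segment, which at the scales this
# package targets is exact and fast enough to avoid seeding heuristics).

#' Construct a protein query
#'
#' @param query_id Identifier.
#' @param sequence Residue string (20-letter alphabet plus X).
#' @param family Optional family tag.
#' @param exon_segments Optional list of `c(start, end)` residue intervals
#'   (1-based closed) marking which part of the protein each coding exon
#'   contributes; used for exon-support bookkeeping in
#'   [merge_hits_to_loci()] and [call_presence()].
#' @return One-row tibble with columns `query_id`, `sequence`, `family`,
#'   `exon_segments` (list-column).
#' @export
protein_query <- function(query_id, sequence, family = NA_character_,
                          exon_segments = NULL) {
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", sequence)) {
    stop("query contains characters outside the residue alphabet")
  }
  if (nchar(sequence) == 0) stop("empty query")
  if (!is.null(exon_segments)) {
    segs <- do.call(rbind, lapply(exon_segments, function(s) s[1:2]))
    o <- order(segs[, 1])
    segs <- segs[o, , drop = FALSE]
    if (nrow(segs) > 1 &&
        any(segs[-1, 1] <= segs[-nrow(segs), 2])) {
      stop("exon segments overlap")
    }
    exon_segments <- lapply(seq_len(nrow(segs)),
                            function(i) as.integer(segs[i, ]))
  }
  tibble::tibble(query_id = query_id, sequence = sequence,
                 family = family,
                 exon_segments = list(exon_segments))
}

#' Six-frame conceptual translation
#'
#' Standard genetic code; frames 2 and 3 drop leading bases, reverse
#' frames translate the reverse complement, trailing partial codons are
#' dropped, stops are retained as `*`, and non-ACGT symbols translate to
#' `X`.
#'
#' @param nt Nucleotide string.
#' @return Named character vector of six residue strings, names
#'   `"1","2","3","-1","-2","-3"`.
# translate, paying the fuzzy-codon machinery only when a sequence
# actually contains an ambiguous base
translate_x <- function(x, fuzzy) {
  if (fuzzy) {
    as.character(Biostrings::translate(x, if.fuzzy.codon = "X"))
  } else {
    as.character(Biostrings::translate(x))
  }
}

#' @export
#' @examples
#' six_frame_translate("ATGAAA")
six_frame_translate <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1, nchar(nt) > 0)
  nt <- toupper(nt)
  nt <- gsub("[^ACGT]", "N", nt)
  fuzzy <- grepl("N", nt, fixed = TRUE)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(x, f) {
    n <- length(x) - f + 1L
    ncod <- n %/% 3L
    if (ncod == 0L) return("")
    translate_x(Biostrings::subseq(x, start = f, width = 3L * ncod),
                fuzzy)
  }
  out <- c(tr1(fwd, 1L), tr1(fwd, 2L), tr1(fwd, 3L),
           tr1(rev, 1L), tr1(rev, 2L), tr1(rev, 3L))
  stats::setNames(out, c("1", "2", "3", "-1", "-2", "-3"))
}

# scoring configuration shared by the search functions
#' Scoring scheme for translated searches
#'
#' BLOSUM62 with affine gap penalties (defaults: open 11, extend 1), raw
#' scores.  Default acceptance thresholds are raw score >= 55 on contigs
#' and >= 45 on short reads, chosen so that a block of about 10-15
#' identical well-conserved residues is detectable; all are adjustable.
#'
#' @param matrix Substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @param min_score_contig,min_score_read Raw-score acceptance thresholds.
#' @return A list of class `"search_scoring"`.
#' @export
search_scoring <- function(matrix = "BLOSUM62", gap_opening = 11,
                           gap_extension = 1, min_score_contig = 55,
                           min_score_read = 45) {
  stopifnot(gap_opening > 0, gap_extension > 0,
            min_score_contig > 0, min_score_read > 0)
  structure(list(matrix = matrix, gap_opening = gap_opening,
                 gap_extension = gap_extension,
                 min_score_contig = min_score_contig,
                 min_score_read = min_score_read),
            class = "search_scoring")
}

scoring_matrix <- function(scoring) {
  if (is.matrix(scoring$matrix)) return(scoring$matrix)
  e <- new.env()
  utils::data(list = scoring$matrix, package = "Biostrings", envir = e)
  get(scoring$matrix, envir = e)
}

# split a frame translation into stop-free segments with 1-based aa offsets
stop_free_segments <- function(aa) {
  if (nchar(aa) == 0) {
    return(tibble::tibble(seg = character(), aa_start = integer()))
  }
  m <- gregexpr("[^*]+", aa)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(seg = character(), aa_start = integer()))
  }
  tibble::tibble(seg = regmatches(aa, gregexpr("[^*]+", aa))[[1]],
                 aa_start = as.integer(m))
}

# map an aa interval in frame coordinates to nt positions in the original
# sequence; returns c(start, end) with start <= end
frame_aa_to_nt <- function(frame, aa_start, aa_end, nt_len) {
  f <- abs(frame)
  p1 <- f + 3L * (aa_start - 1L)
  p2 <- f + 3L * aa_end - 1L
  if (frame > 0) c(p1, p2) else c(nt_len - p2 + 1L, nt_len - p1 + 1L)
}

#' Search a nucleotide sequence with a protein query
#'
#' Aligns the query locally (Smith-Waterman, affine gaps) against every
#' stop-free segment of all six frame translations of the subject and
#' returns all alignments scoring at least `min_score`, sorted by score
#' (ties broken by frame then subject position).
#'
#' @param query A query tibble row from [protein_query()] or a plain
#'   residue string.
#' @param subject_nt Nucleotide string (length >= 3).
#' @param scoring A [search_scoring()] object.
#' @param min_score Raw-score threshold (default: the scoring object's
#'   contig threshold).
#' @param subject_id Label used in the output.
#' @return Tibble of hits: `query_id`, `subject_id`, `frame`, `qstart`,
#'   `qend`, `sstart`, `send` (residue coordinates in the frame
#'   translation), `snt_start`, `snt_end` (nucleotide coordinates in the
#'   subject), `score`, `identity`, `n_indels`, `qaln`, `saln`.
#' @export
search_sequence <- function(query, subject_nt, scoring = search_scoring(),
                            min_score = scoring$min_score_contig,
                            subject_id = "subject") {
  if (is.character(query)) query <- protein_query("query", query)
  stopifnot(nrow(query) == 1)
  if (nchar(subject_nt) < 3) return(empty_hits())
  mat <- scoring_matrix(scoring)
  qseq <- Biostrings::AAString(query$sequence)
  frames <- six_frame_translate(subject_nt)
  nt_len <- nchar(subject_nt)
  segtab <- dplyr::bind_rows(lapply(names(frames), function(fr_name) {
    segs <- stop_free_segments(frames[[fr_name]])
    segs$frame <- as.integer(fr_name)
    segs
  }))
  segtab <- segtab[nchar(segtab$seg) >= 2, ]
  if (nrow(segtab) == 0) return(empty_hits())
  # one vectorized score-only pass; full alignments only above threshold
  sc_all <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(segtab$seg), qseq, type = "local",
    substitutionMatrix = mat, gapOpening = scoring$gap_opening,
    gapExtension = scoring$gap_extension, scoreOnly = TRUE)
  segtab <- segtab[sc_all >= min_score, ]
  if (nrow(segtab) == 0) return(empty_hits())
  rows <- list()
  for (i in seq_len(nrow(segtab))) {
    frame <- segtab$frame[i]
    pa <- Biostrings::pairwiseAlignment(
      qseq, Biostrings::AAString(segtab$seg[i]), type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gap_opening,
      gapExtension = scoring$gap_extension)
    sc <- Biostrings::score(pa)
    qaln <- as.character(Biostrings::alignedPattern(pa))
    saln <- as.character(Biostrings::alignedSubject(pa))
    s_aa_start <- segtab$aa_start[i] +
      Biostrings::start(Biostrings::subject(pa)) - 1L
    s_aa_end <- segtab$aa_start[i] +
      Biostrings::end(Biostrings::subject(pa)) - 1L
    ntc <- frame_aa_to_nt(frame, s_aa_start, s_aa_end, nt_len)
    ncols <- nchar(qaln)
    nmatch <- sum(strsplit(qaln, "")[[1]] == strsplit(saln, "")[[1]])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      query_id = query$query_id,
      subject_id = subject_id,
      frame = frame,
      qstart = Biostrings::start(Biostrings::pattern(pa)),
      qend = Biostrings::end(Biostrings::pattern(pa)),
      sstart = s_aa_start, send = s_aa_end,
      snt_start = ntc[1], snt_end = ntc[2],
      score = sc,
      identity = nmatch / ncols,
      n_indels = stringr::str_count(qaln, "-+") +
        stringr::str_count(saln, "-+"),
      qaln = qaln, saln = saln)
  }
  hits <- dplyr::bind_rows(rows)
  frame_rank <- match(hits$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  hits[order(-hits$score, frame_rank, hits$sstart), ]
}

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 frame = integer(), qstart = integer(), qend = integer(),
                 sstart = integer(), send = integer(),
                 snt_start = integer(), snt_end = integer(),
                 score = numeric(), identity = numeric(),
                 n_indels = integer(), qaln = character(),
                 saln = character())
}

# translate all reads in all six frames and collect stop-free segments;
# returns tibble(read_row, frame, aa_start, seg)
archive_segments <- function(seqs) {
  n <- length(seqs)
  seqs <- gsub("[^ACGT]", "N", toupper(seqs))
  fuzzy <- any(grepl("N", seqs, fixed = TRUE))
  x <- Biostrings::DNAStringSet(seqs)
  widths <- Biostrings::width(x)
  out <- vector("list", 6L)
  k <- 0L
  for (dir in c(1L, -1L)) {
    xx <- if (dir == 1L) x else Biostrings::reverseComplement(x)
    for (f in 1:3) {
      k <- k + 1L
      ncod <- (widths - f + 1L) %/% 3L
      keep <- which(ncod > 0L)
      if (length(keep) == 0) next
      aa <- translate_x(
        Biostrings::subseq(xx[keep], start = f,
                           width = 3L * ncod[keep]),
        fuzzy)
      m <- gregexpr("[^*]+", aa)
      segs <- regmatches(aa, m)
      nseg <- lengths(segs)
      starts <- lapply(m, function(v) if (v[1] == -1) integer() else
                                        as.integer(v))
      out[[k]] <- tibble::tibble(
        read_row = rep(keep, nseg),
        frame = dir * f,
        aa_start = unlist(starts, use.names = FALSE),
        seg = unlist(segs, use.names = FALSE))
    }
  }
  dplyr::bind_rows(out)
}

#' Search a read archive and count supporting spots
#'
#' Every stop-free segment of every frame of every read is scored against
#' each query by exhaustive local alignment.  A spot (a read or a read
#' pair) contributes at most 1 to a query's count no matter how many
#' mates, frames or segments hit.
#'
#' @param queries Query tibble ([protein_query()] rows bound together) or a
#'   single query.
#' @param archive A `read_archive`.
#' @param scoring A [search_scoring()] object.
#' @param min_score Raw-score threshold (default: the scoring object's read
#'   threshold).
#' @return A tibble of class `"spot_hit_table"`: one row per query with
#'   `query_id`, `n_spots`, `spot_ids` (list-column of contributing spot
#'   ids) and `read_hits` (list-column of per-read best hits: read_id,
#'   frame, score).
#' @export
search_archive <- function(queries, archive, scoring = search_scoring(),
                           min_score = scoring$min_score_read) {
  stopifnot(inherits(archive, "read_archive"))
  reads <- archive$reads
  mat <- scoring_matrix(scoring)
  if (nrow(reads) == 0) {
    res <- tibble::tibble(query_id = queries$query_id,
                          n_spots = 0L,
                          spot_ids = rep(list(character()),
                                         nrow(queries)),
                          read_hits = rep(list(tibble::tibble(
                            read_id = character(), frame = integer(),
                            score = numeric())), nrow(queries)))
    class(res) <- c("spot_hit_table", class(res))
    return(res)
  }
  segs <- archive_segments(reads$seq)
  # segments shorter than min_score / max(diagonal) can never reach the
  # threshold and are skipped
  min_len <- ceiling(min_score / max(diag(mat)))
  rows <- vector("list", nrow(queries))
  for (qi in seq_len(nrow(queries))) {
    q <- queries[qi, ]
    use <- segs[nchar(segs$seg) >= min_len, ]
    if (nrow(use) > 0) {
      sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(use$seg),
        Biostrings::AAString(q$sequence), type = "local",
        substitutionMatrix = mat, gapOpening = scoring$gap_opening,
        gapExtension = scoring$gap_extension, scoreOnly = TRUE)
      hit <- use[sc >= min_score, ]
      hit$score <- sc[sc >= min_score]
    } else {
      hit <- use
      hit$score <- numeric()
    }
    if (nrow(hit) > 0) {
      per_read <- hit |>
        dplyr::mutate(read_id = reads$read_id[.data$read_row],
                      spot_id = reads$spot_id[.data$read_row]) |>
        dplyr::group_by(.data$read_id, .data$spot_id) |>
        dplyr::summarise(
          frame = .data$frame[which.max(.data$score)],
          score = max(.data$score), .groups = "drop")
      spot_ids <- sort(unique(per_read$spot_id))
    } else {
      per_read <- tibble::tibble(read_id = character(),
                                 spot_id = character(),
                                 frame = integer(), score = numeric())
      spot_ids <- character()
    }
    rows[[qi]] <- tibble::tibble(
      query_id = q$query_id,
      n_spots = length(spot_ids),
      spot_ids = list(spot_ids),
      read_hits = list(per_read[order(per_read$read_id),
                                c("read_id", "frame", "score")]))
  }
  res <- dplyr::bind_rows(rows)
  class(res) <- c("spot_hit_table", class(res))
  res
}

#' Merge assembly hits into candidate gene loci
#'
#' Hits on the same subject and strand lying within `max_gap_nt` of each
#' other are merged into one locus; when the queries carry exon segments,
#' the locus records which query exons are supported.
#'
#' @param hits Hit tibble from [search_sequence()].
#' @param max_gap_nt Maximum nucleotide gap bridged when chaining hits
#'   (default 50000, accommodating large introns).
#' @param queries Optional query tibble supplying `exon_segments`.
#' @return Tibble of loci: `locus_id`, `subject_id`, `strand`, `start`,
#'   `end`, `n_hits`, `queries` (list), `exon_support` (list of integer
#'   exon indices).
#' @export
merge_hits_to_loci <- function(hits, max_gap_nt = 50000L, queries = NULL) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(locus_id = character(), subject_id = character(),
                          strand = character(), start = integer(),
                          end = integer(), n_hits = integer(),
                          queries = list(), exon_support = list()))
  }
  hits$strand <- ifelse(hits$frame > 0, "+", "-")
  hits <- hits[order(hits$subject_id, hits$strand, hits$snt_start), ]
  grp <- paste(hits$subject_id, hits$strand)
  locus <- integer(nrow(hits))
  cur <- 0L
  cur_end <- -Inf
  cur_grp <- ""
  for (i in seq_len(nrow(hits))) {
    if (grp[i] != cur_grp || hits$snt_start[i] - cur_end > max_gap_nt) {
      cur <- cur + 1L
      cur_grp <- grp[i]
      cur_end <- hits$snt_end[i]
    } else {
      cur_end <- max(cur_end, hits$snt_end[i])
    }
    locus[i] <- cur
  }
  hits$`.locus` <- locus
  exon_of_hit <- function(qid, qstart, qend) {
    if (is.null(queries)) return(integer())
    segs <- queries$exon_segments[[match(qid, queries$query_id)]]
    if (is.null(segs)) return(integer())
    which(vapply(segs, function(s) qstart <= s[2] && qend >= s[1],
                 logical(1)))
  }
  out <- lapply(split(seq_len(nrow(hits)), locus), function(ix) {
    h <- hits[ix, ]
    supp <- sort(unique(unlist(Map(exon_of_hit, h$query_id, h$qstart,
                                   h$qend))))
    tibble::tibble(subject_id = h$subject_id[1], strand = h$strand[1],
                   start = min(h$snt_start), end = max(h$snt_end),
                   n_hits = nrow(h),
                   queries = list(sort(unique(h$query_id))),
                   exon_support = list(as.integer(supp)))
  })
  res <- dplyr::bind_rows(out)
  res <- res[order(res$subject_id, res$strand, res$start), ]
  res$locus_id <- sprintf("locus_%d", seq_len(nrow(res)))
  res[, c("locus_id", "subject_id", "strand", "start", "end", "n_hits",
          "queries", "exon_support")]
}
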