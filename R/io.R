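# Readers and writers for the standard formats the pipeline touches.

#' Write a synthetic genome to FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output file.
#' @param name Sequence name (default `"synthetic_genome"`).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, name = "synthetic_genome") {
  x <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write planted-gene truth annotations as GFF3
#'
#' One `gene` line plus one `CDS` line per exon for every planted gene;
#' lesions are recorded in the gene line's attributes.  Coordinates are
#' 1-based closed, per the GFF3 convention.
#'
#' @param genome A `genome_model`.
#' @param path Output file.
#' @param seqid Sequence name used in column 1.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(genome, path, seqid = "synthetic_genome") {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, genome$size_bp))
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    ex <- f$exons[[1]]
    les <- f$lesions[[1]]
    les_attr <- if (nrow(les) > 0) {
      sprintf(";lesions=%s",
              paste(sprintf("%s@%d", les$type, les$coding_pos),
                    collapse = ","))
    } else ""
    lines <- c(lines, sprintf(
      "%s\tpeptidetect\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%s%s",
      seqid, min(ex$start), max(ex$end), f$strand, f$gene_id, f$family,
      les_attr))
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tpeptidetect\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        seqid, ex$start[j], ex$end[j], f$strand, f$gene_id, j, f$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a read archive to FASTQ
#'
#' Phred+33 with a fixed quality character; byte-identical output for
#' identical archives.
#'
#' @param archive A `read_archive`.
#' @param path Output file.
#' @param quality_char Fixed per-base quality symbol (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(archive, path, quality_char = "I") {
  reads <- archive$reads
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  quals <- Biostrings::BStringSet(
    vapply(nchar(reads$seq), function(n) strrep(quality_char, n),
           character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read archive
#'
#' Mate indices and spot ids are recovered from read names of the form
#' `<spot>.<mate>` when present.
#'
#' @param path FASTQ file.
#' @param pcr_free,tissue Archive metadata.
#' @return A `read_archive` (provenance columns `start`/`strand` are `NA`).
#' @export
read_reads_fastq <- function(path, pcr_free = TRUE, tissue = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(x)
  has_mate <- grepl("\\.[12]$", ids)
  spot <- ifelse(has_mate, sub("\\.[12]$", "", ids), ids)
  mate <- ifelse(has_mate, as.integer(sub("^.*\\.", "", ids)), 1L)
  reads <- tibble::tibble(read_id = ids, spot_id = spot, mate = mate,
                          seq = unname(as.character(x)),
                          source_id = NA_character_,
                          start = NA_integer_, strand = NA_character_)
  structure(list(reads = reads,
                 read_length = if (nrow(reads) > 0) max(nchar(reads$seq))
                               else 0L,
                 paired = any(mate == 2L),
                 pcr_free = pcr_free, tissue = tissue,
                 n_spots = length(unique(spot))),
            class = "read_archive")
}

#' Read protein queries from FASTA
#'
#' @param path Protein FASTA; the family tag may be encoded after a space
#'   in the header (`>id family`).
#' @return Tibble of queries (see [protein_query()]).
#' @export
read_queries_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  fams <- ifelse(grepl("\\s", names(x)),
                 sub("^\\S+\\s+", "", names(x)), NA_character_)
  dplyr::bind_rows(lapply(seq_along(x), function(i) {
    protein_query(ids[i], as.character(x[[i]]), family = fams[i])
  }))
}

#' Write protein queries to FASTA
#'
#' @param queries Query tibble (see [protein_query()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_queries_fasta <- function(queries, path) {
  x <- Biostrings::AAStringSet(stats::setNames(
    queries$sequence,
    ifelse(is.na(queries$family), queries$query_id,
           paste(queries$query_id, queries$family))))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a transcript pool to FASTA
#'
#' @param pool Transcript pool tibble (see [transcript_pool()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(pool, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(pool$sequence,
                                                pool$transcript_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a fixed column order; list-columns are
#' flattened to comma-separated strings.
#'
#' @param x A data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_result <- function(x, path) {
  x <- as.data.frame(lapply(x, function(col) {
    if (is.list(col)) {
      vapply(col, function(v) paste(unlist(v), collapse = ","), character(1))
    } else {
      col
    }
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
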