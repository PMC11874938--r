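# Translated homology search against contigs and reads.

test_that("six-frame translation follows the standard code", {
  fr <- six_frame_translate("ATGAAA")
  expect_identical(fr[["1"]], "MK")
  expect_identical(fr[["2"]], "*")   # TGA
  expect_identical(fr[["-1"]], "FH")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAA")))
  expect_identical(six_frame_translate(rc)[["-1"]], "MK")
  expect_identical(six_frame_translate("TAG")[["1"]], "*")
  expect_identical(six_frame_translate("NNN")[["1"]], "X")
  expect_identical(six_frame_translate("AT")[["1"]], "")
})

test_that("six-frame translation is consistent with subsequence
          translation on random sequences", {
  set.seed(401)
  for (i in 1:20) {
    nt <- random_dna(sample(30:120, 1))
    fr <- six_frame_translate(nt)
    for (f in 1:3) {
      n <- nchar(nt) - f + 1
      ncod <- n %/% 3
      expected <- if (ncod == 0) "" else
        as.character(Biostrings::translate(Biostrings::DNAString(
          substr(nt, f, f + 3 * ncod - 1))))
      expect_identical(fr[[as.character(f)]], expected)
    }
  }
})

test_that("exact encodings give identity-1 hits with strand symmetry", {
  core <- "WFGPRLWFGPRLWFGPRL"
  cds <- paste(c("TGG", "TTT", "GGA", "CCA", "CGT", "CTG")[rep(1:6, 3)],
               collapse = "")
  subj <- paste0(random_dna(30), cds, random_dna(30))
  set.seed(77)
  h <- search_sequence(core, subj, min_score = 45)
  expect_gte(nrow(h), 1)
  expect_identical(h$identity[1], 1)
  expect_identical(h$n_indels[1], 0L)
  expect_gt(h$frame[1], 0)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(subj)))
  h2 <- search_sequence(core, rc, min_score = 45)
  expect_identical(h2$score[1], h$score[1])
  expect_identical(h2$frame[1], -h$frame[1])
  # the mirrored hit covers the mirrored nucleotide interval
  expect_identical(sort(c(h2$snt_start[1], h2$snt_end[1])),
                   sort(nchar(subj) - c(h$snt_start[1], h$snt_end[1]) + 1L))
})

test_that("empty queries are rejected and short subjects give no hits", {
  expect_error(protein_query("q", ""), "empty")
  expect_identical(nrow(search_sequence("WFGPRL", "AC")), 0L)
})

test_that("best hit scores equal an independent Smith-Waterman oracle on
          random instances", {
  set.seed(402)
  for (i in 1:50) {
    q <- random_protein(sample(8:40, 1))
    s <- random_dna(sample(60:300, 1))
    h <- search_sequence(q, s, min_score = 15)
    orac <- oracle_best_score(q, s)
    if (orac >= 15) {
      expect_equal(max(h$score), orac)
    } else {
      expect_identical(nrow(h), 0L)
    }
  }
})

test_that("hits never cross a stop codon in the subject frame", {
  q <- "WFGPRLWFGPRL"
  half <- paste(c("TGG", "TTT", "GGA", "CCA", "CGT", "CTG"), collapse = "")
  subj <- paste0(half, "TAA", half)
  h <- search_sequence(q, subj, min_score = 20)
  h1 <- h[h$frame == 1, ]
  expect_gte(nrow(h1), 2)
  # each in-frame hit stays on one side of the stop at nt 19-21
  expect_true(all(h1$snt_end < 19 | h1$snt_start > 21))
})

test_that("archive search counts each spot once and matches a per-read
          oracle", {
  g <- build_genome(3000, list(
    gene_spec("tpk", "tryptopyrokinin", 3, "WFGPRL", n_exons = 1)),
    seed = 50)
  arc <- simulate_reads(g, coverage = 5, read_length = 150, seed = 51)
  q <- protein_query("tpk", g$features$precursor[1])
  tab <- search_archive(q, arc)
  expect_s3_class(tab, "spot_hit_table")
  # oracle: score every read individually through search_sequence
  hits <- vapply(seq_len(nrow(arc$reads)), function(i) {
    h <- search_sequence(q, arc$reads$seq[i], min_score = 45)
    nrow(h) > 0
  }, logical(1))
  expect_identical(tab$n_spots,
                   length(unique(arc$reads$spot_id[hits])))
  expect_setequal(tab$spot_ids[[1]], unique(arc$reads$spot_id[hits]))
  # order independence
  arc_rev <- arc
  arc_rev$reads <- arc_rev$reads[rev(seq_len(nrow(arc_rev$reads))), ]
  tab_rev <- search_archive(q, arc_rev)
  expect_identical(tab_rev$n_spots, tab$n_spots)
  expect_setequal(tab_rev$spot_ids[[1]], tab$spot_ids[[1]])
})

test_that("empty archives and absent genes give zero spots", {
  g <- build_genome(4000, list(), seed = 60)
  arc0 <- simulate_reads(g, coverage = 0, seed = 61)
  q <- protein_query("tpk",
                     as.character(plant_precursor_spec(
                       "tryptopyrokinin", 3, "WFGPRL")))
  expect_identical(search_archive(q, arc0)$n_spots, 0L)
  arc <- simulate_reads(g, coverage = 10, seed = 62)
  expect_identical(search_archive(q, arc)$n_spots, 0L)
})

test_that("paired mates hitting together still count one spot", {
  prec <- plant_precursor_spec("tryptopyrokinin", 10, "WFGPRL",
                               spacer_len = 2)
  g <- build_genome(3000, list(
    gene_spec("tpk", "tryptopyrokinin",
              precursor = as.character(prec))), seed = 70)
  arc <- simulate_reads(g, coverage = 30, read_length = 100,
                        paired = TRUE, insert_size = 220, seed = 71)
  q <- protein_query("tpk", as.character(prec))
  tab <- search_archive(q, arc)
  hits <- tab$read_hits[[1]]
  spots_from_reads <- unique(sub("\\.[12]$", "", hits$read_id))
  expect_identical(tab$n_spots, length(spots_from_reads))
  expect_gt(nrow(hits), tab$n_spots)  # some spots hit with both mates
})

test_that("a conserved block of 25 identical residues is detected in
          every read fully covering it", {
  block <- "MDWWTKFGHRLVNAPEQWYSMCIDE"  # 25 residues
  expect_identical(nchar(block), 25L)
  g <- build_genome(4000, list(
    gene_spec("b", "block", precursor = paste0(
      random_protein(30), block, random_protein(30)))), seed = 80)
  ex <- g$features$exons[[1]]
  block_nt <- c(ex$start[1] + 30 * 3, ex$start[1] + 55 * 3 - 1)
  arc <- simulate_reads(g, coverage = 20, read_length = 150, seed = 81)
  covering <- arc$reads$start <= block_nt[1] &
    arc$reads$start + 150 - 1 >= block_nt[2]
  expect_gt(sum(covering), 5)
  tab <- search_archive(protein_query("b", block), arc)
  hit_ids <- tab$read_hits[[1]]$read_id
  expect_true(all(arc$reads$read_id[covering] %in% hit_ids))
})

test_that("locus merging matches an interval-clustering oracle and
          never merges strands", {
  set.seed(403)
  q <- protein_query("q", random_protein(40),
                     exon_segments = list(c(1, 20), c(21, 40)))
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    starts <- sort(sample(1:100000, n))
    widths <- sample(50:500, n, replace = TRUE)
    frames <- sample(c(1L, 2L, 3L, -1L, -2L, -3L), n, replace = TRUE)
    hits <- tibble::tibble(
      query_id = "q", subject_id = "chr1", frame = frames,
      qstart = sample(1:20, n, replace = TRUE),
      qend = sample(21:40, n, replace = TRUE),
      sstart = 1L, send = 1L,
      snt_start = starts, snt_end = starts + widths,
      score = 100, identity = 1, n_indels = 0L,
      qaln = "", saln = "")
    gap <- sample(c(100L, 5000L, 50000L), 1)
    loci <- merge_hits_to_loci(hits, max_gap_nt = gap, queries = q)
    for (str in c("+", "-")) {
      idx <- (hits$frame > 0) == (str == "+")
      if (!any(idx)) next
      cl <- cluster_intervals(hits$snt_start[idx], hits$snt_end[idx],
                              gap)
      expect_identical(sum(loci$strand == str), length(unique(cl)))
    }
    expect_true(all(vapply(
      split(loci$strand, loci$locus_id),
      function(s) length(unique(s)) == 1, logical(1))))
  }
})

test_that("locus merging records supported query exons", {
  q <- protein_query("q", random_protein(60),
                     exon_segments = list(c(1, 30), c(31, 60)))
  hits <- tibble::tibble(
    query_id = "q", subject_id = "chr1", frame = c(1L, 1L),
    qstart = c(2L, 35L), qend = c(28L, 58L), sstart = 1L, send = 1L,
    snt_start = c(1000L, 6000L), snt_end = c(1080L, 6070L),
    score = 100, identity = 1, n_indels = 0L, qaln = "", saln = "")
  loci <- merge_hits_to_loci(hits, max_gap_nt = 50000L, queries = q)
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$exon_support[[1]], c(1L, 2L))
  # opposite strands never merge
  hits$frame <- c(1L, -1L)
  loci2 <- merge_hits_to_loci(hits, max_gap_nt = 50000L, queries = q)
  expect_identical(nrow(loci2), 2L)
})
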