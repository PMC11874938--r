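# Synthetic genome, read and lesion generator.

test_that("planted genes translate exactly to their precursor and are
          deterministic for a fixed seed", {
  spec <- gene_spec("g1", "tryptopyrokinin", n_paracopies = 3,
                    core_peptide = "WFGPRL")
  g1 <- build_genome(10000, list(spec), seed = 1)
  g2 <- build_genome(10000, list(spec), seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)
  cds <- spliced_cds(g1, "g1")
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  expect_identical(tr, g1$features$precursor[1])
  expect_match(g1$sequence, "^[ACGT]+$")
  expect_identical(nchar(g1$sequence), 10000L)
  g3 <- build_genome(10000, list(spec), seed = 2)
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("multi-exon and minus-strand genes splice back to the
          precursor, with ordered disjoint exons", {
  for (spec in list(
    gene_spec("g", "RYamide", 5, "NFLGSRY", spacer_len = 3,
              n_exons = 3, intron_len = 120),
    gene_spec("g", "RYamide", 5, "NFLGSRY", spacer_len = 3,
              n_exons = 4, intron_len = 80, strand = "-"))) {
    g <- build_genome(8000, list(spec), seed = 9)
    ex <- g$features$exons[[1]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    expect_true(min(ex$start) >= 1 && max(ex$end) <= g$size_bp)
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(spliced_cds(g, "g"))))
    expect_identical(tr, g$features$precursor[1])
  }
})

test_that("genome construction rejects impossible placements", {
  spec <- gene_spec("big", "tryptopyrokinin", 20, "WFGPRL",
                    spacer_len = 10, n_exons = 5, intron_len = 5000)
  expect_error(build_genome(1000, list(spec), seed = 1),
               "exceeds the genome size")
  crowded <- lapply(1:8, function(i) {
    gene_spec(paste0("g", i), "tryptopyrokinin", 5, "WFGPRL",
              n_exons = 2, intron_len = 100)
  })
  expect_error(build_genome(1500, crowded, seed = 1))
})

test_that("precursor construction follows the cassette layout", {
  p <- plant_precursor_spec("tryptopyrokinin", 3, "WFGPRL")
  expect_identical(
    stringr::str_count(as.character(p), stringr::fixed("WFGPRLGKR")), 3L)
  p1 <- plant_precursor_spec("EFLamide", 1, "SLGSELL")
  expect_identical(
    stringr::str_count(as.character(p1), stringr::fixed("SLGSELLGKR")),
    1L)
  expect_error(plant_precursor_spec("x", 2, "AKRA"), "doublet")
  expect_error(plant_precursor_spec("x", 0, "WFGPRL"))
})

test_that("read simulation hits the requested coverage and stays within
          the source", {
  g <- build_genome(100000, list(), seed = 3)
  arc <- simulate_reads(g, coverage = 50, read_length = 150, seed = 4)
  expect_equal(nrow(arc$reads), 33333, tolerance = 1e-6)
  depth <- nrow(arc$reads) * 150 / 100000
  expect_lt(abs(depth - 50) / 50, 0.02)
  # every read is a verbatim (or reverse-complemented) substring
  idx <- sample(nrow(arc$reads), 50)
  for (i in idx) {
    r <- arc$reads[i, ]
    sub <- substr(g$sequence, r$start, r$start + 149)
    expected <- if (r$strand == "+") sub else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    expect_identical(r$seq, expected)
  }
  expect_true(all(nchar(arc$reads$seq) == 150))
})

test_that("zero coverage gives an empty archive and bad inputs error", {
  g <- build_genome(5000, list(), seed = 5)
  arc <- simulate_reads(g, coverage = 0, seed = 1)
  expect_identical(nrow(arc$reads), 0L)
  expect_identical(arc$n_spots, 0L)
  expect_error(simulate_reads("", coverage = 1, seed = 1), "zero-length")
  expect_error(simulate_reads(g, coverage = 1, error_rate = -0.1,
                              seed = 1), "error_rate")
  expect_error(simulate_reads("ACGT", coverage = 1, read_length = 150,
                              seed = 1), "read_length")
})

test_that("per-position depth is Poisson at the requested coverage", {
  g <- build_genome(100000, list(), seed = 6)
  n_start <- 100000 - 150 + 1
  for (cv in c(1, 5, 20)) {
    arc <- simulate_reads(g, coverage = cv, read_length = 150,
                          seed = 100 + cv)
    depth <- integer(100000)
    for (i in seq_len(nrow(arc$reads))) {
      s <- arc$reads$start[i]
      depth[s:(s + 149)] <- depth[s:(s + 149)] + 1L
    }
    # interior positions spaced beyond the read length, so depths are
    # independent draws from the marginal distribution
    d <- depth[seq(1000, 99000, by = 200)]
    rate <- nrow(arc$reads) * 150 / n_start
    expect_lt(abs(mean(depth[1000:99000]) - cv) / cv, 0.05)
    kmax <- max(d)
    obs <- tabulate(d + 1L, nbins = kmax + 1L)
    exp_p <- dpois(0:kmax, rate)
    exp_p[kmax + 1L] <- exp_p[kmax + 1L] + ppois(kmax, rate,
                                                 lower.tail = FALSE)
    pool <- exp_p * length(d) >= 5
    if (any(!pool)) {
      obs <- c(sum(obs[!pool]), obs[pool])
      exp_p <- c(sum(exp_p[!pool]), exp_p[pool])
    }
    suppressWarnings(test <- chisq.test(obs, p = exp_p / sum(exp_p)))
    expect_gt(test$p.value, 0.01)
  }
})

test_that("paired simulation yields mate pairs from one fragment,
          counted as one spot", {
  g <- build_genome(20000, list(), seed = 7)
  arc <- simulate_reads(g, coverage = 2, read_length = 100,
                        paired = TRUE, insert_size = 300, seed = 8)
  expect_true(arc$paired)
  expect_identical(length(unique(arc$reads$spot_id)),
                   nrow(arc$reads) %/% 2L)
  one <- arc$reads[arc$reads$spot_id == arc$reads$spot_id[1], ]
  expect_identical(nrow(one), 2L)
  expect_setequal(one$mate, c(1L, 2L))
})

test_that("transcript pool sampling follows the abundances", {
  g <- build_genome(6000, list(
    gene_spec("hi", "tryptopyrokinin", 8, "WFGPRL", spacer_len = 3),
    gene_spec("lo", "RYamide", 8, "NFLGSRY", spacer_len = 3)),
    seed = 10)
  pool <- transcript_pool(g, abundances = c(1000, 10))
  arc <- simulate_reads(pool, n_reads = 3000, read_length = 100,
                        tissue = "thorax", seed = 11)
  counts <- table(arc$reads$source_id)
  # binomial 99% interval for the high-abundance transcript
  p <- 1000 / 1010
  ci <- qbinom(c(0.005, 0.995), 3000, p)
  expect_gte(counts[["hi"]], ci[1])
  expect_lte(counts[["hi"]], ci[2])
  expect_identical(arc$tissue, "thorax")
})

test_that("sequencing errors are substitutions at the requested rate", {
  g <- build_genome(50000, list(), seed = 12)
  arc <- simulate_reads(g, coverage = 3, read_length = 150,
                        error_rate = 0.02, seed = 13)
  mism <- 0L; total <- 0L
  for (i in seq_len(nrow(arc$reads))) {
    r <- arc$reads[i, ]
    sub <- substr(g$sequence, r$start, r$start + 149)
    if (r$strand == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_identical(nchar(r$seq), nchar(sub))
    mism <- mism + sum(strsplit(r$seq, "")[[1]] != strsplit(sub, "")[[1]])
    total <- total + 150L
  }
  expect_gt(mism / total, 0.01)
  expect_lt(mism / total, 0.03)
})

test_that("lesion injection records coordinates and changes the
          translation; zero lesions leave the gene untouched", {
  spec <- gene_spec("g", "tryptopyrokinin", 8, "WFGPRL", spacer_len = 4,
                    n_exons = 2, intron_len = 150)
  g <- build_genome(10000, list(spec), seed = 20)
  intact <- spliced_cds(g, "g")
  g0 <- inject_lesions(g, "g", n_frameshifts = 0, n_stops = 0, seed = 1)
  expect_identical(g0, g)
  g5 <- inject_lesions(g, "g", n_frameshifts = 5, n_stops = 1, seed = 21)
  les <- g5$features$lesions[[1]]
  expect_identical(nrow(les), 6L)
  expect_true(all(diff(les$coding_pos) > 0))
  expect_setequal(unique(les$type),
                  c("frameshift_ins", "frameshift_del", "premature_stop"))
  mut <- spliced_cds(g5, "g")
  net <- sum(les$type == "frameshift_ins") -
    sum(les$type == "frameshift_del")
  expect_identical(nchar(mut) - nchar(intact), as.integer(net))
  tr_mut <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mut, 1, 3 * (nchar(mut) %/% 3))),
    if.fuzzy.codon = "X")))
  expect_false(identical(tr_mut, g$features$precursor[1]))
  # sequence upstream of the first lesioned codon is untouched
  first_codon <- min(les$coding_pos - (les$coding_pos - 1L) %% 3L)
  expect_identical(substr(mut, 1, first_codon - 1),
                   substr(intact, 1, first_codon - 1))
  expect_error(inject_lesions(g, "g", n_frameshifts = 50, seed = 1),
               "too short")
})

test_that("FASTA/FASTQ/GFF3 outputs are byte-identical across runs and
          round-trip", {
  spec <- gene_spec("g", "tryptopyrokinin", 3, "WFGPRL")
  g <- build_genome(5000, list(spec), seed = 30)
  arc <- simulate_reads(g, coverage = 2, seed = 31)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fastq"); f2 <- file.path(d, "b.fastq")
  write_reads_fastq(arc, f1)
  write_reads_fastq(simulate_reads(g, coverage = 2, seed = 31), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_reads_fastq(f1)
  expect_identical(back$reads$seq, arc$reads$seq)
  expect_identical(back$reads$spot_id, arc$reads$spot_id)
  fa <- file.path(d, "g.fasta")
  write_genome_fasta(g, fa)
  re <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(re[[1]]), g$sequence)
  gff <- file.path(d, "g.gff3")
  write_truth_gff3(g, gff)
  lines <- readLines(gff)
  expect_identical(lines[1], "##gff-version 3")
  expect_identical(sum(grepl("\tgene\t", lines)), 1L)
  expect_identical(sum(grepl("\tCDS\t", lines)),
                   nrow(g$features$exons[[1]]))
})
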