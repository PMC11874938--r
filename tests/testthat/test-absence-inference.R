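# Coverage model, absence probability, presence calls, expression tables.

test_that("the absence probability follows the closed form", {
  expect_identical(absence_probability(0), 1)
  expect_equal(absence_probability(log(2)), 0.5)
  p50 <- absence_probability(50)
  expect_equal(p50, exp(-50))
  expect_lt(p50, 1e-6)
  # with a model, lambda drives the bound
  m <- coverage_model(genome_size = 1e6, read_count = 10000,
                      read_length = 150, target_length = 300,
                      min_overlap = 45)
  expect_equal(absence_probability(m), exp(-m$lambda))
  expect_equal(absence_probability(m, 0.5), exp(-m$lambda * 0.5))
  expect_error(absence_probability(m, 0))
})

test_that("lambda uses the overlap-aware window and dominates the
          coverage for long targets", {
  m <- coverage_model(genome_size = 1e5, read_count = 2000,
                      read_length = 150, target_length = 300,
                      min_overlap = 45)
  expect_equal(m$coverage, 2000 * 150 / 1e5)
  expect_equal(m$lambda, 2000 * (150 + 300 - 90 + 1) / 1e5)
  expect_gt(m$lambda, m$coverage)
  # degenerate target at the overlap bound: lambda collapses to ~c
  m2 <- coverage_model(1e5, 2000, 150, target_length = 89,
                       min_overlap = 45)
  expect_equal(m2$lambda, 2000 * 150 / 1e5)
})

test_that("p_abs is strictly decreasing in coverage and in target
          length", {
  cs <- seq(0, 60, by = 5)
  ps <- vapply(cs, absence_probability, numeric(1))
  expect_true(all(diff(ps) < 0))
  lts <- seq(100, 1000, by = 100)
  ps2 <- vapply(lts, function(lt) {
    absence_probability(coverage_model(1e5, 1000, 150, lt, 45))
  }, numeric(1))
  expect_true(all(diff(ps2) < 0))
})

test_that("simulated miss fractions agree with exp(-lambda)", {
  cal <- calibrate_by_simulation(c(0.5, 1, 2), replicates = 400,
                                 seed = 42)
  expect_true(all(cal$observed >= cal$ci_lo &
                    cal$observed <= cal$ci_hi))
  cal0 <- calibrate_by_simulation(0, replicates = 100, seed = 1)
  expect_identical(cal0$observed, 1)
  cal50 <- calibrate_by_simulation(50, replicates = 200, seed = 2)
  expect_identical(cal50$observed, 0)
})

test_that("presence calls follow the evidence rules", {
  m50 <- coverage_model(4000, round(50 * 4000 / 150), 150,
                        target_length = 300)
  good_hits <- tibble::tibble(
    query_id = "q", subject_id = "s", frame = 1L,
    qstart = c(1L, 60L), qend = c(50L, 110L), sstart = 1L, send = 1L,
    snt_start = c(100L, 5000L), snt_end = c(250L, 5150L),
    score = 200, identity = c(0.85, 0.9), n_indels = 0L,
    qaln = "", saln = "")
  q <- protein_query("q", random_protein(110),
                     exon_segments = list(c(1L, 55L), c(56L, 110L)))
  call <- call_presence("sp", "g", spots = 12L, hits = good_hits,
                        model = m50, queries = q)
  expect_identical(call$status, "present")
  # an indel in a supporting hit blocks the present call
  bad <- good_hits
  bad$n_indels <- c(1L, 0L)
  call2 <- call_presence("sp", "g", spots = 12L, hits = bad,
                         model = m50, queries = q)
  expect_identical(call2$status, "indeterminate")
  # a single supported exon is insufficient
  call3 <- call_presence("sp", "g", spots = 12L,
                         hits = good_hits[1, ], model = m50,
                         queries = q)
  expect_identical(call3$status, "indeterminate")
  # low identity hits are not supporting evidence
  weak <- good_hits
  weak$identity <- 0.5
  call4 <- call_presence("sp", "g", spots = 12L, hits = weak,
                         model = m50, queries = q)
  expect_identical(call4$status, "indeterminate")
})

test_that("zero spots are absent only at stringent coverage in PCR-free
          archives", {
  m50 <- coverage_model(4000, round(50 * 4000 / 150), 150)
  call <- call_presence("sp", "g", spots = 0L, model = m50)
  expect_identical(call$status, "absent")
  expect_lte(call$p_abs, 1e-6)
  # low coverage: the gene may simply have escaped detection
  m2 <- coverage_model(4000, round(2 * 4000 / 150), 150,
                       target_length = 150)
  call2 <- call_presence("sp", "g", spots = 0L, model = m2)
  expect_identical(call2$status, "indeterminate")
  expect_match(call2$notes, "escaped detection")
  # PCR-amplified archives never support absence
  call3 <- call_presence("sp", "g", spots = 0L, model = m50,
                         pcr_free = FALSE)
  expect_identical(call3$status, "indeterminate")
  expect_match(call3$notes, "PCR-amplified")
})

test_that("no input combination yields absent with nonzero spots", {
  m <- coverage_model(4000, 10000, 150)
  set.seed(610)
  for (i in 1:30) {
    call <- suppressWarnings(call_presence(
      "sp", "g", spots = sample(0:20, 1),
      model = if (runif(1) < 0.5) m else NULL,
      pcr_free = sample(c(TRUE, FALSE), 1)))
    if (call$status == "absent") expect_identical(call$n_spots, 0L)
  }
})

test_that("a pseudogene lesion report dominates, and conflicts warn", {
  p <- plant_precursor_spec("tryptopyrokinin", 8, "WFGPRL", 4)
  g <- build_genome(6000, list(gene_spec(
    "g", "tryptopyrokinin", precursor = as.character(p))), seed = 620)
  g_mut <- inject_lesions(g, "g", n_frameshifts = 3, seed = 621)
  aln <- align_locus_to_reference(spliced_cds(g_mut, "g"),
                                  as.character(p))
  lr <- call_gene_status(aln, family = "tryptopyrokinin")
  m <- coverage_model(6000, 2000, 150)
  call <- call_presence("sp", "g", spots = 40L, lesions = lr, model = m)
  expect_identical(call$status, "pseudogene")
  expect_warning(
    call2 <- call_presence("sp", "g", spots = 0L, lesions = lr,
                           model = m),
    "zero spots")
  expect_identical(call2$status, "indeterminate")
})

test_that("expression tables count spots per tissue with intact row
          totals", {
  set.seed(629)
  g <- build_genome(8000, list(
    gene_spec("tpk", "tryptopyrokinin", 8, "WFGPRL", spacer_len = 3),
    gene_spec("rec", "receptor", precursor = random_protein(100))),
    seed = 629)
  pool_thorax <- transcript_pool(g, abundances = c(100, 1))
  pool_head <- transcript_pool(g, abundances = c(0, 1))
  archives <- list(
    thorax = simulate_reads(pool_thorax, n_reads = 400,
                            read_length = 150, tissue = "thorax",
                            seed = 630),
    head = simulate_reads(pool_head, n_reads = 400, read_length = 150,
                          tissue = "head", seed = 631))
  queries <- dplyr::bind_rows(
    protein_query("tpk", g$features$precursor[1]),
    protein_query("rec", g$features$precursor[2]))
  et <- quantify_expression(queries, archives, per_million = TRUE)
  expect_s3_class(et, "expression_table")
  expect_identical(et$tissue, c("thorax", "head"))
  # counts never exceed the archive totals
  expect_true(all(et$tpk <= et$total_spots))
  expect_true(all(et$rec <= et$total_spots))
  # the thorax-only transcript shows up in the thorax row
  expect_gt(et$tpk[et$tissue == "thorax"], 100)
  expect_identical(et$tpk[et$tissue == "head"], 0L)
  # abundances 100:1 reproduce within a binomial 99% interval
  n_tpk <- et$tpk[et$tissue == "thorax"]
  total <- n_tpk + et$rec[et$tissue == "thorax"]
  ci <- qbinom(c(0.005, 0.995), total, 100 / 101)
  expect_gte(n_tpk, ci[1])
  expect_lte(n_tpk, ci[2])
  # empty archive row is all zero
  g0 <- build_genome(2000, list(), seed = 640)
  empty <- simulate_reads(g0, coverage = 0, tissue = "leg", seed = 641)
  et2 <- quantify_expression(queries, list(leg = empty))
  expect_identical(et2$tpk, 0L)
  expect_identical(et2$total_spots, 0L)
})
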