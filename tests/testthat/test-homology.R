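test_that("local_align scores and reports self-alignments correctly", {
  h <- local_align("ACGT", "ACGT")
  expect_equal(h$score, 8)  # 4 matches at +2, hand-scored DP
  expect_equal(h$pct_identity, 100)
  expect_equal(h$aln_len, 4L)

  s <- random_dna(100)
  h2 <- local_align(s, s)
  expect_equal(h2$pct_identity, 100)
  expect_equal(h2$aln_len, 100L)
  expect_equal(h2$score, 200)
  # Karlin-Altschul: E = K m n exp(-lambda S)
  expect_equal(h2$evalue, 0.13 * 100 * 100 * exp(-0.32 * 200))

  expect_error(local_align("", "ACGT"), "empty")
})

test_that("reverse-complement queries are recovered with both_strands", {
  s <- random_dna(80)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h <- local_align(rc, s, both_strands = TRUE)
  expect_equal(h$strand, "-")
  expect_equal(h$pct_identity, 100)
})

test_that("local_align matches the exhaustive DP oracle on short pairs", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      q <- random_dna(sample(3:12, 1))
      s <- random_dna(sample(3:12, 1))
      expect_equal(local_align(q, s)$score, naive_sw(q, s),
                   info = paste(q, s))
    }
  })
})

test_that("functional annotation applies the 60 % / 1e-5 / 1.2x rules", {
  cfg <- pipeline_config()
  orfs <- tibble::tibble(orf_id = "o1", contig_id = "c", start = 1L,
                         end = 903L, strand = "+",
                         protein = strrep("M", 300),
                         ec_number = NA_character_, product = NA_character_)
  refs <- tibble::tibble(id = c("big", "half", "good", "good2"),
                         length = c(400L, 330L, 330L, 330L),
                         ec_number = c(NA, NA, "4.2.1.17", "1.1.1.1"))
  mk <- function(sid, aln, ev, bits = 200) tibble::tibble(
    query_id = "o1", subject_id = sid, pct_identity = 80,
    aln_len = aln, mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = aln,
    s_start = 1L, s_end = aln, evalue = ev, bitscore = bits)

  # reference 400 aa > 1.2 * 300 -> rejected despite best e-value
  # 150/300 = 50 % aligned -> rejected
  hits <- dplyr::bind_rows(mk("big", 250L, 1e-80),
                           mk("half", 150L, 1e-70),
                           mk("good", 210L, 1e-6))
  ann <- annotate_functions(orfs, hits, refs, cfg)
  expect_equal(ann$reference_id, "good")
  expect_equal(ann$ec_number, "4.2.1.17")
  expect_equal(ann$pct_query_aligned, 0.7)

  # e-value ties break by bitscore then subject id
  hits2 <- dplyr::bind_rows(mk("good", 210L, 1e-6, bits = 100),
                            mk("good2", 210L, 1e-6, bits = 150))
  expect_equal(annotate_functions(orfs, hits2, refs, cfg)$reference_id,
               "good2")

  # no passing hit -> no annotation
  expect_equal(nrow(annotate_functions(orfs, mk("half", 100L, 1e-3), refs,
                                       cfg)), 0L)
})

test_that("equal-e-value out-of-class screen follows the printed rules", {
  mk <- function(qid, cls, ev, aln) tibble::tibble(
    query_id = qid, subject_id = paste0(cls, ev), pct_identity = 95,
    aln_len = aln, mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = aln,
    s_start = 1L, s_end = aln, evalue = ev, bitscore = 100,
    subject_class = cls, query_len = 100L)
  home <- "Betaproteobacteria"
  # equal best e-value out-of-class at 65 % coverage -> flagged
  h1 <- dplyr::bind_rows(mk("g1", home, 1e-80, 90L),
                         mk("g1", "Bacilli", 1e-80, 65L))
  expect_equal(screen_equal_evalue_out_of_class(h1, home), "g1")
  # not the same e-value -> not flagged
  h2 <- dplyr::bind_rows(mk("g2", home, 1e-80, 90L),
                         mk("g2", "Bacilli", 1e-79, 65L))
  expect_equal(length(screen_equal_evalue_out_of_class(h2, home)), 0L)
  # equal e-value but only 50 % coverage -> not flagged
  h3 <- dplyr::bind_rows(mk("g3", home, 1e-80, 90L),
                         mk("g3", "Bacilli", 1e-80, 50L))
  expect_equal(length(screen_equal_evalue_out_of_class(h3, home)), 0L)
})

test_that("MGE filter demands 1e-30, different class, and 60 % on both sides", {
  cfg <- pipeline_config()
  classes <- tibble::tibble(orf_id = "o1", class = "Gammaproteobacteria")
  mk <- function(ev, aln, scls, qlen = 300L, slen = 500L) tibble::tibble(
    query_id = "o1", subject_id = "m1", pct_identity = 90, aln_len = aln,
    mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = aln, s_start = 1L,
    s_end = aln, evalue = ev, bitscore = 100, subject_class = scls,
    query_len = qlen, subject_len = slen)

  # 200/300 = 67 % of query but 200/500 = 40 % of subject -> rejected
  expect_equal(length(mge_homology_filter("o1", mk(1e-40, 200L, "Bacilli"),
                                          classes, cfg)), 0L)
  # e-value 1e-29 misses the 1e-30 bar
  expect_equal(length(mge_homology_filter(
    "o1", mk(1e-29, 280L, "Bacilli", slen = 300L), classes, cfg)), 0L)
  # same-class MGE hit rejected even when everything else passes
  expect_equal(length(mge_homology_filter(
    "o1", mk(1e-40, 280L, "Gammaproteobacteria", slen = 300L),
    classes, cfg)), 0L)
  # all three rules satisfied -> kept
  expect_equal(mge_homology_filter(
    "o1", mk(1e-40, 280L, "Bacilli", slen = 300L), classes, cfg), "o1")
  # hit lacking a subject length is skipped with a warning
  expect_warning(
    out <- mge_homology_filter(
      "o1", mk(1e-40, 280L, "Bacilli", slen = NA_integer_), classes, cfg),
    "subject length")
  expect_equal(length(out), 0L)
})

test_that("filters are monotone in their thresholds", {
  withr::with_seed(5, {
    hits <- tibble::tibble(
      query_id = sprintf("o%02d", 1:40), subject_id = "m",
      pct_identity = runif(40, 50, 100),
      aln_len = sample(100:300, 40, replace = TRUE),
      mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = 1L, s_start = 1L,
      s_end = 1L, evalue = 10^(-runif(40, 0, 60)), bitscore = 100,
      subject_class = sample(c("A1", "B2"), 40, replace = TRUE),
      query_len = 300L, subject_len = 300L)
  })
  classes <- tibble::tibble(orf_id = sprintf("o%02d", 1:40), class = "A1")
  loose <- pipeline_config(mge_evalue = 1e-10, mge_coverage = 0.4)
  tight <- pipeline_config(mge_evalue = 1e-30, mge_coverage = 0.7)
  surv_loose <- mge_homology_filter(classes$orf_id, hits, classes, loose)
  surv_tight <- mge_homology_filter(classes$orf_id, hits, classes, tight)
  expect_true(all(surv_tight %in% surv_loose))
})

test_that("read mapping keeps >= 70 % coverage at e <= 1e-30", {
  withr::with_seed(21, ctg <- random_dna(3000))
  contigs <- tibble::tibble(id = "c1", sequence = ctg, community = "SYN",
                            length = 3000L)
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  mismatch_tail <- function(from, len) {
    chars <- strsplit(substr(ctg, from, from + len - 1L), "")[[1]]
    paste(flip[chars], collapse = "")
  }
  # read 1: full-length perfect match (retained, e ~ 0)
  # read 2: 175/250 = 70 % matches, the rest mismatches at every base
  # read 3: 172/250 = 68.8 % matches -> below the coverage bar
  reads <- tibble::tibble(
    id = c("r_full", "r_70", "r_69"),
    sequence = c(substr(ctg, 501, 750),
                 paste0(substr(ctg, 1001, 1175), mismatch_tail(1176, 75)),
                 paste0(substr(ctg, 2001, 2172), mismatch_tail(2173, 78))))
  mapped <- map_reads_to_contigs(reads, contigs)
  expect_true("r_full" %in% mapped$read_id)
  expect_true("r_70" %in% mapped$read_id)
  expect_false("r_69" %in% mapped$read_id)
  expect_equal(mapped$c_start[mapped$read_id == "r_full"], 501L)

  # a short perfect match passes coverage but fails the e-value bar
  short <- tibble::tibble(id = "r_short", sequence = substr(ctg, 101, 180))
  expect_equal(nrow(map_reads_to_contigs(short, contigs)), 0L)
})

test_that("read span classes are exclusive, exhaustive, and as published", {
  orfs <- tibble::tibble(
    orf_id = c("focal", "nbr"), contig_id = "c1",
    start = c(100L, 450L), end = c(400L, 700L), strand = "+",
    protein = "M", ec_number = NA_character_, product = NA_character_)
  mk <- function(id, a, b) tibble::tibble(
    read_id = id, contig_id = "c1", c_start = a, c_end = b, strand = "+",
    read_coverage = 1, evalue = 0)
  mapped <- dplyr::bind_rows(
    mk("into", 50L, 450L),       # covers ORF and 1 nt of the neighbour
    mk("full", 90L, 410L),       # covers the whole ORF, intergenic ends
    mk("part", 150L, 350L),      # strictly inside the ORF
    mk("ibound", 50L, 300L),     # starts in intergenic sequence
    mk("away", 800L, 900L))      # no overlap: dropped
  spans <- classify_read_spans(mapped, orfs, "focal")
  got <- setNames(spans$span_class, spans$read_id)
  expect_equal(unname(got["into"]), "into_neighbor")
  expect_equal(unname(got["full"]), "full_orf")
  expect_equal(unname(got["part"]), "partial")
  expect_equal(unname(got["ibound"]), "intergenic_bounded")
  expect_false("away" %in% spans$read_id)
  expect_equal(nrow(spans), 4L)  # one class per overlapping read
})
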