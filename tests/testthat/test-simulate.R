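test_that("class models are seeded, separated, and reproducible", {
  m1 <- sample_class_models(2, k = 4, divergence = 0.12, seed = 3)
  m2 <- sample_class_models(2, k = 4, divergence = 0.12, seed = 3)
  expect_equal(m1[[1]]$log_probs, m2[[1]]$log_probs)

  js <- attr(m1, "js_divergence")
  expect_gte(js[1, 2], 0.1)  # well-separated base compositions

  m0 <- sample_class_models(2, k = 2, divergence = 0, seed = 3)
  expect_equal(m0[[1]]$base_probs, m0[[2]]$base_probs)

  expect_error(sample_class_models(1), "at least 2")
})

test_that("generated contigs carry proper reading frames", {
  models <- sample_class_models(2, k = 4, seed = 9)
  layout <- tibble::tibble(start = c(101L, 501L, 1001L),
                           end = c(400L, 899L, 1300L),
                           strand = c("+", "-", "+"))
  g <- generate_contig(models[[1]], 1500L, layout, seed = 4,
                       contig_id = "ctgA")
  expect_equal(nrow(g$orfs), 3L)
  expect_equal(nchar(g$contig$sequence), 1500L)
  for (i in 1:3) {
    coding <- lgtscout:::orf_coding_sequence(g$contig$sequence, g$orfs[i, ])
    expect_equal(substr(coding, 1, 3), "ATG")
    expect_true(substr(coding, nchar(coding) - 2, nchar(coding)) %in%
                  c("TAA", "TAG", "TGA"))
    aa <- g$orfs$protein[i]
    expect_false(grepl("\\*", aa))  # no internal stops
    expect_equal(nchar(aa), (g$orfs$end[i] - g$orfs$start[i] + 1) / 3 - 1)
  }

  # regeneration is bit-identical under the same seed
  g2 <- generate_contig(models[[1]], 1500L, layout, seed = 4,
                        contig_id = "ctgA")
  expect_identical(g$contig$sequence, g2$contig$sequence)

  # a 999-nt contig is valid here but removed by the length filter
  short <- generate_contig(models[[1]], 999L,
                           tibble::tibble(start = 101L, end = 400L,
                                          strand = "+"), seed = 1)
  expect_equal(nrow(filter_contigs_by_length(short$contig, 1000)), 0L)

  expect_error(generate_contig(models[[1]], 1500L,
                               tibble::tibble(start = c(101L, 300L),
                                              end = c(400L, 600L),
                                              strand = "+"), seed = 1),
               "overlapping")
})

test_that("planting a transfer rewrites the slot and emits truth + MGE", {
  models <- sample_class_models(2, k = 4, seed = 10)
  layout <- tibble::tibble(start = c(101L, 501L), end = c(400L, 800L),
                           strand = "+")
  g <- generate_contig(models[[1]], 1200L, layout, seed = 2,
                       contig_id = "ctgB")
  planted <- plant_lgt(g$contig, g$orfs, models[[2]], "ctgB_orf01",
                       recipient_class = models[[1]]$class_label,
                       seed = 6, ec_number = "4.2.1.17",
                       mobility_neighbor = TRUE)
  ev <- planted$event
  expect_equal(ev$donor_class, models[[2]]$class_label)
  expect_equal(ev$recipient_class, models[[1]]$class_label)
  expect_true(ev$donor_class != ev$recipient_class)
  expect_equal(ev$ec_number, "4.2.1.17")

  # the planted ORF's coding sequence changed; the rest did not
  orig <- lgtscout:::orf_coding_sequence(g$contig$sequence, g$orfs[1, ])
  new <- lgtscout:::orf_coding_sequence(planted$contig$sequence,
                                        planted$orfs[1, ])
  expect_false(identical(orig, new))
  expect_identical(substr(g$contig$sequence, 801, 1200),
                   substr(planted$contig$sequence, 801, 1200))

  # the MGE homolog passes the published filter by construction
  h <- local_align(new, planted$mge$sequence)
  hits <- tibble::tibble(
    query_id = ev$orf_id, subject_id = planted$mge$id,
    pct_identity = h$pct_identity, aln_len = h$aln_len, mismatch = 0L,
    gapopen = 0L, q_start = h$q_start, q_end = h$q_end, s_start = h$s_start,
    s_end = h$s_end, evalue = h$evalue, bitscore = h$bitscore,
    subject_class = planted$mge$class, query_len = nchar(new),
    subject_len = nchar(planted$mge$sequence))
  survivors <- mge_homology_filter(
    ev$orf_id, hits,
    tibble::tibble(orf_id = ev$orf_id, class = ev$donor_class))
  expect_equal(survivors, ev$orf_id)

  # the transposase neighbour is found by the mobility scan
  mob <- scan_mobility_genes(planted$orfs)
  expect_true(ev$contig_id %in% mob$contig_id)

  expect_error(plant_lgt(g$contig, g$orfs, models[[2]], "nope",
                         recipient_class = "B", seed = 1),
               "does not match an ORF")
})

test_that("reads are exact substrings at the requested depth", {
  models <- sample_class_models(2, k = 4, seed = 12)
  g <- generate_contig(models[[1]], 1000L,
                       tibble::tibble(start = 101L, end = 400L,
                                      strand = "+"), seed = 3)
  reads <- generate_reads(g$contig, read_length = 100L, depth = 10, seed = 8)
  expect_equal(nrow(reads), 100L)  # 1000 * 10 / 100
  expect_true(all(nchar(reads$sequence) == 100L))
  # error-free reads match their source exactly (on the recorded strand)
  for (i in sample(nrow(reads), 10)) {
    sub <- substr(g$contig$sequence, reads$start[i], reads$end[i])
    if (reads$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_identical(reads$sequence[i], sub)
  }
  # reads crossing the ORF boundary exist at this depth
  expect_true(any(reads$start < 101 & reads$end >= 101))

  expect_identical(generate_reads(g$contig, 100L, 10, seed = 8), reads)
  expect_error(generate_reads(g$contig, 2000L, 10), "exceeds")

  noisy <- generate_reads(g$contig, 100L, 2, error_rate = 0.1, seed = 8)
  mism <- vapply(seq_len(nrow(noisy)), function(i) {
    sub <- substr(g$contig$sequence, noisy$start[i], noisy$end[i])
    if (noisy$strand[i] == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    sum(strsplit(noisy$sequence[i], "")[[1]] != strsplit(sub, "")[[1]])
  }, numeric(1))
  expect_gt(mean(mism), 0)
})

test_that("protein families graft community leaves into the donor clade", {
  fam <- simulate_protein_family("f1", "B", "G", graft = TRUE,
                                 graft_distance = 0.1, seed = 44)
  expect_equal(fam$grafted_id, "f1_sq1")
  f <- fam$family
  expect_equal(sum(f$origin == "reference"), 7L)  # 3 home + 4 donor refs
  # grafted leaf is close to a donor reference, far from its home clade
  chars <- strsplit(f$sequence, "")
  names(chars) <- f$id
  p <- function(a, b) mean(chars[[a]] != chars[[b]])
  expect_lt(p("f1_sq1", "f1_refD1"), 0.2)
  expect_gt(p("f1_sq1", "f1_refH1"), 0.3)

  # without grafting the community leaf stays home
  fam0 <- simulate_protein_family("f1", "B", "G", graft = FALSE, seed = 44)
  expect_true(is.na(fam0$grafted_id))
})

test_that("the reference panel honours transfer_fraction and the seed", {
  panel <- generate_reference_panel_and_trees(n_families = 10,
                                              transfer_fraction = 0.2,
                                              seed = 5)
  expect_equal(length(panel$trees), 10L)
  expect_equal(sum(!is.na(panel$truth$grafted_id)), 2L)
  panel2 <- generate_reference_panel_and_trees(n_families = 10,
                                               transfer_fraction = 0.2,
                                               seed = 5)
  expect_identical(panel$families, panel2$families)

  none <- generate_reference_panel_and_trees(n_families = 5,
                                             transfer_fraction = 0, seed = 5)
  expect_true(all(is.na(none$truth$grafted_id)))

  expect_error(generate_reference_panel_and_trees(transfer_fraction = 1.2),
               "transfer_fraction")
})

test_that("synthetic family hit tables reflect true identities", {
  fam <- simulate_protein_family("f2", "B", "G", seed = 21)$family
  hits <- generate_family_hits(fam)
  expect_equal(nrow(hits), nrow(fam) * (nrow(fam) - 1L))
  i <- which(hits$query_id == "f2_refH1" & hits$subject_id == "f2_refH2")
  chars <- strsplit(fam$sequence, "")
  names(chars) <- fam$id
  expect_equal(hits$pct_identity[i],
               100 * mean(chars[["f2_refH1"]] == chars[["f2_refH2"]]))
  # within-clade pairs qualify for network edges; cross-clade pairs do not
  g <- build_homology_graph(hits)
  comp <- connected_components(g, nodes = fam$id)
  home <- fam$id[fam$class == "B"]
  donor <- fam$id[fam$class == "G"]
  expect_equal(length(unique(comp$cluster[comp$id %in% home])), 1L)
  expect_false(comp$cluster[comp$id == home[1]] ==
                 comp$cluster[comp$id == donor[1]])
})
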