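test_that("network edges honour the 70 % / 60 % / 1e-5 admission (inclusive)", {
  hits <- dplyr::bind_rows(
    edge_hit("a", "b", 70.0, 0.60, 1e-5),   # exactly at all three bounds
    edge_hit("a", "c", 69.9, 0.90, 1e-20),  # identity below bound
    edge_hit("a", "d", 90.0, 0.59, 1e-20),  # coverage below bound
    edge_hit("a", "e", 90.0, 0.90, 2e-5))   # e-value above bound
  g <- build_homology_graph(hits)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$id1, g$id2), c("a", "b"))
})

test_that("duplicate qualifying hits collapse to one edge with the best e", {
  hits <- dplyr::bind_rows(edge_hit("a", "b", 80, 0.9, 1e-10),
                           edge_hit("b", "a", 85, 0.9, 1e-30),
                           edge_hit("a", "a", 100, 1.0, 0))  # self: ignored
  g <- build_homology_graph(hits)
  expect_equal(nrow(g), 1L)
  expect_equal(g$evalue, 1e-30)
})

test_that("connected components partition the node set", {
  g <- tibble::tibble(id1 = c("a", "b"), id2 = c("b", "c"),
                      pct_identity = 80, coverage = 1, evalue = 1e-10)
  comp <- connected_components(g, nodes = c("a", "b", "c", "d", "e"))
  expect_equal(sort(comp$id), c("a", "b", "c", "d", "e"))
  expect_equal(comp$cluster[comp$id %in% c("a", "b", "c")], rep(1L, 3))
  expect_equal(length(unique(comp$cluster)), 3L)  # abc + two singletons
  expect_equal(comp$cluster_size[comp$id == "d"], 1L)

  expect_equal(nrow(connected_components(g[0, ])), 0L)
})

test_that("components match an independent BFS on random graphs", {
  withr::with_seed(42, {
    for (rep in 1:100) {
      nodes <- paste0("n", 1:8)
      pairs <- t(utils::combn(nodes, 2))
      pick <- runif(nrow(pairs)) < 0.2
      edges <- tibble::tibble(id1 = pairs[pick, 1], id2 = pairs[pick, 2],
                              pct_identity = 80, coverage = 1,
                              evalue = 1e-10)
      comp <- connected_components(edges, nodes = nodes)
      oracle <- bfs_components(edges, nodes)
      got <- setNames(comp$cluster, comp$id)[nodes]
      # same partition: co-membership must agree pairwise
      same_got <- outer(got, got, "==")
      same_orc <- outer(oracle, oracle, "==")
      expect_true(all(same_got == same_orc))
    }
  })
})

test_that("tree building handles identical, additive, and tiny inputs", {
  same <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep(strrep("MKV", 20), 3))
  star <- build_tree(same, bootstrap = 0)
  expect_equal(ape::Ntip(star), 3L)
  expect_true(all(star$edge.length == 0))

  expect_error(build_tree(same[1:2, ]), "at least 3")
  expect_error(build_tree(tibble::tibble(id = c("a", "b", "c"),
                                         sequence = c("MK", "MKV", "MKVL"))),
               "equal-length")

  # two well-separated pairs: NJ recovers the generating topology
  fam <- simulate_protein_family("f", "B", "G", n_community = 1L,
                                 n_ref_home = 1L, n_ref_donor = 2L,
                                 clade_sep = 0.8, tip_depth = 0.05,
                                 seq_length = 200L, seed = 5)$family
  tr <- build_tree(fam, bootstrap = 20, seed = 5)
  # the two donor references must be sisters
  pd <- patristic_distances(tr)
  expect_lt(pd["f_refD1", "f_refD2"], min(pd["f_refD1", "f_sq1"],
                                          pd["f_refD1", "f_refH1"]))
})

test_that("external Newick trees give identical downstream calls", {
  fam <- simulate_protein_family("f", "B", "G", seed = 8)$family
  tr <- build_tree(fam, bootstrap = 10, seed = 8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  leaf_info <- fam[, c("id", "class", "origin")]
  expect_equal(tibble::as_tibble(call_incongruent_leaves(tr2, leaf_info)),
               tibble::as_tibble(call_incongruent_leaves(tr, leaf_info)),
               tolerance = 1e-8)
})

test_that("patristic distances equal hand-computed path sums", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,C:0.3);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 0.3)
  expect_equal(d["A", "C"], 0.45)
  expect_equal(d["B", "C"], 0.55)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
})

test_that("patristic distances match the naive path-walk oracle", {
  withr::with_seed(31, {
    for (rep in 1:30) {
      tr <- ape::rtree(sample(4:10, 1))
      expect_equal(patristic_distances(tr), patristic_oracle(tr),
                   tolerance = 1e-12)
    }
  })
})

test_that("patristic distances satisfy the four-point condition", {
  withr::with_seed(13, tr <- ape::rtree(8))
  d <- patristic_distances(tr)
  tips <- tr$tip.label
  combos <- utils::combn(tips, 4)
  for (i in seq_len(ncol(combos))) {
    q <- combos[, i]
    sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                   d[q[1], q[3]] + d[q[2], q[4]],
                   d[q[1], q[4]] + d[q[2], q[3]]))
    expect_lt(sums[3] - sums[2], 1e-9)
  }
})

test_that("supported subtrees are extracted below the leaf cap", {
  clade <- function(prefix, n, support) {
    paste0("(", paste0(prefix, seq_len(n), ":0.1", collapse = ","),
           ")", support, ":0.1")
  }
  # 300 leaves; one 150-leaf clade at 90 % support, the rest at 50 %
  txt <- paste0("(", clade("a", 150, 90), ",", clade("b", 150, 50), ");")
  tr <- ape::read.tree(text = txt)
  res <- extract_supported_subtrees(tr)
  first <- res[res$iteration == 1L, ]
  expect_equal(first$n_leaves, 150L)
  expect_true(all(startsWith(first$members[[1]], "a")))
  expect_equal(first$provenance, "extracted_subtree")
  # the unsupported residual is emitted on a later iteration
  expect_true(any(res$iteration > 1L))
  expect_setequal(unlist(res$members), tr$tip.label)

  # all supports below the bar: emitted whole with a warning
  txt2 <- paste0("(", clade("a", 4, 50), ",", clade("b", 4, 60), ");")
  tr2 <- ape::read.tree(text = txt2)
  cfg <- pipeline_config(subtree_max_leaves = 5L)
  expect_warning(res2 <- extract_supported_subtrees(tr2, cfg), "no supported")
  expect_equal(res2$n_leaves, 8L)

  # a tree already below the cap is returned as-is
  small <- ape::rtree(10)
  res3 <- extract_supported_subtrees(small)
  expect_equal(res3$n_leaves, 10L)
  expect_equal(res3$provenance, "initial_component")

  # a large unsupported tree without labels is an error
  big <- ape::rtree(12)
  big$node.label <- NULL
  expect_error(extract_supported_subtrees(big,
                                          pipeline_config(subtree_max_leaves = 5L)),
               "no support values")
})

test_that("incongruence calls apply the 0.3 subs/site patristic cutoff", {
  # x sits 0.2 from an out-of-class reference, y 0.35, z next to its own class
  txt <- "((x:0.1,refG:0.1):0.5,(y:0.25,refG2:0.1):0.5,(z:0.01,refB:0.01):0.5);"
  tr <- ape::read.tree(text = txt)
  leaf_info <- tibble::tibble(
    id = c("x", "y", "z", "refG", "refG2", "refB"),
    class = c("B", "B", "B", "G", "G", "B"),
    origin = c("AU", "AU", "AU", "reference", "reference", "reference"))
  rep <- call_incongruent_leaves(tr, leaf_info)
  expect_equal(rep$call[rep$focal_id == "x"], TRUE)
  expect_equal(rep$distance[rep$focal_id == "x"], 0.2)
  expect_equal(rep$nearest_class[rep$focal_id == "x"], "G")
  # y: out-of-class nearest at 0.35 -> tallied, not called
  expect_equal(rep$call[rep$focal_id == "y"], FALSE)
  expect_true(rep$out_of_class[rep$focal_id == "y"])
  # z: nearest neighbour is its own class -> no call
  expect_false(rep$out_of_class[rep$focal_id == "z"])
  expect_equal(glance(rep)$n_out_of_class_over_cutoff, 1L)

  calls <- incongruence_calls(rep, contig_of = c(x = "c9"))
  expect_equal(calls$orf_id, "x")
  expect_equal(calls$contig_id, "c9")
  expect_equal(calls$method, "phylogenetic")
  expect_equal(calls$partner_class, "G")
  expect_true(is.na(calls$donor_class))  # undirected: no donor claimed
})

test_that("leaves without a class are excluded with a warning", {
  tr <- ape::read.tree(text = "((x:0.1,refG:0.1):0.1,refB:0.4);")
  leaf_info <- tibble::tibble(id = c("x", "refG"), class = c("B", "G"),
                              origin = c("AU", "reference"))
  expect_warning(rep <- call_incongruent_leaves(tr, leaf_info), "refB")
  expect_equal(rep$focal_id, "x")
})
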