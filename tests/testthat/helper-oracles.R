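# Independent oracles and small fixture builders shared across tests.

# Build a k=1 composition model directly from base probabilities.
model_from_probs <- function(probs, label = "X") {
  lp <- matrix(log(probs), nrow = 1,
               dimnames = list("", c("A", "C", "G", "T")))
  structure(list(class_label = label, k = 1L, pseudocount = 0,
                 log_probs = lp),
            class = "kmer_class_model")
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# Exhaustive affine-gap Smith-Waterman (a gap of length L costs
# gap_open + L * gap_extend, matching the package aligner's convention).
naive_sw <- function(q, s, match = 2, mismatch = -3, gap_open = 5,
                     gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (move along subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Breadth-first-search connected components, independent of igraph.
bfs_components <- function(edges, nodes) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (r in seq_len(nrow(edges))) {
    a <- edges$id1[r]; b <- edges$id2[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (start in nodes) {
    if (!is.na(comp[[start]])) next
    cur <- cur + 1L
    queue <- start
    comp[[start]] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Naive patristic distance: walk each leaf to the root, splice at the LCA.
patristic_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    p <- v
    while (v != root) {
      v <- parent_of[v]
      p <- c(p, v)
    }
    p
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1L)) {
    pi <- path_to_root(i)
    for (j in (i + 1L):ntip) {
      pj <- path_to_root(j)
      lca <- intersect(pi, pj)[1]
      walk <- function(v) {
        s <- 0
        while (v != lca) {
          s <- s + len_of[v]
          v <- parent_of[v]
        }
        s
      }
      d[i, j] <- d[j, i] <- walk(i) + walk(j)
    }
  }
  d
}

# Minimal prediction/score fixtures for the discordance caller.
make_scores <- function(ids, classes, scores, n_scored = 300L) {
  tibble::tibble(
    sequence_id = rep(ids, each = length(classes)),
    class = rep(classes, length(ids)),
    score = as.numeric(t(scores)),
    n_scored = n_scored)
}

make_pred <- function(id, class, group, best, runner) {
  tibble::tibble(sequence_id = id, predicted_class = class,
                 confidence_group = factor(group,
                                           levels = c("I", "II", "III", "IV")),
                 homology_class = class, homology_evalue = 1e-60,
                 best_class = class, best_score = best,
                 runner_up_class = "other", runner_up_score = runner,
                 n_scored = 300L)
}

edge_hit <- function(q, s, ident, cov, ev, qlen = 100L) {
  tibble::tibble(query_id = q, subject_id = s, pct_identity = ident,
                 aln_len = as.integer(round(cov * qlen)), mismatch = 0L,
                 gapopen = 0L, q_start = 1L, q_end = 1L, s_start = 1L,
                 s_end = 1L, evalue = ev, bitscore = 100,
                 subject_class = NA_character_, query_len = qlen)
}

disc_fixture <- function(orf_class = "G", contig_class = "B",
                         s_orf = -1.6, s_contig = -2.0, group = "I",
                         orf_len = 300L) {
  list(
    contig_preds = make_pred("c1", contig_class, "IV", -1.8, -1.9),
    orf_preds = make_pred("o1", orf_class, group, s_orf, s_contig),
    orf_scores = make_scores("o1", c("B", "G"),
                             matrix(c(s_contig, s_orf), 1)),
    orfs = tibble::tibble(orf_id = "o1", contig_id = "c1", start = 101L,
                          end = 100L + orf_len, strand = "+",
                          protein = strrep("M", orf_len / 3),
                          ec_number = NA_character_,
                          product = NA_character_)
  )
}
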