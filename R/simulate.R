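#' Sample synthetic class composition models
#'
#' Constructs one k-mer composition model per taxonomic class. Each class
#' gets a base-composition bias `0.25 + divergence * dir_i`, with direction
#' vectors spread evenly on the centred simplex directions (for two classes:
#' an AT-rich and a GC-rich class), plus a small seeded context-specific
#' jitter so the models are genuinely order-(k-1) Markov chains. Pairwise
#' Jensen-Shannon divergences (natural log) between the base distributions
#' are attached as attribute `js_divergence`; `divergence = 0.12` yields
#' JS of about 0.12 for two classes.
#'
#' @param n_classes Number of classes (>= 2).
#' @param k K-mer order of the models.
#' @param divergence Base-composition bias magnitude in (0, 0.2]; 0 gives
#'   identical marginal base frequencies.
#' @param seed RNG seed; the same seed reproduces identical models.
#' @param class_labels Optional class names (defaults to common bacterial
#'   class names).
#' @param jitter_sd Standard deviation of the per-context log-probability
#'   jitter.
#' @return List of `kmer_class_model` objects with attribute
#'   `js_divergence` (matrix).
#' @export
sample_class_models <- function(n_classes = 2L, k = 4L, divergence = 0.12,
                                seed = 1L, class_labels = NULL,
                                jitter_sd = 0.05) {
  if (n_classes < 2L) stop("need at least 2 classes")
  stopifnot(divergence >= 0, divergence <= 0.2)
  if (is.null(class_labels)) {
    pool <- c("Betaproteobacteria", "Gammaproteobacteria",
              "Alphaproteobacteria", "Deltaproteobacteria", "Bacilli",
              "Cytophagia", "Chlorobia", "Flavobacteriia")
    class_labels <- c(pool, paste0("Class", seq_len(n_classes)))[seq_len(n_classes)]
  }
  e1 <- c(1, -1, -1, 1)
  e2 <- c(1, 1, -1, -1)
  contexts <- if (k == 1L) "" else all_kmers(k - 1L)
  models <- with_seed(seed, {
    lapply(seq_len(n_classes), function(i) {
      theta <- 2 * pi * (i - 1) / n_classes
      dir <- cos(theta) * e1 + sin(theta) * e2
      base <- 0.25 + divergence * dir / max(abs(dir))
      base <- base / sum(base)
      jitter <- matrix(stats::rnorm(length(contexts) * 4, 0, jitter_sd),
                       nrow = length(contexts))
      lp <- log(base)[col(jitter)] + jitter
      probs <- exp(lp) / rowSums(exp(lp))
      dimnames(probs) <- list(contexts, c("A", "C", "G", "T"))
      structure(list(class_label = class_labels[i], k = as.integer(k),
                     pseudocount = 0, log_probs = log(probs),
                     base_probs = base),
                class = "kmer_class_model")
    })
  })
  names(models) <- class_labels
  bases <- do.call(rbind, lapply(models, `[[`, "base_probs"))
  js <- matrix(0, n_classes, n_classes,
               dimnames = list(class_labels, class_labels))
  for (i in seq_len(n_classes - 1L)) {
    for (j in (i + 1L):n_classes) {
      js[i, j] <- js[j, i] <- js_divergence(bases[i, ], bases[j, ])
    }
  }
  attr(models, "js_divergence") <- js
  models
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  (kl(p, m) + kl(q, m)) / 2
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1L) {
    for (i in 2:k) out <- as.vector(t(outer(out, bases, paste0)))
  }
  out
}

# Sample a sequence from an order-(k-1) Markov composition model.
markov_sample <- function(model, length) {
  k <- model$k
  probs <- exp(model$log_probs)
  bases <- c("A", "C", "G", "T")
  marginal <- colMeans(probs)
  marginal <- marginal / sum(marginal)
  if (k == 1L) {
    return(paste(sample(bases, length, replace = TRUE, prob = marginal),
                 collapse = ""))
  }
  cum <- t(apply(probs, 1L, cumsum))
  out <- integer(length)
  init <- sample.int(4L, k - 1L, replace = TRUE, prob = marginal)
  out[seq_len(k - 1L)] <- init
  # context index with last base varying fastest
  idx <- sum((init - 1L) * 4L^((k - 2L):0L)) + 1L
  mod <- 4L^(k - 2L)
  u <- runif(length)
  for (i in k:length) {
    b <- findInterval(u[i], cum[idx, ]) + 1L
    out[i] <- b
    idx <- ((idx - 1L) %% mod) * 4L + b
  }
  paste(bases[out], collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sample_orf_sequence <- function(model, width) {
  stopifnot(width %% 3 == 0, width >= 9)
  marginal <- colMeans(exp(model$log_probs))
  marginal <- marginal / sum(marginal)
  bases <- c("A", "C", "G", "T")
  n_internal <- width / 3 - 2L
  codons <- character(n_internal)
  for (i in seq_len(n_internal)) {
    repeat {
      cod <- paste(sample(bases, 3L, replace = TRUE, prob = marginal),
                   collapse = "")
      if (!(cod %in% STOP_CODONS)) break
    }
    codons[i] <- cod
  }
  paste0("ATG", paste(codons, collapse = ""),
         sample(STOP_CODONS, 1L))
}

translate_orf <- function(coding_seq) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(coding_seq), no.init.codon = FALSE))
  sub("\\*$", "", aa)
}

#' Generate one synthetic contig with ORFs
#'
#' Samples a background sequence from the class's Markov composition model
#' and overwrites proper open reading frames (ATG ... stop, no internal stop
#' codons, sampled from the same model) onto the given layout spans. Proteins
#' are derived by translation. Regeneration under the same seed is
#' bit-identical.
#'
#' @param model A `kmer_class_model` for the contig's class.
#' @param length Contig length in nt.
#' @param orf_layout Tibble with `start`, `end`, `strand`; spans must be
#'   disjoint, in-bounds, and multiples of 3 of at least 9 nt.
#' @param seed RNG seed.
#' @param contig_id,community Identifiers stamped on the records.
#' @return List with `contig` (one-row contig tibble) and `orfs` (ORF
#'   tibble with `ec_number`/`product` columns initialised `NA`).
#' @export
generate_contig <- function(model, length, orf_layout, seed = 1L,
                            contig_id = "contig1", community = "SYN") {
  orf_layout <- dplyr::arrange(orf_layout, .data$start)
  if (nrow(orf_layout)) {
    if (any(orf_layout$start < 1L | orf_layout$end > length)) {
      stop("ORF layout span outside contig bounds")
    }
    if (nrow(orf_layout) > 1L &&
        any(orf_layout$start[-1] <= head(orf_layout$end, -1))) {
      stop("overlapping ORF layout spans")
    }
  }
  with_seed(seed, {
    seq <- markov_sample(model, length)
    orfs <- purrr::map_dfr(seq_len(nrow(orf_layout)), function(i) {
      w <- orf_layout$end[i] - orf_layout$start[i] + 1L
      coding <- sample_orf_sequence(model, w)
      genomic <- if (orf_layout$strand[i] == "-") {
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(coding)))
      } else coding
      substr(seq, orf_layout$start[i], orf_layout$end[i]) <<- genomic
      tibble::tibble(
        orf_id = sprintf("%s_orf%02d", contig_id, i),
        contig_id = contig_id,
        start = orf_layout$start[i], end = orf_layout$end[i],
        strand = orf_layout$strand[i],
        protein = translate_orf(coding),
        ec_number = NA_character_, product = NA_character_)
    })
    list(contig = tibble::tibble(id = contig_id, sequence = seq,
                                 community = community, length = length),
         orfs = orfs)
  })
}

orf_coding_sequence <- function(contig_seq, orf) {
  s <- substr(contig_seq, orf$start, orf$end)
  if (orf$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Plant a lateral transfer into a contig
#'
#' Regenerates one existing ORF slot from a donor class's composition model,
#' emulating an inter-class gene insertion, and emits the ground-truth
#' record. Optionally creates an accompanying MGE database record (a lightly
#' mutated copy of the planted ORF, labelled with the recipient's class so
#' the published different-class MGE rule can fire) and relabels an adjacent
#' ORF as a transposase.
#'
#' @param contig One-row contig tibble.
#' @param orfs ORF tibble for this contig.
#' @param donor_model `kmer_class_model` of the donor class.
#' @param orf_id Which ORF slot receives the transfer (must exist).
#' @param recipient_class Class label of the recipient contig.
#' @param seed RNG seed.
#' @param event_id Identifier for the truth record.
#' @param ec_number Optional EC number annotated onto the planted ORF.
#' @param mge_homolog Emit an MGE homolog record? (default `TRUE`).
#' @param mge_divergence Per-base substitution rate applied to the MGE copy.
#' @param mobility_neighbor Relabel the nearest other ORF on the contig as an
#'   IS-family transposase?
#' @return List: `contig` (modified), `orfs` (modified), `event` (one-row
#'   truth tibble), `mge` (one-row `id`/`sequence`/`class` tibble or `NULL`).
#' @export
plant_lgt <- function(contig, orfs, donor_model, orf_id, recipient_class,
                      seed = 1L, event_id = orf_id, ec_number = NA_character_,
                      mge_homolog = TRUE, mge_divergence = 0.02,
                      mobility_neighbor = FALSE) {
  i <- match(orf_id, orfs$orf_id)
  if (is.na(i)) stop("span does not match an ORF: '", orf_id, "' not found")
  with_seed(seed, {
    w <- orfs$end[i] - orfs$start[i] + 1L
    coding <- sample_orf_sequence(donor_model, w)
    genomic <- if (orfs$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(coding)))
    } else coding
    substr(contig$sequence, orfs$start[i], orfs$end[i]) <- genomic
    orfs$protein[i] <- translate_orf(coding)
    orfs$ec_number[i] <- ec_number
    mge <- NULL
    mge_id <- NA_character_
    if (mge_homolog) {
      mge_id <- paste0("MGE_", orf_id)
      mge <- tibble::tibble(id = mge_id,
                            sequence = mutate_sequence(coding, mge_divergence),
                            class = recipient_class)
    }
    if (mobility_neighbor) {
      others <- which(orfs$orf_id != orf_id)
      if (length(others)) {
        j <- others[which.min(abs(orfs$start[others] - orfs$start[i]))]
        orfs$product[j] <- "IS4 family transposase"
      }
    }
    event <- tibble::tibble(
      event_id = event_id,
      donor_class = donor_model$class_label,
      recipient_class = recipient_class,
      contig_id = contig$id, orf_id = orf_id,
      start = orfs$start[i], end = orfs$end[i], strand = orfs$strand[i],
      ec_number = ec_number, mge_homolog_id = mge_id,
      mobility_neighbor = mobility_neighbor)
    list(contig = contig, orfs = orfs, event = event, mge = mge)
  })
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate error-free (or noisy) reads from contigs
#'
#' Uniform start positions on both strands, exact substrings of the source
#' contig by default; a substitution rate can be configured. Read counts per
#' contig are `round(length * depth / read_length)`.
#'
#' @param contigs Contig tibble.
#' @param read_length Read length in nt (must not exceed the shortest
#'   contig).
#' @param depth Target coverage depth.
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed RNG seed.
#' @return Tibble: `id`, `sequence`, `contig_id`, `start`, `end`, `strand`
#'   (the last four are ground truth, not observables).
#' @export
generate_reads <- function(contigs, read_length = 100L, depth = 10,
                           error_rate = 0, seed = 1L) {
  if (read_length > min(contigs$length)) {
    stop("read_length exceeds the shortest contig")
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(contigs)), function(i) {
      n <- round(contigs$length[i] * depth / read_length)
      starts <- sample.int(contigs$length[i] - read_length + 1L, n,
                           replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(contigs$sequence[i], starts,
                        starts + read_length - 1L)
      flip <- strands == "-"
      if (any(flip)) {
        seqs[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[flip])))
      }
      if (error_rate > 0) {
        seqs <- vapply(seqs, mutate_sequence, character(1), rate = error_rate,
                       USE.NAMES = FALSE)
      }
      tibble::tibble(
        id = sprintf("%s_read%04d", contigs$id[i], seq_len(n)),
        sequence = seqs, contig_id = contigs$id[i],
        start = starts, end = starts + read_length - 1L, strand = strands)
    })
  })
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

evolve_protein <- function(chars, distance) {
  p_sub <- 1 - exp(-distance)
  hit <- which(runif(length(chars)) < p_sub)
  for (i in hit) chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  chars
}

#' Simulate one protein family with an optional grafted transfer
#'
#' Evolves a family down a fixed two-clade topology under a Poisson
#' substitution process: a home clade (community leaves plus reference
#' leaves of the focal class) and a donor clade (reference leaves of a
#' different class) separated by `clade_sep` expected substitutions/site.
#' When `graft = TRUE` one community leaf's sequence is re-simulated from a
#' donor-clade reference at `graft_distance`, emulating a transferred gene:
#' the leaf keeps its home-class label but its sequence now sits inside the
#' donor clade.
#'
#' @param family_id Family identifier.
#' @param home_class,donor_class Class labels of the two clades.
#' @param community Community label for the non-reference leaves.
#' @param n_community,n_ref_home,n_ref_donor Leaf counts per compartment.
#' @param seq_length Protein length (sites).
#' @param clade_sep Expected distance between clade ancestors
#'   (substitutions/site).
#' @param tip_depth Distance from clade ancestor to each tip.
#' @param graft Plant a transfer?
#' @param graft_distance Distance from the donor-clade reference to the
#'   grafted community leaf.
#' @param focal_ids Optional explicit ids for the community leaves (e.g. ORF
#'   ids); defaults to `<family_id>_sq<i>`.
#' @param seed RNG seed.
#' @return List: `family` (tibble `id`, `sequence`, `class`, `origin`),
#'   `grafted_id` (`NA` if no graft).
#' @export
simulate_protein_family <- function(family_id, home_class, donor_class,
                                    community = "SYN", n_community = 3L,
                                    n_ref_home = 3L, n_ref_donor = 4L,
                                    seq_length = 120L, clade_sep = 0.6,
                                    tip_depth = 0.05, graft = FALSE,
                                    graft_distance = 0.1, focal_ids = NULL,
                                    seed = 1L) {
  with_seed(seed, {
    root <- sample(AA_ALPHABET, seq_length, replace = TRUE)
    home_anc <- evolve_protein(root, clade_sep / 2)
    donor_anc <- evolve_protein(root, clade_sep / 2)
    comm_ids <- if (is.null(focal_ids)) {
      sprintf("%s_sq%d", family_id, seq_len(n_community))
    } else focal_ids
    stopifnot(length(comm_ids) == n_community)
    tips <- list()
    for (i in seq_len(n_community)) {
      tips[[comm_ids[i]]] <- list(seq = evolve_protein(home_anc, tip_depth),
                                  class = home_class, origin = community)
    }
    for (i in seq_len(n_ref_home)) {
      tips[[sprintf("%s_refH%d", family_id, i)]] <-
        list(seq = evolve_protein(home_anc, tip_depth),
             class = home_class, origin = "reference")
    }
    donor_ref_ids <- sprintf("%s_refD%d", family_id, seq_len(n_ref_donor))
    for (i in seq_len(n_ref_donor)) {
      tips[[donor_ref_ids[i]]] <-
        list(seq = evolve_protein(donor_anc, tip_depth),
             class = donor_class, origin = "reference")
    }
    grafted_id <- NA_character_
    if (graft) {
      grafted_id <- comm_ids[1]
      donor_src <- tips[[donor_ref_ids[1]]]$seq
      tips[[grafted_id]]$seq <- evolve_protein(donor_src, graft_distance)
    }
    family <- tibble::tibble(
      id = names(tips),
      sequence = vapply(tips, function(t) paste(t$seq, collapse = ""),
                        character(1)),
      class = vapply(tips, `[[`, character(1), "class"),
      origin = vapply(tips, `[[`, character(1), "origin"))
    list(family = family, grafted_id = grafted_id)
  })
}

#' Simulate a reference panel of protein families with planted transfers
#'
#' Wraps [simulate_protein_family()] over `n_families` families, grafting a
#' community leaf into the donor clade for a `transfer_fraction` of them,
#' and builds the per-family trees with the built-in neighbour-joining path.
#' The truth table lists every grafted leaf.
#'
#' @param home_class,donor_class Clade class labels.
#' @param n_families Number of families.
#' @param transfer_fraction Fraction of families receiving a graft (in
#'   \[0, 1\]; the first `round(n_families * transfer_fraction)` families are
#'   grafted).
#' @param graft_distance Planted distance (substitutions/site).
#' @param clade_sep Distance between clade ancestors.
#' @param seed RNG seed.
#' @param bootstrap Bootstrap replicates for [build_tree()] (0 = none;
#'   nearest-neighbour calls need branch lengths only).
#' @param ... Passed through to [simulate_protein_family()].
#' @return List: `families` (list of leaf tibbles), `trees` (list of
#'   [ape::phylo]), `leaf_info` (combined `id`/`class`/`origin` tibble),
#'   `truth` (tibble `family`, `grafted_id`).
#' @export
generate_reference_panel_and_trees <- function(home_class = "Betaproteobacteria",
                                               donor_class = "Gammaproteobacteria",
                                               n_families = 100L,
                                               transfer_fraction = 0.1,
                                               graft_distance = 0.1,
                                               clade_sep = 0.6,
                                               seed = 1L, bootstrap = 0L,
                                               ...) {
  if (transfer_fraction < 0 || transfer_fraction > 1) {
    stop("transfer_fraction must lie in [0, 1]")
  }
  n_graft <- round(n_families * transfer_fraction)
  fams <- lapply(seq_len(n_families), function(i) {
    simulate_protein_family(
      family_id = sprintf("fam%03d", i),
      home_class = home_class, donor_class = donor_class,
      graft = i <= n_graft, graft_distance = graft_distance,
      clade_sep = clade_sep, seed = seed + 13L * i, ...)
  })
  families <- lapply(fams, `[[`, "family")
  trees <- lapply(seq_along(families), function(i) {
    build_tree(families[[i]], bootstrap = bootstrap, seed = seed + 13L * i)
  })
  truth <- tibble::tibble(
    family = sprintf("fam%03d", seq_len(n_families)),
    grafted_id = vapply(fams, `[[`, character(1), "grafted_id"))
  list(families = families, trees = trees,
       leaf_info = dplyr::bind_rows(families)[, c("id", "class", "origin")],
       truth = truth)
}

#' Synthesize a 12-column hit table from a simulated protein family
#'
#' Emits, for every ordered pair of family members, the hit row an
#' all-versus-all protein search would produce: identity is the true
#' per-site agreement, coverage is full (the family is simulated without
#' indels), and e-values/bit scores are derived from the identity so that
#' closer pairs score better.
#'
#' @param family Tibble `id`, `sequence` (equal lengths).
#' @return A hit tibble compatible with [read_hit_table()] output, with
#'   `query_len`/`subject_len` filled.
#' @export
generate_family_hits <- function(family) {
  n <- nrow(family)
  L <- nchar(family$sequence[1])
  chars <- strsplit(family$sequence, "")
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ident <- mean(chars[[i]] == chars[[j]])
      bitscore <- max(2 * L * ident, 30)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = family$id[i], subject_id = family$id[j],
        pct_identity = 100 * ident, aln_len = L,
        mismatch = as.integer(round(L * (1 - ident))), gapopen = 0L,
        q_start = 1L, q_end = L, s_start = 1L, s_end = L,
        evalue = L * L * 2^(-bitscore), bitscore = bitscore,
        subject_class = NA_character_,
        query_len = L, subject_len = L)
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic reference homology hit table for ORFs
#'
#' Emulates the homology side of the classifier: every ORF receives a strong
#' best hit to a reference genome of its true source class and a much weaker
#' hit to a different class, so ORFs land in confidence Groups I-II. Written
#' in the 12-column dialect ingested by [read_hit_table()].
#'
#' @param orfs ORF tibble.
#' @param orf_source_class Character vector (parallel to `orfs`) giving each
#'   ORF's true source class.
#' @param other_class Function mapping a class to some different class (used
#'   for the weaker out-of-class hit); defaults to swapping within the set of
#'   observed classes.
#' @param e_best,e_other E-values of the in-class and out-of-class hits.
#' @return A hit tibble with `subject_class` filled, plus the matching
#'   reference taxonomy tibble as attribute `taxonomy`.
#' @export
generate_orf_hits <- function(orfs, orf_source_class,
                              e_best = 1e-60, e_other = 1e-45,
                              other_class = NULL) {
  classes <- sort(unique(orf_source_class))
  if (is.null(other_class)) {
    other_class <- function(cl) classes[classes != cl][1]
  }
  plen <- nchar(orfs$protein)
  mk <- function(cls, ev, tag) tibble::tibble(
    query_id = orfs$orf_id, subject_id = paste0("ref_", cls, "_", tag),
    pct_identity = ifelse(ev <= 1e-50, 92, 78), aln_len = plen,
    mismatch = 0L, gapopen = 0L, q_start = 1L, q_end = plen,
    s_start = 1L, s_end = plen, evalue = ev,
    bitscore = -log2(ev), subject_class = cls)
  best <- mk(orf_source_class, e_best, "a")
  other <- mk(vapply(orf_source_class, other_class, character(1)),
              e_other, "b")
  hits <- dplyr::bind_rows(best, other)
  tax <- dplyr::distinct(tibble::tibble(id = hits$subject_id,
                                        class = hits$subject_class))
  attr(hits, "taxonomy") <- tax
  hits
}
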