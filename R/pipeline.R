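#' Run the full LGT-detection pipeline on a synthetic community
#'
#' Orchestrates every stage end to end on a generated community with planted
#' transfers: composition classification of contigs and ORFs with confidence
#' groups, discordance calling, protein-family simulation with grafted
#' transfers feeding the homology network / tree / patristic-incongruence
#' branch, the MGE homology screen, the method intersection, directed
#' exchange networks, mobility-gene scanning, contig statistics, and
#' read-spanning validation. All randomness derives from `seed`; re-running
#' with the same seed and configuration produces byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed); TSV/JSON/GraphML
#'   artifacts are written there.
#' @param seed Master seed for every stage.
#' @param config A [pipeline_config()] list.
#' @param n_contigs,n_plants Community size and number of planted
#'   inter-class transfers.
#' @param n_null_families Ungrafted protein families added alongside the
#'   grafted ones (false-positive control for the phylogenetic branch).
#' @param n_read_contigs Number of planted contigs taken into the
#'   read-validation stage.
#' @param quiet Suppress per-stage count messages?
#' @return An object of class `lgt_pipeline_result` (a list of all stage
#'   outputs plus `summary`), invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 42L, config = pipeline_config(),
                         n_contigs = 20L, n_plants = 8L,
                         n_null_families = 8L, n_read_contigs = 1L,
                         quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  k <- config$kmer_order

  ## --- synthetic community ------------------------------------------------
  models <- sample_class_models(2L, k = k, divergence = 0.12, seed = seed)
  classes <- names(models)
  train_seqs <- lapply(seq_along(models), function(i) {
    with_seed(seed + 100L + i, markov_sample(models[[i]], 20000L))
  })
  trained <- lapply(seq_along(models), function(i) {
    train_class_model(train_seqs[[i]], classes[i], k = k, pseudocount = 1)
  })
  names(trained) <- classes

  community <- simulate_community(models, n_contigs, n_plants, seed, config)
  contigs <- filter_contigs_by_length(community$contigs, config$min_contig_len)
  orfs <- community$orfs[community$orfs$contig_id %in% contigs$id, ]
  truth <- community$truth
  if (nrow(truth)) truth <- truth[truth$contig_id %in% contigs$id, ]
  say("community: %d contigs in -> %d retained (>= %d nt), %d ORFs, %d planted",
      n_contigs, nrow(contigs), config$min_contig_len, nrow(orfs), nrow(truth))

  ## --- classification -----------------------------------------------------
  contig_scores <- classify_composition(contigs, trained, both_strands = TRUE)
  contig_preds <- assign_confidence_groups(contig_scores, hits = NULL,
                                           config = config)
  orf_seqs <- tibble::tibble(
    id = orfs$orf_id,
    sequence = vapply(seq_len(nrow(orfs)), function(i) {
      orf_coding_sequence(contigs$sequence[contigs$id == orfs$contig_id[i]],
                          orfs[i, ])
    }, character(1)))
  source_class <- as.character(ifelse(orfs$orf_id %in% truth$orf_id,
                         truth$donor_class[match(orfs$orf_id, truth$orf_id)],
                         community$contig_class[orfs$contig_id]))
  orf_hits <- generate_orf_hits(orfs, source_class)
  orf_scores <- classify_composition(orf_seqs, trained, both_strands = FALSE)
  orf_preds <- assign_confidence_groups(orf_scores, orf_hits, config = config)
  say("classification: %d contigs, %d ORFs scored against %d class models",
      nrow(contig_preds), nrow(orf_preds), length(trained))

  ## --- discordance --------------------------------------------------------
  disc_calls <- call_discordant_orfs(contig_preds, orf_preds, orf_scores,
                                     orfs, config)
  say("discordance: %d ORFs in -> %d eligible (Groups I-II) -> %d called",
      nrow(orf_preds),
      sum(orf_preds$confidence_group %in% c("I", "II")), nrow(disc_calls))

  ## --- phylogenetic incongruence ------------------------------------------
  phylo <- phylo_branch(orfs, truth, community, n_null_families, seed, config)
  phylo_calls <- phylo$calls
  say("phylogenetic: %d families -> %d clusters treed -> %d leaves called",
      phylo$n_families, phylo$n_clusters, nrow(phylo_calls))

  ## --- MGE screen ----------------------------------------------------------
  candidates <- union(disc_calls$orf_id, phylo_calls$orf_id)
  mge_db <- community$mge
  mge_pass <- character()
  if (length(candidates) && nrow(mge_db)) {
    cand_seqs <- orf_seqs[orf_seqs$id %in% candidates, ]
    mge_hits <- purrr::map_dfr(seq_len(nrow(cand_seqs)), function(i) {
      purrr::map_dfr(seq_len(nrow(mge_db)), function(j) {
        h <- local_align(cand_seqs$sequence[i], mge_db$sequence[j])
        h$query_id <- cand_seqs$id[i]
        h$subject_id <- mge_db$id[j]
        h$subject_class <- mge_db$class[j]
        h
      })
    })
    mge_hits <- add_hit_lengths(mge_hits, cand_seqs, mge_db)
    orf_classes <- tibble::tibble(
      orf_id = orf_preds$sequence_id,
      class = orf_preds$predicted_class)
    mge_pass <- mge_homology_filter(candidates, mge_hits, orf_classes, config)
  }
  disc_calls$mge_supported <- disc_calls$orf_id %in% mge_pass
  phylo_calls$mge_supported <- phylo_calls$orf_id %in% mge_pass
  say("MGE screen: %d candidates -> %d supported", length(candidates),
      length(mge_pass))

  ## --- synthesis -----------------------------------------------------------
  ec_table <- read_ec_table(system.file("extdata", "ec_pathways.tsv",
                                        package = "lgtscout"))
  orf_pathways <- map_ec_to_pathways(orfs, ec_table)
  inter <- intersect_method_calls(disc_calls, phylo_calls, mge_pass,
                                  orf_pathways)
  all_calls <- dplyr::bind_rows(disc_calls, phylo_calls)
  mobility <- scan_mobility_genes(orfs)
  all_calls <- flag_mobility_adjacent(all_calls, mobility)
  network <- build_exchange_network(all_calls, orf_pathways,
                                    community = contigs$community[1])
  pathway_calls <- all_calls[all_calls$orf_id %in% orf_pathways$orf_id, ]
  stats <- summarize_contig_stats(contigs, orfs, pathway_calls)
  say("synthesis: %d high-confidence ORFs (both methods + MGE), %d network edges",
      length(inter$high_confidence), nrow(network))

  ## --- read validation ------------------------------------------------------
  read_contig_ids <- head(unique(truth$contig_id), n_read_contigs)
  rv_contigs <- contigs[contigs$id %in% read_contig_ids, ]
  read_spans <- tibble::tibble(read_id = character(), contig_id = character(),
                               orf_id = character(), span_class = character())
  if (nrow(rv_contigs)) {
    reads <- generate_reads(rv_contigs, read_length = 250L, depth = 10,
                            seed = seed + 500L)
    mapped <- map_reads_to_contigs(reads, rv_contigs, config)
    rv_orfs <- truth$orf_id[truth$contig_id %in% read_contig_ids]
    read_spans <- purrr::map_dfr(rv_orfs, function(oid)
      classify_read_spans(mapped, orfs, oid))
  }
  spanning <- read_spans |>
    dplyr::filter(.data$span_class %in% c("full_orf", "into_neighbor")) |>
    dplyr::distinct(.data$orf_id)
  say("read validation: %d reads span ORFs on %d contigs; %d/%d planted ORFs supported",
      nrow(read_spans), nrow(rv_contigs), nrow(spanning),
      length(unique(truth$orf_id[truth$contig_id %in% read_contig_ids])))

  ## --- summary & outputs ----------------------------------------------------
  disc_truth_keys <- paste(truth$orf_id, truth$donor_class,
                           truth$recipient_class)
  disc_call_keys <- paste(disc_calls$orf_id, disc_calls$donor_class,
                          disc_calls$recipient_class)
  grafted <- phylo$truth$grafted_id[!is.na(phylo$truth$grafted_id)]
  ungrafted_leaves <- setdiff(phylo$report$focal_id, grafted)
  n_rv <- length(unique(truth$orf_id[truth$contig_id %in% read_contig_ids]))
  summary <- list(
    seed = seed,
    discordance_recall = mean(disc_truth_keys %in% disc_call_keys),
    discordance_precision = if (nrow(disc_calls)) {
      mean(disc_call_keys %in% disc_truth_keys)
    } else NA_real_,
    phylo_recall = mean(grafted %in% phylo_calls$orf_id),
    phylo_fp_rate = if (length(ungrafted_leaves)) {
      mean(ungrafted_leaves %in% phylo_calls$orf_id)
    } else 0,
    n_high_confidence = length(inter$high_confidence),
    read_span_support_fraction = if (n_rv) nrow(spanning) / n_rv else NA_real_
  )

  write_fasta(contigs, file.path(out_dir, "contigs.fasta"))
  write_orf_table(orfs, file.path(out_dir, "orfs.tsv"))
  readr::write_tsv(truth, file.path(out_dir, "truth_events.tsv"))
  write_predictions(contig_preds, file.path(out_dir, "contig_predictions.tsv"))
  write_predictions(orf_preds, file.path(out_dir, "orf_predictions.tsv"))
  write_calls(disc_calls, file.path(out_dir, "discordance_calls.tsv"))
  readr::write_tsv(tibble::as_tibble(unclass(phylo$report)),
                   file.path(out_dir, "neighbor_report.tsv"))
  write_calls(phylo_calls, file.path(out_dir, "phylo_calls.tsv"))
  writeLines(mge_pass, file.path(out_dir, "mge_supported.txt"))
  jsonlite::write_json(inter$venn, file.path(out_dir, "venn_counts.json"),
                       digits = NA)
  writeLines(inter$high_confidence,
             file.path(out_dir, "high_confidence.txt"))
  write_network_tsv(network, file.path(out_dir, "exchange_network.tsv"))
  write_network_graphml(network, file.path(out_dir, "networks"))
  readr::write_tsv(stats, file.path(out_dir, "contig_stats.tsv"))
  readr::write_tsv(read_spans, file.path(out_dir, "read_spans.tsv"))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  res <- list(
    out_dir = out_dir, config = config, truth = truth,
    contigs = contigs, orfs = orfs,
    contig_preds = contig_preds, orf_preds = orf_preds,
    discordance_calls = disc_calls, neighbor_report = phylo$report,
    phylo_calls = phylo_calls, mge_pass = mge_pass,
    intersection = inter, network = network, contig_stats = stats,
    read_spans = read_spans, summary = summary)
  class(res) <- "lgt_pipeline_result"
  invisible(res)
}

#' @export
print.lgt_pipeline_result <- function(x, ...) {
  cat("<lgt_pipeline_result>\n")
  print(glance(x))
  invisible(x)
}

#' @method glance lgt_pipeline_result
#' @export
glance.lgt_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_contigs = nrow(x$contigs),
    n_orfs = nrow(x$orfs),
    n_planted = nrow(x$truth),
    n_discordance_calls = nrow(x$discordance_calls),
    n_phylo_calls = nrow(x$phylo_calls),
    n_high_confidence = x$summary$n_high_confidence,
    discordance_recall = x$summary$discordance_recall,
    discordance_precision = x$summary$discordance_precision,
    phylo_recall = x$summary$phylo_recall,
    read_span_support_fraction = x$summary$read_span_support_fraction
  )
}

#' Assemble a synthetic community with planted transfers
#'
#' Generates `n_contigs` contigs (alternating between the supplied class
#' models, lengths drawn from `len_range`), lays out open reading frames
#' along each, and plants `n_plants` inter-class transfers: the middle ORF
#' slot of each chosen contig is regenerated from the other class's model,
#' annotated with an EC number from the six energy-related pathways, paired
#' with an MGE homolog record, and (for half the events) flanked by a
#' transposase-annotated neighbour. The machine-readable truth table is
#' sufficient to score any caller.
#'
#' @param models List of >= 2 `kmer_class_model` objects (see
#'   [sample_class_models()]).
#' @param n_contigs,n_plants Community size and number of planted events.
#' @param seed Master seed; every piece derives its own sub-seed.
#' @param config A [pipeline_config()] list.
#' @param len_range Contig length range in nt (sampled on a 500-nt grid).
#' @return List: `contigs`, `orfs`, `truth` (one row per planted event),
#'   `mge` (MGE database records), `contig_class` (named vector of true
#'   contig classes).
#' @export
simulate_community <- function(models, n_contigs = 20L, n_plants = 8L,
                               seed = 1L, config = pipeline_config(),
                               len_range = c(2000L, 6000L)) {
  classes <- names(models)
  ecs <- c("4.2.1.17", "2.3.1.9", "2.7.1.11", "2.7.1.2",
           "6.3.5.4", "1.9.3.1", "2.7.2.3", "5.4.2.1")
  backdrop_ecs <- c("1.1.1.1", "1.2.1.12", "4.2.1.11", "1.6.5.3")
  lens <- with_seed(seed + 7L, sample(seq(len_range[1], len_range[2], by = 500L),
                                      n_contigs, replace = TRUE))
  cls_idx <- rep_len(seq_along(classes), n_contigs)
  pieces <- lapply(seq_len(n_contigs), function(i) {
    layout <- orf_layout_for(lens[i], seed + 20L + i)
    generate_contig(models[[cls_idx[i]]], lens[i], layout,
                    seed = seed + 50L + i,
                    contig_id = sprintf("ctg%03d", i), community = "SYN")
  })
  contigs <- dplyr::bind_rows(lapply(pieces, `[[`, "contig"))
  orf_list <- lapply(pieces, `[[`, "orfs")
  contig_class <- setNames(classes[cls_idx], contigs$id)

  plant_idx <- with_seed(seed + 9L,
                         sample(n_contigs, min(n_plants, n_contigs)))
  truth <- list()
  mge <- list()
  for (p in seq_along(plant_idx)) {
    i <- plant_idx[p]
    orfs_i <- orf_list[[i]]
    if (!nrow(orfs_i)) next
    slot <- orfs_i$orf_id[ceiling(nrow(orfs_i) / 2)]
    donor <- models[[setdiff(seq_along(classes), cls_idx[i])[1]]]
    planted <- plant_lgt(
      contigs[i, ], orfs_i, donor, slot,
      recipient_class = classes[cls_idx[i]],
      seed = seed + 300L + i,
      event_id = sprintf("ev%02d", p),
      ec_number = ecs[(p - 1L) %% length(ecs) + 1L],
      mge_homolog = TRUE,
      mobility_neighbor = p <= ceiling(length(plant_idx) / 2))
    contigs[i, ] <- planted$contig
    orf_list[[i]] <- planted$orfs
    truth[[p]] <- planted$event
    mge[[p]] <- planted$mge
  }
  orfs <- dplyr::bind_rows(orf_list)
  # backdrop enzyme annotations on unplanted first ORFs, so pathways are
  # populated beyond the planted set
  truth_df <- dplyr::bind_rows(truth)
  if (!nrow(truth_df)) {
    truth_df <- tibble::tibble(
      event_id = character(), donor_class = character(),
      recipient_class = character(), contig_id = character(),
      orf_id = character(), start = integer(), end = integer(),
      strand = character(), ec_number = character(),
      mge_homolog_id = character(), mobility_neighbor = logical())
  }
  first_orfs <- orfs |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  free <- setdiff(first_orfs$orf_id, truth_df$orf_id)
  idx <- match(free, orfs$orf_id)
  orfs$ec_number[idx] <- rep_len(backdrop_ecs, length(idx))
  list(contigs = contigs, orfs = orfs, truth = truth_df,
       mge = dplyr::bind_rows(mge), contig_class = contig_class)
}

orf_layout_for <- function(len, seed) {
  with_seed(seed, {
    starts <- integer()
    ends <- integer()
    pos <- 101L
    while (pos + 700L < len - 100L) {
      w <- sample(c(300L, 399L, 450L, 501L, 600L), 1L)
      starts <- c(starts, pos)
      ends <- c(ends, pos + w - 1L)
      pos <- pos + w - 1L + sample(20:50, 1L)
    }
    tibble::tibble(start = starts, end = ends,
                   strand = sample(c("+", "-"), length(starts),
                                   replace = TRUE))
  })
}

# Phylogenetic branch of the pipeline: one grafted family per planted ORF
# (focal leaf named after the ORF), plus ungrafted control families for
# unplanted ORFs; homology network -> components -> trees -> calls.
phylo_branch <- function(orfs, truth, community, n_null_families, seed,
                         config) {
  planted <- truth$orf_id
  unplanted <- setdiff(orfs$orf_id, planted)
  null_focal <- head(unplanted, n_null_families)
  specs <- dplyr::bind_rows(
    tibble::tibble(focal = planted, graft = TRUE),
    tibble::tibble(focal = null_focal, graft = FALSE))
  if (!nrow(specs)) {
    return(list(report = tibble::tibble(focal_id = character()),
                calls = empty_calls(),
                truth = tibble::tibble(family = character(),
                                       grafted_id = character()),
                n_families = 0L, n_clusters = 0L))
  }
  fams <- lapply(seq_len(nrow(specs)), function(i) {
    oid <- specs$focal[i]
    cid <- orfs$contig_id[orfs$orf_id == oid]
    home <- unname(community$contig_class[cid])
    donor <- if (specs$graft[i]) {
      truth$donor_class[truth$orf_id == oid]
    } else {
      setdiff(unique(unname(community$contig_class)), home)[1]
    }
    fam_id <- sprintf("fam_%s", oid)
    simulate_protein_family(
      family_id = fam_id, home_class = home, donor_class = donor,
      community = "SYN", graft = specs$graft[i],
      focal_ids = c(oid, paste0(fam_id, "_sq2"), paste0(fam_id, "_sq3")),
      seed = seed + 700L + i)
  })
  families <- lapply(fams, `[[`, "family")
  hits <- dplyr::bind_rows(lapply(families, generate_family_hits))
  graph <- build_homology_graph(hits, config)
  all_leaves <- dplyr::bind_rows(families)
  comp <- connected_components(graph, nodes = all_leaves$id)
  leaf_info <- all_leaves[, c("id", "class", "origin")]
  seq_of <- setNames(all_leaves$sequence, all_leaves$id)
  reports <- list()
  n_clusters <- 0L
  for (cl in unique(comp$cluster[comp$cluster_size >= 3L])) {
    members <- comp$id[comp$cluster == cl]
    prots <- tibble::tibble(id = members, sequence = unname(seq_of[members]))
    tree <- build_tree(prots, bootstrap = 25L, seed = seed + 900L + cl)
    sub <- extract_supported_subtrees(tree, config)
    n_clusters <- n_clusters + 1L
    reports[[length(reports) + 1L]] <-
      call_incongruent_leaves(tree, leaf_info, config)
  }
  report <- dplyr::bind_rows(reports)
  if (nrow(report)) class(report) <- c("lgt_neighbor_report", class(report))
  contig_of <- setNames(orfs$contig_id, orfs$orf_id)
  calls <- if (nrow(report)) incongruence_calls(report, contig_of)
           else empty_calls()
  list(report = report, calls = calls,
       truth = tibble::tibble(
         family = vapply(seq_len(nrow(specs)), function(i)
           sprintf("fam_%s", specs$focal[i]), character(1)),
         grafted_id = ifelse(specs$graft, specs$focal, NA_character_)),
       n_families = length(families), n_clusters = n_clusters)
}
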