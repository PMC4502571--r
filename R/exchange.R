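#' Map annotated ORFs onto metabolic pathways
#'
#' Assigns each ORF's EC number to pathway labels via an EC-to-pathway table
#' (the packaged toy table covers six energy-related KEGG pathways: BM, CAC,
#' GG, PPP, PM, NM; an EC may belong to several pathways). ORFs with no EC,
#' a malformed EC (warned), or an EC outside the table are unassigned.
#'
#' @param annotations Tibble with `orf_id` and `ec_number` (e.g. from
#'   [annotate_functions()] or an ORF table).
#' @param pathway_table Tibble from [read_ec_table()].
#' @return Long tibble: `orf_id`, `ec_number`, `pathway`; zero rows for an
#'   ORF means unassigned.
#' @export
map_ec_to_pathways <- function(annotations, pathway_table) {
  ann <- dplyr::filter(annotations, !is.na(.data$ec_number))
  ok <- grepl("^\\d+\\.\\d+\\.\\d+\\.(\\d+|-)$", ann$ec_number)
  if (any(!ok)) {
    warning("malformed EC number(s) left unassigned: ",
            paste(unique(ann$ec_number[!ok]), collapse = ", "))
    ann <- ann[ok, ]
  }
  dplyr::inner_join(ann[, c("orf_id", "ec_number")], pathway_table,
                    by = "ec_number", relationship = "many-to-many")
}

#' Intersect the two detection methods and the MGE screen
#'
#' Produces the per-pathway three-way partition of called ORFs (discordance
#' only, phylogenetic only, both) and the high-confidence set: ORFs called
#' by both methods that also pass the MGE screen. Counts obey
#' inclusion-exclusion by construction.
#'
#' @param discordance_calls,phylo_calls `lgt_calls` tibbles.
#' @param mge_pass_ids Character vector of ORF ids passing
#'   [mge_homology_filter()].
#' @param orf_pathways Optional pathway assignment from
#'   [map_ec_to_pathways()]; when supplied, venn counts are also reported per
#'   pathway.
#' @return A list with `venn` (tibble: `pathway` (or `"all"`),
#'   `discordance_only`, `phylo_only`, `both`) and `high_confidence`
#'   (character vector of ORF ids in both methods and MGE-supported).
#' @export
intersect_method_calls <- function(discordance_calls, phylo_calls,
                                   mge_pass_ids = character(),
                                   orf_pathways = NULL) {
  d <- unique(discordance_calls$orf_id)
  p <- unique(phylo_calls$orf_id)
  venn_of <- function(d, p, label) {
    tibble::tibble(pathway = label,
                   discordance_only = length(setdiff(d, p)),
                   phylo_only = length(setdiff(p, d)),
                   both = length(intersect(d, p)))
  }
  venn <- venn_of(d, p, "all")
  if (!is.null(orf_pathways) && nrow(orf_pathways)) {
    per <- lapply(sort(unique(orf_pathways$pathway)), function(pw) {
      ids <- orf_pathways$orf_id[orf_pathways$pathway == pw]
      venn_of(intersect(d, ids), intersect(p, ids), pw)
    })
    venn <- dplyr::bind_rows(venn, per)
  }
  list(venn = venn,
       high_confidence = sort(intersect(intersect(d, p), mge_pass_ids)))
}

#' Build directed genetic-exchange networks
#'
#' One network per pathway: taxonomic classes are nodes; each directed edge
#' runs from donor to recipient class with multiplicity equal to the number
#' of witnessing calls (witnesses stay itemised). Only oriented discordance
#' calls produce arrows; undirected phylogenetic calls are rendered as a
#' separate undirected layer (`directed = FALSE`, classes in lexicographic
#' order). Self-loops (donor == recipient) never occur for valid calls.
#'
#' @param calls An `lgt_calls` tibble (both methods may be mixed).
#' @param orf_pathways Pathway assignment from [map_ec_to_pathways()].
#' @param community Community label stamped on every edge.
#' @return A tibble of class `lgt_exchange_network`: `community`, `pathway`,
#'   `from`, `to`, `directed`, `multiplicity`, `witnesses` (list of
#'   `(ec_number, orf_id)` tibbles).
#' @export
build_exchange_network <- function(calls, orf_pathways,
                                   community = "community") {
  df <- dplyr::inner_join(tibble::as_tibble(unclass(calls)), orf_pathways,
                          by = "orf_id", relationship = "many-to-many")
  directed <- df[df$method == "discordance", ]
  undirected <- df[df$method == "phylogenetic", ]
  dir_edges <- if (nrow(directed)) {
    directed |>
      dplyr::group_by(.data$pathway, from = .data$donor_class,
                      to = .data$recipient_class) |>
      dplyr::summarise(
        directed = TRUE, multiplicity = dplyr::n(),
        witnesses = list(data.frame(ec_number = ec_number, orf_id = orf_id)),
        .groups = "drop")
  } else NULL
  und_edges <- if (nrow(undirected)) {
    undirected |>
      dplyr::mutate(from = pmin(.data$recipient_class, .data$partner_class),
                    to = pmax(.data$recipient_class, .data$partner_class)) |>
      dplyr::group_by(.data$pathway, .data$from, .data$to) |>
      dplyr::summarise(
        directed = FALSE, multiplicity = dplyr::n(),
        witnesses = list(data.frame(ec_number = ec_number, orf_id = orf_id)),
        .groups = "drop")
  } else NULL
  net <- dplyr::bind_rows(dir_edges, und_edges)
  if (is.null(net) || !nrow(net)) {
    net <- tibble::tibble(pathway = character(), from = character(),
                          to = character(), directed = logical(),
                          multiplicity = integer(), witnesses = list())
  }
  net <- dplyr::mutate(net, community = community, .before = 1) |>
    dplyr::arrange(.data$pathway, .data$from, .data$to)
  class(net) <- c("lgt_exchange_network", class(net))
  net
}

#' Export an exchange network
#'
#' `write_network_tsv()` writes a flat edge list (witness ORFs collapsed to a
#' comma-separated column); `write_network_graphml()` writes one GraphML file
#' per pathway via igraph.
#'
#' @param network An `lgt_exchange_network`.
#' @param path Output TSV path, or a directory for GraphML files.
#' @return The written path(s), invisibly.
#' @export
write_network_tsv <- function(network, path) {
  flat <- network |>
    dplyr::mutate(witness_orfs = vapply(
      .data$witnesses, function(w) paste(w$orf_id, collapse = ","),
      character(1))) |>
    dplyr::select(-"witnesses")
  readr::write_tsv(tibble::as_tibble(unclass(flat)), path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(network, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- character()
  for (pw in unique(network$pathway)) {
    sub <- network[network$pathway == pw, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = sub$from, to = sub$to,
                 weight = sub$multiplicity, directed_edge = sub$directed),
      directed = TRUE)
    f <- file.path(path, paste0("exchange_", pw, ".graphml"))
    igraph::write_graph(g, f, format = "graphml")
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Scan contig annotations for mobility genes
#'
#' Case-insensitive keyword match on ORF product text to locate transposases
#' and integrases; a call's `mobility_adjacent` flag should be set when its
#' contig carries at least one hit (see [flag_mobility_adjacent()]).
#'
#' @param orfs ORF tibble with `product` text.
#' @param keywords Keyword-to-label character vector; names are labels.
#' @return Tibble: `orf_id`, `contig_id`, `mobility_gene`.
#' @export
scan_mobility_genes <- function(orfs,
                                keywords = c(transposase = "transposase",
                                             integrase = "integrase")) {
  hits <- lapply(names(keywords), function(lbl) {
    idx <- grepl(keywords[[lbl]], orfs$product, ignore.case = TRUE)
    tibble::tibble(orf_id = orfs$orf_id[idx], contig_id = orfs$contig_id[idx],
                   mobility_gene = lbl)
  })
  dplyr::bind_rows(hits) |> dplyr::arrange(.data$orf_id)
}

#' Flag calls on contigs carrying mobility genes
#'
#' @param calls An `lgt_calls` tibble.
#' @param mobility Output of [scan_mobility_genes()].
#' @return `calls` with `mobility_adjacent` set.
#' @export
flag_mobility_adjacent <- function(calls, mobility) {
  calls$mobility_adjacent <- calls$contig_id %in% mobility$contig_id
  calls
}

#' Contig length and gene-count summary for LGT-bearing contigs
#'
#' Reproduces the shape of the published length-statistics table: per
#' community, three rows — all retained contigs, contigs carrying at least
#' one call in the pathways of interest, and the subset of those that also
#' carry a transposase/integrase. Means are reported to two decimals; empty
#' subsets yield `NA` rows (as in the published table's blank entries).
#'
#' @param contigs Retained contig tibble.
#' @param orfs ORF tibble.
#' @param calls An `lgt_calls` tibble restricted to the pathways of interest
#'   (with `mobility_adjacent` flagged).
#' @return Tibble: `community`, `group`, `n_contigs`, `mean_length`,
#'   `mean_genes`.
#' @export
summarize_contig_stats <- function(contigs, orfs, calls) {
  gene_counts <- dplyr::count(orfs, .data$contig_id, name = "n_genes")
  base <- contigs |>
    dplyr::left_join(gene_counts, by = c(id = "contig_id")) |>
    dplyr::mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L))
  lgt_ids <- unique(calls$contig_id)
  mob_ids <- unique(calls$contig_id[calls$mobility_adjacent])
  row_for <- function(sub, community, group) {
    tibble::tibble(
      community = community, group = group, n_contigs = nrow(sub),
      mean_length = if (nrow(sub)) round(mean(sub$length), 2) else NA_real_,
      mean_genes = if (nrow(sub)) round(mean(sub$n_genes), 2) else NA_real_)
  }
  purrr::map_dfr(unique(base$community), function(comm) {
    sub <- base[base$community == comm, ]
    dplyr::bind_rows(
      row_for(sub, comm, "all"),
      row_for(sub[sub$id %in% lgt_ids, ], comm, "lgt_six_pathways"),
      row_for(sub[sub$id %in% mob_ids, ], comm,
              "lgt_transposases_integrases"))
  })
}
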