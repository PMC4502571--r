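#' Build a protein homology network
#'
#' Nodes are sequences; an undirected edge joins two sequences when some hit
#' between them has at least 70 % identity, covers at least 60 % of the
#' query, and has an e-value of 1e-5 or smaller (all boundaries inclusive).
#' An edge is admitted if either direction qualifies; duplicate qualifying
#' hits collapse to a single edge keeping the best (smallest) e-value.
#'
#' @param hits Hit tibble with `query_len` filled (see [add_hit_lengths()]).
#' @param config A [pipeline_config()] list.
#' @return A tibble of class `lgt_homology_graph` with columns `id1`, `id2`
#'   (lexicographically ordered pair), `pct_identity`, `coverage`, `evalue`.
#' @export
build_homology_graph <- function(hits, config = pipeline_config()) {
  stopifnot("query_len" %in% names(hits))
  edges <- hits |>
    dplyr::filter(
      .data$query_id != .data$subject_id,
      .data$pct_identity >= config$net_identity,
      .data$aln_len / .data$query_len >= config$net_coverage,
      .data$evalue <= config$net_evalue
    ) |>
    dplyr::mutate(
      id1 = pmin(.data$query_id, .data$subject_id),
      id2 = pmax(.data$query_id, .data$subject_id),
      coverage = .data$aln_len / .data$query_len
    ) |>
    dplyr::group_by(.data$id1, .data$id2) |>
    dplyr::arrange(.data$evalue, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("id1", "id2", "pct_identity", "coverage", "evalue")
  class(edges) <- c("lgt_homology_graph", class(edges))
  edges
}

#' Connected components of a homology network
#'
#' Splits the network into connected components (clusters). Vertices come
#' from the edge list plus any extra ids in `nodes`; ids in `nodes` without
#' edges form singleton components. Components are numbered deterministically
#' by their lexicographically smallest member.
#'
#' @param graph Edge tibble from [build_homology_graph()].
#' @param nodes Optional character vector of all node ids (to report
#'   singletons).
#' @return Tibble: `id`, `cluster` (integer), `cluster_size`.
#' @export
connected_components <- function(graph, nodes = NULL) {
  all_ids <- sort(unique(c(graph$id1, graph$id2, nodes)))
  if (!length(all_ids)) {
    return(tibble::tibble(id = character(), cluster = integer(),
                          cluster_size = integer()))
  }
  g <- igraph::graph_from_data_frame(
    graph[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = all_ids))
  comp <- igraph::components(g)
  memb <- comp$membership[all_ids]
  # renumber by smallest member id for determinism
  first_member <- tapply(all_ids, memb, min)
  new_id <- rank(first_member[as.character(sort(unique(memb)))],
                 ties.method = "first")
  names(new_id) <- sort(unique(memb))
  cluster <- as.integer(new_id[as.character(memb)])
  sizes <- table(cluster)
  tibble::tibble(id = all_ids, cluster = cluster,
                 cluster_size = as.integer(sizes[as.character(cluster)])) |>
    dplyr::arrange(.data$cluster, .data$id)
}

#' Build a phylogenetic tree for a protein cluster
#'
#' The built-in path computes Poisson-corrected pairwise distances,
#' `d = -ln(1 - p)` with `p` the per-site proportion of differences, over
#' equal-length (aligned) sequences, builds a neighbour-joining tree, and
#' attaches bootstrap support (percent of column-resampled replicates
#' recovering each internal bipartition) to internal nodes. Trees produced by
#' external likelihood software are the fidelity route and enter through
#' [read_newick()]; downstream results are identical given the same tree.
#'
#' @param proteins Tibble with `id` and `sequence`; at least 3 sequences of
#'   equal length.
#' @param bootstrap Number of bootstrap replicates (0 skips support).
#' @param seed RNG seed for bootstrap resampling.
#' @return An [ape::phylo] tree with branch lengths in substitutions/site and
#'   node labels holding percent support.
#' @export
build_tree <- function(proteins, bootstrap = 100L, seed = 1L) {
  if (nrow(proteins) < 3L) stop("need at least 3 sequences to build a tree")
  lens <- nchar(proteins$sequence)
  if (length(unique(lens)) != 1L) {
    stop("built-in tree path requires aligned (equal-length) sequences; ",
         "align externally or supply a Newick tree")
  }
  mat <- do.call(rbind, strsplit(proteins$sequence, ""))
  rownames(mat) <- proteins$id
  tree <- nj_from_chars(mat)
  if (bootstrap > 0L && nrow(proteins) > 3L) {
    with_seed(seed, {
      part <- ape::prop.part(tree)
      boots <- lapply(seq_len(bootstrap), function(b) {
        cols <- sample.int(ncol(mat), replace = TRUE)
        nj_from_chars(mat[, cols, drop = FALSE])
      })
      cl <- ape::prop.clades(tree, boots, rooted = FALSE)
      cl[is.na(cl)] <- 0L
      tree$node.label <- as.character(round(100 * cl / bootstrap))
      tree$node.label[1] <- ""  # root of the unrooted representation
    })
  } else if (bootstrap > 0L) {
    tree$node.label <- rep("", tree$Nnode)
  }
  tree
}

poisson_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(mat[i, ] != mat[j, ])
      d[i, j] <- d[j, i] <- -log(max(1 - p, 0.01))
    }
  }
  d
}

nj_from_chars <- function(mat) {
  d <- poisson_dist(mat)
  if (nrow(d) == 3L) {
    # three-point formula; ape::nj needs >= 4 taxa
    x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    txt <- sprintf("(%s:%.10f,%s:%.10f,%s:%.10f);",
                   rownames(d)[1], max(x, 0), rownames(d)[2], max(y, 0),
                   rownames(d)[3], max(z, 0))
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Extract well-supported subtrees below a size cap
#'
#' Recursively decomposes a supported tree into maximal clades whose support
#' is at least `subtree_support` (default 70 %) and whose leaf count is at
#' most `subtree_max_leaves` (default 200). Leaves not captured by any
#' supported clade form a residual that is re-cut at the next iteration
#' (optionally re-built first via `rebuild`); a region that cannot be split
#' is emitted whole with a warning. Support is read from node labels and
#' attaches to the child node of each edge; the input tree is treated as
#' rooted at its file root.
#'
#' @param tree An [ape::phylo] tree with numeric node labels (percent
#'   support); trees without supports raise an error pointing to the built-in
#'   bootstrap.
#' @param config A [pipeline_config()] list.
#' @param rebuild Optional `function(tip_ids, iteration)` returning a new
#'   supported tree for a residual set (the re-align/re-build hook); when
#'   `NULL` the residual subtree is re-cut as-is.
#' @return Tibble: `cluster` (int), `members` (list of tip ids), `n_leaves`,
#'   `provenance` (`"extracted_subtree"` or `"initial_component"`),
#'   `iteration`.
#' @export
extract_supported_subtrees <- function(tree, config = pipeline_config(),
                                       rebuild = NULL) {
  cap <- config$subtree_max_leaves
  thr <- config$subtree_support
  if (ape::Ntip(tree) > cap &&
      (is.null(tree$node.label) || !any(nzchar(tree$node.label)))) {
    stop("tree has no support values; build with build_tree() ",
         "(bootstrap > 0) or supply supports in the Newick node labels")
  }
  out <- list()
  emit <- function(members, provenance, iteration) {
    n <- length(members)
    out[[length(out) + 1L]] <<- tibble::tibble(
      members = list(members), n_leaves = n,
      provenance = provenance, iteration = iteration)
  }
  recurse <- function(tr, iteration, rebuilt) {
    ntip <- ape::Ntip(tr)
    if (ntip <= cap) {
      emit(tr$tip.label,
           if (iteration == 1L) "initial_component" else "extracted_subtree",
           iteration)
      return(invisible())
    }
    supp <- suppressWarnings(as.numeric(tr$node.label))
    good_nodes <- which(!is.na(supp) & supp >= thr) + ntip
    clades <- lapply(good_nodes, function(nd)
      ape::extract.clade(tr, nd)$tip.label)
    sizes <- lengths(clades)
    keep <- sizes >= 2L & sizes <= cap
    clades <- clades[keep]
    # maximal: drop clades nested inside another kept clade
    if (length(clades) > 1L) {
      nested <- vapply(seq_along(clades), function(i)
        any(vapply(seq_along(clades), function(j)
          i != j && all(clades[[i]] %in% clades[[j]]), logical(1))),
        logical(1))
      clades <- clades[!nested]
    }
    if (!length(clades)) {
      if (!is.null(rebuild) && !rebuilt) {
        recurse(rebuild(tr$tip.label, iteration + 1L), iteration + 1L, TRUE)
      } else {
        warning("clade of ", ntip, " leaves has no supported split below the ",
                cap, "-leaf cap; emitted whole")
        emit(tr$tip.label, "extracted_subtree", iteration)
      }
      return(invisible())
    }
    for (cl in clades) emit(cl, "extracted_subtree", iteration)
    residual <- setdiff(tr$tip.label, unlist(clades))
    if (length(residual) >= 2L) {
      sub <- if (!is.null(rebuild)) rebuild(residual, iteration + 1L)
             else ape::keep.tip(tr, residual)
      recurse(sub, iteration + 1L, FALSE)
    }
    invisible()
  }
  recurse(tree, 1L, FALSE)
  res <- dplyr::bind_rows(out)
  res$cluster <- seq_len(nrow(res))
  dplyr::select(res, "cluster", dplyr::everything())
}

#' Patristic distances between all leaf pairs
#'
#' The patristic distance between two leaves is the sum of branch lengths
#' along the unique path connecting them, in substitutions per site.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A symmetric matrix (leaf x leaf) with zero diagonal, leaf ids as
#'   dimnames.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::dist.nodes(tree)[seq_len(ape::Ntip(tree)), seq_len(ape::Ntip(tree))]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Call phylogenetic incongruence from nearest patristic neighbours
#'
#' For each community (non-reference) leaf, finds the nearest neighbour by
#' patristic distance among leaves of the same community and reference
#' leaves. An undirected transfer call is emitted when the neighbour's
#' taxonomic class differs from the focal leaf's and the patristic distance
#' is below `patristic_cutoff` (default 0.3 substitutions/site; the cutoff
#' applies to the patristic distance). Out-of-class nearest neighbours beyond
#' the cutoff are tallied but not called. Ties on distance are broken
#' lexicographically by leaf id. Leaves missing a class are excluded with a
#' warning.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param leaf_info Tibble with `id`, `class`, `origin` (community label or
#'   `"reference"`), one row per leaf.
#' @param config A [pipeline_config()] list.
#' @return A neighbour report of class `lgt_neighbor_report`: one row per
#'   community leaf with `focal_id`, `focal_class`, `origin`,
#'   `nearest_same_id`, `nearest_same_dist`, `nearest_ref_id`,
#'   `nearest_ref_dist`, `nearest_id`, `nearest_class`, `distance`,
#'   `out_of_class`, `call`.
#' @export
call_incongruent_leaves <- function(tree, leaf_info,
                                    config = pipeline_config()) {
  missing_cls <- tree$tip.label[!(tree$tip.label %in%
                                    leaf_info$id[!is.na(leaf_info$class)])]
  if (length(missing_cls)) {
    warning("leaves without a class excluded: ",
            paste(missing_cls, collapse = ", "))
  }
  info <- leaf_info[match(tree$tip.label, leaf_info$id), ]
  keep <- !is.na(info$class)
  d <- patristic_distances(tree)
  focal_ids <- tree$tip.label[keep & !is.na(info$origin) &
                                info$origin != "reference"]
  rows <- lapply(focal_ids, function(f) {
    forigin <- info$origin[match(f, info$id)]
    fclass <- info$class[match(f, info$id)]
    nearest_in <- function(cands) {
      cands <- setdiff(cands, f)
      if (!length(cands)) return(list(id = NA_character_, dist = NA_real_))
      dd <- d[f, cands]
      ord <- order(dd, cands)
      list(id = cands[ord[1]], dist = unname(dd[ord[1]]))
    }
    same <- nearest_in(info$id[keep & info$origin == forigin])
    ref <- nearest_in(info$id[keep & info$origin == "reference"])
    cand <- dplyr::bind_rows(
      tibble::tibble(id = same$id, dist = same$dist),
      tibble::tibble(id = ref$id, dist = ref$dist))
    cand <- cand[!is.na(cand$id), ]
    if (!nrow(cand)) return(NULL)
    cand <- cand[order(cand$dist, cand$id), ]
    ncls <- info$class[match(cand$id[1], info$id)]
    tibble::tibble(
      focal_id = f, focal_class = fclass, origin = forigin,
      nearest_same_id = same$id, nearest_same_dist = same$dist,
      nearest_ref_id = ref$id, nearest_ref_dist = ref$dist,
      nearest_id = cand$id[1], nearest_class = ncls,
      distance = cand$dist[1],
      out_of_class = ncls != fclass,
      call = ncls != fclass & cand$dist[1] < config$patristic_cutoff
    )
  })
  rep <- dplyr::bind_rows(rows)
  if (nrow(rep)) rep <- dplyr::arrange(rep, .data$focal_id)
  class(rep) <- c("lgt_neighbor_report", class(rep))
  rep
}

#' @method glance lgt_neighbor_report
#' @export
glance.lgt_neighbor_report <- function(x, ...) {
  tibble::tibble(
    n_leaves = nrow(x),
    n_called = sum(x$call),
    n_out_of_class_over_cutoff = sum(x$out_of_class & !x$call)
  )
}

#' Convert a neighbour report into undirected transfer calls
#'
#' @param report An `lgt_neighbor_report` from [call_incongruent_leaves()].
#' @param contig_of Optional named character vector mapping focal ids to
#'   contig ids.
#' @return An `lgt_calls` tibble with `method = "phylogenetic"`; the
#'   partnership is undirected (`partner_class` holds the neighbour's class,
#'   `recipient_class` the focal sequence's own class, `donor_class` is `NA`).
#' @export
incongruence_calls <- function(report, contig_of = NULL) {
  called <- report[report$call, ]
  if (!nrow(called)) return(empty_calls())
  new_calls(tibble::tibble(
    orf_id = called$focal_id,
    contig_id = if (is.null(contig_of)) NA_character_
                else unname(contig_of[called$focal_id]),
    method = "phylogenetic",
    donor_class = NA_character_,
    recipient_class = called$focal_class,
    partner_class = called$nearest_class,
    nb_improvement = NA_real_,
    patristic_distance = called$distance,
    orf_group = NA_character_,
    contig_group = NA_character_,
    mge_supported = FALSE,
    mobility_adjacent = FALSE
  ))
}
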