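#' Functional annotation from top protein hits
#'
#' Annotates each ORF with its best-e-value reference hit that passes all
#' three published rules: at least 60 % of the predicted protein aligned, an
#' e-value of 1e-5 or smaller, and neither sequence more than 1.2 times the
#' length of the other. Ties on e-value are broken by bit score, then subject
#' id. ORFs with no passing hit are absent from the result.
#'
#' @param orfs ORF tibble (see [read_orf_table()]); protein lengths are taken
#'   from the `protein` column.
#' @param hits Protein-level hit tibble whose `query_id` matches `orf_id`.
#' @param subject_info Tibble describing the reference proteins: `id`,
#'   `length` (aa), and optional `ec_number`, `product` carried onto the
#'   annotation.
#' @param config A [pipeline_config()] list.
#' @return Tibble: `orf_id`, `reference_id`, `ec_number`, `product`,
#'   `pct_query_aligned`, `evalue`, `len_ratio`.
#' @export
annotate_functions <- function(orfs, hits, subject_info,
                               config = pipeline_config()) {
  qlen <- nchar(orfs$protein)[match(hits$query_id, orfs$orf_id)]
  slen <- subject_info$length[match(hits$subject_id, subject_info$id)]
  cand <- hits |>
    dplyr::mutate(
      query_len = qlen, subject_len = slen,
      pct_query_aligned = .data$aln_len / .data$query_len,
      len_ratio = pmax(.data$query_len, .data$subject_len) /
        pmin(.data$query_len, .data$subject_len)
    ) |>
    dplyr::filter(
      .data$evalue <= config$annot_evalue,
      .data$pct_query_aligned >= config$annot_coverage,
      .data$len_ratio <= config$annot_len_ratio
    )
  ann <- cand |>
    dplyr::group_by(orf_id = .data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  extra <- function(col) {
    if (col %in% names(subject_info)) {
      subject_info[[col]][match(ann$subject_id, subject_info$id)]
    } else NA_character_
  }
  tibble::tibble(
    orf_id = ann$orf_id,
    reference_id = ann$subject_id,
    ec_number = extra("ec_number"),
    product = extra("product"),
    pct_query_aligned = ann$pct_query_aligned,
    evalue = ann$evalue,
    len_ratio = ann$len_ratio
  )
}

#' Equal-e-value out-of-class screen (reference-genome self-screen)
#'
#' Flags query sequences that have at least one hit outside their home class
#' whose e-value equals the best overall hit's e-value and whose alignment
#' covers at least `min_coverage` of the query — the screen applied to a
#' closed reference genome against a genome panel to surface recently
#' acquired genes.
#'
#' @param hits Hit tibble with `subject_class` and `query_len` filled (see
#'   [add_hit_lengths()]).
#' @param home_class Taxonomic class of the query genome.
#' @param min_coverage Minimum fraction of the query covered by the
#'   out-of-class alignment (default 0.60; coverage is measured on the query).
#' @return Character vector of flagged query ids.
#' @export
screen_equal_evalue_out_of_class <- function(hits, home_class,
                                             min_coverage = 0.60) {
  stopifnot("query_len" %in% names(hits))
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(flagged = {
      best_e <- min(.data$evalue)
      any(!is.na(.data$subject_class) &
            .data$subject_class != home_class &
            .data$evalue == best_e &
            .data$aln_len / .data$query_len >= min_coverage)
    }, .groups = "drop") |>
    dplyr::filter(.data$flagged) |>
    dplyr::pull("query_id")
}

#' Mobile-genetic-element homology filter
#'
#' Keeps candidate ORFs with at least one hit to the MGE database satisfying
#' all three published conditions simultaneously: e-value at most 1e-30, MGE
#' sequence from a different taxonomic class than the ORF, and an alignment
#' covering at least 60 % of the query ORF and 60 % of the subject MGE
#' sequence. Hits lacking a subject length are skipped with a warning.
#'
#' @param candidate_ids Character vector of candidate ORF ids.
#' @param mge_hits Hit tibble against the MGE database with `subject_class`,
#'   `query_len` and `subject_len` columns (see [add_hit_lengths()]).
#' @param orf_classes Tibble (`orf_id`, `class`) giving each candidate's
#'   taxonomic class.
#' @param config A [pipeline_config()] list.
#' @return The surviving subset of `candidate_ids` (original order).
#' @export
mge_homology_filter <- function(candidate_ids, mge_hits, orf_classes,
                                config = pipeline_config()) {
  if (!nrow(mge_hits)) return(character())
  if (anyNA(mge_hits$subject_len)) {
    warning(sum(is.na(mge_hits$subject_len)),
            " MGE hit(s) lack a subject length; skipped")
    mge_hits <- dplyr::filter(mge_hits, !is.na(.data$subject_len))
  }
  qclass <- orf_classes$class[match(mge_hits$query_id, orf_classes$orf_id)]
  pass <- mge_hits$evalue <= config$mge_evalue &
    !is.na(mge_hits$subject_class) & !is.na(qclass) &
    mge_hits$subject_class != qclass &
    mge_hits$aln_len >= config$mge_coverage * mge_hits$query_len &
    mge_hits$aln_len >= config$mge_coverage * mge_hits$subject_len
  supported <- unique(mge_hits$query_id[pass])
  candidate_ids[candidate_ids %in% supported]
}

#' Map reads back to contigs
#'
#' Aligns every read against every contig (both strands) with the built-in
#' local aligner and retains alignments in which at least `read_coverage`
#' (default 70 %) of the read aligns at an e-value of at most `read_evalue`
#' (default 1e-30). A read may map to several contigs.
#'
#' @param reads Tibble with `id`, `sequence`.
#' @param contigs Contig tibble with `id`, `sequence`.
#' @param config A [pipeline_config()] list.
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (as in
#'   [local_align()]).
#' @param K,lambda Karlin-Altschul constants for the e-value.
#' @return Tibble: `read_id`, `contig_id`, `c_start`, `c_end` (contig
#'   coordinates of the alignment), `strand`, `read_coverage`, `evalue`.
#' @export
map_reads_to_contigs <- function(reads, contigs, config = pipeline_config(),
                                 match = 2, mismatch = -3, gap_open = 5,
                                 gap_extend = 2, K = 0.13, lambda = 0.32) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  fwd <- Biostrings::DNAStringSet(reads$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  read_len <- nchar(reads$sequence)
  res <- purrr::map_dfr(seq_len(nrow(contigs)), function(j) {
    subj <- Biostrings::DNAString(contigs$sequence[j])
    one_strand <- function(set, strand) {
      pa <- Biostrings::pairwiseAlignment(
        set, subj, type = "local", substitutionMatrix = submat,
        gapOpening = gap_open, gapExtension = gap_extend)
      s <- Biostrings::score(pa)
      tibble::tibble(
        read_id = reads$id, contig_id = contigs$id[j],
        c_start = pa@subject@range@start,
        c_end = pa@subject@range@start + pa@subject@range@width - 1L,
        strand = strand,
        score = s,
        read_coverage = Biostrings::nchar(pa) / read_len,
        evalue = K * read_len * nchar(contigs$sequence[j]) * exp(-lambda * s)
      )
    }
    both <- dplyr::bind_rows(one_strand(fwd, "+"), one_strand(rev, "-"))
    # keep the better orientation per read
    both |>
      dplyr::group_by(.data$read_id) |>
      dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup() |>
      dplyr::select(-"score")
  })
  dplyr::filter(res, .data$read_coverage >= config$read_coverage,
                .data$evalue <= config$read_evalue)
}

#' Classify read alignments relative to a putatively transferred ORF
#'
#' Each retained read mapping that overlaps the focal ORF is classified by
#' how its contig-coordinate span relates to the ORF and its neighbours:
#'
#' * `into_neighbor` — overlaps the focal ORF and at least 1 nt of another
#'   ORF on the contig;
#' * `full_orf` — covers the entire focal ORF;
#' * `intergenic_bounded` — extends beyond the focal ORF on at least one side
#'   but every such end terminates in intergenic sequence;
#' * `partial` — lies entirely within the focal ORF.
#'
#' Classes are mutually exclusive and exhaustive for overlapping alignments,
#' in that precedence order.
#'
#' @param mapped_reads Output of [map_reads_to_contigs()].
#' @param orfs ORF tibble for the contig(s) involved.
#' @param focal_orf_id Id of the putatively transferred ORF.
#' @return Tibble: `read_id`, `contig_id`, `orf_id`, `span_class`.
#' @export
classify_read_spans <- function(mapped_reads, orfs, focal_orf_id) {
  focal <- orfs[orfs$orf_id == focal_orf_id, ]
  if (nrow(focal) != 1L) stop("focal ORF '", focal_orf_id, "' not found")
  neighbors <- orfs[orfs$contig_id == focal$contig_id &
                      orfs$orf_id != focal_orf_id, ]
  on_contig <- mapped_reads[mapped_reads$contig_id == focal$contig_id, ]
  overlaps <- on_contig$c_start <= focal$end & on_contig$c_end >= focal$start
  on_contig <- on_contig[overlaps, ]
  if (!nrow(on_contig)) {
    return(tibble::tibble(read_id = character(), contig_id = character(),
                          orf_id = character(), span_class = character()))
  }
  span_class <- vapply(seq_len(nrow(on_contig)), function(i) {
    a <- c(on_contig$c_start[i], on_contig$c_end[i])
    hits_neighbor <- nrow(neighbors) > 0 &&
      any(a[1] <= neighbors$end & a[2] >= neighbors$start)
    if (hits_neighbor) return("into_neighbor")
    if (a[1] <= focal$start && a[2] >= focal$end) return("full_orf")
    if (a[1] < focal$start || a[2] > focal$end) return("intergenic_bounded")
    "partial"
  }, character(1))
  tibble::tibble(read_id = on_contig$read_id, contig_id = on_contig$contig_id,
                 orf_id = focal_orf_id, span_class = span_class)
}
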