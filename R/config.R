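#' Pipeline configuration
#'
#' Builds the list of thresholds that drive every filter in the pipeline.
#' Defaults are the published operating point of the method:
#'
#' * `min_contig_len` — contigs shorter than this (nt) are discarded before
#'   classification (default 1000).
#' * `nb_improvement` — minimum relative improvement of the ORF's naive-Bayes
#'   composition score over the contig-class score for a discordance call
#'   (default 0.15).
#' * `group2_order_gap` — orders of magnitude separating the best homology
#'   e-value from the best different-class e-value for a Group II assignment
#'   (default 10).
#' * `group3_ratio` — naive-Bayes likelihood ratio (best class vs runner-up)
#'   for a Group III assignment (default 1.5), applied to total likelihoods.
#' * `net_identity`, `net_coverage`, `net_evalue` — homology-network edge
#'   admission: percent identity >= 70, query coverage >= 0.60, e <= 1e-5.
#' * `subtree_support`, `subtree_max_leaves` — supported-subtree extraction:
#'   support >= 70 %, iterate until subtrees hold <= 200 leaves.
#' * `patristic_cutoff` — maximum patristic distance (substitutions/site) to an
#'   out-of-class nearest neighbour for an incongruence call (default 0.3).
#' * `mge_evalue`, `mge_coverage` — MGE screen: e <= 1e-30 and alignment
#'   covering >= 60 % of both query and subject.
#' * `annot_evalue`, `annot_coverage`, `annot_len_ratio` — functional
#'   annotation: e <= 1e-5, >= 60 % of the query aligned, neither sequence
#'   more than 1.2 times the length of the other.
#' * `read_coverage`, `read_evalue` — read validation: >= 70 % of the read
#'   aligned at e <= 1e-30.
#' * `kmer_order` — k-mer length of the composition models (default 4, i.e. an
#'   order-3 Markov chain over nucleotides).
#' * `rng_seed` — seed used by pipeline-level simulation stages.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `lgt_config`.
#' @examples
#' cfg <- pipeline_config(patristic_cutoff = 0.25)
#' cfg$patristic_cutoff
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_contig_len    = 1000L,
    nb_improvement    = 0.15,
    group2_order_gap  = 10,
    group3_ratio      = 1.5,
    net_identity      = 70,
    net_coverage      = 0.60,
    net_evalue        = 1e-5,
    subtree_support   = 70,
    subtree_max_leaves = 200L,
    patristic_cutoff  = 0.3,
    mge_evalue        = 1e-30,
    mge_coverage      = 0.60,
    annot_evalue      = 1e-5,
    annot_coverage    = 0.60,
    annot_len_ratio   = 1.2,
    read_coverage     = 0.70,
    read_evalue       = 1e-30,
    kmer_order        = 4L,
    rng_seed          = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "lgt_config")
}

validate_config <- function(cfg) {
  fracs <- c("nb_improvement", "net_coverage", "mge_coverage",
             "annot_coverage", "read_coverage")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("configuration field '", f, "' must be a fraction in (0, 1]")
    }
  }
  if (cfg$min_contig_len < 1) stop("min_contig_len must be >= 1")
  if (cfg$kmer_order < 1) stop("kmer_order must be >= 1")
  if (cfg$patristic_cutoff <= 0) stop("patristic_cutoff must be positive")
  if (cfg$group3_ratio <= 1) stop("group3_ratio must exceed 1")
  invisible(cfg)
}

#' Read a JSON configuration file
#'
#' Reads a JSON object whose fields override [pipeline_config()] defaults.
#' Fields absent from the file keep their defaults.
#'
#' @param path Path to a JSON file.
#' @return An `lgt_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, as.list(overrides))
}

#' @export
print.lgt_config <- function(x, ...) {
  cat("<lgt_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Floor for zero e-values so order-of-magnitude arithmetic stays defined.
EVALUE_FLOOR <- 1e-200
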