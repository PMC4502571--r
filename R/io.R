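#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence`, in file order. An empty file yields zero rows.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a contig", "ACGT", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  first <- readLines(path, n = 1L)
  if (!startsWith(trimws(first), ">")) {
    stop("malformed FASTA at line 1 of '", path, "': expected '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  tibble::tibble(id = ids, sequence = unname(as.character(set)))
}

#' Write a tibble of sequences to FASTA
#'
#' @param seqs A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a contig table
#'
#' Validates sequences over \{A,C,G,T,N\} and derives lengths. Ambiguous `N`
#' bases are permitted; composition scoring skips k-mers containing them.
#'
#' @param seqs Tibble with `id`, `sequence` (e.g. from [read_fasta()]).
#' @param community Community label stored with every contig (e.g. `"AU"`).
#' @return Tibble with `id`, `sequence`, `community`, `length`.
#' @export
as_contigs <- function(seqs, community = "community") {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  if (anyDuplicated(seqs$id)) stop("contig ids must be unique within a community")
  bad <- grepl("[^ACGTN]", seqs$sequence)
  if (any(bad)) {
    stop("contig '", seqs$id[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  }
  tibble::tibble(
    id = seqs$id,
    sequence = seqs$sequence,
    community = community,
    length = nchar(seqs$sequence)
  )
}

hit_columns <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatch", "gapopen", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Read a 12-column tabular homology hit file
#'
#' Ingests the standard 12-column tab-separated local-alignment output dialect
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' query/subject coordinates, e-value, bit score). Additional columns are
#' ignored.
#'
#' @param path Path to the tab-separated hit file.
#' @param taxonomy Optional taxonomy tibble (`id`, `class`); when supplied,
#'   `subject_class` is filled for mapped subject ids and left `NA` otherwise.
#' @return A tibble of alignment hits, one row per input row.
#' @export
read_hit_table <- function(path, taxonomy = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    hits <- tibble::as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), hit_columns))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nfield <- lengths(fields)
    if (any(nfield < 12L)) {
      stop("hit table parse error at row ", which(nfield < 12L)[1],
           ": expected 12 tab-separated columns, found ", nfield[nfield < 12L][1])
    }
    m <- t(vapply(fields, function(f) f[1:12], character(12)))
    hits <- tibble::tibble(
      query_id = m[, 1], subject_id = m[, 2],
      pct_identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
      mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
      q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
      s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
      evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
    )
    if (anyNA(hits$evalue) || anyNA(hits$pct_identity)) {
      stop("hit table parse error at row ",
           which(is.na(hits$evalue) | is.na(hits$pct_identity))[1],
           ": non-numeric value in a numeric column")
    }
  }
  hits$subject_class <- if (is.null(taxonomy)) {
    NA_character_
  } else {
    taxonomy$class[match(hits$subject_id, taxonomy$id)]
  }
  hits
}

#' Write hits in the 12-column tabular dialect
#'
#' @param hits Tibble with the columns produced by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, hit_columns]
  out$evalue <- formatC(out$evalue, format = "e", digits = 2)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a two-column taxonomy map
#'
#' @param path Tab-separated file: sequence/genome id, class label. A header
#'   row is not expected.
#' @return Tibble with `id` and `class`.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_names = c("id", "class"),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  tx
}

#' @rdname read_taxonomy
#' @param taxonomy Tibble with `id` and `class`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy[, c("id", "class")], path, col_names = FALSE)
  invisible(path)
}

orf_columns <- c("orf_id", "contig_id", "start", "end", "strand",
                 "protein", "ec_number", "product")

#' Read and write ORF call tables
#'
#' ORF coordinates follow the GFF3 convention: 1-based, inclusive, with
#' `start <= end` on both strands and `strand` in `{+,-}`. The table carries
#' the translated protein and optional EC number / product text.
#'
#' @param path Tab-separated file with columns `orf_id`, `contig_id`, `start`,
#'   `end`, `strand`, `protein`, `ec_number`, `product` (header required).
#' @return A tibble of ORF records.
#' @export
read_orf_table <- function(path) {
  orfs <- readr::read_tsv(path, col_types = readr::cols(
    orf_id = readr::col_character(), contig_id = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer(),
    strand = readr::col_character(), protein = readr::col_character(),
    ec_number = readr::col_character(), product = readr::col_character()
  ), progress = FALSE)
  validate_orfs(orfs)
  orfs
}

#' @rdname read_orf_table
#' @param orfs A tibble of ORF records.
#' @export
write_orf_table <- function(orfs, path) {
  readr::write_tsv(orfs[, orf_columns], path)
  invisible(path)
}

validate_orfs <- function(orfs, contigs = NULL) {
  stopifnot(all(c("orf_id", "contig_id", "start", "end", "strand") %in% names(orfs)))
  if (any(orfs$start > orfs$end)) {
    stop("ORF '", orfs$orf_id[which(orfs$start > orfs$end)[1]], "' has start > end")
  }
  if (!all(orfs$strand %in% c("+", "-"))) stop("ORF strand must be '+' or '-'")
  if (!is.null(contigs)) {
    len <- contigs$length[match(orfs$contig_id, contigs$id)]
    bad <- is.na(len) | orfs$start < 1L | orfs$end > len
    if (any(bad)) {
      stop("ORF '", orfs$orf_id[which(bad)[1]], "' lies outside its parent contig")
    }
  }
  invisible(orfs)
}

#' Read a Newick tree
#'
#' Branch supports are carried as node labels; omitted branch lengths are set
#' to 0 with a warning. Round-tripping through [write_newick()] preserves
#' topology, branch lengths (>= 6 significant digits) and support labels.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  if (is.null(tree$edge.length)) {
    warning("tree in '", path, "' has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree in '", path, "' omits some branch lengths; treating them as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' Length-filter contigs
#'
#' Keeps exactly the contigs whose length is at least `min_len` nucleotides
#' (the published pipeline retains contigs of at least 1000 nt). Idempotent
#' and order-preserving.
#'
#' @param contigs Contig tibble (see [as_contigs()]).
#' @param min_len Minimum retained length in nt.
#' @return The retained rows of `contigs`.
#' @export
filter_contigs_by_length <- function(contigs, min_len = 1000L) {
  stopifnot(min_len >= 1)
  dplyr::filter(contigs, .data$length >= min_len)
}

#' Read an EC-to-pathway table
#'
#' @param path Tab-separated file with header columns `ec_number` and
#'   `pathway`; one row per (EC, pathway) membership. A toy table covering six
#'   energy-related KEGG pathways (BM, CAC, GG, PPP, PM, NM) ships with the
#'   package, see `system.file("extdata", "ec_pathways.tsv", package = "lgtscout")`.
#' @return Tibble with `ec_number` and `pathway`.
#' @export
read_ec_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    ec_number = readr::col_character(), pathway = readr::col_character()
  ), progress = FALSE)
}
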