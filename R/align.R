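#' Optimal local alignment with Karlin-Altschul e-values
#'
#' Smith-Waterman local alignment (affine gaps) of one query against one
#' subject, reported as a one-row hit table compatible with
#' [read_hit_table()]. E-values follow the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with fixed constants (defaults
#' `K = 0.13`, `lambda = 0.32`, suited to the default +2/-3 nucleotide
#' scoring); bit scores are `(lambda * S - ln K) / ln 2`. A gap of length L
#' costs `gap_open + L * gap_extend`.
#'
#' @param query,subject Non-empty sequence strings. Protein input is detected
#'   from the alphabet (or forced with `type = "protein"`) and scored with
#'   BLOSUM62.
#' @param match,mismatch Nucleotide match/mismatch scores.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param both_strands Also align the reverse complement of the query and keep
#'   the better orientation (nucleotide only).
#' @param K,lambda Karlin-Altschul constants.
#' @param type `"auto"`, `"nucleotide"` or `"protein"`.
#' @return A one-row tibble with the 12 standard hit columns plus `strand`
#'   (`"+"` or `"-"`: orientation of the query in the reported alignment) and
#'   `score` (raw Smith-Waterman score).
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2, both_strands = FALSE,
                        K = 0.13, lambda = 0.32, type = "auto") {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence in local_align")
  if (type == "auto") {
    type <- if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", subject)) {
      "protein"
    } else "nucleotide"
  }
  if (type == "protein") {
    submat <- get_blosum62()
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    best <- pa
    strand <- "+"
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    align1 <- function(q) Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    fwd <- align1(query)
    best <- fwd
    strand <- "+"
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(query)))
      rev <- align1(rc)
      if (Biostrings::score(rev) > Biostrings::score(fwd)) {
        best <- rev
        strand <- "-"
      }
    }
  }
  s <- Biostrings::score(best)
  qa <- as.character(Biostrings::alignedPattern(best))
  sa <- as.character(Biostrings::alignedSubject(best))
  aln_len <- nchar(qa)
  qc <- strsplit(qa, "")[[1]]
  sc <- strsplit(sa, "")[[1]]
  n_ident <- sum(qc == sc & qc != "-")
  gapopen <- count_gap_openings(qc) + count_gap_openings(sc)
  m <- nchar(query)
  n <- nchar(subject)
  ev <- K * m * n * exp(-lambda * s)
  tibble::tibble(
    query_id = "query", subject_id = "subject",
    pct_identity = 100 * n_ident / aln_len,
    aln_len = aln_len,
    mismatch = sum(qc != sc & qc != "-" & sc != "-"),
    gapopen = gapopen,
    q_start = best@pattern@range@start,
    q_end = best@pattern@range@start + best@pattern@range@width - 1L,
    s_start = best@subject@range@start,
    s_end = best@subject@range@start + best@subject@range@width - 1L,
    evalue = ev,
    bitscore = (lambda * s - log(K)) / log(2),
    subject_class = NA_character_,
    strand = strand,
    score = s
  )
}

count_gap_openings <- function(chars) {
  r <- rle(chars == "-")
  sum(r$values)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Attach query/subject sequence lengths to a hit table
#'
#' Several published filters are expressed as fractions of the query or
#' subject length; this helper joins those lengths onto a hit table.
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param query_seqs,subject_seqs Tibbles with `id` and either `sequence` or
#'   `length`; `NULL` leaves the corresponding column untouched/absent.
#' @return `hits` with `query_len` and/or `subject_len` columns added.
#' @export
add_hit_lengths <- function(hits, query_seqs = NULL, subject_seqs = NULL) {
  len_of <- function(df) {
    if ("length" %in% names(df)) df$length else nchar(df$sequence)
  }
  if (!is.null(query_seqs)) {
    hits$query_len <- len_of(query_seqs)[match(hits$query_id, query_seqs$id)]
  }
  if (!is.null(subject_seqs)) {
    hits$subject_len <- len_of(subject_seqs)[match(hits$subject_id,
                                                   subject_seqs$id)]
  }
  hits
}
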