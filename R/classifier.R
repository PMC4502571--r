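#' Train a k-mer naive-Bayes composition model for one taxonomic class
#'
#' Fits an order-(k-1) Markov chain over nucleotides: for every (k-1)-mer
#' context the conditional probability of the next base is estimated as
#' `(count + pseudocount) / (context_total + 4 * pseudocount)`. Both strands
#' of every training sequence are counted, so models are reverse-complement
#' symmetric by construction. k-mers containing `N` are skipped.
#'
#' @param sequences Character vector of training nucleotide sequences (or a
#'   tibble with a `sequence` column).
#' @param class_label Taxonomic class the model represents.
#' @param k K-mer length (>= 1); `k = 1` is a base-composition model.
#' @param pseudocount Additive smoothing count; with no data for a context and
#'   a positive pseudocount the conditional distribution is uniform.
#' @return An object of class `kmer_class_model`: a list with `class_label`,
#'   `k`, `pseudocount` and a `log_probs` matrix (contexts x A,C,G,T; natural
#'   log).
#' @examples
#' m <- train_class_model(c("ACGTACGTAC"), "X", k = 2)
#' rowSums(exp(m$log_probs))  # each context normalises to 1
#' @export
train_class_model <- function(sequences, class_label, k = 4L, pseudocount = 1) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- sequences[nzchar(sequences)]
  if (!length(sequences) || sum(nchar(sequences)) == 0) {
    stop("empty training set for class '", class_label, "'")
  }
  stopifnot(k >= 1)
  dna <- Biostrings::DNAStringSet(sequences)
  both <- c(dna, Biostrings::reverseComplement(dna))
  counts <- colSums(Biostrings::oligonucleotideFrequency(both, width = k))
  # oligonucleotideFrequency orders k-mers with the last base varying fastest
  mat <- matrix(counts, ncol = 4L, byrow = TRUE)
  colnames(mat) <- c("A", "C", "G", "T")
  rownames(mat) <- if (k == 1L) "" else {
    unique(substr(names(counts), 1L, k - 1L))
  }
  totals <- rowSums(mat) + 4 * pseudocount
  probs <- (mat + pseudocount) / totals
  # contexts never observed under zero smoothing: uniform (they are unscorable
  # from data; this keeps every row a proper distribution)
  empty <- rowSums(mat) == 0 & pseudocount == 0
  probs[empty, ] <- 0.25
  structure(
    list(class_label = class_label, k = as.integer(k),
         pseudocount = pseudocount, log_probs = log(probs)),
    class = "kmer_class_model"
  )
}

#' @export
print.kmer_class_model <- function(x, ...) {
  cat(sprintf("<kmer_class_model> class '%s', k = %d, %d contexts\n",
              x$class_label, x$k, nrow(x$log_probs)))
  invisible(x)
}

kmer_log_vector <- function(model) {
  # log p for every k-mer, in oligonucleotideFrequency order
  as.vector(t(model$log_probs))
}

#' Score a sequence under a composition model
#'
#' Returns the mean per-base natural-log likelihood of the sequence under the
#' model: the sum of log conditional probabilities over all k-mer windows
#' divided by the number of scored windows. Windows containing `N` are
#' skipped. Unoriented sequences (contigs) can be scored on both strands,
#' keeping the better one.
#'
#' @param model A `kmer_class_model`.
#' @param sequence A nucleotide string of length >= k.
#' @param both_strands Score the reverse complement too and return the max?
#'   Use `TRUE` for unoriented contigs, `FALSE` (default) for oriented ORFs.
#' @return Mean per-base log-likelihood (natural log / nt), with attribute
#'   `n_scored` giving the number of scored positions.
#' @export
score_sequence <- function(model, sequence, both_strands = FALSE) {
  k <- model$k
  if (nchar(sequence) < k) {
    stop("sequence shorter than k = ", k, "; cannot score")
  }
  score_one <- function(s) {
    counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                                   width = k)
    n <- sum(counts)
    if (n == 0) return(c(NA_real_, 0))
    lv <- kmer_log_vector(model)
    used <- counts > 0  # avoid 0 * -Inf for zero-probability k-mers
    c(sum(counts[used] * lv[used]) / n, n)
  }
  fwd <- score_one(sequence)
  if (both_strands) {
    rev <- score_one(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sequence))))
    res <- if (is.na(rev[1]) || (!is.na(fwd[1]) && fwd[1] >= rev[1])) fwd else rev
  } else {
    res <- fwd
  }
  if (is.na(res[1])) stop("no scorable k-mers (all windows contain N)")
  structure(res[1], n_scored = as.integer(res[2]))
}

#' Composition-score sequences against a set of class models
#'
#' @param seqs Tibble with `id` and `sequence` columns (contigs or ORF
#'   nucleotide sequences), or a named character vector.
#' @param models List of `kmer_class_model` objects (>= 2), one per class.
#' @param both_strands Passed to [score_sequence()]; `TRUE` for contigs.
#' @return A long tibble: `sequence_id`, `class`, `score` (mean per-base log
#'   likelihood), `n_scored`.
#' @export
classify_composition <- function(seqs, models, both_strands = FALSE) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble::tibble(id = names(seqs), sequence = unname(seqs))
  }
  stopifnot(length(models) >= 2)
  purrr::map_dfr(models, function(m) {
    sc <- lapply(seqs$sequence, function(s)
      score_sequence(m, s, both_strands = both_strands))
    tibble::tibble(
      sequence_id = seqs$id,
      class = m$class_label,
      score = vapply(sc, as.numeric, numeric(1)),
      n_scored = vapply(sc, attr, integer(1), "n_scored")
    )
  })
}

#' Best and runner-up composition class per sequence
#'
#' Ties on score are broken lexicographically by class name, with a warning.
#'
#' @param scores Long score tibble from [classify_composition()].
#' @return One row per sequence: `sequence_id`, `best_class`, `best_score`,
#'   `runner_up_class`, `runner_up_score`, `n_scored`.
#' @export
composition_best <- function(scores) {
  ranked <- scores |>
    dplyr::group_by(.data$sequence_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$class, .by_group = TRUE) |>
    dplyr::summarise(
      best_class = .data$class[1], best_score = .data$score[1],
      runner_up_class = .data$class[2], runner_up_score = .data$score[2],
      n_scored = .data$n_scored[1],
      tied = sum(.data$score == .data$score[1]) > 1L,
      .groups = "drop"
    )
  if (any(ranked$tied)) {
    warning("composition score tie for ",
            paste(ranked$sequence_id[ranked$tied], collapse = ", "),
            "; broken lexicographically by class name")
  }
  dplyr::select(ranked, -"tied")
}

#' Assign four-tier confidence groups from homology and composition evidence
#'
#' Each sequence is assigned to the first satisfied tier:
#'
#' * **Group I** — the homology-based class equals the composition-based class.
#' * **Group II** — the best homology e-value is at least `group2_order_gap`
#'   (default 10) orders of magnitude smaller than the best hit from a
#'   different class (zero e-values are floored at 1e-200).
#' * **Group III** — the naive-Bayes likelihood of the best class is at least
#'   `group3_ratio` (default 1.5) times the runner-up class's likelihood,
#'   evaluated on total log-likelihoods: `totalL_best - totalL_runner >=
#'   log(group3_ratio)`.
#' * **Group IV** — fallback: the best naive-Bayes likelihood alone.
#'
#' The predicted class is the homology class for Groups I-II and the
#' composition-best class for Groups III-IV.
#'
#' @param scores Long score tibble from [classify_composition()].
#' @param hits Optional alignment-hit tibble (see [read_hit_table()]) whose
#'   `query_id` matches `scores$sequence_id` and whose `subject_class` is
#'   filled; hits without a class are ignored.
#' @param config An [pipeline_config()] list.
#' @return One row per sequence: `sequence_id`, `predicted_class`,
#'   `confidence_group` (`"I"`..`"IV"`), `homology_class`, `homology_evalue`,
#'   plus the [composition_best()] columns.
#' @export
assign_confidence_groups <- function(scores, hits = NULL,
                                     config = pipeline_config()) {
  comp <- composition_best(scores)
  hom <- homology_summary(hits)
  res <- dplyr::left_join(comp, hom, by = "sequence_id")
  lr <- log(config$group3_ratio)
  total_gap <- (res$best_score - res$runner_up_score) * res$n_scored
  e_best <- pmax(res$homology_evalue, EVALUE_FLOOR)
  e_other <- pmax(res$homology_other_evalue, EVALUE_FLOOR)
  g1 <- !is.na(res$homology_class) & res$homology_class == res$best_class
  g2 <- !is.na(e_best) & !is.na(e_other) &
    (log10(e_other) - log10(e_best)) >= config$group2_order_gap
  g3 <- !is.na(total_gap) & total_gap >= lr
  group <- dplyr::case_when(g1 ~ "I", g2 ~ "II", g3 ~ "III", TRUE ~ "IV")
  res$confidence_group <- factor(group, levels = c("I", "II", "III", "IV"))
  res$predicted_class <- ifelse(group %in% c("I", "II"),
                                res$homology_class, res$best_class)
  dplyr::select(res, "sequence_id", "predicted_class", "confidence_group",
                "homology_class", "homology_evalue", dplyr::everything(),
                -"homology_other_evalue")
}

# Best hit (min e-value, ties by bitscore then subject id) and best hit from a
# different class than the best hit's, per query.
homology_summary <- function(hits) {
  empty <- tibble::tibble(sequence_id = character(),
                          homology_class = character(),
                          homology_evalue = numeric(),
                          homology_other_evalue = numeric())
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits <- dplyr::filter(hits, !is.na(.data$subject_class))
  if (!nrow(hits)) return(empty)
  hits |>
    dplyr::group_by(sequence_id = .data$query_id) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::summarise(
      homology_class = .data$subject_class[1],
      homology_evalue = .data$evalue[1],
      homology_other_evalue = {
        other <- .data$evalue[.data$subject_class != .data$subject_class[1]]
        if (length(other)) min(other) else NA_real_
      },
      .groups = "drop"
    )
}

#' Write composition predictions to TSV
#'
#' @param preds Output of [assign_confidence_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  out <- dplyr::select(preds, "sequence_id", "predicted_class",
                       "confidence_group", "best_score", "runner_up_score")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Serialise a composition model to JSON (and back)
#'
#' @param model A `kmer_class_model`.
#' @param path JSON path.
#' @return `path` invisibly, or the restored model for `read_class_model()`.
#' @export
write_class_model <- function(model, path) {
  jsonlite::write_json(list(
    class_label = model$class_label, k = model$k,
    pseudocount = model$pseudocount,
    contexts = rownames(model$log_probs),
    log_probs = unname(as.data.frame(model$log_probs))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_model
#' @export
read_class_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lp <- as.matrix(x$log_probs)
  dimnames(lp) <- list(x$contexts, c("A", "C", "G", "T"))
  structure(list(class_label = x$class_label, k = as.integer(x$k),
                 pseudocount = x$pseudocount, log_probs = lp),
            class = "kmer_class_model")
}
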