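#' Call LGT by classification discordance
#'
#' Emits one candidate transfer per ORF whose class-level classification
#' disagrees with its parent contig's, subject to the published filters:
#' only ORFs from confidence Groups I-II are eligible (their classifications
#' are considered accurate), and the ORF's composition score under its own
#' class must be at least `nb_improvement` (default 15 %) better than under
#' the contig's class, measured as relative improvement of mean per-base
#' log-likelihoods: `(s_orf_class - s_contig_class) / |s_contig_class|`.
#' The transfer is oriented: the donor is the ORF's classification, the
#' recipient is the contig's.
#'
#' ORFs shorter than `3 * kmer_order` nt are never called (insufficient
#' composition signal); ORFs whose score vector lacks the contig's class are
#' skipped with a warning.
#'
#' @param contig_preds Contig predictions from [assign_confidence_groups()]
#'   (any confidence group; the contig's group is recorded in the output).
#' @param orf_preds ORF predictions from [assign_confidence_groups()].
#' @param orf_scores Long ORF score tibble from [classify_composition()]
#'   (must contain each ORF's score under the contig's predicted class).
#' @param orfs ORF tibble linking `orf_id` to `contig_id` (with `start`,
#'   `end` for the length guard).
#' @param config A [pipeline_config()] list.
#' @return A tibble of calls with class `lgt_calls`: `orf_id`, `contig_id`,
#'   `method` (`"discordance"`), `donor_class`, `recipient_class`,
#'   `nb_improvement`, `orf_group`, `contig_group`, `mge_supported`,
#'   `mobility_adjacent` (the last two initialised `FALSE`, filled by the
#'   downstream screens).
#' @export
call_discordant_orfs <- function(contig_preds, orf_preds, orf_scores, orfs,
                                 config = pipeline_config()) {
  eligible <- dplyr::filter(orf_preds,
                            .data$confidence_group %in% c("I", "II"))
  df <- eligible |>
    dplyr::inner_join(dplyr::select(orfs, "orf_id", "contig_id",
                                    "start", "end"),
                      by = c(sequence_id = "orf_id")) |>
    dplyr::inner_join(
      dplyr::select(contig_preds, contig_id = "sequence_id",
                    contig_class = "predicted_class",
                    contig_group = "confidence_group"),
      by = "contig_id")
  df <- dplyr::filter(df, .data$end - .data$start + 1L >= 3L * config$kmer_order)
  df <- dplyr::filter(df, .data$predicted_class != .data$contig_class)
  if (!nrow(df)) return(empty_calls())

  score_of <- function(ids, classes) {
    key <- paste(ids, classes)
    lookup <- setNames(orf_scores$score,
                       paste(orf_scores$sequence_id, orf_scores$class))
    unname(lookup[key])
  }
  s_orf <- score_of(df$sequence_id, df$predicted_class)
  s_contig <- score_of(df$sequence_id, df$contig_class)
  missing <- is.na(s_contig) | is.na(s_orf)
  if (any(missing)) {
    warning("contig class missing from score vector for ",
            paste(df$sequence_id[missing], collapse = ", "), "; skipped")
    df <- df[!missing, ]
    s_orf <- s_orf[!missing]
    s_contig <- s_contig[!missing]
  }
  improvement <- (s_orf - s_contig) / abs(s_contig)
  keep <- improvement >= config$nb_improvement
  df <- df[keep, ]
  if (!nrow(df)) return(empty_calls())
  new_calls(tibble::tibble(
    orf_id = df$sequence_id,
    contig_id = df$contig_id,
    method = "discordance",
    donor_class = df$predicted_class,
    recipient_class = df$contig_class,
    partner_class = NA_character_,
    nb_improvement = improvement[keep],
    patristic_distance = NA_real_,
    orf_group = as.character(df$confidence_group),
    contig_group = as.character(df$contig_group),
    mge_supported = FALSE,
    mobility_adjacent = FALSE
  ))
}

empty_calls <- function() {
  new_calls(tibble::tibble(
    orf_id = character(), contig_id = character(), method = character(),
    donor_class = character(), recipient_class = character(),
    partner_class = character(), nb_improvement = numeric(),
    patristic_distance = numeric(), orf_group = character(),
    contig_group = character(), mge_supported = logical(),
    mobility_adjacent = logical()
  ))
}

new_calls <- function(df) {
  class(df) <- c("lgt_calls", class(df))
  df
}

#' @method tidy lgt_calls
#' @export
tidy.lgt_calls <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance lgt_calls
#' @export
glance.lgt_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x),
    n_discordance = sum(x$method == "discordance"),
    n_phylogenetic = sum(x$method == "phylogenetic"),
    n_mge_supported = sum(x$mge_supported),
    n_mobility_adjacent = sum(x$mobility_adjacent)
  )
}

#' Per-gene taxonomic mosaic of a contig
#'
#' Lays out the class assignment of each ORF along a contig, with intergenic
#' gaps labelled, for rendering mosaic figures of mixed-ancestry contigs.
#' Overlapping ORFs are both reported and flagged.
#'
#' @param contig One-row contig tibble (`id`, `length`).
#' @param orfs ORF tibble for this contig (`orf_id`, `start`, `end`).
#' @param orf_preds ORF predictions from [assign_confidence_groups()];
#'   unclassified ORFs show class `NA`.
#' @return A tibble with class `lgt_mosaic`: `contig_id`, `start`, `end`,
#'   `feature` (`"orf"`/`"intergenic"`), `orf_id`, `class`, `overlap`.
#' @export
contig_mosaic <- function(contig, orfs, orf_preds = NULL) {
  stopifnot(nrow(contig) == 1L)
  orfs <- orfs[orfs$contig_id == contig$id, ]
  orfs <- dplyr::arrange(orfs, .data$start)
  cls <- if (!is.null(orf_preds)) {
    orf_preds$predicted_class[match(orfs$orf_id, orf_preds$sequence_id)]
  } else rep(NA_character_, nrow(orfs))
  blocks <- list()
  cursor <- 1L
  if (nrow(orfs)) {
    overlap <- c(FALSE, orfs$start[-1] <= head(orfs$end, -1))
    for (i in seq_len(nrow(orfs))) {
      if (orfs$start[i] > cursor) {
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          contig_id = contig$id, start = cursor, end = orfs$start[i] - 1L,
          feature = "intergenic", orf_id = NA_character_,
          class = NA_character_, overlap = FALSE)
      }
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        contig_id = contig$id, start = orfs$start[i], end = orfs$end[i],
        feature = "orf", orf_id = orfs$orf_id[i], class = cls[i],
        overlap = overlap[i] ||
          (i < nrow(orfs) && orfs$start[i + 1L] <= orfs$end[i]))
      cursor <- max(cursor, orfs$end[i] + 1L)
    }
  }
  if (cursor <= contig$length) {
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      contig_id = contig$id, start = cursor, end = contig$length,
      feature = "intergenic", orf_id = NA_character_, class = NA_character_,
      overlap = FALSE)
  }
  out <- dplyr::bind_rows(blocks)
  class(out) <- c("lgt_mosaic", class(out))
  out
}

#' Write discordance calls to TSV
#'
#' @param calls An `lgt_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(tibble::as_tibble(unclass(calls)), path)
  invisible(path)
}
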