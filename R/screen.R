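#' Specificity screening thresholds
#'
#' A hit "qualifies" (counts against a candidate probe) when its E-value is
#' strictly below `max_evalue` AND its identity over aligned columns is at
#' least `min_identity_pct` AND its alignment length is at least
#' `min_hitlen_pct` percent of the query window. Defaults: E < 1,
#' identity >= 90%, length >= 90% of the window.
#'
#' @param max_evalue Upper E-value bound, exclusive (> 0).
#' @param min_identity_pct Minimum percent identity over aligned columns.
#' @param min_hitlen_pct Minimum alignment length as a percent of the query.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(max_evalue = 1, min_identity_pct = 90,
                              min_hitlen_pct = 90) {
  stopifnot(max_evalue > 0,
            min_identity_pct > 0, min_identity_pct <= 100,
            min_hitlen_pct > 0, min_hitlen_pct <= 100)
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct,
                 min_hitlen_pct = min_hitlen_pct),
            class = "screen_thresholds")
}

#' Does a hit qualify under the screening thresholds?
#'
#' Vectorized over the rows of `hits`. The E-value comparison is strict
#' (`<`); the identity and length comparisons are inclusive (`>=`), with the
#' length requirement measured against the query window length.
#'
#' @param hits Hit tibble (see [align_fragments()] / [parse_tabular_hits()]).
#' @param query_len Query window length(s), recycled against rows of `hits`.
#' @param thresholds A [screen_thresholds()] object.
#' @return Logical vector, one element per hit.
#' @export
qualifies <- function(hits, query_len, thresholds = screen_thresholds()) {
  stopifnot(all(query_len >= 1))
  hits$evalue < thresholds$max_evalue &
    hits$identity_pct >= thresholds$min_identity_pct &
    hits$aln_len >= (thresholds$min_hitlen_pct / 100) * query_len
}

#' Parse alignment hits in 12-column BLAST tabular format
#'
#' Reads the standard tab-separated layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Comment lines
#' starting with `#` are skipped; extra trailing columns are ignored; fewer
#' than 12 columns is an error.
#'
#' @param x Path to a tabular hits file, or a character vector of lines.
#' @return Hit tibble with the same core columns as [align_fragments()].
#' @export
parse_tabular_hits <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) return(empty_hits()[, 1:12])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("malformed tabular line (", nf[nf < 12L][1], " fields, need >= 12): ",
         substr(lines[which(nf < 12L)[1]], 1, 60), call. = FALSE)
  }
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
    if (anyNA(v)) stop("unparseable numeric in tabular column ", i, call. = FALSE)
    v
  }
  tibble::tibble(
    query_id = vapply(fields, `[[`, "", 1L),
    subject_id = vapply(fields, `[[`, "", 2L),
    identity_pct = num(3L),
    aln_len = as.integer(num(4L)),
    mismatches = as.integer(num(5L)),
    gap_opens = as.integer(num(6L)),
    qstart = as.integer(num(7L)),
    qend = as.integer(num(8L)),
    sstart = as.integer(num(9L)),
    send = as.integer(num(10L)),
    evalue = num(11L),
    bitscore = num(12L)
  )
}

#' Tally qualifying hits per candidate fragment
#'
#' One row per fragment (fragments without any hit tally zero). The best hit
#' of a fragment is its qualifying hit with the smallest E-value, ties broken
#' by highest bit score, then lexicographically smallest subject id.
#'
#' @param hits Hit tibble; every `query_id` must be a known `fragment_id`.
#' @param fragments Fragment tibble from [fragment_sequences()].
#' @param thresholds [screen_thresholds()] used for qualification.
#' @return Tibble with `fragment_id`, `parent_id`, `offset`,
#'   `qualifying_hits`, `best_subject`, `best_identity`, `best_evalue`.
#' @export
tally_hits <- function(hits, fragments, thresholds = screen_thresholds()) {
  orphan <- setdiff(unique(hits$query_id), fragments$fragment_id)
  if (length(orphan)) {
    stop("hits refer to unknown fragment(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  qlen <- stats::setNames(nchar(fragments$sequence), fragments$fragment_id)
  if (nrow(hits)) {
    qual <- hits[qualifies(hits, qlen[hits$query_id], thresholds), , drop = FALSE]
  } else {
    qual <- hits
  }
  best <- qual |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$subject_id) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      qualifying_hits = dplyr::n(),
      best_subject = dplyr::first(.data$subject_id),
      best_identity = dplyr::first(.data$identity_pct),
      best_evalue = dplyr::first(.data$evalue),
      .groups = "drop"
    )
  fragments |>
    dplyr::select("fragment_id", "parent_id", "offset") |>
    dplyr::left_join(best, by = c(fragment_id = "query_id")) |>
    dplyr::mutate(
      qualifying_hits = dplyr::coalesce(.data$qualifying_hits, 0L)
    )
}
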