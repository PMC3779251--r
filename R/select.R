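#' Select final probes with the smallest number of qualifying hits
#'
#' Ranks candidate windows per target gene by ascending qualifying-hit
#' count; among equal tallies, hairpin-free candidates come first, then ties
#' break by ascending `(parent_id, offset)`. Selection is fully
#' deterministic.
#'
#' With `spacing = "none"` the top `k` candidates per parent are taken in
#' sort order. With `spacing = "greedy"` candidates are still consumed
#' stratum by stratum (a worse tally or a hairpin flag is never preferred),
#' but within a stratum each pick maximizes the minimum offset distance to
#' the probes already chosen on that parent, so the selected probes tile the
#' gene; the first pick on a parent is the lowest-offset candidate of the
#' best stratum.
#'
#' @param tallies Tally tibble from [tally_hits()] (columns `fragment_id`,
#'   `parent_id`, `offset`, `qualifying_hits`). If a logical `hairpin_flag`
#'   column is present (see [screen_hairpins()]) it participates in ranking;
#'   otherwise all candidates count as unflagged.
#' @param k Number of probes requested per target gene (>= 1).
#' @param spacing `"none"` (pure minimal-hit sort, the default) or
#'   `"greedy"`.
#' @param exclude_hairpins If `TRUE`, hairpin-flagged candidates are dropped
#'   rather than merely demoted.
#' @return Tibble of selected probes: the tally columns plus `rank` (1-based
#'   within each parent). Fewer than `k` rows per parent are returned when
#'   candidates run out; a warning is emitted if any selected probe has a
#'   positive tally.
#' @export
select_probes <- function(tallies, k = 5L, spacing = c("none", "greedy"),
                          exclude_hairpins = FALSE) {
  spacing <- match.arg(spacing)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (nrow(tallies) == 0L) stop("empty candidate set", call. = FALSE)
  if (!"hairpin_flag" %in% names(tallies)) tallies$hairpin_flag <- FALSE
  if (exclude_hairpins) {
    tallies <- dplyr::filter(tallies, !.data$hairpin_flag)
    if (nrow(tallies) == 0L) stop("all candidates hairpin-flagged", call. = FALSE)
  }
  sorted <- dplyr::arrange(tallies, .data$qualifying_hits, .data$hairpin_flag,
                           .data$parent_id, .data$offset)
  picked <- sorted |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::group_modify(~ pick_within_parent(.x, k, spacing)) |>
    dplyr::ungroup() |>
    dplyr::relocate("fragment_id")
  if (any(picked$qualifying_hits > 0L)) {
    warning(sum(picked$qualifying_hits > 0L),
            " selected probe(s) have qualifying hits > 0", call. = FALSE)
  }
  picked
}

# Candidates arrive sorted by (hits, hairpin_flag, offset).
pick_within_parent <- function(cands, k, spacing) {
  if (spacing == "none") {
    out <- utils::head(cands, k)
    out$rank <- seq_len(nrow(out))
    return(out)
  }
  # cands are pre-sorted, so unique() yields strata in ranking order
  keys <- paste(cands$qualifying_hits, cands$hairpin_flag)
  chosen <- cands[0, , drop = FALSE]
  for (kk in unique(keys)) {
    stratum <- cands[keys == kk, , drop = FALSE]
    while (nrow(chosen) < k && nrow(stratum) > 0L) {
      if (nrow(chosen) == 0L) {
        i <- which.min(stratum$offset)
      } else {
        mind <- vapply(stratum$offset,
                       function(o) min(abs(o - chosen$offset)), numeric(1))
        best <- max(mind)
        i <- which(mind == best)
        i <- i[which.min(stratum$offset[i])]
      }
      chosen <- dplyr::bind_rows(chosen, stratum[i, , drop = FALSE])
      stratum <- stratum[-i, , drop = FALSE]
    }
    if (nrow(chosen) >= k) break
  }
  chosen$rank <- seq_len(nrow(chosen))
  chosen
}
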