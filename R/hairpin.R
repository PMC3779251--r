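#' Hairpin screening parameters
#'
#' A hairpin (inverted repeat) is a stem of `stem_len` Watson-Crick pairs
#' between an upstream arm and the reverse complement of a downstream arm,
#' separated by an unpaired loop. Defaults (stem >= 6 pairs, loop >= 3 nt,
#' no mismatches) flag structures stable enough to compete with probe-target
#' hybridization; they are package choices, tunable per assay.
#'
#' @param min_stem Minimum stem length in base pairs (>= 2).
#' @param min_loop Minimum loop length in nucleotides (>= 0). Loops shorter
#'   than 3 nt are sterically strained in practice.
#' @param max_mismatch Maximum mismatched pairs tolerated within a stem.
#' @param allow_gu If `TRUE`, count G-T (G-U in RNA) wobble pairs as paired;
#'   off by default for DNA probes.
#' @return A list of class `hairpin_params`.
#' @export
hairpin_params <- function(min_stem = 6L, min_loop = 3L, max_mismatch = 0L,
                           allow_gu = FALSE) {
  stopifnot(min_stem >= 2, min_loop >= 0, max_mismatch >= 0)
  structure(list(min_stem = as.integer(min_stem),
                 min_loop = as.integer(min_loop),
                 max_mismatch = as.integer(max_mismatch),
                 allow_gu = isTRUE(allow_gu)),
            class = "hairpin_params")
}

#' Find self-annealing hairpin sites in a probe sequence
#'
#' Enumerates every maximal inverted repeat: arm 1 at `arm1_start` pairs with
#' the reverse complement of arm 2 at `arm2_start`, with
#' `arm1_start + stem_len + loop_len = arm2_start` (all offsets 0-based).
#' A repeat is maximal when its stem can be extended neither outward nor
#' inward within the mismatch budget; the loop floor then filters which
#' maximal repeats are reported (see the methods vignette for why maximality
#' ignores `min_loop`). Results are ordered by `arm1_start`, then
#' `arm2_start`, then `stem_len`, and are deterministic.
#'
#' @param sequence A single nucleotide string.
#' @param params [hairpin_params()].
#' @return Tibble with `arm1_start`, `arm2_start`, `stem_len`, `loop_len`,
#'   `mismatches`. Sequences too short to fold return an empty tibble.
#' @examples
#' find_hairpins("AACCGGTTTTCCGGTT", hairpin_params())
#' @export
find_hairpins <- function(sequence, params = hairpin_params()) {
  stopifnot(length(sequence) == 1L, is.character(sequence))
  sequence <- toupper(sequence)
  if (nchar(sequence) < 2L * params$min_stem + params$min_loop) {
    message("sequence shorter than 2*min_stem + min_loop; no structure possible")
    return(tibble::as_tibble(.hairpins_cpp(integer(), params$min_stem,
                                           params$min_loop, params$max_mismatch,
                                           params$allow_gu)))
  }
  df <- .hairpins_cpp(encode_seq(sequence), params$min_stem, params$min_loop,
                      params$max_mismatch, params$allow_gu)
  tibble::as_tibble(df)
}

#' Flag a single probe for hairpin structure
#'
#' @param sequence A single nucleotide string.
#' @param params [hairpin_params()].
#' @return List with `flag` (`TRUE` iff any hairpin was found) and `matches`
#'   (the [find_hairpins()] tibble).
#' @export
flag_probe <- function(sequence, params = hairpin_params()) {
  m <- find_hairpins(sequence, params)
  list(flag = nrow(m) > 0L, matches = m)
}

#' Screen a fragment table for hairpins
#'
#' Adds per-fragment hairpin annotation columns used by [select_probes()].
#'
#' @param fragments Fragment tibble with a `sequence` column.
#' @param params [hairpin_params()].
#' @return `fragments` with added `hairpin_flag` (logical), `n_hairpins` and
#'   `max_stem_len` columns.
#' @export
screen_hairpins <- function(fragments, params = hairpin_params()) {
  res <- purrr::map(fragments$sequence, function(s) {
    m <- suppressMessages(find_hairpins(s, params))
    list(n = nrow(m), stem = if (nrow(m)) max(m$stem_len) else 0L)
  })
  dplyr::mutate(fragments,
                n_hairpins = purrr::map_int(res, "n"),
                max_stem_len = purrr::map_int(res, "stem"),
                hairpin_flag = .data$n_hairpins > 0L)
}
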