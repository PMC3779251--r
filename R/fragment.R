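#' Virtually fragment target genes into overlapping candidate windows
#'
#' Slides a fixed-width window along each target sequence in steps of
#' `leap` nucleotides. Windows start at offsets `0, leap, 2*leap, ...` while
#' the full window still fits; no shorter tail window is emitted, so every
#' candidate probe has exactly `window` nucleotides. For a target of length
#' `L` this yields `floor((L - window)/leap) + 1` fragments.
#'
#' @param targets Tibble with columns `id` and `sequence` (e.g. the
#'   `targets` element of [collect_sets()]).
#' @param window Window (probe) size in nucleotides; default 100.
#' @param leap Step between successive window starts; default 5.
#' @return Tibble with columns `fragment_id` (`"<parent>:<offset>"`),
#'   `parent_id`, `offset` (0-based start within the parent) and `sequence`.
#' @examples
#' fragment_sequences(tibble::tibble(id = "g", sequence = strrep("ACGT", 30)),
#'                    window = 100, leap = 5)
#' @export
fragment_sequences <- function(targets, window = 100L, leap = 5L) {
  window <- as.integer(window); leap <- as.integer(leap)
  if (is.na(window) || window < 1L) stop("window must be >= 1", call. = FALSE)
  if (is.na(leap) || leap < 1L) stop("leap must be >= 1", call. = FALSE)
  lens <- nchar(targets$sequence)
  short <- lens < window
  if (any(short)) {
    stop("target shorter than window: ",
         paste(targets$id[short], collapse = ", "), call. = FALSE)
  }
  purrr::map2_dfr(targets$id, targets$sequence, function(id, seq) {
    offs <- seq.int(0L, nchar(seq) - window, by = leap)
    tibble::tibble(
      fragment_id = paste0(id, ":", offs),
      parent_id = id,
      offset = offs,
      sequence = substring(seq, offs + 1L, offs + window)
    )
  })
}
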