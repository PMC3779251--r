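#' Karlin-Altschul scoring parameters
#'
#' Parameters of the extreme-value statistics used to convert raw local
#' alignment scores into E-values, `E = K * m * n * exp(-lambda * S)`.
#' Defaults are the ungapped values for the match +1 / mismatch -2
#' nucleotide scheme (`lambda = 1.28` nats per score unit, `K = 0.46`).
#' The screening filter is insensitive to modest inaccuracy here: any hit
#' passing the 90% identity / 90% coverage thresholds on a 100-nt window has
#' an E-value many orders of magnitude below 1.
#'
#' @param lambda Scale of the score distribution, nats per score unit (> 0).
#' @param K Search-space correction constant (> 0).
#' @param match Match reward (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @return A list of class `ka_params`.
#' @export
karlin_altschul <- function(lambda = 1.28, K = 0.46, match = 1L, mismatch = -2L) {
  stopifnot(lambda > 0, K > 0, match > 0, mismatch < 0)
  structure(list(lambda = lambda, K = K,
                 match = as.integer(match), mismatch = as.integer(mismatch)),
            class = "ka_params")
}

#' Karlin-Altschul E-value of a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a length-`m` query and a search
#' space of `n` residues. Strictly decreasing in `S`, linear in `m` and `n`.
#'
#' @param score Raw alignment score(s), >= 0.
#' @param m Query length (>= 1).
#' @param n Total database length in residues (>= 1).
#' @param ka [karlin_altschul()] parameters.
#' @return Numeric E-value(s).
#' @examples
#' evalue(0, m = 100, n = 10000)  # K * m * n = 460000
#' @export
evalue <- function(score, m, n, ka = karlin_altschul()) {
  stopifnot(all(m >= 1), all(n >= 1), all(score >= 0))
  ka$K * m * n * exp(-ka$lambda * score)
}

bitscore <- function(score, ka = karlin_altschul()) {
  (ka$lambda * score - log(ka$K)) / log(2)
}

# A,C,G,T -> 0..3; anything else (incl. N) -> 4, which matches nothing.
encode_seq <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]],
                c("A", "C", "G", "T")) - 1L
  code[is.na(code)] <- 4L
  code
}

#' Align candidate fragments against the subject transcript set
#'
#' Local alignment of every fragment against both strands of every subject,
#' the in-package counterpart of a nucleotide BLAST search. Two backends:
#'
#' * `mode = "seed_extend"` (default): only fragment/subject/strand pairs
#'   sharing at least one exact k-mer (default `k = 11`, the classic
#'   nucleotide seed length) are aligned by full Smith-Waterman. Pairs with
#'   no shared word cannot produce a qualifying high-identity hit and are
#'   skipped.
#' * `mode = "exhaustive"`: Smith-Waterman on every pair; the slow oracle the
#'   seeded backend is validated against.
#'
#' Within an aligned pair, additional high-scoring segment pairs (HSPs) are
#' recovered by masking each reported subject interval and re-aligning, so
#' duplicated homology at distinct loci of one subject is counted per locus.
#' Hits with E-value above `max_evalue_report` are dropped.
#'
#' @param fragments Fragment tibble from [fragment_sequences()].
#' @param subjects Tibble with columns `id`, `sequence`.
#' @param mode `"seed_extend"` or `"exhaustive"`.
#' @param ka [karlin_altschul()] scoring/statistics parameters.
#' @param k Seed word size for `seed_extend` (default 11).
#' @param gap_open,gap_ext Positive gap-opening and gap-extension costs.
#' @param max_evalue_report Reporting cap on E-values (default 10, well above
#'   the screening threshold of 1).
#' @param max_hsps Maximum HSPs recovered per fragment/subject/strand pair.
#' @return Tibble of hits: `query_id`, `subject_id`, `identity_pct`,
#'   `aln_len`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, plus `score` and `strand`. Minus-strand
#'   hits carry `sstart > send` (BLAST convention).
#' @export
align_fragments <- function(fragments, subjects,
                            mode = c("seed_extend", "exhaustive"),
                            ka = karlin_altschul(), k = 11L,
                            gap_open = 5L, gap_ext = 2L,
                            max_evalue_report = 10, max_hsps = 16L) {
  mode <- match.arg(mode)
  if (nrow(fragments) == 0L || nrow(subjects) == 0L) {
    stop("empty fragments or subjects", call. = FALSE)
  }
  qlens <- nchar(fragments$sequence)
  if (mode == "seed_extend" && k > min(qlens)) {
    stop("seed size k (", k, ") larger than the shortest fragment (",
         min(qlens), ")", call. = FALSE)
  }
  n_db <- sum(nchar(subjects$sequence))

  q_codes <- lapply(fragments$sequence, encode_seq)
  s_fwd <- lapply(subjects$sequence, encode_seq)
  s_rev <- lapply(revcomp(subjects$sequence), encode_seq)

  pairs <- if (mode == "exhaustive") {
    tidyr::expand_grid(qi = seq_len(nrow(fragments)),
                       si = seq_len(nrow(subjects)),
                       strand = c("+", "-"))
  } else {
    seed_pairs(fragments$sequence, subjects$sequence, k = k)
  }
  if (nrow(pairs) == 0L) return(empty_hits())

  out <- purrr::pmap_dfr(pairs, function(qi, si, strand) {
    m <- qlens[[qi]]
    # report down to the score whose E-value reaches the cap
    floor_s <- max(1L, as.integer(ceiling(
      log(ka$K * m * n_db / max_evalue_report) / ka$lambda)))
    scode <- if (strand == "+") s_fwd[[si]] else s_rev[[si]]
    df <- .sw_hits_cpp(q_codes[[qi]], scode,
                       ka$match, -ka$mismatch, as.integer(gap_open),
                       as.integer(gap_ext), floor_s, as.integer(max_hsps))
    if (nrow(df) == 0L) return(NULL)
    slen <- nchar(subjects$sequence[[si]])
    sstart <- df$sstart; send <- df$send
    if (strand == "-") {
      sstart <- slen - df$sstart + 1L
      send <- slen - df$send + 1L
    }
    tibble::tibble(
      query_id = fragments$fragment_id[[qi]],
      subject_id = subjects$id[[si]],
      identity_pct = 100 * df$matches / df$aln_len,
      aln_len = df$aln_len,
      mismatches = df$mismatches,
      gap_opens = df$gap_opens,
      qstart = df$qstart, qend = df$qend,
      sstart = sstart, send = send,
      evalue = evalue(df$score, m = m, n = n_db, ka = ka),
      bitscore = bitscore(df$score, ka = ka),
      score = df$score,
      strand = strand
    )
  })
  if (is.null(out) || nrow(out) == 0L) return(empty_hits())
  dplyr::arrange(out, .data$query_id, .data$subject_id, .data$evalue)
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(),
    identity_pct = numeric(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(), evalue = numeric(),
    bitscore = numeric(), score = integer(), strand = character()
  )
}

# Fragment/subject/strand pairs sharing >= 1 exact k-mer.
seed_pairs <- function(qseqs, sseqs, k) {
  kmerize <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- purrr::imap_dfr(qseqs, ~ tibble::tibble(kmer = kmerize(.x), qi = .y))
  hit_pairs <- function(seqs, strand) {
    sk <- purrr::imap_dfr(seqs, ~ tibble::tibble(kmer = kmerize(.x), si = .y))
    dplyr::inner_join(qk, sk, by = "kmer",
                      relationship = "many-to-many") |>
      dplyr::distinct(.data$qi, .data$si) |>
      dplyr::mutate(strand = strand)
  }
  dplyr::bind_rows(
    hit_pairs(sseqs, "+"),
    hit_pairs(revcomp(sseqs), "-")
  ) |>
    dplyr::select("qi", "si", "strand")
}
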