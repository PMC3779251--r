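# Independent oracles used across the suite. These deliberately share no
# code with the package implementation they check.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force window offset enumeration: every o with o mod leap == 0 and
# o + W <= L.
oracle_offsets <- function(L, W, leap) {
  o <- 0:L
  o[o %% leap == 0 & o + W <= L]
}

# Plain-R maximal inverted-repeat enumerator: O(n^3) triples, pairing
# looked up in a precomputed complementarity matrix.
oracle_hairpins <- function(seq, min_stem = 6, min_loop = 3,
                            max_mismatch = 0, allow_gu = FALSE) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  P <- outer(s, s, function(x, y) y == unname(comp[x]) & x %in% names(comp))
  if (allow_gu) {
    P <- P | outer(s, s, function(x, y) (x == "G" & y == "T") | (x == "T" & y == "G"))
  }
  pair <- function(a, b) a >= 1 && b >= 1 && a <= n && b <= n && P[a, b]
  out <- list()
  for (i in 0:(n - 1)) {
    for (L in 2:n) {
      if (i + 2 * L > n) break
      for (g in 0:n) {
        j <- i + L + g
        if (j + L > n) break
        t <- seq_len(L) - 1L
        m0 <- L - sum(P[cbind(i + t + 1L, j + L - t)])
        if (m0 > max_mismatch) next
        add_out <- if (pair(i, j + L + 1L)) 0L else 1L
        add_in <- if (pair(i + L + 1L, j)) 0L else 1L
        ext_out <- i - 1 >= 0 && j + L + 1 <= n &&
          (m0 + add_out) <= max_mismatch
        ext_in <- g >= 2 && (m0 + add_in) <= max_mismatch
        if (ext_out || ext_in) next
        if (L < min_stem || g < min_loop) next
        out[[length(out) + 1L]] <-
          data.frame(arm1_start = i, arm2_start = j, stem_len = L,
                     loop_len = g, mismatches = m0)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(arm1_start = integer(), arm2_start = integer(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$arm1_start, df$arm2_start, df$stem_len), , drop = FALSE]
}

# Best local alignment score by Biostrings (independent dynamic-programming
# engine) under the same scoring scheme as the internal aligner.
oracle_local_score <- function(query, subject, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE))
}

# Small deterministic target + subject set with an optional verbatim plant.
make_pair_fixture <- function(seed, n_subjects = 10, subject_len = 300,
                              target_len = 345, gc = 0.5) {
  withr::with_seed(seed, {
    target <- rand_dna(target_len, gc)
    subjects <- tibble::tibble(
      id = sprintf("s%02d", seq_len(n_subjects)),
      sequence = vapply(seq_len(n_subjects), function(i) rand_dna(subject_len, gc), "")
    )
    list(target = tibble::tibble(id = "tgt", sequence = target),
         subjects = subjects)
  })
}

write_tabular_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
                   hits$query_id, hits$subject_id, hits$identity_pct,
                   hits$aln_len, hits$mismatches, hits$gap_opens,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  path
}
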