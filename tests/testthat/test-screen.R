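test_that("Karlin-Altschul E-values follow the closed form", {
  # S = 0: E = K*m*n
  expect_equal(evalue(0, m = 100, n = 10000), 460000)
  # independently evaluated closed form, K=0.46, lambda=1.28, S=20
  expect_equal(evalue(20, m = 100, n = 10000), 3.50605798947593e-06,
               tolerance = 1e-12)
  # linear in n, strictly decreasing in S
  expect_equal(evalue(20, 100, 20000), 2 * evalue(20, 100, 10000))
  s <- 0:50
  expect_true(all(diff(evalue(s, 100, 1e4)) < 0))
})

test_that("hit qualification applies strict E-value and inclusive percent rules", {
  hit <- function(id, len, ev) tibble::tibble(identity_pct = id, aln_len = len,
                                              evalue = ev)
  t <- screen_thresholds()
  expect_true(qualifies(hit(100, 100, 1e-40), 100, t))
  expect_false(qualifies(hit(89.9, 100, 1e-40), 100, t))
  expect_false(qualifies(hit(95, 89, 1e-20), 100, t)) # 89 < 0.9 * 100
  expect_true(qualifies(hit(95, 90, 1e-20), 100, t))
  expect_false(qualifies(hit(100, 100, 1), 100, t))   # E-value bound is strict
  expect_true(qualifies(hit(100, 100, 0.999), 100, t))
})

test_that("tabular hit parsing maps the 12 standard columns", {
  h <- parse_tabular_hits(
    "f:0\tg1\t100.000\t100\t0\t0\t1\t100\t201\t300\t1e-48\t185")
  expect_equal(h$query_id, "f:0")
  expect_equal(h$subject_id, "g1")
  expect_equal(h$identity_pct, 100)
  expect_equal(h$aln_len, 100L)
  expect_equal(h$sstart, 201L)
  expect_equal(h$evalue, 1e-48)
  expect_equal(h$bitscore, 185)

  expect_equal(nrow(parse_tabular_hits(character())), 0L)
  expect_equal(nrow(parse_tabular_hits(c("# comment", "  "))), 0L)
  expect_error(parse_tabular_hits("a\tb\t1\t2\t3\t4\t5\t6\t7\t8\t9"),
               "malformed tabular line")
  # extra columns are ignored
  h2 <- parse_tabular_hits(
    "f:0\tg1\t90\t90\t9\t0\t1\t90\t1\t90\t1e-20\t80\textra\tcols")
  expect_equal(h2$bitscore, 80)
})

test_that("a verbatim planted fragment is found with full identity by both backends", {
  fix <- make_pair_fixture(seed = 5)
  frags <- fragment_sequences(fix$target, window = 100, leap = 50)
  planted <- frags$sequence[[2]]
  subjects <- fix$subjects
  subjects$sequence[[4]] <- paste0(substr(subjects$sequence[[4]], 1, 100),
                                   planted,
                                   substr(subjects$sequence[[4]], 101, 300))
  for (mode in c("seed_extend", "exhaustive")) {
    hits <- align_fragments(frags, subjects, mode = mode)
    top <- hits[hits$query_id == frags$fragment_id[[2]] &
                  hits$subject_id == "s04", , drop = FALSE]
    expect_true(any(top$identity_pct == 100 & top$aln_len == 100),
                label = paste("exact hit in mode", mode))
  }
})

test_that("unrelated random subjects never reach the 90/90 thresholds", {
  fix <- make_pair_fixture(seed = 42, n_subjects = 20, subject_len = 300)
  frags <- fragment_sequences(fix$target, window = 100, leap = 100)
  hits <- align_fragments(frags, fix$subjects, mode = "exhaustive")
  expect_false(any(hits$identity_pct >= 90 & hits$aln_len >= 90))
})

test_that("internal alignment scores match an independent local-alignment engine", {
  withr::with_seed(9, {
    for (rep in 1:8) {
      q <- rand_dna(60)
      s <- rand_dna(200)
      # embed a mutated copy half the time so scores are non-trivial
      if (rep %% 2 == 0) {
        s <- paste0(substr(s, 1, 50),
                    gsub("A", "C", substr(q, 1, 50)),
                    substr(s, 51, 200))
      }
      frags <- tibble::tibble(fragment_id = "q:0", parent_id = "q",
                              offset = 0L, sequence = q)
      hits <- align_fragments(frags, tibble::tibble(id = "s", sequence = s),
                              mode = "exhaustive", max_evalue_report = 1e6)
      fwd <- hits[hits$strand == "+", , drop = FALSE]
      expect_equal(max(fwd$score), oracle_local_score(q, s))
    }
  })
})

test_that("tallies count qualifying hits per fragment, zero included", {
  frags <- tibble::tibble(
    fragment_id = c("t:0", "t:5", "t:10"), parent_id = "t",
    offset = c(0L, 5L, 10L), sequence = strrep("A", 100)
  )
  tal <- tally_hits(empty_hits <- parse_tabular_hits(character()), frags)
  expect_equal(tal$qualifying_hits, c(0L, 0L, 0L))

  hits <- parse_tabular_hits(c(
    "t:0\tg1\t100\t100\t0\t0\t1\t100\t1\t100\t1e-40\t180",
    "t:0\tg2\t95\t95\t4\t0\t1\t95\t1\t95\t1e-30\t150",
    "t:5\tg1\t80\t100\t20\t0\t1\t100\t1\t100\t1e-10\t90"  # identity below 90
  ))
  tal <- tally_hits(hits, frags)
  expect_equal(tal$qualifying_hits, c(2L, 0L, 0L))
  expect_equal(tal$best_subject[[1]], "g1") # smallest evalue wins
  expect_error(tally_hits(parse_tabular_hits(
    "zz:0\tg1\t100\t100\t0\t0\t1\t100\t1\t100\t1e-40\t180"), frags),
    "unknown fragment")
})

test_that("best-hit ties break by bitscore then subject id", {
  frags <- tibble::tibble(fragment_id = "t:0", parent_id = "t", offset = 0L,
                          sequence = strrep("A", 100))
  hits <- parse_tabular_hits(c(
    "t:0\tgB\t100\t100\t0\t0\t1\t100\t1\t100\t1e-40\t180",
    "t:0\tgA\t100\t100\t0\t0\t1\t100\t1\t100\t1e-40\t180",
    "t:0\tgC\t100\t100\t0\t0\t1\t100\t1\t100\t1e-40\t200"
  ))
  tal <- tally_hits(hits, frags)
  expect_equal(tal$best_subject, "gC") # same evalue, highest bitscore
})

test_that("relaxing any threshold never decreases a tally", {
  withr::with_seed(13, {
    frags <- tibble::tibble(fragment_id = sprintf("t:%d", 0:9), parent_id = "t",
                            offset = seq(0L, 45L, 5L), sequence = strrep("A", 100))
    hits <- tibble::tibble(
      query_id = sample(frags$fragment_id, 200, TRUE),
      subject_id = sample(sprintf("g%d", 1:8), 200, TRUE),
      identity_pct = runif(200, 70, 100),
      aln_len = sample(60:100, 200, TRUE),
      evalue = 10^runif(200, -30, 1),
      bitscore = runif(200, 20, 200)
    )
    base <- screen_thresholds()
    t0 <- tally_hits(hits, frags, base)$qualifying_hits
    relaxed <- list(
      screen_thresholds(max_evalue = 10),
      screen_thresholds(min_identity_pct = 75),
      screen_thresholds(min_hitlen_pct = 60)
    )
    for (t in relaxed) {
      expect_true(all(tally_hits(hits, frags, t)$qualifying_hits >= t0))
    }
  })
})

test_that("seeded and exhaustive backends agree on qualifying tallies", {
  for (seed in 1:10) {
    sim <- simulate_genome(
      seed = seed, n_cds = 10, cds_len_range = c(200L, 300L), rrna_len = 320,
      plants = data.frame(window_offset = c(50, 150), identity = c(1, 0.95),
                          host_cds = c(2, 7))
    )
    sets <- collect_sets(sim$annotations, sim$genome)
    frags <- fragment_sequences(sets$targets, window = 100, leap = 10)
    frags <- frags[frags$parent_id == sets$targets$id[[1]], , drop = FALSE]
    tal_seed <- tally_hits(align_fragments(frags, sets$subjects,
                                           mode = "seed_extend"), frags)
    tal_full <- tally_hits(align_fragments(frags, sets$subjects,
                                           mode = "exhaustive"), frags)
    expect_equal(tal_seed$qualifying_hits, tal_full$qualifying_hits,
                 label = paste("seed", seed))
  }
})

test_that("tallies from externally formatted hits match the internal path", {
  sim <- simulate_genome(seed = 21, n_cds = 8, cds_len_range = c(200L, 300L),
                         rrna_len = 300,
                         plants = data.frame(window_offset = 100, identity = 1,
                                             host_cds = 3))
  sets <- collect_sets(sim$annotations, sim$genome)
  frags <- fragment_sequences(sets$targets[1, ], window = 100, leap = 20)
  hits <- align_fragments(frags, sets$subjects)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(hits, tsv)
  reparsed <- parse_tabular_hits(tsv)
  expect_equal(tally_hits(reparsed, frags)$qualifying_hits,
               tally_hits(hits, frags)$qualifying_hits)
})
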