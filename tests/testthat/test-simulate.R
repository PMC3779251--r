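test_that("the simulator is deterministic and byte-identical per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_genome(seed = 6, n_cds = 5, rrna_len = 300,
                        cds_len_range = c(150L, 250L), out_dir = d1)
  s2 <- simulate_genome(seed = 6, n_cds = 5, rrna_len = 300,
                        cds_len_range = c(150L, 250L), out_dir = d2)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$annotations, s2$annotations)
  for (f in c("genome.fasta", "annotations.gff3", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- simulate_genome(seed = 7, n_cds = 5, rrna_len = 300,
                        cds_len_range = c(150L, 250L))
  expect_false(identical(s1$genome$sequence, s3$genome$sequence))
})

test_that("written fixtures round-trip through the package readers", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(seed = 12, n_cds = 4, rrna_len = 250,
                         cds_len_range = c(150L, 250L), out_dir = d)
  g <- read_genome(file.path(d, "genome.fasta"))
  expect_equal(g$sequence, sim$genome$sequence)
  ann <- read_annotations(file.path(d, "annotations.gff3"))
  expect_setequal(ann$locus_tag, sim$annotations$locus_tag)
  merged <- merge(ann, sim$annotations, by = "locus_tag")
  expect_equal(merged$start.x, merged$start.y)
  expect_equal(merged$strand.x, merged$strand.y)
})

test_that("rRNA copies are identical sequences at distinct loci", {
  sim <- simulate_genome(seed = 2, n_cds = 3, rrna_copies = 3, rrna_len = 200,
                         cds_len_range = c(150L, 250L))
  sets <- collect_sets(sim$annotations, sim$genome)
  expect_equal(nrow(sets$targets), 3L)
  expect_equal(unique(sets$targets$sequence), sim$rrna)
  locs <- sim$annotations[sim$annotations$feature_kind == "rRNA", ]
  expect_equal(anyDuplicated(locs$start), 0L)
})

test_that("realized GC tracks the requested fraction for long sequences", {
  withr::with_seed(1, {
    for (gc in c(0.4, 0.67)) {
      sim <- simulate_genome(seed = sample.int(1000, 1), n_cds = 2,
                             cds_len_range = c(1000L, 1200L), gc = gc,
                             rrna_len = 1000)
      gcount <- function(s) {
        ch <- strsplit(s, "")[[1]]
        mean(ch %in% c("G", "C"))
      }
      expect_lt(abs(gcount(sim$rrna) - gc), 0.05)
      cds <- collect_sets(sim$annotations, sim$genome)$subjects$sequence
      expect_lt(abs(gcount(paste(cds, collapse = "")) - gc), 0.05)
    }
  })
})

test_that("plant bookkeeping validates its inputs", {
  expect_error(simulate_genome(seed = 1, n_cds = 2,
                               plants = data.frame(window_offset = 0,
                                                   identity = 1.2,
                                                   host_cds = 1)))
  expect_error(simulate_genome(seed = 1, n_cds = 2, rrna_len = 150,
                               plants = data.frame(window_offset = 100,
                                                   identity = 1,
                                                   host_cds = 1)))
  expect_error(simulate_genome(seed = 1, n_cds = 2,
                               plants = data.frame(window_offset = 0,
                                                   identity = 1,
                                                   host_cds = 5)))
})

test_that("truth labels windows by plant coverage", {
  sim <- simulate_genome(seed = 9, n_cds = 6, rrna_len = 400,
                         cds_len_range = c(200L, 300L),
                         plants = data.frame(window_offset = 100, identity = 1,
                                             host_cds = 2))
  tr <- sim$truth
  expect_equal(tr$expected[tr$offset == 100], "hit")
  expect_true(all(tr$expected[tr$offset < 5 | tr$offset > 200] == "no_hit"))
  expect_true(all(tr$expected[tr$offset %in% c(5, 195)] == "ambiguous"))
  no_plant <- simulate_genome(seed = 9, n_cds = 3, rrna_len = 300,
                              cds_len_range = c(150L, 250L))
  expect_true(all(no_plant$truth$expected == "no_hit"))
})

test_that("planted homology is recovered and clean fixtures stay clean", {
  for (seed in 1:10) {
    sim <- simulate_genome(
      seed = seed, n_cds = 6, cds_len_range = c(250L, 400L), rrna_len = 300,
      plants = data.frame(window_offset = 100,
                          identity = c(0.95, 0.70), host_cds = c(2, 5))
    )
    sets <- collect_sets(sim$annotations, sim$genome)
    frags <- fragment_sequences(sets$targets[1, ], window = 100, leap = 5)
    tal <- tally_hits(align_fragments(frags, sets$subjects), frags)
    tal <- merge(tal, sim$truth, by = "offset")
    # the 95%-identity plant forces hits on fully covered windows
    expect_true(all(tal$qualifying_hits[tal$expected == "hit"] >= 1),
                label = paste("recovery, seed", seed))
    # windows away from any plant never hit; the 70% plant must not rescue
    host5 <- tal$qualifying_hits[tal$expected == "no_hit"]
    expect_true(all(host5 == 0), label = paste("specificity, seed", seed))
  }
})

test_that("end-to-end design avoids planted windows while clean ones remain", {
  sim <- simulate_genome(seed = 15, n_cds = 8, cds_len_range = c(250L, 400L),
                         rrna_len = 400,
                         plants = data.frame(window_offset = 150, identity = 1,
                                             host_cds = 4))
  res <- run_design(genome = sim$genome, annotation = sim$annotations, k = 5)
  expect_true(all(res$probes$qualifying_hits == 0))
  # windows sharing >= 90 nt with the exact plant are guaranteed qualifying
  # hits (identity 100% over >= 90% of the window), so selection must skip
  # them while zero-hit windows remain
  offs <- sim$truth$offset
  overlap <- pmin(offs + 100, 150 + 100) - pmax(offs, 150)
  core <- offs[overlap >= 90]
  tal1 <- res$tallies[res$tallies$parent_id == res$targets$id[[1]], ]
  expect_true(all(tal1$qualifying_hits[tal1$offset %in% core] >= 1))
  expect_false(any(res$probes$offset %in% core))
})
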