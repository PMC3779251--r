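#' Simulate a small genome with duplicated rRNA operons and planted homology
#'
#' Generates a deterministic synthetic genome that mimics the layout the
#' probe designer faces in a real bacterium: a set of random protein-coding
#' genes (CDS), two (or more) identical copies of an rRNA gene at distinct
#' loci, and optionally "plants" - windows of the rRNA copied into a chosen
#' CDS at a controlled per-base identity. Plants create known ground truth:
#' an exact plant forces a qualifying hit for every rRNA window it covers,
#' while untouched CDS of a few hundred bases cannot reach the 90%/90%
#' screening thresholds by chance.
#'
#' Defaults emulate a strongly GC-rich actinobacterial genome (GC 0.67, the
#' neighbourhood of *Mycobacterium*), scaled down to run in seconds: 20 CDS
#' of 300-900 nt and a 1500-nt rRNA (16S-like) present in two copies.
#' Substitution-only mutation keeps the planted identity analytic:
#' expected identity = `identity` exactly.
#'
#' @param seed Integer seed; every random draw flows from it, and two calls
#'   with the same arguments are byte-identical.
#' @param n_cds Number of CDS features.
#' @param cds_len_range Length range (min, max) of each CDS, nt.
#' @param gc GC fraction of all random sequence.
#' @param rrna_len Length of the rRNA gene, nt.
#' @param rrna_copies Number of identical rRNA gene copies (default 2,
#'   mirroring paralogous operons).
#' @param plants `NULL`, or a data frame with columns `window_offset`
#'   (0-based start of the copied rRNA window), `identity` (expected
#'   fraction, 0-1), `host_cds` (1-based CDS index) and optionally
#'   `plant_len` (default 100).
#' @param window Probe window size used to enumerate truth rows (default 100).
#' @param leap Fragmentation leap used for the truth table (default 5).
#' @param spacer_len_range Length range of random intergenic spacers, nt.
#' @param out_dir If non-`NULL`, writes `genome.fasta`, `annotations.gff3`
#'   and `truth.tsv` there.
#' @return List with `genome` (one-row tibble `id`, `sequence`),
#'   `annotations` (tibble as from [read_annotations()]), `truth` (tibble
#'   with one row per rRNA window offset: `offset`, `covered_by_plant`,
#'   `plant_identity`, `expected` in `hit`/`no_hit`/`ambiguous`), `rrna`
#'   (the rRNA sequence) and the normalized `plants` table.
#' @export
simulate_genome <- function(seed = 1L, n_cds = 20L, cds_len_range = c(300L, 900L),
                            gc = 0.67, rrna_len = 1500L, rrna_copies = 2L,
                            plants = NULL, window = 100L, leap = 5L,
                            spacer_len_range = c(50L, 200L), out_dir = NULL) {
  stopifnot(gc > 0, gc < 1, n_cds >= 1, rrna_copies >= 1,
            rrna_len >= window)
  plants <- normalize_plants(plants, n_cds, rrna_len, window)
  withr::with_seed(as.integer(seed), {
    rrna <- random_dna(rrna_len, gc)
    cds <- purrr::map_chr(seq_len(n_cds), function(i) {
      random_dna(sample(cds_len_range[1]:cds_len_range[2], 1L), gc)
    })
    # plant rRNA windows into host CDS (substitutions only)
    for (p in seq_len(nrow(plants))) {
      host <- plants$host_cds[[p]]
      plen <- plants$plant_len[[p]]
      frag <- substring(rrna, plants$window_offset[[p]] + 1L,
                        plants$window_offset[[p]] + plen)
      frag <- mutate_sequence(frag, 1 - plants$identity[[p]])
      hseq <- cds[[host]]
      if (nchar(hseq) < plen) {
        stop("host CDS ", host, " shorter than the plant", call. = FALSE)
      }
      at <- sample.int(nchar(hseq) - plen + 1L, 1L)
      substr(hseq, at, at + plen - 1L) <- frag
      cds[[host]] <- hseq
      prev <- plants$placed_at[seq_len(p - 1L)][plants$host_cds[seq_len(p - 1L)] == host]
      if (any(abs(prev - at) < plen)) {
        stop("overlapping plants in CDS ", host, call. = FALSE)
      }
      plants$placed_at[[p]] <- at
    }
    # feature order: shuffle CDS and rRNA copies together
    feats <- tibble::tibble(
      locus_tag = c(sprintf("CDS_%04d", seq_len(n_cds)),
                    sprintf("RRNA_%04d", seq_len(rrna_copies))),
      feature_kind = c(rep("CDS", n_cds), rep("rRNA", rrna_copies)),
      sequence = c(cds, rep(rrna, rrna_copies)),
      strand = c(sample(c("+", "-"), n_cds, replace = TRUE),
                 rep("+", rrna_copies)),
      product = c(rep("hypothetical protein", n_cds),
                  rep("ribosomal RNA", rrna_copies))
    )
    feats <- feats[sample.int(nrow(feats)), , drop = FALSE]
    # assemble genome: spacer, feature, spacer, feature, ..., spacer
    pieces <- character(2L * nrow(feats) + 1L)
    pos <- 0L
    starts <- ends <- integer(nrow(feats))
    for (i in seq_len(nrow(feats))) {
      sp <- random_dna(sample(spacer_len_range[1]:spacer_len_range[2], 1L), gc)
      pieces[[2L * i - 1L]] <- sp
      pos <- pos + nchar(sp)
      fs <- feats$sequence[[i]]
      genomic <- if (feats$strand[[i]] == "-") revcomp(fs) else fs
      pieces[[2L * i]] <- genomic
      starts[[i]] <- pos + 1L
      ends[[i]] <- pos + nchar(genomic)
      pos <- pos + nchar(genomic)
    }
    pieces[[2L * nrow(feats) + 1L]] <-
      random_dna(sample(spacer_len_range[1]:spacer_len_range[2], 1L), gc)
    genome_seq <- paste(pieces, collapse = "")
  })
  annotations <- tibble::tibble(
    locus_tag = feats$locus_tag,
    feature_kind = feats$feature_kind,
    start = starts, end = ends,
    strand = feats$strand,
    product = feats$product
  )
  genome <- tibble::tibble(id = sprintf("synth_seed%d", as.integer(seed)),
                           sequence = genome_seq)
  truth <- plant_truth(plants, rrna_len, window, leap)
  out <- list(genome = genome, annotations = annotations, truth = truth,
              rrna = rrna, plants = plants)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(out_dir, "genome.fasta"))
    write_gff3(annotations, genome, file.path(out_dir, "annotations.gff3"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
    out$paths <- list(genome = file.path(out_dir, "genome.fasta"),
                      annotations = file.path(out_dir, "annotations.gff3"),
                      truth = file.path(out_dir, "truth.tsv"))
  }
  out
}

normalize_plants <- function(plants, n_cds, rrna_len, window) {
  if (is.null(plants) || (is.data.frame(plants) && nrow(plants) == 0L)) {
    return(tibble::tibble(window_offset = integer(), identity = numeric(),
                          host_cds = integer(), plant_len = integer(),
                          placed_at = integer()))
  }
  plants <- tibble::as_tibble(plants)
  if (!"plant_len" %in% names(plants)) plants$plant_len <- as.integer(window)
  stopifnot(all(plants$identity >= 0), all(plants$identity <= 1),
            all(plants$host_cds >= 1), all(plants$host_cds <= n_cds),
            all(plants$window_offset >= 0),
            all(plants$window_offset + plants$plant_len <= rrna_len))
  plants$placed_at <- NA_integer_
  plants
}

# Expected screening outcome per rRNA window. Only windows lying entirely
# inside a high-identity plant are guaranteed a qualifying hit (a window must
# be covered over >= 90% of its length); windows not touching any plant are
# guaranteed none; everything else is ambiguous.
plant_truth <- function(plants, rrna_len, window, leap) {
  offs <- seq.int(0L, rrna_len - window, by = leap)
  covered <- rep(FALSE, length(offs))
  ident <- rep(NA_real_, length(offs))
  touches <- rep(FALSE, length(offs))
  for (p in seq_len(nrow(plants))) {
    p0 <- plants$window_offset[[p]]
    p1 <- p0 + plants$plant_len[[p]]
    inside <- offs >= p0 & (offs + window) <= p1
    overlap <- offs < p1 & (offs + window) > p0
    covered <- covered | inside
    touches <- touches | overlap
    ident[inside] <- pmax(ident[inside], plants$identity[[p]], na.rm = TRUE)
  }
  tibble::tibble(
    offset = offs,
    covered_by_plant = covered,
    plant_identity = ident,
    expected = dplyr::case_when(
      covered & ident >= 0.95 ~ "hit",
      !touches ~ "no_hit",
      TRUE ~ "ambiguous"
    )
  )
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitution-only mutation at per-base rate p; substituted bases always
# change, so realized identity is Binomial(n, 1 - p)/n with mean 1 - p.
mutate_sequence <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

# Plain GFF3 writer for the simulator's feature table.
write_gff3 <- function(annotations, genome, path) {
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", genome$id, nchar(genome$sequence)),
    sprintf("%s\triboprobe_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;product=%s",
            genome$id, annotations$feature_kind, annotations$start,
            annotations$end, annotations$strand, annotations$locus_tag,
            annotations$locus_tag, annotations$product)
  )
  writeLines(lines, path)
  invisible(path)
}
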