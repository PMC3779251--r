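#' Run the full probe design pipeline
#'
#' Executes extract -> fragment -> specificity screen -> hairpin screen ->
#' selection on a genome + annotation pair and returns a `probe_design`
#' object. The pipeline is deterministic: rerunning with identical inputs
#' and parameters reproduces identical probes and reports.
#'
#' @param genome Path to a FASTA/GenBank genome file, or a one-row tibble
#'   from [read_genome()].
#' @param annotation Path to a GenBank/GFF3 annotation file, or a tibble
#'   from [read_annotations()]. May be omitted when `genome` is a GenBank
#'   file carrying its own feature table.
#' @param targets Target selector passed to [collect_sets()]: locus tags or
#'   `"kind:rRNA"`.
#' @param window,leap Fragmentation parameters (see [fragment_sequences()]).
#' @param thresholds [screen_thresholds()] for hit qualification.
#' @param hairpin [hairpin_params()] for the structure screen.
#' @param k Probes to select per target gene.
#' @param spacing,exclude_hairpins Passed to [select_probes()].
#' @param subject_kinds Feature kinds screened against (default `"CDS"`).
#' @param mode Alignment backend mode (see [align_fragments()]); ignored
#'   when `hits_file` is given.
#' @param hits_file Optional path to pre-computed hits in 12-column BLAST
#'   tabular format; replaces the internal aligner.
#' @param ka [karlin_altschul()] parameters for the internal aligner.
#' @param out_dir If non-`NULL`, artifacts are written there:
#'   `probes.fasta`, `probes.tsv`, `fragments.tsv`, `summary.json`,
#'   `run_log.txt`.
#' @return A `probe_design` object: list with `probes`, `tallies`,
#'   `fragments`, `hits`, `targets`, `subjects` and `params`. Methods:
#'   [print()], [tidy()], [glance()], [autoplot()].
#' @export
run_design <- function(genome, annotation = NULL, targets = "kind:rRNA",
                       window = 100L, leap = 5L,
                       thresholds = screen_thresholds(),
                       hairpin = hairpin_params(),
                       k = 5L, spacing = c("none", "greedy"),
                       exclude_hairpins = FALSE,
                       subject_kinds = "CDS",
                       mode = c("seed_extend", "exhaustive"),
                       hits_file = NULL,
                       ka = karlin_altschul(),
                       out_dir = NULL) {
  spacing <- match.arg(spacing)
  mode <- match.arg(mode)
  genome_path <- NULL
  if (is.character(genome)) {
    genome_path <- genome
    genome <- read_genome(genome)
  }
  if (is.null(annotation)) {
    if (is.null(genome_path)) {
      stop("annotation is required when the genome is given in memory",
           call. = FALSE)
    }
    annotation <- genome_path # GenBank file carrying its own features
  }
  if (is.character(annotation)) {
    annotation <- read_annotations(annotation)
  }

  sets <- collect_sets(annotation, genome, targets = targets,
                       subject_kinds = subject_kinds)
  fragments <- fragment_sequences(sets$targets, window = window, leap = leap)
  hits <- if (is.null(hits_file)) {
    align_fragments(fragments, sets$subjects, mode = mode, ka = ka)
  } else {
    parse_tabular_hits(hits_file)
  }
  tallies <- tally_hits(hits, fragments, thresholds = thresholds)
  frag_hp <- screen_hairpins(fragments, hairpin)
  tallies <- dplyr::left_join(
    tallies,
    dplyr::select(frag_hp, "fragment_id", "hairpin_flag", "n_hairpins"),
    by = "fragment_id"
  )
  probes <- select_probes(tallies, k = k, spacing = spacing,
                          exclude_hairpins = exclude_hairpins)
  probes <- dplyr::left_join(
    probes, dplyr::select(fragments, "fragment_id", "sequence"),
    by = "fragment_id"
  )

  res <- structure(list(
    probes = probes,
    tallies = tallies,
    fragments = fragments,
    hits = hits,
    targets = sets$targets,
    subjects = sets$subjects,
    params = list(window = window, leap = leap, thresholds = thresholds,
                  hairpin = hairpin, k = k, spacing = spacing,
                  exclude_hairpins = exclude_hairpins,
                  subject_kinds = subject_kinds,
                  backend = if (is.null(hits_file)) mode else "tabular",
                  ka = ka)
  ), class = "probe_design")
  if (!is.null(out_dir)) write_design_artifacts(res, out_dir)
  res
}

write_design_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probes_fa <- dplyr::transmute(
    res$probes,
    id = sprintf("%s|rank%d|hits%d", .data$fragment_id, .data$rank,
                 .data$qualifying_hits),
    sequence = .data$sequence
  )
  write_fasta(probes_fa, file.path(out_dir, "probes.fasta"))
  readr::write_tsv(res$probes, file.path(out_dir, "probes.tsv"))
  readr::write_tsv(res$tallies, file.path(out_dir, "fragments.tsv"))
  g <- glance(res)
  jsonlite::write_json(as.list(g), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(
    sprintf("riboprobe %s", as.character(utils::packageVersion("riboprobe"))),
    sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("window=%d leap=%d k=%d spacing=%s backend=%s",
            res$params$window, res$params$leap, res$params$k,
            res$params$spacing, res$params$backend),
    sprintf("thresholds: evalue<%g identity>=%g%% hitlen>=%g%%",
            res$params$thresholds$max_evalue,
            res$params$thresholds$min_identity_pct,
            res$params$thresholds$min_hitlen_pct),
    sprintf("targets: %s", paste(res$targets$id, collapse = ", ")),
    sprintf("subjects: %d sequences, %d nt", nrow(res$subjects),
            sum(nchar(res$subjects$sequence)))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.probe_design <- function(x, ...) {
  g <- glance(x)
  cat("<probe_design>\n")
  cat(sprintf("  targets: %d gene(s), %d candidate window(s) of %d nt (leap %d)\n",
              g$n_targets, g$n_fragments, x$params$window, x$params$leap))
  cat(sprintf("  subjects: %d transcript(s), %d nt screened (backend %s)\n",
              nrow(x$subjects), sum(nchar(x$subjects$sequence)),
              x$params$backend))
  cat(sprintf("  zero-hit windows: %d/%d; selected probes: %d (max tally %d)\n",
              g$n_zero_hit, g$n_fragments, g$n_selected, g$max_hits_selected))
  invisible(x)
}

#' Tidy the selected probes of a design run
#'
#' @param x A `probe_design` object.
#' @param ... Unused.
#' @return The selected-probe tibble (one row per probe with rank, tally,
#'   hairpin flag and sequence).
#' @method tidy probe_design
#' @export
tidy.probe_design <- function(x, ...) x$probes

#' One-row summary of a design run
#'
#' @param x A `probe_design` object.
#' @param ... Unused.
#' @return One-row tibble: target/fragment/hit counts, zero-hit window
#'   count, number of selected probes and their worst tally.
#' @method glance probe_design
#' @export
glance.probe_design <- function(x, ...) {
  tibble::tibble(
    n_targets = nrow(x$targets),
    n_subjects = nrow(x$subjects),
    n_fragments = nrow(x$fragments),
    n_hits = nrow(x$hits),
    n_zero_hit = sum(x$tallies$qualifying_hits == 0L),
    n_hairpin_flagged = sum(x$tallies$hairpin_flag),
    n_selected = nrow(x$probes),
    max_hits_selected = if (nrow(x$probes)) max(x$probes$qualifying_hits) else NA_integer_
  )
}

#' Plot the qualifying-hit profile of a design run
#'
#' One panel per target gene: qualifying hits of every candidate window by
#' its offset, with the selected probes marked.
#'
#' @param object A `probe_design` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probe_design
#' @export
autoplot.probe_design <- function(object, ...) {
  ggplot(object$tallies, aes(x = .data$offset, y = .data$qualifying_hits)) +
    geom_step(colour = "grey40") +
    geom_point(data = object$probes,
               aes(colour = factor(.data$rank)), size = 2) +
    facet_wrap(~parent_id, ncol = 1) +
    labs(x = "window offset in target gene (nt)",
         y = "qualifying hits",
         colour = "probe rank",
         title = "Candidate-window specificity profile") +
    theme_minimal()
}
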