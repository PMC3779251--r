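#' Read a genome sequence from FASTA or GenBank
#'
#' Reads a single-record genome file and returns the sequence normalized to
#' upper case over the alphabet `A`, `C`, `G`, `T`, `N`. Multi-record files
#' are rejected: the design pipeline targets one replicon at a time.
#'
#' @param path Path to the genome file.
#' @param format `"auto"` (default, guessed from the first non-blank line),
#'   `"fasta"` or `"genbank"`.
#' @param strict If `TRUE` (default) any residue outside `A/C/G/T/N` after
#'   upper-casing is an error; if `FALSE`, IUPAC ambiguity codes and other
#'   letters are mapped to `N`.
#' @return A one-row tibble with columns `id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank"),
                        strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("genome file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) && startsWith(first[[1]], ">")) "fasta"
              else if (length(first) && grepl("^LOCUS", first[[1]])) "genbank"
              else stop("cannot guess format of ", path,
                        " (expected FASTA '>' or GenBank 'LOCUS')", call. = FALSE)
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no sequence records in ", path, call. = FALSE)
    if (length(set) > 1L) {
      stop("multiple records in ", path,
           ": the genome reader accepts exactly one sequence", call. = FALSE)
    }
    id <- sub("\\s.*$", "", names(set)[[1]])
    seq <- as.character(set[[1]])
  } else {
    gb <- parse_genbank(path)
    id <- gb$id
    seq <- gb$sequence
  }
  tibble::tibble(id = id, sequence = normalize_residues(seq, strict = strict))
}

# Upper-case and police the nucleotide alphabet.
normalize_residues <- function(seq, strict = TRUE) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    if (strict) {
      stop("illegal residue(s) ", paste(unique(strsplit(bad, "")[[1]]), collapse = ","),
           " (strict mode accepts only A/C/G/T/N)", call. = FALSE)
    }
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  seq
}

#' Read genome annotations (GenBank flat file or GFF3)
#'
#' Retains `CDS`, `rRNA` and `tRNA` features that carry a `locus_tag`;
#' features without one are skipped with a warning. Coordinates stay in the
#' 1-based inclusive convention both dialects use; strand is mapped to
#' `"+"`/`"-"`. Compound (`join`/`order`) and origin-spanning locations are
#' rejected.
#'
#' @param path Path to the annotation file.
#' @param dialect `"auto"` (default), `"genbank"` or `"gff3"`.
#' @return A tibble with columns `locus_tag`, `feature_kind`, `start`, `end`,
#'   `strand`, `product`.
#' @export
read_annotations <- function(path, dialect = c("auto", "genbank", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    dialect <- if (length(first) && grepl("^LOCUS", first[[1]])) "genbank"
               else if (length(first) && grepl("^##gff|\t", first[[1]])) "gff3"
               else stop("cannot guess annotation dialect of ", path, call. = FALSE)
  }
  recs <- if (dialect == "genbank") parse_genbank(path)$features else read_gff3(path)
  if (anyDuplicated(recs$locus_tag)) {
    dup <- unique(recs$locus_tag[duplicated(recs$locus_tag)])
    stop("duplicated locus_tag(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(recs$end < recs$start)) {
    stop("malformed coordinates: end < start for ",
         recs$locus_tag[which(recs$end < recs$start)[1]], call. = FALSE)
  }
  recs
}

KEPT_KINDS <- c("CDS", "rRNA", "tRNA")

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df <- df[df$type %in% KEPT_KINDS, , drop = FALSE]
  lt <- if ("locus_tag" %in% names(df)) as.character(df$locus_tag) else rep(NA_character_, nrow(df))
  keep <- !is.na(lt) & nzchar(lt)
  if (any(!keep)) {
    warning(sum(!keep), " feature(s) without locus_tag skipped", call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  lt <- lt[keep]
  prod <- if ("product" %in% names(df)) as.character(df$product) else rep(NA_character_, nrow(df))
  tibble::tibble(
    locus_tag = lt,
    feature_kind = as.character(df$type),
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
    product = prod
  )
}

# Minimal GenBank flat-file parser: LOCUS/VERSION header, FEATURES table
# (CDS/rRNA/tRNA with locus_tag and product qualifiers), ORIGIN sequence.
# Compound locations (join/order) and partial-only weirdness are rejected;
# '<'/'>' partial markers are stripped.
parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1]])) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  if (sum(grepl("^LOCUS", lines)) > 1L) {
    stop("multiple records in ", path,
         ": the GenBank reader accepts exactly one record", call. = FALSE)
  }
  id <- strsplit(trimws(sub("^LOCUS", "", lines[[1]])), "\\s+")[[1]][1]
  vline <- grep("^VERSION", lines, value = TRUE)
  if (length(vline)) {
    v <- strsplit(trimws(sub("^VERSION", "", vline[[1]])), "\\s+")[[1]][1]
    if (!is.na(v) && nzchar(v)) id <- v
  }

  feat_from <- grep("^FEATURES", lines)
  orig_from <- grep("^ORIGIN", lines)
  features <- tibble::tibble(
    locus_tag = character(), feature_kind = character(),
    start = integer(), end = integer(), strand = character(),
    product = character()
  )
  if (length(feat_from)) {
    to <- if (length(orig_from)) orig_from[[1]] - 1L else length(lines)
    flines <- lines[(feat_from[[1]] + 1L):to]
    features <- parse_genbank_features(flines)
  }
  sequence <- ""
  if (length(orig_from)) {
    slines <- lines[(orig_from[[1]] + 1L):length(lines)]
    slines <- slines[!grepl("^//", slines)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(slines, collapse = "")))
  }
  list(id = id, sequence = sequence, features = features)
}

parse_genbank_features <- function(flines) {
  # A new feature starts at column 6 (5 spaces + key); qualifiers start with /.
  is_key <- grepl("^ {5}\\S", flines)
  idx <- which(is_key)
  out <- vector("list", length(idx))
  n_no_tag <- 0L
  for (i in seq_along(idx)) {
    from <- idx[[i]]
    to <- if (i < length(idx)) idx[[i + 1L]] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[[1]])
    if (!key %in% KEPT_KINDS) next
    loc <- trimws(sub("^ {5}\\S+\\s*", "", block[[1]]))
    # location may continue on following lines until a qualifier starts
    j <- 2L
    while (j <= length(block) && !grepl("^\\s+/", block[[j]])) {
      loc <- paste0(loc, trimws(block[[j]]))
      j <- j + 1L
    }
    parsed <- parse_genbank_location(loc)
    quals <- paste(trimws(block[-1]), collapse = " ")
    lt <- qual_value(quals, "locus_tag")
    prod <- qual_value(quals, "product")
    if (is.na(lt)) {
      n_no_tag <- n_no_tag + 1L
      next
    }
    out[[i]] <- tibble::tibble(
      locus_tag = lt, feature_kind = key,
      start = parsed$start, end = parsed$end, strand = parsed$strand,
      product = prod
    )
  }
  if (n_no_tag > 0L) {
    warning(n_no_tag, " feature(s) without locus_tag skipped", call. = FALSE)
  }
  dplyr::bind_rows(out)
}

parse_genbank_location <- function(loc) {
  if (grepl("join\\(|order\\(", loc)) {
    stop("compound (join/order) feature locations are not supported: ", loc,
         call. = FALSE)
  }
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- gsub("[<>]", "", loc)
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3L) {
    stop("malformed coordinates in location: ", loc, call. = FALSE)
  }
  start <- as.integer(m[[2]]); end <- as.integer(m[[3]])
  if (end < start) stop("malformed coordinates: end < start in ", loc, call. = FALSE)
  list(start = start, end = end, strand = strand)
}

qual_value <- function(quals, name) {
  pat <- paste0("/", name, "=\"([^\"]*)\"")
  m <- regmatches(quals, regexec(pat, quals))[[1]]
  if (length(m) == 2L) m[[2]] else NA_character_
}

#' Extract strand-correct feature sequences from a genome
#'
#' For each annotation record, slices `genome$sequence[start..end]` (1-based
#' inclusive) and reverse-complements minus-strand features, so the returned
#' sequence always reads 5'->3' in the feature's own sense.
#'
#' @param records Annotation tibble as returned by [read_annotations()].
#' @param genome One-row genome tibble from [read_genome()].
#' @return `records` with an added `sequence` column.
#' @export
extract_features <- function(records, genome) {
  stopifnot(nrow(genome) == 1L)
  glen <- nchar(genome$sequence)
  bad <- records$start < 1L | records$end > glen | records$start > records$end
  if (any(bad)) {
    stop("feature coordinates out of genome bounds for ",
         paste(utils::head(records$locus_tag[bad], 5), collapse = ", "),
         " (genome length ", glen, ")", call. = FALSE)
  }
  seqs <- substring(genome$sequence, records$start, records$end)
  minus <- records$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  dplyr::mutate(records, sequence = seqs)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of DNA sequences (may contain `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Partition features into alignment targets and subjects
#'
#' Targets are the genes probes are designed against (here typically the
#' rRNA genes); subjects are the transcript set candidate probes must not
#' resemble (by default all CDS). Target records never appear among subjects.
#'
#' @param records Annotation tibble.
#' @param genome One-row genome tibble.
#' @param targets Either a character vector of locus tags, or a rule string
#'   `"kind:<feature_kind>"`, e.g. `"kind:rRNA"` (the default).
#' @param subject_kinds Feature kinds used as the screening subjects
#'   (default `"CDS"`).
#' @return A list with tibbles `targets` and `subjects`, each with columns
#'   `id` and `sequence`.
#' @export
collect_sets <- function(records, genome, targets = "kind:rRNA",
                         subject_kinds = "CDS") {
  if (length(targets) == 1L && grepl("^kind:", targets)) {
    kind <- sub("^kind:", "", targets)
    sel <- records$feature_kind == kind
  } else {
    sel <- records$locus_tag %in% targets
    missing <- setdiff(targets, records$locus_tag)
    if (length(missing)) {
      stop("no targets: locus tag(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (!any(sel)) stop("no targets matched the selector", call. = FALSE)
  with_seq <- extract_features(records, genome)
  tg <- with_seq[sel, , drop = FALSE]
  sj <- with_seq[!sel & with_seq$feature_kind %in% subject_kinds, , drop = FALSE]
  list(
    targets = tibble::tibble(id = tg$locus_tag, sequence = tg$sequence),
    subjects = tibble::tibble(id = sj$locus_tag, sequence = sj$sequence)
  )
}

#' Read and write sequence sets as FASTA
#'
#' Thin wrappers over Biostrings keeping the package's tabular
#' (`id`, `sequence`) representation. FASTA is written at 70 columns.
#'
#' @param x Tibble with columns `id` and `sequence`.
#' @param path Output (or input) FASTA path.
#' @return `write_fasta` returns `path` invisibly; `read_fasta` returns a
#'   tibble with columns `id` and `sequence`.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = sub("\\s.*$", "", names(set)),
                 sequence = unname(as.character(set)))
}
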