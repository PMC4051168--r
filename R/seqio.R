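# Readers/writers for the on-disk formats and the shared domain types.
#
# Conventions: sequences are uppercased on read (soft-masking is ignored);
# qualities are Phred+33 decoded to plain integer vectors; BLAST m8
# coordinates stay 1-based inclusive as in the AlignmentHit type, while
# BED/TargetInterval intervals are 0-based half-open.

parse_error <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  stop(structure(list(message = msg, call = NULL),
                 class = c("oralcap_parse_error", "error", "condition")))
}

#' Construct a set of sequence records
#'
#' The universal carrier for reads and reference sequences: a data frame with
#' columns `id`, `sequence` and an optional `qualities` list-column of integer
#' Phred scores.
#'
#' @param id character vector of non-empty record ids.
#' @param sequence character vector over `{A,C,G,T,N}` (uppercased).
#' @param qualities optional list of integer vectors, one per record, each the
#'   same length as its sequence.
#' @return a `data.frame` with columns `id`, `sequence` and, when supplied,
#'   `qualities`.
#' @export
seq_records <- function(id, sequence, qualities = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have equal length")
  if (any(!nzchar(id))) stop("record ids must be non-empty")
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  if (!is.null(qualities)) {
    if (length(qualities) != length(id))
      stop("qualities must have one entry per record")
    bad <- which(vapply(qualities, length, 0L) != nchar(sequence))
    if (length(bad))
      stop(sprintf("qualities length != sequence length for record(s): %s",
                   paste(id[bad], collapse = ", ")))
    out$qualities <- I(lapply(qualities, as.integer))
  }
  out
}

#' Construct a genome metadata table
#'
#' One row per reference genome: its length and species/genus/phylum
#' annotation, used for length-normalized abundance and taxonomic rollup.
#'
#' @param genome_id unique genome identifiers.
#' @param length_bp positive integer genome lengths.
#' @param species,genus,phylum taxonomy strings.
#' @return data.frame with the five columns above.
#' @export
genome_meta <- function(genome_id, length_bp, species, genus, phylum) {
  genome_id <- as.character(genome_id)
  if (anyDuplicated(genome_id)) stop("genome_id must be unique")
  length_bp <- as.numeric(length_bp)
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  data.frame(genome_id = genome_id, length_bp = length_bp,
             species = as.character(species), genus = as.character(genus),
             phylum = as.character(phylum), stringsAsFactors = FALSE)
}

m8_cols <- c("query_id", "subject_id", "percent_identity", "aln_length",
             "mismatches", "gap_opens", "q_start", "q_end", "s_start",
             "s_end", "evalue", "bit_score")

#' Validate a table of alignment hits
#'
#' Checks the AlignmentHit invariants: the 12 m8 columns plus `query_length`,
#' `q_start <= q_end <= query_length`, identity in `[0, 100]`.
#'
#' @param hits data.frame of hits.
#' @return `hits`, invisibly, after validation.
#' @export
validate_hits <- function(hits) {
  need <- c(m8_cols, "query_length")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$q_start > hits$q_end))
      stop("q_start > q_end in hits table")
    if (any(hits$q_end > hits$query_length))
      stop("q_end exceeds query_length in hits table")
    if (any(hits$percent_identity < 0 | hits$percent_identity > 100))
      stop("percent_identity outside [0, 100]")
    if (any(hits$evalue < 0)) stop("negative e-value in hits table")
  }
  invisible(hits)
}

empty_hits <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    percent_identity = numeric(), aln_length = integer(),
                    mismatches = integer(), gap_opens = integer(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    evalue = numeric(), bit_score = numeric(),
                    query_length = integer(), stringsAsFactors = FALSE)
  out
}

#' Read a FASTA file
#'
#' @param path path to a plain-text or gzipped FASTA file.
#' @return a [seq_records()] data frame (no qualities); empty file gives a
#'   zero-row frame. Wrapped sequence lines are concatenated; sequences are
#'   uppercased.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) | seq_along(lines) == 0
  ids <- character(); seqs <- character()
  cur_id <- NULL; cur_seq <- character(); cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur_seq, collapse = "")
    if (!nzchar(s)) parse_error(sprintf("record '%s' has empty sequence", cur_id),
                                cur_line)
    ids[[length(ids) + 1L]] <<- cur_id
    seqs[[length(seqs) + 1L]] <<- toupper(s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*$", ln)) next
    if (startsWith(ln, ">")) {
      flush()
      cur_id <- sub("^>\\s*", "", ln)
      cur_id <- sub("\\s.*$", "", cur_id)
      if (!nzchar(cur_id)) parse_error("empty FASTA header", i)
      cur_seq <- character(); cur_line <- i
    } else {
      if (is.null(cur_id)) parse_error("sequence data before first header", i)
      cur_seq[[length(cur_seq) + 1L]] <- gsub("\\s", "", ln)
    }
  }
  flush()
  if (!length(ids)) return(seq_records(character(), character()))
  seq_records(ids, seqs)
}

#' Write a FASTA file
#'
#' @param records a [seq_records()] frame.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a 4-line-per-record FASTQ file (optionally gzipped).
#' @return a [seq_records()] frame with a `qualities` list-column of integer
#'   Phred scores.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) return(seq_records(character(), character(), list()))
  if (length(lines) %% 4L != 0L)
    parse_error("FASTQ file length is not a multiple of 4", length(lines))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) parse_error("FASTQ header does not start with '@'",
                               (bad[1] - 1L) * 4L + 1L)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) parse_error("FASTQ separator line does not start with '+'",
                               (bad[1] - 1L) * 4L + 3L)
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    parse_error(sprintf("sequence/quality length mismatch for read '%s'",
                        sub("^@", "", sub("\\s.*$", "", hdr[bad[1]]))),
                (bad[1] - 1L) * 4L + 4L)
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  quals <- lapply(qual, function(qs) utf8ToInt(qs) - 33L)
  seq_records(ids, seqs, quals)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param records a [seq_records()] frame carrying qualities; records without
#'   qualities are written at a constant Q40.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  n <- nrow(records)
  qs <- if ("qualities" %in% names(records)) records$qualities
        else lapply(nchar(records$sequence), function(l) rep.int(40L, l))
  qstr <- vapply(qs, function(q) intToUtf8(q + 33L), "")
  out <- character(4L * n)
  if (n) {
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", records$id)
    out[seq(2L, by = 4L, length.out = n)] <- records$sequence
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- qstr
  }
  writeLines(out, path)
  invisible(path)
}

#' Read BLAST tabular (m8) alignments
#'
#' Reads the 12-column tab-separated m8 dialect and attaches each query's read
#' length from a sidecar map (m8 itself carries no query length, but the tier
#' rules need read coverage = alignment span / read length).
#'
#' @param path path to the m8 file.
#' @param read_lengths named integer vector or list mapping `query_id` to read
#'   length in bp.
#' @return an AlignmentHit data.frame (the 12 m8 columns plus `query_length`).
#' @export
read_m8 <- function(path, read_lengths) {
  if (!file.exists(path)) stop("no such file: ", path)
  read_lengths <- unlist(read_lengths)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) parse_error("expected 12 tab-separated columns", bad[1])
  m <- do.call(rbind, parts)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(hits$query_id), names(read_lengths))
  if (length(unknown))
    stop("query id(s) absent from read_lengths: ",
         paste(unknown, collapse = ", "))
  hits$query_length <- as.integer(read_lengths[hits$query_id])
  validate_hits(hits)
  hits
}

fmt_num <- function(x) {
  # 6 significant digits, no scientific-notation surprises on round trip
  ifelse(x == floor(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                               trim = TRUE),
         formatC(x, digits = 6, format = "g"))
}

#' Write domain tables to disk
#'
#' Deterministic writer for the pipeline's tabular outputs. Rows are sorted by
#' primary key; BED is written 0-based half-open; floats are written to 6
#' significant digits.
#'
#' @param objects the table to write: an AlignmentHit frame (`m8`), an
#'   abundance table (`abundance_tsv`), a genotype-call frame
#'   (`genotype_tsv`), a substitution profile (`profile_tsv`) or a
#'   TargetInterval frame (`bed`).
#' @param path output path.
#' @param kind one of `"m8"`, `"abundance_tsv"`, `"genotype_tsv"`,
#'   `"profile_tsv"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_tables <- function(objects, path, kind) {
  kinds <- c("m8", "abundance_tsv", "genotype_tsv", "profile_tsv", "bed")
  if (!kind %in% kinds)
    stop("unknown kind '", kind, "'; expected one of: ",
         paste(kinds, collapse = ", "))
  if (kind == "m8") {
    h <- objects
    h <- h[order(h$query_id, h$subject_id, -h$bit_score), , drop = FALSE]
    rows <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                    h$query_id, h$subject_id, fmt_num(h$percent_identity),
                    as.integer(h$aln_length), as.integer(h$mismatches),
                    as.integer(h$gap_opens), as.integer(h$q_start),
                    as.integer(h$q_end), as.integer(h$s_start),
                    as.integer(h$s_end),
                    formatC(h$evalue, digits = 6, format = "g"),
                    fmt_num(h$bit_score))
    writeLines(rows, path)
    return(invisible(path))
  }
  if (kind == "bed") {
    b <- objects[order(objects$chrom, objects$start), , drop = FALSE]
    if (nrow(b) && any(b$start >= b$end)) stop("BED intervals need start < end")
    writeLines(sprintf("%s\t%d\t%d", b$chrom, as.integer(b$start),
                       as.integer(b$end)), path)
    return(invisible(path))
  }
  df <- if (kind == "abundance_tsv") abundance_to_df(objects)
        else if (kind == "profile_tsv") profile_to_df(objects)
        else objects
  key <- intersect(c("taxon", "gene", "strand", "position", "pos", "sample"),
                   names(df))
  if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back tables written by [write_tables()]
#'
#' @param path file path.
#' @param kind one of `"abundance_tsv"`, `"genotype_tsv"`, `"profile_tsv"`,
#'   `"bed"` (use [read_m8()] for `m8`).
#' @return a data.frame.
#' @export
read_tables <- function(path, kind) {
  if (kind == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end"),
                     colClasses = c("character", "integer", "integer"))
    return(df)
  }
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read 3-column BED target intervals (0-based half-open)
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`; errors (with the line
#'   number) when `start >= end`.
#' @export
read_bed <- function(path) {
  df <- read_tables(path, "bed")
  bad <- which(df$start >= df$end)
  if (length(bad)) parse_error("interval with start >= end", bad[1])
  df
}
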