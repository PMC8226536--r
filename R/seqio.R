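#' Construct a sequence record
#'
#' A sequence record is a named nucleotide sequence over the alphabet
#' \code{A, C, G, T, N}. Sequences are stored uppercase.
#'
#' @param id Non-empty record identifier.
#' @param seq Nucleotide string of length >= 1.
#' @param allow_n Whether \code{N} is permitted (\code{TRUE} for genomic
#'   sequence, \code{FALSE} for synthesized oligos such as primers).
#' @return An object of class \code{seq_record} with fields \code{id} and
#'   \code{seq}.
#' @export
seq_record <- function(id, seq, allow_n = TRUE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("seq_record: 'id' must be a non-empty string")
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq))
    stop("seq_record: 'seq' must be a non-empty string")
  check_alphabet(seq, id = id, allow_n = allow_n)
  structure(list(id = id, seq = seq), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)\n", x$id, nchar(x$seq)))
  invisible(x)
}

# Accept a seq_record, a DNAString-like object, or a plain string.
as_seq_string <- function(x) {
  if (inherits(x, "seq_record")) return(x$seq)
  toupper(as.character(x))
}

record_id <- function(x, default = "seq") {
  if (inherits(x, "seq_record")) x$id else default
}

check_alphabet <- function(seq, id = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pat, seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' in '%s' at position %d",
                 substr(seq, bad, bad), id, bad))
  invisible(TRUE)
}

#' Parse a FASTA file into sequence records
#'
#' Sequences are uppercased on input; the record order of the file is
#' preserved. Duplicate ids, an empty file, and characters outside
#' \code{A, C, G, T, N} are errors (the offending position is reported).
#'
#' @param path Path to a FASTA file.
#' @param text Alternatively, FASTA content as a character scalar/vector.
#' @return A list of [seq_record] objects.
#' @export
parse_fasta <- function(path = NULL, text = NULL) {
  if (is.null(path) && is.null(text))
    stop("parse_fasta: supply 'path' or 'text'")
  if (!is.null(text)) {
    path <- tempfile(fileext = ".fa")
    on.exit(unlink(path), add = TRUE)
    writeLines(text, path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("parse_fasta: ", conditionMessage(e)))
  if (length(set) == 0L)
    stop("parse_fasta: no FASTA records found")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("parse_fasta: duplicate record id '", dup[[1L]], "'")
  seqs <- toupper(as.character(set))
  mapply(function(i, s) seq_record(i, s), ids, seqs,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records as FASTA
#'
#' Lines are wrapped at 70 columns; a write/parse round trip is the identity.
#'
#' @param records A list of [seq_record] objects (or a single record).
#' @param path Output file path.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- Biostrings::BStringSet(vapply(records, as_seq_string, ""))
  names(seqs) <- vapply(records, record_id, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Sequence string (or [seq_record]) over \code{A, C, G, T, N}.
#' @return The reverse complement string; length is preserved and the
#'   operation is an involution.
#' @export
reverse_complement <- function(seq) {
  s <- as_seq_string(seq)
  check_alphabet(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Construct a 1-based inclusive genomic interval
#'
#' @param chrom Chromosome/record name.
#' @param start,end 1-based inclusive bounds, \code{start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return An object of class \code{genomic_interval}.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end))
    stop("genomic_interval: non-integer bounds")
  if (start < 1L) stop("genomic_interval: start must be >= 1")
  if (start > end) stop("genomic_interval: start > end")
  if (!strand %in% c("+", "-")) stop("genomic_interval: bad strand")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d(%s) span %d bp\n",
              x$chrom, x$start, x$end, x$strand, interval_span(x)))
  invisible(x)
}

#' Parse a coordinate string into a genomic interval
#'
#' Accepts the form \code{"<chrom>: <start>-<end>"} with optional whitespace,
#' e.g. \code{"chr19: 44891220-44903689"}. Strand defaults to \code{"+"}.
#'
#' @param text Coordinate string.
#' @return A [genomic_interval].
#' @export
parse_coordinate <- function(text) {
  m <- regmatches(text,
                  regexec("^\\s*(\\S+?)\\s*:\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$",
                          text))[[1L]]
  if (length(m) != 4L)
    stop("parse_coordinate: malformed coordinate string '", text, "'")
  genomic_interval(m[[2L]], as.integer(m[[3L]]), as.integer(m[[4L]]))
}

#' Span of a genomic interval in base pairs
#'
#' @param interval A [genomic_interval].
#' @return Integer span \code{end - start + 1}.
#' @export
interval_span <- function(interval) {
  interval$end - interval$start + 1L
}

#' Format a genomic interval as a coordinate string
#' @param interval A [genomic_interval].
#' @return \code{"<chrom>: <start>-<end>"}.
#' @export
format_coordinate <- function(interval) {
  sprintf("%s: %d-%d", interval$chrom, interval$start, interval$end)
}

intervals_overlap <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start <= b$end && b$start <= a$end
}

#' Construct a gene model from ordered exons
#'
#' Exons are 1-based inclusive genomic intervals on one chromosome, sorted and
#' non-overlapping; introns are derived as the gaps between consecutive exons.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exon_starts,exon_ends Integer vectors of equal length (>= 1).
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  exon_starts <- as.integer(exon_starts); exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) < 1L || length(exon_starts) != length(exon_ends))
    stop("gene_model: need >= 1 exon with matching starts/ends")
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
  if (any(exon_starts > exon_ends))
    stop("gene_model: exon start > end")
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] <= exon_ends[-length(exon_ends)]))
    stop("gene_model: exons overlap")
  if (!strand %in% c("+", "-")) stop("gene_model: bad strand")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = data.frame(start = exon_starts, end = exon_ends)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s(%s): %d exons, %d introns, span %d bp\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              nrow(x$exons) - 1L, model_span(x)$end - model_span(x)$start + 1L))
  invisible(x)
}

#' Introns of a gene model
#'
#' @param model A [gene_model].
#' @return Data frame of intron \code{start}/\code{end} (0 rows for a
#'   single-exon gene); intron count is exon count minus one.
#' @export
model_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-n] + 1L, end = ex$start[-1L] - 1L)
}

model_span <- function(model) {
  genomic_interval(model$chrom, min(model$exons$start), max(model$exons$end),
                   model$strand)
}

#' Read a BED-like exon annotation into a gene model
#'
#' Four tab-separated columns: chrom, 0-based start, end, name. All rows are
#' taken as exons of a single gene in transcript order.
#'
#' @param path Input file.
#' @param gene_id Gene id for the resulting model.
#' @param strand Strand of the gene.
#' @return A [gene_model].
#' @export
read_gene_model_bed <- function(path, gene_id = "gene", strand = "+") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name"),
                          stringsAsFactors = FALSE)
  if (length(unique(df$chrom)) != 1L)
    stop("read_gene_model_bed: exons span multiple chromosomes")
  gene_model(gene_id, df$chrom[[1L]], strand, df$start + 1L, df$end)
}

#' Write a gene model as BED-like exon annotation
#' @param model A [gene_model].
#' @param path Output file.
#' @export
write_gene_model_bed <- function(model, path) {
  ex <- model$exons
  df <- data.frame(chrom = model$chrom, start = ex$start - 1L, end = ex$end,
                   name = paste0(model$gene_id, "_exon", seq_len(nrow(ex))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Extract the subsequence of a chromosome record for an interval, oriented by
# its strand.  `record` must be the chromosome named by the interval.
extract_interval <- function(record, interval) {
  if (!identical(record_id(record, interval$chrom), interval$chrom))
    warning("extract_interval: record id differs from interval chrom")
  s <- substr(as_seq_string(record), interval$start, interval$end)
  if (interval$strand == "-") s <- reverse_complement(s)
  s
}

#' Spliced cDNA of a gene model from its chromosome sequence
#'
#' Concatenates exon sequences in transcript order (reverse-complemented for a
#' minus-strand gene).
#'
#' @param record Chromosome [seq_record] containing the gene.
#' @param model A [gene_model].
#' @return cDNA sequence string.
#' @export
splice_cdna <- function(record, model) {
  s <- as_seq_string(record)
  parts <- substring(s, model$exons$start, model$exons$end)
  cdna <- paste(parts, collapse = "")
  if (model$strand == "-") cdna <- reverse_complement(cdna)
  cdna
}
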