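# Pseudogene discovery: seed-and-extend homology search of a cDNA against a
# genome, colinear chaining (so the parent locus chains across its introns
# while processed copies chain contiguously), banded alignment over each
# chain, and parent/pseudogene/paralog classification.

#' Find cDNA-homologous loci in a genome
#'
#' Seed-and-extend search on both strands: exact k-mer seeds are grouped into
#' colinear diagonal blocks, blocks are chained (allowing intron-sized gaps on
#' the genomic side only), each chain is aligned segment-wise with a banded
#' affine-gap aligner, and hit boundaries are refined by ungapped X-drop
#' extension. Genomic-side gaps of at least \code{g_intron} bp are counted as
#' intron-scale gap blocks and excluded from identity columns.
#'
#' @param cdna Query cDNA ([seq_record] or string).
#' @param genome List of chromosome [seq_record]s (or a single record).
#' @param k Seed length.
#' @param max_chain_gap Maximum genomic gap bridged within one chain (allows
#'   introns at the parent locus).
#' @param min_identity,min_coverage Reporting thresholds.
#' @param g_intron Minimum genomic gap treated as an intron.
#' @param band Banded-alignment half-width margin.
#' @param scoring Alignment scoring, see [default_scoring()].
#' @return List of \code{homology_hit} objects sorted by descending identity;
#'   overlapping hits on the same locus are merged (best score kept, ties to
#'   the leftmost target start).
#' @export
find_homologous_loci <- function(cdna, genome, k = 12L,
                                 max_chain_gap = 30000L,
                                 min_identity = 0.70, min_coverage = 0.50,
                                 g_intron = 50L, band = 32L,
                                 scoring = default_scoring()) {
  qseq <- as_seq_string(cdna)
  qid <- record_id(cdna, "query")
  if (inherits(genome, "seq_record")) genome <- list(genome)
  if (length(genome) == 0L) stop("find_homologous_loci: empty genome")
  if (k > nchar(qseq)) stop("find_homologous_loci: k exceeds cDNA length")

  hits <- list()
  for (rec in genome) {
    L <- nchar(as_seq_string(rec))
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") as_seq_string(rec)
              else reverse_complement(rec)
      seeds <- kmer_seeds(qseq, sseq, k)
      if (nrow(seeds) == 0L) next
      blocks <- seed_blocks(seeds, k)
      chains <- chain_blocks(blocks, max_chain_gap = max_chain_gap)
      for (ch in chains) {
        h <- align_chain(qseq, sseq, ch, scoring = scoring,
                         g_intron = g_intron, band = band)
        if (is.null(h)) next
        s1 <- h$s_start; s2 <- h$s_end
        if (strand == "-") { s1 <- L - h$s_end + 1L; s2 <- L - h$s_start + 1L }
        segs <- h$segments
        segs$ss <- segs$ss - h$s_start + 1L   # local to the oriented locus
        segs$se <- segs$se - h$s_start + 1L
        hits[[length(hits) + 1L]] <- structure(
          list(query_id = qid, q_start = h$q_start, q_end = h$q_end,
               target = genomic_interval(record_id(rec), s1, s2, strand),
               columns = h$columns, matches = h$matches,
               identity = h$identity, gap_blocks = h$gap_blocks,
               coverage = h$query_aligned / nchar(qseq),
               score = h$score, segments = segs),
          class = "homology_hit")
      }
    }
  }
  hits <- merge_overlapping_hits(hits)
  keep <- vapply(hits, function(h)
    isTRUE(h$identity >= min_identity && h$coverage >= min_coverage), TRUE)
  hits <- hits[keep]
  ord <- order(-vapply(hits, `[[`, 0, "identity"),
               vapply(hits, function(h) h$target$chrom, ""),
               vapply(hits, function(h) h$target$start, 0L))
  hits[ord]
}

#' @export
print.homology_hit <- function(x, ...) {
  cat(sprintf(
    "<hit> %s[%d-%d] -> %s:%d-%d(%s) id=%.4f cov=%.3f introns=%d score=%.0f\n",
    x$query_id, x$q_start, x$q_end, x$target$chrom, x$target$start,
    x$target$end, x$target$strand, x$identity, x$coverage, x$gap_blocks,
    x$score))
  invisible(x)
}

# --- internals ---------------------------------------------------------------

# exact k-mer matches (query position, subject position); seeds whose k-mer
# occurs unusually often in the query are dropped as low complexity
kmer_seeds <- function(qseq, sseq, k, max_occ = 24L) {
  nq <- nchar(qseq); ns <- nchar(sseq)
  if (ns < k) return(data.frame(qpos = integer(), spos = integer()))
  qk <- substring(qseq, seq_len(nq - k + 1L), seq_len(nq - k + 1L) + k - 1L)
  sk <- substring(sseq, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
  qpos_by_kmer <- split(seq_along(qk), qk)
  qpos_by_kmer <- qpos_by_kmer[lengths(qpos_by_kmer) <= max_occ]
  hit_idx <- which(sk %in% names(qpos_by_kmer))
  if (length(hit_idx) == 0L)
    return(data.frame(qpos = integer(), spos = integer()))
  ql <- qpos_by_kmer[sk[hit_idx]]
  data.frame(qpos = unlist(ql, use.names = FALSE),
             spos = rep.int(hit_idx, lengths(ql)))
}

# group seeds into near-diagonal colinear blocks; blocks with a single seed
# are discarded as noise
seed_blocks <- function(seeds, k, diag_tol = 16L, qjump = 200L) {
  d <- seeds$spos - seeds$qpos
  o <- order(d, seeds$qpos)
  d <- d[o]; qp <- seeds$qpos[o]; sp <- seeds$spos[o]
  brk <- c(TRUE, diff(d) > diag_tol | diff(qp) > qjump)
  grp <- cumsum(brk)
  qs <- tapply(qp, grp, min); qe <- tapply(qp, grp, max) + k - 1L
  ss <- tapply(sp, grp, min); se <- tapply(sp, grp, max) + k - 1L
  n <- tapply(qp, grp, length)
  df <- data.frame(qs = as.integer(qs), qe = as.integer(qe),
                   ss = as.integer(ss), se = as.integer(se),
                   nseeds = as.integer(n))
  df[df$nseeds >= 2L, , drop = FALSE]
}

# Colinear chaining by dynamic programming: the heaviest chain (query bases
# covered, minus small gap penalties) is extracted, its blocks removed, and
# the process repeats.  Genomic gaps up to max_chain_gap are allowed
# (introns); query gaps are capped so flank noise cannot bridge loci.  A
# short spurious repeat that conflicts with a real exon block loses the
# weight comparison and is left for a later (low-coverage, filtered) chain.
chain_blocks <- function(blocks, max_chain_gap, max_qgap = 300L,
                         overlap_tol = 20L) {
  if (nrow(blocks) == 0L) return(list())
  blocks <- blocks[order(blocks$ss, blocks$qs), , drop = FALSE]
  n <- nrow(blocks)
  w <- as.numeric(blocks$qe - blocks$qs + 1L)
  used <- rep(FALSE, n)
  chains <- list()
  repeat {
    avail <- which(!used)
    if (length(avail) == 0L) break
    dp <- rep(-Inf, n); parent <- rep(NA_integer_, n)
    for (ii in avail) {
      dp[[ii]] <- w[[ii]]
      prev <- avail[avail < ii]
      for (jj in prev) {
        qgap <- blocks$qs[[ii]] - blocks$qe[[jj]] - 1L
        sgap <- blocks$ss[[ii]] - blocks$se[[jj]] - 1L
        if (qgap >= -overlap_tol && sgap >= -overlap_tol &&
            qgap <= max_qgap && sgap <= max_chain_gap) {
          cand <- dp[[jj]] + w[[ii]] - min(abs(qgap), 100L) / 10
          if (cand > dp[[ii]]) { dp[[ii]] <- cand; parent[[ii]] <- jj }
        }
      }
    }
    end <- avail[[which.max(dp[avail])]]
    path <- end
    while (!is.na(parent[[path[[1L]]]])) path <- c(parent[[path[[1L]]]], path)
    used[path] <- TRUE
    chains[[length(chains) + 1L]] <- blocks[path, , drop = FALSE]
  }
  chains
}

# clip small overlaps between consecutive blocks along the diagonal
clip_chain <- function(ch) {
  keep <- rep(TRUE, nrow(ch))
  for (i in seq_len(nrow(ch))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    shift <- max(ch$qe[prev] + 1L - ch$qs[i], ch$se[prev] + 1L - ch$ss[i], 0L)
    if (shift > 0L) {
      ch$qs[i] <- ch$qs[i] + shift
      ch$ss[i] <- ch$ss[i] + shift
    }
    if (ch$qs[i] > ch$qe[i] || ch$ss[i] > ch$se[i]) keep[i] <- FALSE
  }
  ch[keep, , drop = FALSE]
}

align_chain <- function(qseq, sseq, ch, scoring, g_intron, band,
                        x_drop = 20) {
  ch <- clip_chain(ch)
  if (nrow(ch) == 0L) return(NULL)

  # X-drop extension of block edges into intron-scale inter-block gaps, so
  # mismatch-rich exon margins next to introns still get aligned; budgets
  # keep the two extensions inside the gap
  if (nrow(ch) > 1L) {
    for (i in seq_len(nrow(ch) - 1L)) {
      qgap <- ch$qs[i + 1L] - ch$qe[i] - 1L
      sgap <- ch$ss[i + 1L] - ch$se[i] - 1L
      if (abs(sgap - qgap) >= g_intron) {
        bud <- min(qgap, sgap)
        er <- if (bud > 0L)
          xdrop_extend_cpp(qseq, sseq, ch$qe[i], ch$se[i], 1L,
                           scoring$match, scoring$mismatch, x_drop, bud)
        else 0L
        ch$qe[i] <- ch$qe[i] + er; ch$se[i] <- ch$se[i] + er
        bud <- min(qgap - er, sgap - er)
        el <- if (bud > 0L)
          xdrop_extend_cpp(qseq, sseq, ch$qs[i + 1L], ch$ss[i + 1L], -1L,
                           scoring$match, scoring$mismatch, x_drop, bud)
        else 0L
        ch$qs[i + 1L] <- ch$qs[i + 1L] - el
        ch$ss[i + 1L] <- ch$ss[i + 1L] - el
      }
    }
  }

  matches <- 0L; columns <- 0L; qaligned <- 0L; gap_blocks <- 0L; score <- 0

  add_aln <- function(qa, sa) {
    aln <- align_pair(qa, sa, band = band, scoring = scoring)
    st <- alignment_stats(aln, g_intron = g_intron)
    matches <<- matches + st$matches
    columns <<- columns + st$columns
    qaligned <<- qaligned + st$query_aligned
    gap_blocks <<- gap_blocks + st$gap_blocks
    score <<- score + aln$score
  }

  for (i in seq_len(nrow(ch))) {
    add_aln(substr(qseq, ch$qs[i], ch$qe[i]), substr(sseq, ch$ss[i], ch$se[i]))
    if (i < nrow(ch)) {
      qgap <- ch$qs[i + 1L] - ch$qe[i] - 1L
      sgap <- ch$ss[i + 1L] - ch$se[i] - 1L
      if (sgap - qgap >= g_intron) {
        gap_blocks <- gap_blocks + 1L       # genomic-side intron; query gap
      } else if (qgap - sgap >= g_intron) { # unaligned, excluded from columns
        # large query-side surplus: leave unaligned (coverage loss only)
      } else if (qgap > 0L && sgap > 0L) {
        add_aln(substr(qseq, ch$qe[i] + 1L, ch$qs[i + 1L] - 1L),
                substr(sseq, ch$se[i] + 1L, ch$ss[i + 1L] - 1L))
      } else if (qgap > 0L || sgap > 0L) {
        g <- max(qgap, sgap)
        columns <- columns + g
        score <- score + scoring$gap_open + scoring$gap_extend * g
      }
    }
  }

  # X-drop boundary refinement beyond the outermost seeds
  q1 <- ch$qs[1L]; s1 <- ch$ss[1L]
  qn <- ch$qe[nrow(ch)]; sn <- ch$se[nrow(ch)]
  extl <- xdrop_extend_cpp(qseq, sseq, q1, s1, -1L,
                           scoring$match, scoring$mismatch, x_drop)
  extr <- xdrop_extend_cpp(qseq, sseq, qn, sn, 1L,
                           scoring$match, scoring$mismatch, x_drop)
  if (extl > 0L) {
    qa <- substr(qseq, q1 - extl, q1 - 1L); sa <- substr(sseq, s1 - extl, s1 - 1L)
    mm <- sum(strsplit(qa, "")[[1L]] == strsplit(sa, "")[[1L]])
    matches <- matches + mm; columns <- columns + extl; qaligned <- qaligned + extl
    score <- score + mm * scoring$match + (extl - mm) * scoring$mismatch
  }
  if (extr > 0L) {
    qa <- substr(qseq, qn + 1L, qn + extr); sa <- substr(sseq, sn + 1L, sn + extr)
    mm <- sum(strsplit(qa, "")[[1L]] == strsplit(sa, "")[[1L]])
    matches <- matches + mm; columns <- columns + extr; qaligned <- qaligned + extr
    score <- score + mm * scoring$match + (extr - mm) * scoring$mismatch
  }

  if (columns == 0L) return(NULL)
  segs <- data.frame(qs = ch$qs, qe = ch$qe, ss = ch$ss, se = ch$se)
  segs$qs[1L] <- q1 - extl; segs$ss[1L] <- s1 - extl
  segs$qe[nrow(segs)] <- qn + extr; segs$se[nrow(segs)] <- sn + extr
  list(q_start = q1 - extl, q_end = qn + extr,
       s_start = s1 - extl, s_end = sn + extr,
       matches = matches, columns = columns,
       identity = matches / columns, gap_blocks = gap_blocks,
       query_aligned = qaligned, score = score, segments = segs)
}

merge_overlapping_hits <- function(hits) {
  if (length(hits) <= 1L) return(hits)
  used <- rep(FALSE, length(hits))
  out <- list()
  for (i in seq_along(hits)) {
    if (used[i]) next
    group <- i
    for (j in seq_along(hits)) {
      if (j == i || used[j]) next
      if (intervals_overlap(hits[[i]]$target, hits[[j]]$target)) {
        group <- c(group, j)
      }
    }
    used[group] <- TRUE
    scores <- vapply(hits[group], `[[`, 0, "score")
    starts <- vapply(hits[group], function(h) h$target$start, 0L)
    best <- group[order(-scores, starts)][1L]
    out[[length(out) + 1L]] <- hits[[best]]
  }
  out
}

# --- classification ----------------------------------------------------------

# longest open reading frame (ATG..stop, nt incl. stop codon) over the three
# forward frames of an oriented sequence; an ORF still open at the end counts;
# codons containing N are treated as unknown (neither start nor stop)
longest_orf_length <- function(seq) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  best <- 0L
  for (f in 0:2) {
    if (n - f < 3L) next
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open) && codons[[i]] == "ATG") open <- i
      if (!is.na(open) && is_stop[[i]]) {
        best <- max(best, (i - open + 1L) * 3L)
        open <- NA_integer_
      }
    }
    if (!is.na(open)) best <- max(best, (length(codons) - open + 1L) * 3L)
  }
  best
}

# Putative transcript of a hit in query coordinates: aligned target segments
# are projected onto the query, unaligned positions are imputed from the
# query cDNA when given (or N otherwise).  Splices out intron-scale gaps so
# the reading frame of an intron-bearing locus can be assessed.
project_hit_transcript <- function(hit, record, cdna = NULL) {
  oriented <- extract_interval(record, hit$target)
  qlen <- if (!is.null(cdna)) nchar(as_seq_string(cdna)) else hit$q_end
  out <- if (!is.null(cdna)) strsplit(as_seq_string(cdna), "", fixed = TRUE)[[1L]]
         else rep("N", qlen)
  for (i in seq_len(nrow(hit$segments))) {
    sg <- hit$segments[i, ]
    tseg <- substr(oriented, sg$ss, sg$se)
    qw <- sg$qe - sg$qs + 1L
    if (nchar(tseg) == qw) {
      out[sg$qs:sg$qe] <- strsplit(tseg, "", fixed = TRUE)[[1L]]
    } else if (!is.null(cdna)) {
      qseg <- substr(as_seq_string(cdna), sg$qs, sg$qe)
      aln <- align_pair(qseg, tseg,
                        band = abs(nchar(tseg) - qw) + 32L)
      qc <- strsplit(aln$q_aln, "", fixed = TRUE)[[1L]]
      sc <- strsplit(aln$s_aln, "", fixed = TRUE)[[1L]]
      proj <- sc[qc != "-"]
      proj[proj == "-"] <- "N"
      out[sg$qs:sg$qe] <- proj
    } else {
      w <- min(nchar(tseg), qw)
      out[sg$qs:(sg$qs + w - 1L)] <-
        strsplit(substr(tseg, 1L, w), "", fixed = TRUE)[[1L]]
    }
  }
  paste(out, collapse = "")
}

#' Classify a homology hit as parent, pseudogene, or paralog
#'
#' A locus is the parent iff it overlaps the parent gene model; otherwise it
#' is a pseudogene iff it is intronless (no genomic-side gap block of at least
#' \code{g_intron} bp in the hit) or its longest open reading frame falls
#' below \code{orf_frac} of the parent CDS length; otherwise it is a diverged
#' paralog.
#'
#' @param hit A \code{homology_hit} from [find_homologous_loci()].
#' @param parent_model The parent [gene_model].
#' @param parent_cds CDS interval on the parent cDNA, as \code{c(start, end)}
#'   (1-based inclusive, nt).
#' @param genome List of chromosome [seq_record]s (to extract the locus
#'   sequence for ORF scanning).
#' @param cdna Optional query cDNA: for intron-bearing loci the ORF is judged
#'   on the spliced, query-projected transcript (unaligned positions imputed
#'   from the cDNA; without it they count as unknown, which is conservative
#'   against calling the frame intact).
#' @param orf_frac ORF-intact threshold as a fraction of parent CDS length.
#' @param g_intron Minimum genomic gap treated as an intron.
#' @return An object of class \code{locus_classification}.
#' @export
classify_locus <- function(hit, parent_model, parent_cds, genome,
                           cdna = NULL, orf_frac = 0.9, g_intron = 50L) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  intronless <- hit$gap_blocks == 0L
  ids <- vapply(genome, record_id, "")
  ri <- match(hit$target$chrom, ids)
  if (is.na(ri))
    stop("classify_locus: no genome record named '", hit$target$chrom, "'")
  locus_seq <- if (!intronless && !is.null(hit$segments))
    project_hit_transcript(hit, genome[[ri]], cdna = cdna)
  else extract_interval(genome[[ri]], hit$target)
  cds_len <- parent_cds[[2L]] - parent_cds[[1L]] + 1L
  orf_len <- longest_orf_length(locus_seq)
  orf_intact <- orf_len >= orf_frac * cds_len
  is_parent <- intervals_overlap(hit$target, model_span(parent_model))
  cls <- if (is_parent) "parent"
         else if (intronless || !orf_intact) "pseudogene"
         else "paralog"
  structure(list(hit = hit, class = cls, intronless = intronless,
                 orf_intact = orf_intact,
                 orf_fraction = orf_len / cds_len),
            class = "locus_classification")
}

#' @export
print.locus_classification <- function(x, ...) {
  cat(sprintf("<locus> %s:%d-%d %s (intronless=%s, orf_intact=%s)\n",
              x$hit$target$chrom, x$hit$target$start, x$hit$target$end,
              x$class, x$intronless, x$orf_intact))
  invisible(x)
}

#' Tabulate classified loci as a catalog
#'
#' One row per locus with its name, coordinate string, span, percent identity
#' (2 decimals), and class. The parent is listed first, then loci in order of
#' descending identity.
#'
#' @param classifications List of \code{locus_classification} objects.
#' @param names Optional character vector of locus names (recycled by
#'   position); defaults to the coordinate string.
#' @return Data frame with columns \code{name}, \code{coordinate},
#'   \code{span_bp}, \code{identity_pct}, \code{class}.
#' @export
catalog_report <- function(classifications, names = NULL) {
  if (length(classifications) == 0L)
    stop("catalog_report: need at least one classification")
  rows <- lapply(classifications, function(cl) {
    tgt <- cl$hit$target
    data.frame(name = format_coordinate(tgt),
               coordinate = format_coordinate(tgt),
               span_bp = interval_span(tgt),
               identity_pct = sprintf("%.2f", 100 * cl$hit$identity),
               class = cl$class,
               identity_raw = cl$hit$identity,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(names)) df$name <- names
  ord <- order(df$class != "parent", -df$identity_raw, df$coordinate)
  df <- df[ord, c("name", "coordinate", "span_bp", "identity_pct", "class")]
  rownames(df) <- NULL
  df
}
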