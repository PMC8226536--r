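# Assay design against a paralog family: find target-unique variants via a
# star alignment, then build the three assay classes used to discriminate a
# parent gene from its processed pseudogenes: allele-specific primers (3'
# terminus on a discriminating base), splice-junction cDNA assays, and
# primary-transcript assays targeting intron sequence absent from pseudogenes.

#' Star alignment of paralogs onto a target sequence
#'
#' Each paralog is aligned pairwise to the target with the package's
#' affine-gap aligner and projected onto target coordinates: every target
#' position carries each paralog's base (or \code{"-"}) plus the paralog
#' coordinate of that base. Pairwise-to-target projection avoids the ordering
#' nondeterminism of a full multiple alignment; columns where the target has
#' a gap (paralog insertions) are dropped.
#'
#' @param target Target [seq_record] (or string).
#' @param paralogs List of paralog [seq_record]s.
#' @param min_coverage Paralogs whose alignable coverage of the target falls
#'   below this fraction are excluded with a warning.
#' @return A \code{column_table}: data frame with \code{position},
#'   \code{target}, and per paralog \code{<id>} (base) and \code{<id>_pos}
#'   columns. Paralog ids are kept in \code{attr(, "paralogs")}.
#' @export
align_to_target <- function(target, paralogs, min_coverage = 0.5) {
  tseq <- as_seq_string(target)
  if (length(paralogs) == 0L) stop("align_to_target: need >= 1 paralog")
  if (inherits(paralogs, "seq_record")) paralogs <- list(paralogs)
  n <- nchar(tseq)
  tbl <- data.frame(position = seq_len(n),
                    target = strsplit(tseq, "", fixed = TRUE)[[1L]],
                    stringsAsFactors = FALSE)
  kept <- character()
  for (p in paralogs) {
    pid <- record_id(p)
    pseq <- as_seq_string(p)
    band <- abs(nchar(pseq) - n) + 64L
    aln <- align_pair(tseq, pseq, band = band)
    qc <- strsplit(aln$q_aln, "", fixed = TRUE)[[1L]]
    sc <- strsplit(aln$s_aln, "", fixed = TRUE)[[1L]]
    on_target <- qc != "-"
    base <- sc[on_target]
    ppos <- cumsum(sc != "-")[on_target]
    ppos[base == "-"] <- NA_integer_
    cov <- sum(base != "-") / n
    if (cov < min_coverage) {
      warning("align_to_target: paralog '", pid, "' covers only ",
              sprintf("%.0f%%", 100 * cov), " of the target; excluded")
      next
    }
    tbl[[pid]] <- base
    tbl[[paste0(pid, "_pos")]] <- as.integer(ppos)
    kept <- c(kept, pid)
  }
  if (length(kept) == 0L)
    stop("align_to_target: no paralog passed the coverage filter")
  structure(tbl, paralogs = kept, class = c("column_table", "data.frame"))
}

#' Find discriminating sites in a column table
#'
#' \code{unique_to_target}: positions where the target base differs from
#' every paralog (base or gap). \code{unique_to_paralog}: positions where the
#' named paralog differs from the target and from every other paralog --
#' these are the sites on which paralog-specific allele primers are anchored.
#'
#' @param tbl A \code{column_table} from [align_to_target()].
#' @param mode \code{"unique_to_target"} or \code{"unique_to_paralog"}.
#' @param paralog Paralog id (required for \code{unique_to_paralog}).
#' @return Data frame of sites: \code{position} (target coordinate),
#'   \code{target_base}, \code{distinguishes} (comma-joined paralog ids), and
#'   for \code{unique_to_paralog} also \code{paralog_base} and
#'   \code{paralog_pos} (the site's coordinate on the paralog itself).
#' @export
find_discriminating_sites <- function(tbl,
                                      mode = c("unique_to_target",
                                               "unique_to_paralog"),
                                      paralog = NULL) {
  mode <- match.arg(mode)
  ids <- attr(tbl, "paralogs")
  bases <- as.matrix(tbl[, ids, drop = FALSE])
  if (mode == "unique_to_target") {
    diff_all <- rowSums(bases != tbl$target) == length(ids)
    idx <- which(diff_all)
    out <- data.frame(position = tbl$position[idx],
                      target_base = tbl$target[idx],
                      distinguishes = rep(paste(ids, collapse = ","),
                                          length(idx)),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(paralog) || !paralog %in% ids)
      stop("find_discriminating_sites: unknown paralog id '",
           if (is.null(paralog)) "NULL" else paralog, "'")
    others <- setdiff(ids, paralog)
    pb <- bases[, paralog]
    ok <- pb != tbl$target & pb != "-"
    if (length(others))
      ok <- ok & rowSums(bases[, others, drop = FALSE] != pb) == length(others)
    idx <- which(ok)
    out <- data.frame(position = tbl$position[idx],
                      target_base = tbl$target[idx],
                      paralog_base = pb[idx],
                      paralog_pos = tbl[[paste0(paralog, "_pos")]][idx],
                      distinguishes = rep(paralog, length(idx)),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# --- melting temperature -----------------------------------------------------

# nearest-neighbor duplex parameters, unified set: dH kcal/mol, dS cal/(mol K)
nn_params <- function() {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
          CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
          CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
          CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
          CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
          CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
  list(dH = dH, dS = dS)
}

#' Primer melting temperature
#'
#' Nearest-neighbor Tm with the unified duplex parameter set, entropic salt
#' correction \code{0.368 (N-1) ln[Na+]}, and total-strand concentration term
#' \code{R ln(C/4)} for a non-self-complementary duplex. Primers shorter than
#' 14 nt use the Wallace rule \code{2(A+T) + 4(G+C)}.
#'
#' @param seq Primer sequence, \code{A/C/G/T} only, length >= 8.
#' @param na Monovalent cation concentration, mol/L.
#' @param conc Primer concentration, mol/L.
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, na = 0.05, conc = 5e-7) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  if (n < 8L) stop("melting_temperature: primer shorter than 8 nt")
  check_alphabet(s, id = "primer", allow_n = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  gc <- sum(ch %in% c("G", "C"))
  if (n < 14L) return(2 * (n - gc) + 4 * gc)
  p <- nn_params()
  steps <- paste0(ch[-n], ch[-1L])
  dH <- sum(p$dH[steps])
  dS <- sum(p$dS[steps])
  # duplex initiation: terminal G.C vs A.T
  for (term in ch[c(1L, n)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  dS <- dS + 0.368 * (n - 1) * log(na)
  R <- 1.9872
  dH * 1000 / (dS + R * log(conc / 4)) - 273.15
}

gc_fraction <- function(seq) {
  ch <- strsplit(as_seq_string(seq), "", fixed = TRUE)[[1L]]
  mean(ch %in% c("G", "C"))
}

# --- primers and assays ------------------------------------------------------

#' Construct a primer record
#'
#' @param name Primer name.
#' @param seq Primer sequence, 5'->3'.
#' @param strand \code{"+"} (sequence equals template top strand) or
#'   \code{"-"} (sequence is the reverse complement of the covered template
#'   interval; 3' end at the interval's left bound).
#' @param start,end Covered interval on the design template (1-based).
#' @param tm Melting temperature (computed if \code{NULL}).
#' @param anchored_offsets Integer offsets from the 3' end (0 = terminal base)
#'   that sit on discriminating sites.
#' @return Object of class \code{pcr_primer}.
#' @export
pcr_primer <- function(name, seq, strand, start, end, tm = NULL,
                       anchored_offsets = integer()) {
  seq <- as_seq_string(seq)
  check_alphabet(seq, id = name, allow_n = FALSE)
  if (is.null(tm)) tm <- melting_temperature(seq)
  structure(list(name = name, seq = seq, strand = strand,
                 start = as.integer(start), end = as.integer(end), tm = tm,
                 anchored_offsets = as.integer(anchored_offsets)),
            class = "pcr_primer")
}

#' @export
print.pcr_primer <- function(x, ...) {
  cat(sprintf("<primer> %s %s (%s) %d-%d Tm=%.1f anchors=[%s]\n",
              x$name, x$seq, x$strand, x$start, x$end, x$tm,
              paste(x$anchored_offsets, collapse = ",")))
  invisible(x)
}

#' Construct an assay design
#'
#' @param id Assay id.
#' @param class One of \code{allele_specific}, \code{splice_junction},
#'   \code{exon_intron}, \code{intra_intron}.
#' @param forward,reverse [pcr_primer]s on opposite strands, 3' ends facing.
#' @param amplicon_bp Expected amplicon length on the design template
#'   (distance between the primers' outer ends).
#' @param template_id Id of the design template.
#' @param probe Optional internal probe sequence.
#' @return Object of class \code{assay_design}.
#' @export
assay_design <- function(id, class, forward, reverse, amplicon_bp,
                         template_id = NA_character_, probe = NULL) {
  stopifnot(class %in% c("allele_specific", "splice_junction",
                         "exon_intron", "intra_intron"))
  if (identical(forward$strand, reverse$strand))
    stop("assay_design: primers must be on opposite strands")
  structure(list(id = id, class = class, forward = forward,
                 reverse = reverse, probe = probe,
                 amplicon_bp = as.integer(amplicon_bp),
                 template_id = template_id),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay> %s [%s] amplicon %d bp on %s\n  F: %s\n  R: %s\n",
              x$id, x$class, x$amplicon_bp, x$template_id,
              x$forward$seq, x$reverse$seq))
  invisible(x)
}

default_design_constraints <- function() {
  list(len_range = c(18L, 25L), tm_range = c(57, 63), tm_target = 60,
       gc_range = c(0.35, 0.65), product_range = c(70L, 250L),
       anchor_window = 5L, min_overhang = 4L)
}

# candidate primer on + strand with 3' end at `e` / on - strand with 3' end
# at `s`; returns NULL if out of template or failing hard validity
make_fwd <- function(template, e, L) {
  s <- e - L + 1L
  if (s < 1L) return(NULL)
  list(seq = substr(template, s, e), strand = "+", start = s, end = e)
}
make_rev <- function(template, s, L) {
  e <- s + L - 1L
  if (e > nchar(template)) return(NULL)
  list(seq = reverse_complement(substr(template, s, e)), strand = "-",
       start = s, end = e)
}

cand_ok <- function(cand, cons) {
  !is.null(cand) &&
    !grepl("N", cand$seq, fixed = TRUE) &&
    gc_fraction(cand$seq) >= cons$gc_range[[1L]] &&
    gc_fraction(cand$seq) <= cons$gc_range[[2L]]
}

# rank candidates: prefer Tm inside the window, then closest to target Tm,
# then leftmost; returns the candidate list ordered best-first
rank_by_tm <- function(cands, cons) {
  if (length(cands) == 0L) return(cands)
  tm <- vapply(cands, function(c) melting_temperature(c$seq), 0)
  inside <- tm >= cons$tm_range[[1L]] & tm <= cons$tm_range[[2L]]
  start <- vapply(cands, `[[`, 0L, "start")
  ord <- order(!inside, abs(tm - cons$tm_target), start)
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$tm <- tm[ord][[i]]
  cands
}

#' Enumerate allele-specific primer candidates
#'
#' Returns every primer within the length window whose 3'-terminal base lies
#' on a discriminating site, on either strand, filtered by Tm and GC windows
#' and sorted by (number of 3'-anchored sites desc, Tm closeness to target
#' asc, position asc). An empty site list or over-constrained windows yield
#' an empty list, not an error.
#'
#' @param template Design template ([seq_record] or string); site positions
#'   refer to this template.
#' @param sites Data frame with a \code{position} column (e.g. from
#'   [find_discriminating_sites()], using \code{paralog_pos} when designing on
#'   the paralog itself), or an integer vector of positions.
#' @param constraints See [default_design_constraints()]; additionally
#'   \code{require_second_site} demands a second site within the 3'
#'   \code{anchor_window}.
#' @param require_second_site Require >= 2 anchored sites in the 3' window.
#' @return List of [pcr_primer]s.
#' @export
enumerate_allele_specific_primers <- function(template, sites,
                                              constraints =
                                                default_design_constraints(),
                                              require_second_site = FALSE) {
  tpl <- as_seq_string(template)
  pos <- if (is.data.frame(sites)) sites$position else as.integer(sites)
  pos <- sort(unique(pos))
  if (length(pos) == 0L) return(list())
  cons <- constraints
  site_set <- pos
  out <- list()
  for (p in pos) {
    for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
      for (str in c("+", "-")) {
        cand <- if (str == "+") make_fwd(tpl, p, L) else make_rev(tpl, p, L)
        if (!cand_ok(cand, cons)) next
        tm <- melting_temperature(cand$seq)
        if (tm < cons$tm_range[[1L]] || tm > cons$tm_range[[2L]]) next
        offs <- 0:(cons$anchor_window - 1L)
        tpos <- if (str == "+") p - offs else p + offs
        anchored <- offs[tpos %in% site_set &
                           tpos >= cand$start & tpos <= cand$end]
        if (require_second_site && length(anchored) < 2L) next
        out[[length(out) + 1L]] <-
          pcr_primer(sprintf("as_%s_%d_%d", str, p, L), cand$seq, str,
                     cand$start, cand$end, tm = tm,
                     anchored_offsets = anchored)
      }
    }
  }
  if (length(out) == 0L) return(out)
  n_anchor <- vapply(out, function(x) length(x$anchored_offsets), 0L)
  tmdev <- vapply(out, function(x) abs(x$tm - cons$tm_target), 0)
  start <- vapply(out, `[[`, 0L, "start")
  strand <- vapply(out, `[[`, "", "strand")
  out[order(-n_anchor, tmdev, start, strand)]
}

# best reverse mate for a forward primer: product length within the window,
# no overlap with the forward 3' end
find_mate <- function(template, fwd, cons) {
  f1 <- fwd$start
  cands <- list()
  for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
    smin <- max(fwd$end + 1L, f1 + cons$product_range[[1L]] - L)
    smax <- f1 + cons$product_range[[2L]] - L
    if (smax < smin) next
    for (s in seq.int(smin, smax)) {
      cand <- make_rev(template, s, L)
      if (cand_ok(cand, cons)) cands[[length(cands) + 1L]] <- cand
    }
  }
  ranked <- rank_by_tm(cands, cons)
  if (length(ranked) == 0L) return(NULL)
  ranked[[1L]]
}

# best forward mate upstream of a reverse primer
find_mate_upstream <- function(template, rev, cons) {
  r2 <- rev$end
  cands <- list()
  for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
    emin <- max(L, r2 - cons$product_range[[2L]] + L)
    emax <- min(rev$start - 1L, r2 - cons$product_range[[1L]] + L)
    if (emax < emin) next
    for (e in seq.int(emin, emax)) {
      cand <- make_fwd(template, e, L)
      if (cand_ok(cand, cons)) cands[[length(cands) + 1L]] <- cand
    }
  }
  ranked <- rank_by_tm(cands, cons)
  if (length(ranked) == 0L) return(NULL)
  ranked[[1L]]
}

#' Design an allele-specific assay
#'
#' Picks the best-ranked allele-specific primer (see
#' [enumerate_allele_specific_primers()]) as the forward primer and pairs it
#' with an ordinary reverse primer within the product-size window.
#'
#' @inheritParams enumerate_allele_specific_primers
#' @param id Assay id.
#' @return An [assay_design] of class tag \code{allele_specific}.
#' @export
design_allele_specific_assay <- function(template, sites, id = "allele",
                                         constraints =
                                           default_design_constraints()) {
  tpl <- as_seq_string(template)
  prims <- enumerate_allele_specific_primers(template, sites, constraints)
  for (asp in prims) {
    if (asp$strand == "+") {
      mate <- find_mate(tpl, asp, constraints)
      if (is.null(mate)) next
      fwd <- asp; fwd$name <- paste0(id, "_F")
      rev <- pcr_primer(paste0(id, "_R"), mate$seq, "-", mate$start,
                        mate$end, tm = mate$tm)
    } else {
      mate <- find_mate_upstream(tpl, asp, constraints)
      if (is.null(mate)) next
      rev <- asp; rev$name <- paste0(id, "_R")
      fwd <- pcr_primer(paste0(id, "_F"), mate$seq, "+", mate$start,
                        mate$end, tm = mate$tm)
    }
    return(assay_design(id, "allele_specific", fwd, rev,
                        amplicon_bp = rev$end - fwd$start + 1L,
                        template_id = record_id(template, "template")))
  }
  stop("design_allele_specific_assay: no feasible design")
}

#' Design a splice-junction cDNA assay
#'
#' One primer straddles the junction between exons i and i+1 on the spliced
#' cDNA with at least \code{min_overhang} bases on each side, so the primer
#' cannot bind genomic DNA where the intron interrupts its 3' anchor; the
#' mate is placed within the product-size window.
#'
#' @param model Parent [gene_model].
#' @param cdna Spliced cDNA ([seq_record] or string), transcript orientation.
#' @param exon_pair Index i of the upstream exon (pair i, i+1), or
#'   \code{c(i, i + 1)}.
#' @param constraints See [default_design_constraints()].
#' @param id Assay id.
#' @return An [assay_design] of class tag \code{splice_junction} with
#'   coordinates on the cDNA.
#' @export
design_junction_assay <- function(model, cdna, exon_pair,
                                  constraints = default_design_constraints(),
                                  id = NULL) {
  i <- exon_pair[[1L]]
  if (length(exon_pair) > 1L && exon_pair[[2L]] != i + 1L)
    stop("design_junction_assay: exons must be adjacent")
  widths <- model$exons$end - model$exons$start + 1L
  if (i < 1L || i + 1L > length(widths))
    stop("design_junction_assay: no exon pair (", i, ", ", i + 1L, ")")
  tpl <- as_seq_string(cdna)
  J <- sum(widths[seq_len(i)])  # cDNA position of the last base of exon i
  cons <- constraints
  ov <- cons$min_overhang
  cands <- list()
  for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
    es <- seq.int(J + ov, J + L - ov)
    for (e in es) {
      if (e > nchar(tpl)) next
      cand <- make_fwd(tpl, e, L)
      if (cand_ok(cand, cons)) cands[[length(cands) + 1L]] <- cand
    }
  }
  ranked <- rank_by_tm(cands, cons)
  if (is.null(id)) id <- sprintf("Ex%d-Ex%d", i, i + 1L)
  for (fwd_c in ranked) {
    fwd <- pcr_primer(paste0(id, "_F"), fwd_c$seq, "+", fwd_c$start,
                      fwd_c$end, tm = fwd_c$tm)
    mate <- find_mate(tpl, fwd, cons)
    if (!is.null(mate)) {
      rev <- pcr_primer(paste0(id, "_R"), mate$seq, "-", mate$start,
                        mate$end, tm = mate$tm)
      return(assay_design(id, "splice_junction", fwd, rev,
                          amplicon_bp = rev$end - fwd$start + 1L,
                          template_id = record_id(cdna, "cdna")))
    }
  }
  stop("design_junction_assay: no feasible design")
}

#' Design a primary-transcript (intron-targeted) assay
#'
#' \code{exon_intron}: forward primer inside exon i, reverse inside intron i,
#' so the amplicon crosses the exon/intron boundary present only in the
#' primary transcript. \code{intra_intron}: both primers inside intron i.
#' Either way the assay cannot amplify spliced mRNA or intronless pseudogene
#' templates.
#'
#' @param model Parent [gene_model] (plus-strand / transcript orientation).
#' @param genomic Chromosome or region [seq_record] containing the gene.
#' @param mode \code{"exon_intron"} or \code{"intra_intron"}.
#' @param intron Intron index i.
#' @param offset Coordinate offset: record position = chrom position -
#'   \code{offset} (0 when \code{genomic} is the whole chromosome).
#' @param constraints See [default_design_constraints()].
#' @param id Assay id.
#' @return An [assay_design] with coordinates local to \code{genomic}.
#' @export
design_primary_transcript_assay <- function(model, genomic,
                                            mode = c("exon_intron",
                                                     "intra_intron"),
                                            intron,
                                            offset = 0L,
                                            constraints =
                                              default_design_constraints(),
                                            id = NULL) {
  mode <- match.arg(mode)
  if (model$strand != "+")
    stop("design_primary_transcript_assay: supply the gene in transcript ",
         "orientation (plus strand)")
  introns <- model_introns(model)
  if (nrow(introns) == 0L)
    stop("no introns: primary-transcript design impossible")
  if (intron < 1L || intron > nrow(introns))
    stop("design_primary_transcript_assay: no intron ", intron)
  tpl <- as_seq_string(genomic)
  cons <- constraints
  ex <- c(model$exons$start[[intron]], model$exons$end[[intron]]) - offset
  iv <- c(introns$start[[intron]], introns$end[[intron]]) - offset
  if (mode == "intra_intron" &&
      iv[[2L]] - iv[[1L]] + 1L < cons$product_range[[1L]])
    stop("design_primary_transcript_assay: intron ", intron,
         " shorter than the minimum product size")

  if (is.null(id))
    id <- if (mode == "exon_intron") sprintf("Ex%d-IVS%d", intron, intron)
          else sprintf("IVS%d", intron)

  # forward candidates: near the exon 3' end (exon_intron) or in the first
  # stretch of the intron (intra_intron)
  fr <- if (mode == "exon_intron") {
    c(max(ex[[1L]], ex[[2L]] - 120L), ex[[2L]])
  } else {
    c(iv[[1L]], min(iv[[2L]], iv[[1L]] + 150L))
  }
  cands <- list()
  for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
    if (fr[[1L]] + L - 1L > fr[[2L]]) next
    for (e in seq.int(fr[[1L]] + L - 1L, fr[[2L]])) {
      cand <- make_fwd(tpl, e, L)
      if (!is.null(cand) && cand$start >= fr[[1L]] && cand_ok(cand, cons))
        cands[[length(cands) + 1L]] <- cand
    }
  }
  ranked <- rank_by_tm(cands, cons)
  for (fwd_c in ranked) {
    fwd <- pcr_primer(paste0(id, "_F"), fwd_c$seq, "+", fwd_c$start,
                      fwd_c$end, tm = fwd_c$tm)
    # reverse mate constrained to the intron
    f1 <- fwd$start
    mates <- list()
    for (L in seq.int(cons$len_range[[1L]], cons$len_range[[2L]])) {
      smin <- max(iv[[1L]], fwd$end + 1L, f1 + cons$product_range[[1L]] - L)
      smax <- min(iv[[2L]] - L + 1L, f1 + cons$product_range[[2L]] - L)
      if (smax < smin) next
      for (s in seq.int(smin, smax)) {
        cand <- make_rev(tpl, s, L)
        if (cand_ok(cand, cons)) mates[[length(mates) + 1L]] <- cand
      }
    }
    mates <- rank_by_tm(mates, cons)
    if (length(mates)) {
      m <- mates[[1L]]
      rev <- pcr_primer(paste0(id, "_R"), m$seq, "-", m$start, m$end,
                        tm = m$tm)
      return(assay_design(id, mode, fwd, rev,
                          amplicon_bp = rev$end - fwd$start + 1L,
                          template_id = record_id(genomic, "genomic")))
    }
  }
  stop("design_primary_transcript_assay: no feasible design")
}

#' Map a cDNA position to its genomic coordinate
#'
#' @param model A [gene_model].
#' @param pos Position on the spliced cDNA (transcript orientation).
#' @return Genomic (chromosome) coordinate.
#' @export
cdna_pos_to_genomic <- function(model, pos) {
  widths <- model$exons$end - model$exons$start + 1L
  cum <- cumsum(widths)
  vapply(pos, function(p) {
    if (p < 1L || p > sum(widths)) stop("cdna_pos_to_genomic: out of range")
    if (model$strand == "-") p <- sum(widths) - p + 1L
    i <- which(cum >= p)[[1L]]
    before <- if (i == 1L) 0L else cum[[i - 1L]]
    model$exons$start[[i]] + (p - before) - 1L
  }, 0L)
}
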