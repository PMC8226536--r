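# In-silico PCR with a 3'-weighted mismatch model.  Polymerase extension is
# far more sensitive to mismatches near the primer 3' terminus than elsewhere,
# so each primer position carries a weight and a binding site's score is the
# product of (1 - w) over its mismatched positions.  A single 3'-terminal
# mismatch scores 0.1 -- allele-specific primers are "leaky", not silent.

#' Position-weight profile for primer-binding mismatches
#'
#' Weights indexed by offset from the 3' end: 0.9 at offset 0, 0.6 at offsets
#' 1-2, 0.3 at offsets 3-4, 0.1 elsewhere.
#'
#' @param len Primer length.
#' @return Numeric vector of length \code{len}; element i is the weight at 3'
#'   offset i - 1.
#' @export
mismatch_weight_profile <- function(len) {
  w <- rep(0.1, len)
  w[seq_len(min(5L, len))] <- c(0.9, 0.6, 0.6, 0.3, 0.3)[seq_len(min(5L, len))]
  w
}

#' Find primer binding sites on a template
#'
#' Scans both strands for ungapped binding sites with at most
#' \code{max_total_mm} mismatches (indels are not allowed in binding). Each
#' site's score is \code{prod(1 - w)} over mismatched positions using
#' [mismatch_weight_profile()]; a perfect match scores 1.
#'
#' @param primer [pcr_primer], [seq_record] or sequence string (5'->3').
#' @param template Template [seq_record] or string.
#' @param max_total_mm Maximum total mismatches per site.
#' @return Data frame with \code{template_id}, \code{strand} (\code{"+"}:
#'   primer extends rightward, 3' end = \code{end}; \code{"-"}: primer binds
#'   the top strand's complement, 3' end = \code{start}), \code{start},
#'   \code{end}, \code{pos3}, \code{mm_total}, \code{mm_anchor} (mismatches
#'   in the five 3'-most positions) and \code{score}.
#' @export
find_binding_sites <- function(primer, template, max_total_mm = 3L) {
  pseq <- if (inherits(primer, "pcr_primer")) primer$seq
          else as_seq_string(primer)
  tseq <- as_seq_string(template)
  tid <- record_id(template, "template")
  L <- nchar(pseq)
  n <- nchar(tseq)
  if (L > n) stop("find_binding_sites: primer longer than template")
  w <- mismatch_weight_profile(L)
  tch <- strsplit(tseq, "", fixed = TRUE)[[1L]]
  out <- list()
  scan <- function(pat_ch, strand) {
    # window matrix: rows = primer positions 5'->3' along the template
    starts <- seq_len(n - L + 1L)
    idx <- outer(0:(L - 1L), starts, `+`)
    M <- matrix(tch[idx], nrow = L)
    mm <- M != pat_ch
    tot <- colSums(mm)
    hit <- which(tot <= max_total_mm)
    if (length(hit) == 0L) return(NULL)
    # offset from 3' end for template row r
    offs <- if (strand == "+") (L - 1L):0 else 0:(L - 1L)
    logf <- log1p(-w[offs + 1L])
    score <- exp(colSums(mm[, hit, drop = FALSE] * logf))
    anchor_rows <- which(offs <= 4L)
    mm_anchor <- colSums(mm[anchor_rows, hit, drop = FALSE])
    data.frame(template_id = tid, strand = strand,
               start = starts[hit], end = starts[hit] + L - 1L,
               pos3 = if (strand == "+") starts[hit] + L - 1L else starts[hit],
               mm_total = tot[hit], mm_anchor = mm_anchor, score = score,
               stringsAsFactors = FALSE)
  }
  pch <- strsplit(pseq, "", fixed = TRUE)[[1L]]
  rcch <- strsplit(reverse_complement(pseq), "", fixed = TRUE)[[1L]]
  res <- rbind(scan(pch, "+"), scan(rcch, "-"))
  if (is.null(res))
    res <- data.frame(template_id = character(), strand = character(),
                      start = integer(), end = integer(), pos3 = integer(),
                      mm_total = integer(), mm_anchor = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Predict amplification of an assay on a template
#'
#' Considers every orientation-compatible pair of binding sites (one primer
#' on each strand, 3' ends facing, product at most \code{max_product}) and
#' selects the pair with maximal combined score
#' \code{min(forward score, reverse score)}, ties going to the shortest
#' product. Calls: \code{robust} if score >= \code{theta_robust}; \code{none}
#' if score < \code{theta_weak} or no compatible pair exists; \code{weak}
#' otherwise.
#'
#' @param assay An [assay_design].
#' @param template Template [seq_record] or string.
#' @param theta_robust,theta_weak Call thresholds on the combined score.
#' @param max_product Maximum product length considered.
#' @param max_total_mm Maximum mismatches per binding site.
#' @return Object of class \code{amplification_prediction} with fields
#'   \code{assay_id}, \code{template_id}, \code{product_bp} (NA if none),
#'   \code{score} and \code{call}.
#' @export
predict_amplification <- function(assay, template, theta_robust = 0.5,
                                  theta_weak = 0.05, max_product = 2000L,
                                  max_total_mm = 3L) {
  tid <- record_id(template, "template")
  sf <- find_binding_sites(assay$forward, template, max_total_mm)
  sr <- find_binding_sites(assay$reverse, template, max_total_mm)
  best <- NULL
  consider <- function(plus, minus) {
    # plus: site with 3' end at its right bound; minus: 3' end at left bound
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        p <- plus[i, ]; m <- minus[j, ]
        if (m$start <= p$end) next              # 3' ends must face
        prod <- m$end - p$start + 1L
        if (prod > max_product) next
        sc <- min(p$score, m$score)
        if (is.null(best) || sc > best$score ||
            (sc == best$score && prod < best$product_bp)) {
          best <<- list(score = sc, product_bp = prod)
        }
      }
    }
  }
  consider(sf[sf$strand == "+", , drop = FALSE],
           sr[sr$strand == "-", , drop = FALSE])
  consider(sr[sr$strand == "+", , drop = FALSE],
           sf[sf$strand == "-", , drop = FALSE])
  if (is.null(best)) {
    score <- 0; product <- NA_integer_; call <- "none"
  } else {
    score <- best$score; product <- best$product_bp
    call <- if (score >= theta_robust) "robust"
            else if (score < theta_weak) "none" else "weak"
    if (call == "none") product <- NA_integer_
  }
  structure(list(assay_id = assay$id, template_id = tid,
                 product_bp = product, score = score, call = call),
            class = "amplification_prediction")
}

#' @export
print.amplification_prediction <- function(x, ...) {
  cat(sprintf("<amp> %s x %s: %s (score %.3f, product %s bp)\n",
              x$assay_id, x$template_id, x$call, x$score,
              ifelse(is.na(x$product_bp), "-", x$product_bp)))
  invisible(x)
}

#' Cross-amplification matrix of assays against templates
#'
#' Full assay-by-template grid of [predict_amplification()] results with
#' deterministic ordering (input order preserved).
#'
#' @param assays List of [assay_design]s.
#' @param templates List of template [seq_record]s.
#' @param ... Passed to [predict_amplification()].
#' @return Object of class \code{cross_amp_matrix}: a long data frame with
#'   \code{assay_id}, \code{template_id}, \code{product_bp}, \code{score},
#'   \code{call}; \code{print()} renders a call grid.
#' @export
cross_amplification_matrix <- function(assays, templates, ...) {
  if (length(assays) == 0L) stop("cross_amplification_matrix: no assays")
  rows <- list()
  for (a in assays) {
    for (t in templates) {
      p <- predict_amplification(a, t, ...)
      rows[[length(rows) + 1L]] <-
        data.frame(assay_id = p$assay_id, template_id = p$template_id,
                   product_bp = p$product_bp, score = p$score,
                   call = p$call, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(assay_id = character(), template_id = character(),
                        product_bp = integer(), score = numeric(),
                        call = character(), stringsAsFactors = FALSE)
  structure(df, class = c("cross_amp_matrix", "data.frame"))
}

#' @export
print.cross_amp_matrix <- function(x, ...) {
  if (nrow(x) == 0L) { cat("<cross_amp_matrix> empty\n"); return(invisible(x)) }
  sym <- c(robust = "R", weak = "w", none = ".")
  grid <- tapply(sym[x$call], list(x$assay_id, x$template_id), `[[`, 1L)
  grid <- grid[unique(x$assay_id), unique(x$template_id), drop = FALSE]
  cat("<cross_amp_matrix> R = robust, w = weak, . = none\n")
  print(as.table(grid))
  invisible(x)
}

#' Look up a call in a cross-amplification matrix
#' @param x A \code{cross_amp_matrix}.
#' @param assay_id,template_id Row selector.
#' @return The call string.
#' @export
amp_call <- function(x, assay_id, template_id) {
  r <- x$assay_id == assay_id & x$template_id == template_id
  if (!any(r)) stop("amp_call: no such assay/template pair")
  x$call[r][[1L]]
}

# --- poly-T sizing -----------------------------------------------------------

#' Expected capillary amplicon size for a poly-T tract
#'
#' The sizing amplicon consists of a fixed 179-bp flank plus the
#' homopolymer; the expected size is \code{179 + polyt_length}.
#'
#' @param polyt_length Poly-T tract length in bases (>= 0).
#' @return Expected amplicon size in bp.
#' @export
expected_amplicon_size <- function(polyt_length) {
  if (any(polyt_length < 0)) stop("expected_amplicon_size: negative length")
  179L + as.integer(polyt_length)
}

#' Classify an observed amplicon size into poly-T genotype bins
#'
#' Bins follow the printed windows: \code{S} for sizes <= 198 bp (poly-T <=
#' 19), \code{L} for 199-208 bp (poly-T 20-29), \code{VL} for >= 209 bp
#' (poly-T >= 30). The inferred tract length is \code{size - 179}.
#'
#' @param observed_size_bp Observed amplicon size(s) in bp (>= 179).
#' @return Data frame with \code{size_bp}, \code{bin}, \code{polyt_length}.
#' @export
classify_polyt <- function(observed_size_bp) {
  s <- as.integer(observed_size_bp)
  if (any(s < 179L)) stop("classify_polyt: size below flank length (179 bp)")
  bin <- ifelse(s <= 198L, "S", ifelse(s <= 208L, "L", "VL"))
  data.frame(size_bp = s, bin = bin, polyt_length = s - 179L,
             stringsAsFactors = FALSE)
}
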