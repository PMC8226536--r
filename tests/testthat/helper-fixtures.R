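# Test-local helpers. Sequence construction here deliberately uses base R
# only, so fixtures and oracles stay independent of the package's own
# sequence machinery.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute the bases at `positions` with a different random base
substitute_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions)
    ch[[p]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[p]]), 1L)
  paste(ch, collapse = "")
}

base_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rc_naive <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(rev(unname(base_complement[ch])), collapse = "")
}

# small locus-set configuration for fast homology tests
small_locus_config <- function(seed, divergences = c(0.02, 0.08, 0.15),
                               strands = c("+", "-", "+")) {
  locus_set_config(
    seed = seed,
    exon_lengths = c(300L, 300L, 300L),
    intron_lengths = c(400L, 500L),
    cds = c(31L, 870L),
    pseudogenes = data.frame(name = paste0("C", seq_along(divergences)),
                             divergence = divergences,
                             truncate_5p = 0L,
                             orf_disrupt = TRUE,
                             strand = strands,
                             stringsAsFactors = FALSE),
    paralog = list(name = "TL", cds_divergence = 0.15,
                   noncds_divergence = 0.32, include = FALSE),
    conserved = integer(),
    flank = 500L)
}

# brute-force binding-site oracle: direct sliding-window scan, independent of
# the package's matrix implementation
bf_sites <- function(pseq, tseq, maxmm = 3L) {
  L <- nchar(pseq); n <- nchar(tseq)
  w <- c(0.9, 0.6, 0.6, 0.3, 0.3, rep(0.1, max(0L, L - 5L)))
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") pseq else rc_naive(pseq)
    pc <- strsplit(pat, "")[[1L]]
    for (s in seq_len(n - L + 1L)) {
      win <- strsplit(substr(tseq, s, s + L - 1L), "")[[1L]]
      mmpos <- which(win != pc)
      if (length(mmpos) > maxmm) next
      offs <- if (strand == "+") L - mmpos else mmpos - 1L
      sc <- prod(1 - w[offs + 1L])
      out <- rbind(out, data.frame(strand = strand, start = s,
                                   mm = length(mmpos), score = sc))
    }
  }
  out
}

# brute-force amplification oracle over all orientation-compatible site pairs
bf_predict <- function(fwd, rev, tseq, theta_r = 0.5, theta_w = 0.05,
                       max_product = 2000L, maxmm = 3L) {
  sf <- bf_sites(fwd, tseq, maxmm); sr <- bf_sites(rev, tseq, maxmm)
  best <- NULL
  pair_up <- function(plus, plus_len, minus, minus_len) {
    if (is.null(plus) || is.null(minus)) return()
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      p <- plus[i, ]; m <- minus[j, ]
      if (p$strand != "+" || m$strand != "-") next
      if (m$start <= p$start + plus_len - 1L) next
      prod <- (m$start + minus_len - 1L) - p$start + 1L
      if (prod > max_product) next
      sc <- min(p$score, m$score)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && prod < best$prod))
        best <<- list(score = sc, prod = prod)
    }
  }
  pair_up(sf, nchar(fwd), sr, nchar(rev))
  pair_up(sr, nchar(rev), sf, nchar(fwd))
  if (is.null(best)) return(list(call = "none", score = 0))
  call <- if (best$score >= theta_r) "robust"
          else if (best$score < theta_w) "none" else "weak"
  list(call = call, score = best$score, prod = best$prod)
}

# Biostrings full-DP global alignment score with the package's scoring
# scheme; serves as the independent alignment oracle
oracle_align_score <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  pw <- Biostrings::pairwiseAlignment(q, s, substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2,
                                      type = "global")
  list(score = Biostrings::score(pw),
       identity = Biostrings::nmatch(pw) / Biostrings::nchar(pw))
}
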