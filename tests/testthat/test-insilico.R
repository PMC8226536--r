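test_that("binding sites score 1 on perfect match and 0.1 on a 3'-terminal mismatch", {
  set.seed(601)
  tpl <- seq_record("tpl", rand_dna(300))
  primer <- substr(tpl$seq, 101L, 120L)
  s <- find_binding_sites(primer, tpl)
  plus <- s[s$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 101L)
  expect_equal(plus$pos3, 120L)
  expect_equal(plus$score, 1)

  # mismatch at the primer's 3'-terminal base
  ch <- strsplit(primer, "")[[1L]]
  ch[20L] <- setdiff(c("A", "C", "G", "T"), ch[20L])[[1L]]
  s2 <- find_binding_sites(paste(ch, collapse = ""), tpl)
  p2 <- s2[s2$strand == "+" & s2$start == 101L, ]
  expect_equal(p2$mm_total, 1L)
  expect_equal(p2$mm_anchor, 1L)
  expect_equal(p2$score, 0.1, tolerance = 1e-12)
})

test_that("site scanning equals the exhaustive sliding-window oracle", {
  set.seed(602)
  for (i in 1:8) {
    tpl <- rand_dna(400)
    # embed a degenerate copy of a primer so hits exist
    primer <- rand_dna(18L)
    at <- sample(300L, 1L)
    degr <- substitute_at(primer, sample(18L, sample(0:3, 1L)))
    tseq <- paste0(substr(tpl, 1L, at - 1L), degr,
                   substr(tpl, at + 18L, nchar(tpl)))
    got <- find_binding_sites(primer, seq_record("t", tseq))
    want <- bf_sites(primer, tseq)
    got <- got[order(got$strand, got$start), ]
    want <- want[order(want$strand, want$start), ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$mm_total, want$mm)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

make_assay <- function(fwd, rev, id = "a") {
  assay_design(id, "splice_junction",
               pcr_primer("F", fwd, "+", 1L, nchar(fwd)),
               pcr_primer("R", rev, "-", 1L, nchar(rev)),
               amplicon_bp = 100L, template_id = "design")
}

test_that("amplification calls follow the combined-score thresholds", {
  set.seed(603)
  tpl <- seq_record("t", rand_dna(500))
  fwd <- substr(tpl$seq, 101L, 120L)
  rev <- rc_naive(substr(tpl$seq, 231L, 250L))
  asy <- make_assay(fwd, rev)
  p <- predict_amplification(asy, tpl)
  expect_equal(p$call, "robust")
  expect_equal(p$product_bp, 150L)
  expect_equal(p$score, 1)

  # absent reverse primer: no orientation-compatible pair
  p2 <- predict_amplification(make_assay(fwd, rand_dna(20L)), tpl)
  expect_equal(p2$call, "none")
  expect_true(is.na(p2$product_bp))

  # single 3'-terminal mismatch on the forward primer: leaky (weak)
  ch <- strsplit(fwd, "")[[1L]]
  ch[20L] <- setdiff(c("A", "C", "G", "T"), ch[20L])[[1L]]
  p3 <- predict_amplification(make_assay(paste(ch, collapse = ""), rev), tpl)
  expect_equal(p3$call, "weak")
  expect_equal(p3$score, 0.1, tolerance = 1e-12)
})

test_that("amplification prediction equals the exhaustive site-pair oracle", {
  set.seed(604)
  for (i in 1:8) {
    n <- sample(500:2000, 1L)
    tseq <- rand_dna(n)
    fwd <- substr(tseq, 51L, 70L)
    at <- sample(150:(n - 20L), 1L)
    rev <- rc_naive(substr(tseq, at, at + 19L))
    # degrade both primers a little
    fwd <- substitute_at(fwd, sample(20L, sample(0:2, 1L)))
    rev <- substitute_at(rev, sample(20L, sample(0:2, 1L)))
    got <- predict_amplification(make_assay(fwd, rev), seq_record("t", tseq))
    want <- bf_predict(fwd, rev, tseq)
    expect_equal(got$call, want$call)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    if (got$call != "none") expect_equal(got$product_bp, want$prod)
  }
})

test_that("binding scores are monotone: extra mismatches never help", {
  set.seed(605)
  tpl <- seq_record("t", rand_dna(300))
  primer <- substr(tpl$seq, 101L, 122L)
  score_of <- function(p) {
    s <- find_binding_sites(p, tpl)
    s <- s[s$strand == "+" & s$start == 101L, ]
    if (nrow(s) == 0L) 0 else s$score
  }
  prev <- score_of(primer)
  mutated <- primer
  for (k in 1:3) {
    pos <- sample(22L, 1L)
    ch <- strsplit(mutated, "")[[1L]]
    orig <- strsplit(primer, "")[[1L]][[pos]]
    if (ch[[pos]] == orig)
      ch[[pos]] <- setdiff(c("A", "C", "G", "T"), ch[[pos]])[[1L]]
    mutated <- paste(ch, collapse = "")
    cur <- score_of(mutated)
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("raising the robust threshold never upgrades a call", {
  set.seed(606)
  tpl <- seq_record("t", rand_dna(400))
  fwd <- substitute_at(substr(tpl$seq, 51L, 70L), c(3L, 19L))
  rev <- rc_naive(substr(tpl$seq, 181L, 200L))
  asy <- make_assay(fwd, rev)
  rank <- c(none = 0L, weak = 1L, robust = 2L)
  calls <- vapply(c(0.2, 0.5, 0.9),
                  function(th) predict_amplification(asy, tpl,
                                                     theta_robust = th)$call,
                  "")
  expect_true(all(diff(rank[calls]) <= 0L))
})

test_that("an empty template list yields an empty matrix", {
  set.seed(607)
  tpl <- seq_record("t", rand_dna(200))
  asy <- make_assay(substr(tpl$seq, 11L, 30L),
                    rc_naive(substr(tpl$seq, 141L, 160L)))
  m <- cross_amplification_matrix(list(asy), list())
  expect_s3_class(m, "cross_amp_matrix")
  expect_equal(nrow(m), 0L)
  expect_error(cross_amplification_matrix(list(), list(tpl)), "no assays")
})

test_that("poly-T amplicon sizing reproduces the printed windows exactly", {
  expect_equal(expected_amplicon_size(19L), 198L)
  expect_equal(expected_amplicon_size(0L), 179L)
  expect_equal(expected_amplicon_size(30L), 209L)
  expect_error(expected_amplicon_size(-1L), "negative")

  expect_equal(classify_polyt(198L)$bin, "S")
  expect_equal(classify_polyt(203L)$bin, "L")
  cc <- classify_polyt(209L)
  expect_equal(cc$bin, "VL")
  expect_equal(cc$polyt_length, 30L)
  expect_equal(classify_polyt(c(198L, 199L, 208L, 209L))$bin,
               c("S", "L", "L", "VL"))
  expect_error(classify_polyt(178L), "below flank")
})
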