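test_that("star alignment projects paralog bases onto target coordinates", {
  set.seed(501)
  tgt <- seq_record("T", rand_dna(400))
  same <- seq_record("same", tgt$seq)
  tbl <- align_to_target(tgt, list(same))
  expect_true(all(tbl$same == tbl$target))
  expect_equal(tbl$same_pos, tbl$position)

  p <- 137L
  mut <- seq_record("mut", substitute_at(tgt$seq, p))
  tbl <- align_to_target(tgt, list(mut))
  expect_equal(which(tbl$mut != tbl$target), p)

  planted <- sort(sample(400L, 12L))
  multi <- seq_record("m", substitute_at(tgt$seq, planted))
  tbl <- align_to_target(tgt, list(multi))
  expect_equal(which(tbl$m != tbl$target), planted)
})

test_that("low-coverage paralogs are excluded with a warning", {
  set.seed(502)
  tgt <- seq_record("T", rand_dna(600))
  frag <- seq_record("frag", substr(tgt$seq, 1L, 150L))
  good <- seq_record("good", substitute_at(tgt$seq, 5L))
  expect_warning(tbl <- align_to_target(tgt, list(good, frag)), "frag")
  expect_equal(attr(tbl, "paralogs"), "good")
})

test_that("discriminating sites distinguish target-unique and paralog-unique variants", {
  set.seed(503)
  tgt <- seq_record("T", rand_dna(300))
  identical1 <- seq_record("a", tgt$seq)
  identical2 <- seq_record("b", tgt$seq)
  tbl <- align_to_target(tgt, list(identical1, identical2))
  expect_equal(nrow(find_discriminating_sites(tbl, "unique_to_target")), 0L)

  pa <- 40L
  onediff <- seq_record("a", substitute_at(tgt$seq, pa))
  tbl <- align_to_target(tgt, list(onediff, identical2))
  up <- find_discriminating_sites(tbl, "unique_to_paralog", paralog = "a")
  expect_equal(up$position, pa)
  expect_equal(up$distinguishes, "a")
  # the same column is NOT target-unique: paralog b agrees with the target
  expect_equal(nrow(find_discriminating_sites(tbl, "unique_to_target")), 0L)
  expect_error(find_discriminating_sites(tbl, "unique_to_paralog",
                                         paralog = "zz"), "unknown paralog")
})

test_that("a near-identical copy leaves almost no copy-specific sites", {
  # the analogue of the pseudogene so close to the cDNA that its
  # allele-specific primers inevitably cross-react with the target
  set.seed(504)
  tgt <- seq_record("T", rand_dna(800))
  near <- seq_record("P1", substitute_at(tgt$seq, c(200L, 600L)))
  far <- seq_record("P3", substitute_at(tgt$seq, sort(sample(800L, 80L))))
  tbl <- align_to_target(tgt, list(near, far))
  sites <- find_discriminating_sites(tbl, "unique_to_paralog", paralog = "P1")
  expect_lte(nrow(sites), 2L)
})

test_that("melting temperature follows Wallace for short and nearest-neighbor for long primers", {
  expect_equal(melting_temperature("AAAAAAAAAA"), 20)
  expect_equal(melting_temperature("GGGGGGGGGG"), 40)
  # frozen hand computation (explicit table sums) for a fixed 20-mer,
  # 50 mM Na+, 500 nM primer
  expect_equal(melting_temperature("ACGTTGCAATGCCGTAGGCT"), 60.4411,
               tolerance = 1e-4)
  expect_error(melting_temperature("ACGTACGN"), "invalid character")
  expect_error(melting_temperature("ACGTA"), "shorter than 8")
})

test_that("allele-specific primers anchor their 3' terminus on a site", {
  set.seed(505)
  tpl <- seq_record("tpl", rand_dna(500))
  expect_equal(enumerate_allele_specific_primers(tpl, integer()), list())
  p <- 250L
  prims <- enumerate_allele_specific_primers(tpl, p)
  expect_gt(length(prims), 0L)
  for (pr in prims) {
    three_prime <- if (pr$strand == "+") pr$end else pr$start
    expect_equal(three_prime, p)
    expect_true(0L %in% pr$anchored_offsets)
    expect_gte(nchar(pr$seq), 18L)
    expect_lte(nchar(pr$seq), 25L)
    expect_gte(pr$tm, 57); expect_lte(pr$tm, 63)
  }
})

test_that("primer enumeration equals brute force over (start, length, strand)", {
  set.seed(506)
  tpl <- rand_dna(450)
  sites <- sort(sample(60:420, 3L))
  got <- enumerate_allele_specific_primers(tpl, sites)
  # independent brute force
  want <- 0L
  for (p in sites) for (L in 18:25) for (str in c("+", "-")) {
    if (str == "+") { a <- p - L + 1L; b <- p } else { a <- p; b <- p + L - 1L }
    if (a < 1L || b > nchar(tpl)) next
    sq <- substr(tpl, a, b)
    if (str == "-") sq <- rc_naive(sq)
    gc <- mean(strsplit(sq, "")[[1L]] %in% c("G", "C"))
    tm <- melting_temperature(sq)
    if (gc >= 0.35 && gc <= 0.65 && tm >= 57 && tm <= 63) want <- want + 1L
  }
  expect_equal(length(got), want)
})

test_that("allele-specific primer termini differ from every paralog at the site", {
  set.seed(507)
  tgt <- seq_record("T", rand_dna(600))
  paralogs <- lapply(c("p1", "p2"), function(nm)
    seq_record(nm, substitute_at(tgt$seq, sort(sample(600L, 25L)))))
  tbl <- align_to_target(tgt, paralogs)
  sites <- find_discriminating_sites(tbl, "unique_to_target")
  prims <- enumerate_allele_specific_primers(tgt, sites)
  for (pr in utils::head(prims, 10L)) {
    three_prime <- if (pr$strand == "+") pr$end else pr$start
    row <- tbl[tbl$position == three_prime, ]
    tb <- row$target
    expect_true(all(c(row$p1, row$p2) != tb))
    # the primer's 3'-terminal base is the target base at that column
    term <- substr(pr$seq, nchar(pr$seq), nchar(pr$seq))
    expect_equal(if (pr$strand == "+") term else rc_naive(term), tb)
  }
})

test_that("junction assays straddle the exon junction with enough overhang", {
  set.seed(508)
  ex1 <- rand_dna(60); ex2 <- rand_dna(60); intron <- rand_dna(300)
  chrom <- seq_record("chrJ", paste0(ex1, intron, ex2))
  gm <- gene_model("g", "chrJ", "+", c(1L, 361L), c(60L, 420L))
  cdna <- seq_record("cdna", paste0(ex1, ex2))
  asy <- design_junction_assay(gm, cdna, 1L)
  expect_equal(asy$class, "splice_junction")
  fwd <- asy$forward
  expect_gte(fwd$end - 60L, 4L)        # >= 4 bases in exon 2
  expect_gte(60L - fwd$start + 1L, 4L) # >= 4 bases in exon 1
  expect_gte(asy$amplicon_bp, 70L); expect_lte(asy$amplicon_bp, 250L)
  expect_error(design_junction_assay(gm, cdna, 2L), "no exon pair")
})

test_that("a junction amplicon is shorter on cDNA than its genomic footprint", {
  ls <- generate_locus_set(small_locus_config(seed = 509))
  asy <- design_junction_assay(ls$model, ls$cdna, 1L)
  g_start <- cdna_pos_to_genomic(ls$model, asy$forward$start)
  g_end <- cdna_pos_to_genomic(ls$model, asy$reverse$end)
  genomic_span <- g_end - g_start + 1L
  intron1 <- ls$config$intron_lengths[[1L]]
  expect_equal(genomic_span, asy$amplicon_bp + intron1)
})

test_that("primary-transcript assays sit on or across intron sequence", {
  ls <- generate_locus_set(small_locus_config(seed = 510))
  chrom <- ls$genome[[1L]]
  introns <- model_introns(ls$model)

  ii <- design_primary_transcript_assay(ls$model, chrom, "intra_intron", 1L)
  expect_equal(ii$class, "intra_intron")
  expect_gte(ii$forward$start, introns$start[[1L]])
  expect_lte(ii$reverse$end, introns$end[[1L]])

  ei <- design_primary_transcript_assay(ls$model, chrom, "exon_intron", 1L)
  expect_equal(ei$class, "exon_intron")
  boundary <- ls$model$exons$end[[1L]]
  expect_lte(ei$forward$end, boundary)
  expect_gte(ei$forward$start, ls$model$exons$start[[1L]])
  expect_gte(ei$reverse$start, introns$start[[1L]])
  expect_lte(ei$reverse$end, introns$end[[1L]])
  # amplicon crosses the exon/intron boundary
  expect_lte(ei$forward$start, boundary)
  expect_gt(ei$reverse$end, boundary)

  single <- gene_model("s", "chrX", "+", 1L, 500L)
  expect_error(design_primary_transcript_assay(single, chrom, "intra_intron",
                                               1L),
               "no introns")
})
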