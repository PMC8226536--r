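test_that("pairwise distances follow the p and JC69 formulas with pairwise deletion", {
  a <- strrep("ACGT", 25L)
  expect_equal(pairwise_distance(a, a, "p"), 0)
  expect_equal(pairwise_distance(a, a, "jc69"), 0)
  # p = 0.10 over 100 columns: frozen closed form
  b <- paste0(strrep("T", 10L), substr(a, 11L, 100L))
  b <- paste0(chartr("ACGT", "CAGT", substr(a, 1L, 13L)), substr(a, 14L, 100L))
  p <- pairwise_distance(a, b, "p")
  expect_equal(pairwise_distance(a, b, "jc69"),
               -0.75 * log(1 - 4 * p / 3))
  x <- "AC--GT"; y <- "ACGG-T"
  expect_equal(pairwise_distance(x, y, "p"), 0)  # gap columns dropped
  expect_error(pairwise_distance("----", "AAAA"), "no comparable")
  far <- chartr("ACGT", "GTAC", a)
  expect_error(pairwise_distance(a, far, "jc69"), "undefined")
})

test_that("a frozen 10% p-distance maps to the known JC69 value", {
  set.seed(801)
  a <- rand_dna(200)
  b <- substitute_at(a, sample(200L, 20L))
  expect_equal(pairwise_distance(a, b, "p"), 0.10)
  expect_equal(pairwise_distance(a, b, "jc69"), 0.1073256, tolerance = 1e-6)
})

test_that("three taxa produce the closed-form star solution", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  el <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2L]])
  expect_equal(el[["a"]], 0.5)
  expect_equal(el[["b"]], 1.5)
  expect_equal(el[["c"]], 2.5)
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3 taxa")
  D2 <- D; D2[1L, 2L] <- 5
  expect_error(nj_tree(D2), "non-symmetric")
})

test_that("NJ exactly recovers random additive trees", {
  set.seed(802)
  for (i in 1:30) {
    ntax <- sample(4:8, 1L)
    true <- ape::rtree(ntax, rooted = FALSE,
                       br = function(n) stats::runif(n, 0.05, 1))
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    mine <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true), mine), 0,
                 ignore_attr = TRUE)
    Dhat <- ape::cophenetic.phylo(mine)[rownames(D), colnames(D)]
    expect_equal(Dhat, D, tolerance = 1e-8)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(803)
  for (i in 1:5) {
    ntax <- sample(5:8, 1L)
    true <- ape::rtree(ntax, rooted = FALSE)
    D <- ape::cophenetic.phylo(true) + matrix(stats::runif(ntax^2, 0, 0.02),
                                              ntax)
    D <- (D + t(D)) / 2; diag(D) <- 0
    mine <- nj_tree(D)
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("an all-equal distance matrix resolves deterministically", {
  ids <- c("a", "b", "c", "d", "e")
  D <- matrix(1, 5L, 5L, dimnames = list(ids, ids)); diag(D) <- 0
  t1 <- attr(nj_tree(D), "newick")
  t2 <- attr(nj_tree(D), "newick")
  expect_equal(t1, t2)
  # tie rule: the lexicographically smallest pair joins first
  expect_match(t1, "\\(a:[0-9.e-]+,b:[0-9.e-]+\\)")
})

test_that("bootstrap supports are reproducible and saturate on clean signal", {
  set.seed(804)
  # conflict-free alignment: two clades separated by many fixed differences
  core <- rand_dna(300)
  blockA <- substitute_at(core, 1:60)
  aln <- c(a1 = blockA, a2 = substitute_at(blockA, 251:255),
           b1 = core, b2 = substitute_at(core, 261:265),
           b3 = substitute_at(core, 271:275))
  tr <- suppressWarnings(bootstrap_support(aln, 50L, seed = 11))
  sup <- attr(tr, "support")
  # the a1+a2 bipartition is recovered in every replicate (100% support)
  expect_true(any(sup == 100L, na.rm = TRUE))
  tr2 <- suppressWarnings(bootstrap_support(aln, 50L, seed = 11))
  expect_equal(attr(tr2, "support"), sup)
  expect_equal(ape::write.tree(tr2), ape::write.tree(tr))
  # single replicate: support counts are 0 or 1 of 1
  tr3 <- suppressWarnings(bootstrap_support(aln, 1L, seed = 12))
  expect_true(all(attr(tr3, "support") %in% c(0L, 100L), na.rm = TRUE))
})

test_that("a nearly identical copy sits closest to the parent cDNA in the tree", {
  # each copy diverges independently from the cDNA, so the true tree is a
  # star centred on the parent; the meaningful, resolution-independent
  # statement of the family structure is that the least-diverged copy is the
  # cDNA's nearest neighbour by patristic distance -- the same closeness
  # that makes its allele-specific primers cross-react with the target
  cfg <- locus_set_config(seed = 805,
                          pseudogenes = data.frame(
                            name = c("P1", "P1b", "P2", "P3", "P4"),
                            divergence = c(0.012, 0.0445, 0.0412, 0.1274,
                                           0.0459),
                            truncate_5p = 0L, orf_disrupt = TRUE,
                            strand = "+", stringsAsFactors = FALSE))
  ls <- generate_locus_set(cfg)
  tbl <- align_to_target(ls$cdna, ls$pseudogene_cdnas)
  aln <- c(CDNA = paste(tbl$target, collapse = ""))
  for (nm in names(ls$pseudogene_cdnas))
    aln[[nm]] <- paste(tbl[[nm]], collapse = "")
  tr <- nj_tree(distance_matrix(aln, "jc69"))
  patristic <- ape::cophenetic.phylo(tr)["CDNA", ]
  nearest <- names(which.min(patristic[names(patristic) != "CDNA"]))
  expect_equal(nearest, "P1")
})

test_that("newick output round-trips through ape", {
  D <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3L,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
})
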