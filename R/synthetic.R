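# Seeded generators that emulate the study's data-generating reality: a
# multi-exon parent gene whose spliced cDNA has been retrocopied into several
# intronless, 87-96%-identical genomic loci plus one diverged intron-bearing
# paralog; triplicate-CT cohorts with a planted group effect; digital-PCR
# partition counts; an oxidative-stress cell-line panel; and a poly-T sizing
# cohort.  Every generator is a pure function of its config and seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic locus set
#'
#' Defaults emulate the structure of a ten-exon parent gene (1676-nt cDNA,
#' 12,470-bp genomic span) with five processed copies whose divergences match
#' the published identity band (87.3-95.9%), two of them 5'-truncated, all
#' with a disrupted reading frame, plus one intron-retaining paralog at 25%
#' divergence. A window around the exon 4/5 junction (the region measured by
#' total-pool cDNA assays) is held invariant in the pseudogene copies,
#' mirroring the observed conservation of that region across the family.
#'
#' @param seed Integer seed.
#' @param exon_lengths,intron_lengths Parent gene structure (nt).
#' @param cds CDS interval on the cDNA, \code{c(start, end)}.
#' @param pseudogenes Data frame with \code{name}, \code{divergence} (in
#'   \code{[0, 0.3]}), \code{truncate_5p} (nt removed from the 5' end),
#'   \code{orf_disrupt}, \code{strand}.
#' @param paralog List with \code{name}, \code{cds_divergence} (coding
#'   exons, held lower by purifying selection), \code{noncds_divergence}
#'   (UTRs and introns, drifting faster), \code{include}.
#' @param conserved cDNA window \code{c(start, end)} protected from mutation
#'   in pseudogene copies.
#' @param flank Random flanking sequence per locus (nt).
#' @return Object of class \code{locus_set_config}.
#' @export
locus_set_config <- function(seed = 1L,
                             exon_lengths = c(120L, 150L, 180L, 160L, 140L,
                                              200L, 170L, 190L, 180L, 186L),
                             intron_lengths = c(800L, 2000L, 1500L, 900L,
                                                1200L, 1600L, 700L, 1000L,
                                                1094L),
                             cds = c(100L, 1119L),
                             pseudogenes = data.frame(
                               name = c("P1", "P1b", "P2", "P3", "P4"),
                               divergence = c(0.043, 0.0445, 0.0412,
                                              0.1274, 0.0459),
                               truncate_5p = c(0L, 0L, 0L, 220L, 214L),
                               orf_disrupt = TRUE,
                               strand = c("+", "+", "-", "+", "+"),
                               stringsAsFactors = FALSE),
                             paralog = list(name = "TL",
                                            cds_divergence = 0.15,
                                            noncds_divergence = 0.32,
                                            include = TRUE),
                             conserved = c(500L, 860L),
                             flank = 1000L) {
  if (length(intron_lengths) != length(exon_lengths) - 1L)
    stop("locus_set_config: need exactly one intron between consecutive exons")
  if (length(exon_lengths) < 2L)
    stop("locus_set_config: parent gene needs >= 1 intron")
  if (any(pseudogenes$divergence < 0 | pseudogenes$divergence > 0.3))
    stop("locus_set_config: divergence out of range [0, 0.3]")
  if ((cds[[2L]] - cds[[1L]] + 1L) %% 3L != 0L)
    stop("locus_set_config: CDS length must be a multiple of 3")
  structure(list(seed = seed, exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 cds = as.integer(cds), pseudogenes = pseudogenes,
                 paralog = paralog, conserved = as.integer(conserved),
                 flank = as.integer(flank)),
            class = "locus_set_config")
}

# substitutions at an exact count drawn outside protected positions
mutate_seq <- function(seq, n_mut, protect = integer()) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- setdiff(seq_along(ch), protect)
  if (n_mut > length(ok))
    stop("mutate_seq: more mutations requested than mutable positions")
  pos <- sort(sample(ok, n_mut))
  for (p in pos) {
    ch[[p]] <- sample(setdiff(c("A", "C", "G", "T"), ch[[p]]), 1L)
  }
  paste(ch, collapse = "")
}

# repair stop codons in the CDS frame (third base swap), preserving the ORF
repair_orf <- function(seq, cds) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  starts <- seq.int(cds[[1L]], cds[[2L]] - 3L, by = 3L)  # keep final stop
  for (s in starts) {
    codon <- paste(ch[s:(s + 2L)], collapse = "")
    if (codon %in% STOP_CODONS) ch[[s + 2L]] <- "T"      # TAA/TAG/TGA -> ..T
  }
  # TGA -> TGT handled; TAA -> TAT, TAG -> TAT: none are stops
  paste(ch, collapse = "")
}

#' Generate the synthetic locus set
#'
#' Builds the parent gene (CDS-bearing cDNA split over exons, embedded with
#' introns and random flanks on its own chromosome), each pseudogene as a
#' mutated, optionally truncated, intronless insertion of the spliced cDNA
#' at a distinct locus, and optionally a diverged paralog retaining introns
#' and a full ORF. Deterministic: repeated calls with the same config are
#' byte-identical.
#'
#' @param config A [locus_set_config()].
#' @return List with \code{genome} (list of chromosome [seq_record]s),
#'   \code{model} (parent [gene_model]), \code{cdna}, \code{cds},
#'   \code{pseudogene_cdnas} (planted copy sequences in cDNA orientation),
#'   \code{paralog_cdna} (or NULL), \code{truth} (per-locus data frame), and
#'   \code{config}.
#' @export
generate_locus_set <- function(config = locus_set_config()) {
  stopifnot(inherits(config, "locus_set_config"))
  with_seed(config$seed, {
    exl <- config$exon_lengths; inl <- config$intron_lengths
    cds <- config$cds
    n_cdna <- sum(exl)
    if (cds[[2L]] > n_cdna) stop("generate_locus_set: CDS beyond cDNA")

    # parent cDNA with a real ORF: ATG + sense codons + TAA
    pre <- random_dna(cds[[1L]] - 1L)
    n_codons <- (cds[[2L]] - cds[[1L]] + 1L) / 3L
    sense <- setdiff(
      apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                        c("A","C","G","T")), 1L, paste, collapse = ""),
      STOP_CODONS)
    body <- paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = "")
    post <- random_dna(n_cdna - cds[[2L]])
    cdna <- paste0(pre, "ATG", body, "TAA", post)
    stopifnot(nchar(cdna) == n_cdna)

    # parent chromosome
    introns <- vapply(inl, random_dna, "")
    exon_seqs <- substring(cdna, cumsum(c(1L, exl[-length(exl)])),
                           cumsum(exl))
    gene_seq <- exon_seqs[[1L]]
    for (i in seq_along(introns))
      gene_seq <- paste0(gene_seq, introns[[i]], exon_seqs[[i + 1L]])
    fl5 <- random_dna(config$flank); fl3 <- random_dna(config$flank)
    chrA <- paste0(fl5, gene_seq, fl3)
    exon_starts <- integer(length(exl)); pos <- config$flank + 1L
    for (i in seq_along(exl)) {
      exon_starts[[i]] <- pos
      pos <- pos + exl[[i]] + if (i <= length(inl)) inl[[i]] else 0L
    }
    model <- gene_model("PARENT", "chrA", "+", exon_starts,
                        exon_starts + exl - 1L)
    genome <- list(seq_record("chrA", chrA))
    truth <- data.frame(name = "PARENT", chrom = "chrA",
                        start = config$flank + 1L,
                        end = config$flank + nchar(gene_seq),
                        strand = "+", class = "parent", divergence = 0,
                        length = nchar(gene_seq), truncated = FALSE,
                        orf_disrupted = FALSE, stringsAsFactors = FALSE)

    # pseudogene loci
    pg <- config$pseudogenes
    pg_cdnas <- list()
    chrom_names <- paste0("chr", LETTERS[seq_len(nrow(pg)) + 1L])
    for (i in seq_len(nrow(pg))) {
      trunc <- pg$truncate_5p[[i]]
      copy <- substr(cdna, trunc + 1L, n_cdna)
      L <- nchar(copy)
      protect <- integer()
      if (length(config$conserved) == 2L) {
        cons <- config$conserved - trunc
        cons <- pmax(pmin(cons, L), 0L)
        if (cons[[2L]] >= 1L && cons[[1L]] <= cons[[2L]] && cons[[1L]] >= 1L)
          protect <- seq.int(cons[[1L]], cons[[2L]])
      }
      copy <- mutate_seq(copy, round(pg$divergence[[i]] * L), protect)
      if (isTRUE(pg$orf_disrupt[[i]])) {
        dis <- cds[[1L]] + 3L * 83L - trunc   # codon boundary in parent frame
        if (dis >= 1L && dis + 2L <= L)
          copy <- paste0(substr(copy, 1L, dis - 1L), "TAA",
                         substr(copy, dis + 3L, L))
      }
      fl5 <- random_dna(config$flank); fl3 <- random_dna(config$flank)
      insert <- if (pg$strand[[i]] == "-") reverse_complement(copy) else copy
      genome[[length(genome) + 1L]] <-
        seq_record(chrom_names[[i]], paste0(fl5, insert, fl3))
      pg_cdnas[[pg$name[[i]]]] <- seq_record(pg$name[[i]], copy)
      truth <- rbind(truth, data.frame(
        name = pg$name[[i]], chrom = chrom_names[[i]],
        start = config$flank + 1L, end = config$flank + L,
        strand = pg$strand[[i]], class = "pseudogene",
        divergence = pg$divergence[[i]], length = L,
        truncated = trunc > 0L,
        orf_disrupted = isTRUE(pg$orf_disrupt[[i]]),
        stringsAsFactors = FALSE))
    }

    # diverged paralog retaining introns and a full ORF; its coding exons
    # stay closer to the parent than its UTRs and introns
    paralog_cdna <- NULL
    if (isTRUE(config$paralog$include)) {
      d_cds <- config$paralog$cds_divergence
      d_non <- config$paralog$noncds_divergence
      cds_pos <- seq.int(cds[[1L]], cds[[2L]])
      non_pos <- setdiff(seq_len(n_cdna), cds_pos)
      anchors <- c(cds[[1L]]:(cds[[1L]] + 2L), (cds[[2L]] - 2L):cds[[2L]])
      pcdna <- mutate_seq(cdna, round(d_cds * (length(cds_pos) - 6L)),
                          protect = c(non_pos, anchors))
      pcdna <- mutate_seq(pcdna, round(d_non * length(non_pos)),
                          protect = cds_pos)
      pcdna <- repair_orf(pcdna, cds)
      pd <- (d_cds * length(cds_pos) + d_non * length(non_pos)) / n_cdna
      pintrons <- vapply(introns, function(s)
        mutate_seq(s, round(d_non * nchar(s))), "")
      pexons <- substring(pcdna, cumsum(c(1L, exl[-length(exl)])),
                          cumsum(exl))
      pgene <- pexons[[1L]]
      for (i in seq_along(pintrons))
        pgene <- paste0(pgene, pintrons[[i]], pexons[[i + 1L]])
      chrom <- paste0("chr", LETTERS[nrow(pg) + 2L])
      fl5 <- random_dna(config$flank); fl3 <- random_dna(config$flank)
      genome[[length(genome) + 1L]] <-
        seq_record(chrom, paste0(fl5, pgene, fl3))
      paralog_cdna <- seq_record(config$paralog$name, pcdna)
      truth <- rbind(truth, data.frame(
        name = config$paralog$name, chrom = chrom,
        start = config$flank + 1L, end = config$flank + nchar(pgene),
        strand = "+", class = "paralog", divergence = pd,
        length = nchar(pgene), truncated = FALSE, orf_disrupted = FALSE,
        stringsAsFactors = FALSE))
    }

    list(genome = genome, model = model,
         cdna = seq_record("CDNA", cdna), cds = cds,
         pseudogene_cdnas = pg_cdnas, paralog_cdna = paralog_cdna,
         truth = truth, config = config)
  })
}

#' Cohort configuration for synthetic CT tables
#'
#' Defaults match the study design: 47 case (AD) and 20 control samples,
#' triplicate CTs with replicate SD 0.15 cycles, and a planted case effect
#' of -1.32 cycles on the normalized delta-CT (a ~2.5-fold increase under
#' \code{2^-ddCT}). Genotype columns for six markers are drawn at plausible
#' frequencies; the e4-carrier frequency differs by group as in the study
#' demographics.
#'
#' @param seed Integer seed.
#' @param n_ad,n_ctrl Group sizes (>= 2).
#' @param effect Planted group effect on delta-CT, cycles (AD minus control).
#' @param baseline_dct Baseline delta-CT, cycles.
#' @param replicate_sd Per-replicate CT standard deviation, cycles (> 0).
#' @param ref_ct_mean Mean reference-assay CT, cycles.
#' @param n_reps Replicates per assay.
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(seed = 1L, n_ad = 47L, n_ctrl = 20L,
                          effect = -1.32, baseline_dct = 5,
                          replicate_sd = 0.15, ref_ct_mean = 20,
                          n_reps = 3L) {
  if (n_ad < 2L || n_ctrl < 2L) stop("cohort_config: group sizes must be >= 2")
  if (replicate_sd <= 0) stop("cohort_config: replicate SD must be > 0")
  structure(list(seed = seed, n_ad = as.integer(n_ad),
                 n_ctrl = as.integer(n_ctrl), effect = effect,
                 baseline_dct = baseline_dct, replicate_sd = replicate_sd,
                 ref_ct_mean = ref_ct_mean, n_reps = as.integer(n_reps)),
            class = "cohort_config")
}

#' Generate a synthetic cohort CT table
#'
#' One row per sample and assay (\code{"IVS9"} target, \code{"ACTB"}
#' reference) with replicate CT columns: reference CTs are
#' \code{Normal(ref_ct_mean, sd)}; target CTs add the baseline delta-CT plus
#' the planted group effect for AD samples. Six genotype marker columns are
#' included.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns \code{sample}, \code{group}, \code{assay},
#'   \code{rep1..repN}, and genotype columns.
#' @export
generate_ct_table <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_ad + config$n_ctrl
    samples <- sprintf("S%03d", seq_len(n))
    group <- c(rep("AD", config$n_ad), rep("Control", config$n_ctrl))
    e4_p <- ifelse(group == "AD", 0.617, 0.15)
    geno <- data.frame(
      rs429358_e4 = ifelse(stats::rbinom(n, 1L, e4_p) == 1L, "e4+", "e4-"),
      rs71352238 = stats::rbinom(n, 2L, 0.35),
      rs2075650 = stats::rbinom(n, 2L, 0.35),
      rs10524523 = sample(c("S", "L", "VL"), n, replace = TRUE,
                          prob = c(0.45, 0.40, 0.15)),
      rs741780 = stats::rbinom(n, 2L, 0.40),
      rs10119 = stats::rbinom(n, 2L, 0.40),
      stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(n)) {
      dct <- config$baseline_dct + if (group[[i]] == "AD") config$effect else 0
      ref <- stats::rnorm(config$n_reps, config$ref_ct_mean,
                          config$replicate_sd)
      tgt <- stats::rnorm(config$n_reps, config$ref_ct_mean + dct,
                          config$replicate_sd)
      base <- data.frame(sample = samples[[i]], group = group[[i]],
                         stringsAsFactors = FALSE)
      r1 <- cbind(base, assay = "IVS9",
                  stats::setNames(as.data.frame(t(tgt)),
                                  paste0("rep", seq_len(config$n_reps))))
      r2 <- cbind(base, assay = "ACTB",
                  stats::setNames(as.data.frame(t(ref)),
                                  paste0("rep", seq_len(config$n_reps))))
      rows[[length(rows) + 1L]] <- cbind(rbind(r1, r2), geno[i, , drop = FALSE],
                                         row.names = NULL)
    }
    do.call(rbind, rows)
  })
}

#' Simulate digital-PCR partition counts
#'
#' Each partition is positive with probability
#' \code{1 - exp(-concentration * volume)} (Poisson occupancy).
#'
#' @param concentration True concentration, copies/uL (>= 0).
#' @param partitions Number of partitions (default 26,000, the nanoplate
#'   format used for the study's absolute quantification).
#' @param volume_ul Partition volume, uL.
#' @param seed Integer seed.
#' @return Data frame with \code{concentration}, \code{positives},
#'   \code{total}, \code{volume_ul}.
#' @export
generate_dpcr_partitions <- function(concentration, partitions = 26000L,
                                     volume_ul = 0.00091, seed = 1L) {
  if (concentration < 0) stop("generate_dpcr_partitions: negative concentration")
  with_seed(seed, {
    p <- 1 - exp(-concentration * volume_ul)
    pos <- stats::rbinom(1L, partitions, p)
    data.frame(concentration = concentration, positives = pos,
               total = partitions, volume_ul = volume_ul)
  })
}

#' Generate an oxidative-stress (H2O2) cell-line dataset
#'
#' Per cell line, paired treated/untreated measurements realizing the
#' configured effect multipliers: target-RNA fold change (default sampled
#' uniformly in 1.2-1.5), mitochondrial DNA copy-number fold change (0.2-0.6)
#' and JC-1 membrane-potential fold change (0.2-0.75) -- the directions and
#' ranges of the study's stressed-cell panel. A length-1 effect is used as a
#' fixed multiplier; a length-2 effect as a uniform sampling range.
#'
#' @param rna_effect,mtdna_effect,mmp_effect Effect multiplier (scalar) or
#'   range \code{c(lo, hi)}; all must be > 0.
#' @param cell_lines Cell-line names.
#' @param n_treatments Independent treatments per line.
#' @param ct_sd Per-replicate CT noise, cycles.
#' @param mmp_sdlog Lognormal noise SD of fluorescence intensities.
#' @param seed Integer seed.
#' @return List with \code{rna} and \code{mtdna} CT tables (assays
#'   \code{IVS9}/\code{ACTB} and \code{MT}/\code{HGB}), \code{mmp}
#'   intensities, and \code{truth} (per-line multipliers).
#' @export
generate_h2o2_dataset <- function(rna_effect = c(1.2, 1.5),
                                  mtdna_effect = c(0.2, 0.6),
                                  mmp_effect = c(0.2, 0.75),
                                  cell_lines = c("HepG2", "U-118", "U-87",
                                                 "LN-229"),
                                  n_treatments = 3L,
                                  ct_sd = 0.05, mmp_sdlog = 0.05,
                                  seed = 1L) {
  for (e in list(rna_effect, mtdna_effect, mmp_effect))
    if (any(e <= 0)) stop("generate_h2o2_dataset: effect multipliers must be > 0")
  draw <- function(e) if (length(e) == 1L) rep(e, length(cell_lines))
                      else stats::runif(length(cell_lines), e[[1L]], e[[2L]])
  with_seed(seed, {
    m_rna <- draw(rna_effect); m_mt <- draw(mtdna_effect)
    m_mmp <- draw(mmp_effect)
    ct_rows <- function(cl, cond, trt, assay_t, assay_r, dct) {
      ref <- stats::rnorm(3L, 20, ct_sd)
      tgt <- stats::rnorm(3L, 20 + dct, ct_sd)
      sample <- sprintf("%s_t%d_%s", cl, trt, cond)
      rbind(
        data.frame(cell_line = cl, sample = sample, condition = cond,
                   assay = assay_t, rep1 = tgt[[1L]], rep2 = tgt[[2L]],
                   rep3 = tgt[[3L]], stringsAsFactors = FALSE),
        data.frame(cell_line = cl, sample = sample, condition = cond,
                   assay = assay_r, rep1 = ref[[1L]], rep2 = ref[[2L]],
                   rep3 = ref[[3L]], stringsAsFactors = FALSE))
    }
    rna <- list(); mtdna <- list(); mmp <- list()
    for (k in seq_along(cell_lines)) {
      cl <- cell_lines[[k]]
      for (t in seq_len(n_treatments)) {
        rna[[length(rna) + 1L]] <-
          rbind(ct_rows(cl, "untreated", t, "IVS9", "ACTB", 5),
                ct_rows(cl, "treated", t, "IVS9", "ACTB",
                        5 - log2(m_rna[[k]])))
        mtdna[[length(mtdna) + 1L]] <-
          rbind(ct_rows(cl, "untreated", t, "MT", "HGB", -5),
                ct_rows(cl, "treated", t, "MT", "HGB",
                        -5 - log2(m_mt[[k]])))
        noise <- function() exp(stats::rnorm(1L, 0, mmp_sdlog))
        mmp[[length(mmp) + 1L]] <- data.frame(
          cell_line = cl, treatment = t,
          condition = c("untreated", "treated"),
          red = c(3000 * noise(), 3000 * m_mmp[[k]] * noise()),
          green = c(1000 * noise(), 1000 * noise()),
          stringsAsFactors = FALSE)
      }
    }
    list(rna = do.call(rbind, rna), mtdna = do.call(rbind, mtdna),
         mmp = do.call(rbind, mmp),
         truth = data.frame(cell_line = cell_lines, rna_mult = m_rna,
                            mtdna_mult = m_mt, mmp_mult = m_mmp,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a poly-T sizing cohort
#'
#' Per allele, the observed capillary size is \code{179 + length} plus
#' uniform \code{{-1, 0, +1}} bp electrophoretic noise. Alleles whose length
#' sits on a bin edge (19/20 and 29/30) are flagged: +/-1 bp noise can move
#' them across the printed genotype windows.
#'
#' @param genotypes List of length-2 integer vectors (two poly-T allele
#'   lengths per sample), optionally named.
#' @param seed Integer seed.
#' @return Data frame with \code{sample}, \code{allele}, \code{polyt_length},
#'   \code{observed_size}, \code{boundary_risk}.
#' @export
generate_polyt_cohort <- function(genotypes, seed = 1L) {
  lens <- unlist(genotypes)
  if (any(lens < 0)) stop("generate_polyt_cohort: negative poly-T length")
  nm <- names(genotypes)
  if (is.null(nm)) nm <- sprintf("G%02d", seq_along(genotypes))
  with_seed(seed, {
    rows <- list()
    for (i in seq_along(genotypes)) {
      for (a in 1:2) {
        L <- genotypes[[i]][[a]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = nm[[i]], allele = a, polyt_length = L,
          observed_size = expected_amplicon_size(L) +
            sample(c(-1L, 0L, 1L), 1L),
          boundary_risk = L %in% c(19L, 20L, 29L, 30L),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
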