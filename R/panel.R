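#' Design the standard discrimination assay panel for a locus set
#'
#' Assembles, from a [generate_locus_set()] result (or any equivalent
#' structure), the panel used to demonstrate pseudogene discrimination: a
#' splice-junction cDNA assay over the given exon pair (the total-pool
#' analogue of commercial expression assays), an exon-intron and an
#' intra-intron primary-transcript assay, and one allele-specific assay per
#' pseudogene anchored on sites unique to that pseudogene.
#'
#' @param locus_set List with \code{cdna}, \code{model}, \code{genome},
#'   \code{pseudogene_cdnas}.
#' @param junction_exon Upstream exon of the junction assay.
#' @param exon_intron_intron Intron index of the exon-intron assay.
#' @param intra_intron_intron Intron index of the intra-intron assay.
#' @param constraints See [default_design_constraints()].
#' @return List with \code{assays} (named list of [assay_design]s) and
#'   \code{templates} (named list of [seq_record]s: \code{cdna},
#'   \code{genomic}, one per pseudogene) ready for
#'   [cross_amplification_matrix()].
#' @export
design_assay_panel <- function(locus_set, junction_exon = 4L,
                               exon_intron_intron = 6L,
                               intra_intron_intron = 9L,
                               constraints = default_design_constraints()) {
  cdna <- locus_set$cdna
  model <- locus_set$model
  genomic <- locus_set$genome[[1L]]
  assays <- list()
  assays[[sprintf("Ex%d-Ex%d", junction_exon, junction_exon + 1L)]] <-
    design_junction_assay(model, cdna, junction_exon,
                          constraints = constraints,
                          id = sprintf("Ex%d-Ex%d", junction_exon,
                                       junction_exon + 1L))
  assays[[sprintf("Ex%d-IVS%d", exon_intron_intron, exon_intron_intron)]] <-
    design_primary_transcript_assay(model, genomic, "exon_intron",
                                    exon_intron_intron,
                                    constraints = constraints,
                                    id = sprintf("Ex%d-IVS%d",
                                                 exon_intron_intron,
                                                 exon_intron_intron))
  assays[[sprintf("IVS%d", intra_intron_intron)]] <-
    design_primary_transcript_assay(model, genomic, "intra_intron",
                                    intra_intron_intron,
                                    constraints = constraints,
                                    id = sprintf("IVS%d",
                                                 intra_intron_intron))
  tbl <- align_to_target(cdna, locus_set$pseudogene_cdnas)
  for (nm in names(locus_set$pseudogene_cdnas)) {
    sites <- find_discriminating_sites(tbl, "unique_to_paralog",
                                       paralog = nm)
    assays[[paste0(nm, "_as")]] <-
      design_allele_specific_assay(locus_set$pseudogene_cdnas[[nm]],
                                   sites$paralog_pos,
                                   id = paste0(nm, "_as"),
                                   constraints = constraints)
  }
  templates <- c(list(cdna = cdna, genomic = genomic),
                 locus_set$pseudogene_cdnas)
  list(assays = assays, templates = templates)
}
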