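#' Simulation configuration
#'
#' Builds the configuration object consumed by the diploid-genome simulator.
#' Defaults encode the generative assumptions the downstream analyses rely
#' on: multiple TSSs per start cluster within 60 bp, a pyrimidine-purine
#' initiator hierarchy (CA > TA > TG > CG), AT-dependent melting around the
#' start site, promoter-proximal pausing 20-60 bp downstream of the TSS on a
#' C base after a G-rich stretch, tethering of the pause to the
#' pre-initiation complex, and reciprocal-cross allelic effects.
#'
#' @param seed Integer seed; every stage of the simulator derives its RNG
#'   state deterministically from it.
#' @param n_loci Number of transcribed loci to plant.
#' @param contig_length Contig length in bp; if `NULL`, sized from `n_loci`.
#' @param snp_density,indel_density Background variant densities per bp.
#' @param max_indel Maximum background/planted indel length (bp).
#' @param mean_tagged_per_tsc Mean allele-informative (tagged) promoter reads
#'   per start cluster per sample.
#' @param tagging_p Probability that a simulated read carries an
#'   allele-informative variant; untagged reads are emitted with
#'   `allele = "untagged"`.
#' @param init_weights Named numeric initiator weights for dinucleotides
#'   CA, TA, TG, CG (rate multipliers at the -1/0 initiator).
#' @param at_alpha Coefficient on the AT fraction of the +/-5 bp window
#'   around the TSS (initiator positions excluded) in the initiation rate.
#' @param pause_w_c,pause_w_g Energy weights for a C at the active site and
#'   per G in the 10 bp upstream (the transcription bubble).
#' @param pause_w_d Distance-tether penalty per bp deviation from the
#'   preferred TSS-to-pause distance (models the physical link between
#'   paused Pol II and the pre-initiation complex).
#' @param pause_window Inclusive offset window (bp downstream of the TSS)
#'   searched for the pause.
#' @param pause_jitter_p Geometric parameter of the symmetric read 3'-end
#'   jitter, truncated to +/-4 bp.
#' @param class_props Named proportions over effect classes
#'   `none, abundance, shape_single, shape_multi, termination, imprinted`.
#' @param abundance_ratio Planted allelic rate ratio for abundance loci.
#' @param imprint_ratio Parent-of-origin rate ratio for imprinted loci.
#' @param shape_single_fold,shape_multi_fold Fold changes for shape effects
#'   (one TSS, or three TSSs, shifted on one allele).
#' @param init_snp_prob Probability that a class-"none" locus carries a
#'   planted initiator SNP at the maxTSS (fuel for the dinucleotide
#'   hierarchy and redistribution analyses).
#' @param init_snp_n_tss Range of TSSs per initiator-SNP locus. The default
#'   (3-5) feeds the redistribution analysis; hierarchy-recovery designs use
#'   `c(1, 1)` so the planted SNP site is the maxTSS by construction.
#' @param pause_csnp_prob,pause_indel_prob Probabilities that a
#'   class-"none" locus carries a planted active-site C SNP, or a planted
#'   indel between TSS and pause.
#' @param redistribute_initiation If `TRUE`, initiation lost at a weakened
#'   initiator is redistributed to member TSSs within +/-20 bp, conserving
#'   the locus total (local search model of start-site selection).
#' @param organs Character vector of organ labels.
#' @param n_reps Biological replicates per organ x cross.
#' @param gb_read_density Mean gene-body reads per kb per sample at
#'   relative expression 1.
#' @param unit_length_range Range of transcription-unit lengths (bp).
#' @param termination_frac_range Planted allelic termination extension as a
#'   fraction of unit length (long allele transcribes further).
#' @param structure_change_prob Probability that a termination locus also
#'   changes mature-mRNA primary structure (novel 3' exon on the long
#'   allele).
#' @param stability_base_sd,stability_coupling_sd SD of log2 allelic
#'   stability ratios for unflagged vs structure-changed loci.
#' @param mrna_depth Mean mRNA reads per kb of exon at relative
#'   expression 1.
#' @param overdispersion If > 0, counts are drawn negative-binomial with
#'   this dispersion instead of Poisson.
#' @param promoter_only If `TRUE`, units are short and gene-body coverage
#'   minimal (fast promoter-focused simulations).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 60L,
                       contig_length = NULL,
                       snp_density = 1 / 150,
                       indel_density = 1 / 1200,
                       max_indel = 10L,
                       mean_tagged_per_tsc = 40,
                       tagging_p = 0.25,
                       init_weights = c(CA = 1, TA = 0.5, TG = 0.25, CG = 0.1),
                       at_alpha = 0.5,
                       pause_w_c = 2,
                       pause_w_g = 0.1,
                       pause_w_d = 0.5,
                       pause_window = c(20L, 60L),
                       pause_jitter_p = 0.5,
                       class_props = c(none = 0.40, abundance = 0.15,
                                       shape_single = 0.10, shape_multi = 0.10,
                                       termination = 0.15, imprinted = 0.10),
                       abundance_ratio = 3,
                       imprint_ratio = 4,
                       shape_single_fold = 4,
                       shape_multi_fold = 2,
                       init_snp_prob = 0.35,
                       init_snp_n_tss = c(3L, 5L),
                       pause_csnp_prob = 0.2,
                       pause_indel_prob = 0.2,
                       redistribute_initiation = FALSE,
                       organs = "organ1",
                       n_reps = 2L,
                       gb_read_density = 1.0,
                       unit_length_range = c(8000L, 15000L),
                       termination_frac_range = c(0.15, 0.45),
                       structure_change_prob = 0.5,
                       stability_base_sd = 0.15,
                       stability_coupling_sd = 0.8,
                       mrna_depth = 100,
                       overdispersion = 0,
                       promoter_only = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n_loci >= 1L)
  if (any(init_weights <= 0)) stop("init_weights must be > 0")
  if (tagging_p < 0 || tagging_p > 1) stop("tagging_p must be in [0,1]")
  if (abs(sum(class_props) - 1) > 1e-8) stop("class_props must sum to 1")
  if (pause_window[1] >= pause_window[2]) stop("pause_window must be increasing")
  if (promoter_only) {
    unit_length_range <- c(1500L, 2500L)
    gb_read_density <- min(gb_read_density, 0.2)
  }
  locus_span <- as.integer(ceiling(1.5 * max(unit_length_range)) + 4000L)
  if (is.null(contig_length)) contig_length <- as.integer(n_loci) * locus_span + 10000L
  if (contig_length < 10000L) stop("contig too short: need at least 10 kb")
  if (contig_length < n_loci * locus_span) {
    stop("contig too short for requested loci: need >= n_loci * (max unit length + 4 kb)")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Analysis configuration
#'
#' Thresholds and windows used across the pipeline, with the defaults used
#' throughout: 5-read TSS support, 60 bp cluster merging, abundance/shape FDR
#' 0.10 with a FDR > 0.90 no-change control set, 5 bp profile bins tested in
#' 10 bp bins at FDR 0.05, a TATA scan window of -35..-20 with log-likelihood
#' score threshold 3, +/-20 bp redistribution window, 10-50 bp TSS-pause
#' pairing, 5-read minimum allelic depth with allelic ratio bounds 0.5-2,
#' pause context blocks (-20..-11, -10..-1, +1..+10), termination end rule in
#' the final 10% of the unit with a 50% length cap, a 10 kb mRNA upstream
#' window, 10-read stability minimum, 500 bp gene-body skip, and an HMM
#' switch-probability grid.
#'
#' @param ... Overrides for any default listed above.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    min_tss_reads = 5L,
    tsc_merge_gap = 60L,
    fdr_abundance = 0.10,
    fdr_background = 0.90,
    snp_profile_bin = 5L,
    snp_test_bin = 10L,
    snp_profile_window = 100L,
    enrichment_fdr = 0.05,
    tata_window = c(-35L, -20L),
    tata_threshold = 3,
    shooting_window = 20L,
    pause_pair_window = c(10L, 50L),
    pause_min_allelic_reads = 5L,
    pause_ratio_bounds = c(0.5, 2),
    pause_blocks = list(block1 = c(-20L, -11L), block2 = c(-10L, -1L),
                        block3 = c(1L, 10L)),
    termination_final_frac = 0.10,
    termination_length_cap = 0.50,
    rnaseq_upstream = 10000L,
    stability_min_reads = 10L,
    gene_body_skip = 500L,
    min_gene_length = 10000L,
    hmm_tau_grid = c(1e-5, 1e-4),
    hmm_rho = 0.9,
    hmm_tau = 1e-4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown analysis_config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$fdr_abundance > 0, cfg$fdr_abundance < 1,
            cfg$fdr_background > 0, cfg$fdr_background < 1,
            cfg$pause_pair_window[1] < cfg$pause_pair_window[2])
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose keys are `analysis_config()` fields.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' Write an analysis configuration to YAML
#'
#' @param config An `analysis_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
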