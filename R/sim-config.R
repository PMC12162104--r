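#' Configuration for the synthetic mutagenesis study generator
#'
#' Builds and validates the parameter set for the synthetic-data module.
#' Defaults emulate the statistical structure of a sodium-azide
#' mutagenesis experiment at toy scale: induced SNVs dominated by C>T*
#' (79.1% of the induced spectrum), a CC-context placement bias for
#' forward-strand C>T (and the GG mirror for G>A), 1-bp-dominated induced
#' indels (28.3% of insertions and 36.4% of deletions are 1 bp),
#' parent-vs-reference heterogeneity shared by every line, and landrace
#' standing variation with a 1/i allele-count spectrum and a CpG-leaning
#' substitution spectrum calibrated so that Ts/Tv = 1.74.
#'
#' @param seed Integer seed; every generator call derives its stream
#'   from it, so identical configs give byte-identical outputs.
#' @param genome_length Total genome length in bp across chromosomes.
#' @param n_chromosomes Number of chromosomes (equal lengths).
#' @param gc_fraction GC content of the simulated reference.
#' @param n_mut_lines Number of mutagenized lines.
#' @param mean_induced_snv Poisson mean of induced SNVs per line.
#' @param mean_induced_indel Poisson mean of induced small indels per line.
#' @param spectrum_probs Named length-6 probability vector over the
#'   collapsed substitution classes (see [collapse_spectrum()]) for
#'   induced SNVs; must sum to 1.
#' @param cc_context_enrichment Odds multiplier applied to C-followed-by-C
#'   sites (and the reverse-complement G-preceded-by-G sites) when
#'   placing induced C>T* mutations.
#' @param indel_1bp_fraction_ins,indel_1bp_fraction_del Fraction of
#'   induced insertions / deletions that are exactly 1 bp.
#' @param deletion_fraction Fraction of induced indels that are deletions.
#' @param n_landraces Number of untreated landrace samples (>= 2).
#' @param n_landrace_segsites Number of segregating sites to simulate in
#'   the landrace panel.
#' @param landrace_spectrum_probs Collapsed-class probabilities for
#'   landrace SNPs. The default places 0.40 on C>T* and 0.235 on A>G*
#'   (transitions 0.635, transversions 0.365), giving Ts/Tv
#'   = 0.635/0.365 = 1.74 in expectation.
#' @param cpg_enrichment Odds multiplier for placing landrace C>T*
#'   changes at CpG (C-followed-by-G) sites.
#' @param n_parent_diffs Number of parent-vs-reference heterogeneity
#'   variants.
#' @param mask_fraction Fraction of each chromosome made uncallable.
#' @param n_genes Number of toy gene models stamped onto the genome.
#' @param het_fraction_induced Fraction of induced variants still
#'   heterozygous at sampling (residual heterozygosity after selfing).
#' @param generations Selfing generations used for the spontaneous
#'   variant expectation.
#' @param spont_snv_rate,spont_indel_rate Spontaneous per-site rates fed
#'   to [selfing_expectation()] to set per-line spontaneous Poisson means.
#' @param contaminate_masks If TRUE, variants may be placed inside
#'   uncallable regions (used to exercise the filters).
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_chromosomes = 2L,
                       gc_fraction = 0.44,
                       n_mut_lines = 11L,
                       mean_induced_snv = 200,
                       mean_induced_indel = 45,
                       spectrum_probs = c("A>C*" = 0.0418, "A>G*" = 0.0418,
                                          "A>T*" = 0.0418, "C>A*" = 0.0418,
                                          "C>G*" = 0.0418, "C>T*" = 0.791),
                       cc_context_enrichment = 6,
                       indel_1bp_fraction_ins = 0.283,
                       indel_1bp_fraction_del = 0.364,
                       deletion_fraction = 0.583,
                       n_landraces = 13L,
                       n_landrace_segsites = 5000,
                       landrace_spectrum_probs = c("A>C*" = 0.090, "A>G*" = 0.235,
                                                   "A>T*" = 0.095, "C>A*" = 0.090,
                                                   "C>G*" = 0.090, "C>T*" = 0.400),
                       cpg_enrichment = 6,
                       n_parent_diffs = 500L,
                       mask_fraction = 0.2,
                       n_genes = 30L,
                       het_fraction_induced = 0.03,
                       generations = 7L,
                       spont_snv_rate = 6.53e-9,
                       spont_indel_rate = 0.95e-9,
                       contaminate_masks = FALSE) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_chromosomes = as.integer(n_chromosomes),
              gc_fraction = gc_fraction, n_mut_lines = as.integer(n_mut_lines),
              mean_induced_snv = mean_induced_snv,
              mean_induced_indel = mean_induced_indel,
              spectrum_probs = spectrum_probs,
              cc_context_enrichment = cc_context_enrichment,
              indel_1bp_fraction_ins = indel_1bp_fraction_ins,
              indel_1bp_fraction_del = indel_1bp_fraction_del,
              deletion_fraction = deletion_fraction,
              n_landraces = as.integer(n_landraces),
              n_landrace_segsites = n_landrace_segsites,
              landrace_spectrum_probs = landrace_spectrum_probs,
              cpg_enrichment = cpg_enrichment,
              n_parent_diffs = as.integer(n_parent_diffs),
              mask_fraction = mask_fraction, n_genes = as.integer(n_genes),
              het_fraction_induced = het_fraction_induced,
              generations = as.integer(generations),
              spont_snv_rate = spont_snv_rate,
              spont_indel_rate = spont_indel_rate,
              contaminate_masks = isTRUE(contaminate_masks))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length < 1000) stop("genome_length must be >= 1000")
  props <- c(cfg$gc_fraction, cfg$indel_1bp_fraction_ins,
             cfg$indel_1bp_fraction_del, cfg$deletion_fraction,
             cfg$mask_fraction, cfg$het_fraction_induced)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  for (nm in c("spectrum_probs", "landrace_spectrum_probs")) {
    p <- cfg[[nm]]
    if (length(p) != 6 || !setequal(names(p), SPECTRUM_CLASSES)) {
      stop(nm, " must be a named length-6 vector over the collapsed classes")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be non-negative and sum to 1")
    }
  }
  counts <- c(cfg$n_mut_lines, cfg$mean_induced_snv, cfg$mean_induced_indel,
              cfg$n_landrace_segsites, cfg$n_parent_diffs, cfg$n_genes,
              cfg$generations)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$cc_context_enrichment <= 0 || cfg$cpg_enrichment <= 0) {
    stop("context enrichment multipliers must be positive")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mutagenesis study configuration\n")
  cat(sprintf("  genome: %s bp on %d chromosome(s), GC %.2f, %.0f%% masked\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              x$gc_fraction, 100 * x$mask_fraction))
  cat(sprintf("  %d mutagenized lines: ~%g induced SNVs + ~%g indels each (C>T* = %.1f%%)\n",
              x$n_mut_lines, x$mean_induced_snv, x$mean_induced_indel,
              100 * x$spectrum_probs[["C>T*"]]))
  cat(sprintf("  %d landraces, %g segregating sites; %d parent-vs-reference diffs\n",
              x$n_landraces, x$n_landrace_segsites, x$n_parent_diffs))
  invisible(x)
}
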