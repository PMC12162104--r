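# Shared fixtures, built once per test run.

fx_env <- new.env()

small_cfg <- function(...) {
  sim_config(seed = 42, genome_length = 3e5, n_chromosomes = 2,
             n_genes = 10, n_mut_lines = 11, mean_induced_snv = 60,
             mean_induced_indel = 15, n_parent_diffs = 100,
             n_landrace_segsites = 800, ...)
}

small_study <- function() {
  if (is.null(fx_env$st)) fx_env$st <- simulate_study(small_cfg())
  fx_env$st
}

vkey <- function(d) paste(d$sample, d$chrom, d$pos, d$ref, d$alt)
skey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)

# minimal variant-table constructor for filter tests
mk_var <- function(sample, chrom, pos, ref = "C", alt = "T", gt = "hom_alt",
                   dp = 30L, gq = 99L, ab = NA_real_, qual = 100,
                   support = NA_integer_) {
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             vtype = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                            ifelse(nchar(alt) > nchar(ref), "insertion",
                                   "deletion")),
             length = nchar(alt) - nchar(ref), gt = gt, dp = dp, gq = gq,
             ab = ab, qual = qual, support = support)
}

# single-chromosome genome from a string
mk_genome <- function(..., names_ = NULL) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- if (is.null(names_)) paste0("chr", seq_along(seqs)) else names_
  g
}

# hand-built single-gene model on an explicit genome string
mk_gene <- function(gene_id, chrom, strand, start, end, cds_start, cds_end,
                    phase = NULL) {
  cds <- data.frame(start = cds_start, end = cds_end)
  if (is.null(phase)) {
    lens <- cds$end - cds$start + 1L
    ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    ph <- integer(nrow(cds))
    ph[ord] <- c(0L, cumsum(lens[ord])[-nrow(cds)]) %% 3L
    cds$phase <- ph
  } else {
    cds$phase <- phase
  }
  gene_models(list(list(gene_id = gene_id, chrom = chrom, strand = strand,
                        start = start, end = end, cds = cds)))
}
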