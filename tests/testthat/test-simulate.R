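# Synthetic-data generator: config validation, reference and masks,
# gene models, variant placement, truth-table completeness, determinism.

test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(genome_length = 500), "genome_length")
  expect_error(sim_config(gc_fraction = 1.2), "proportions")
  bad <- c("A>C*" = 0.5, "A>G*" = 0.2, "A>T*" = 0.2, "C>A*" = 0.2,
           "C>G*" = 0.0, "C>T*" = 0.0)
  expect_error(sim_config(spectrum_probs = bad), "sum to 1")
  expect_error(sim_config(mean_induced_snv = -5), "counts")
})

test_that("reference masks hit the requested uncallable fraction", {
  cfg <- sim_config(seed = 5, genome_length = 1e6, n_chromosomes = 1,
                    mask_fraction = 0.25, n_genes = 0)
  ref <- sim_reference(cfg)
  unc <- ref$masks[ref$masks$label != "low_complexity", ]
  frac <- sum(unc$end - unc$start) / 1e6
  expect_lt(abs(frac - 0.25), 0.02)
  # callable + uncallable partition the chromosome
  expect_equal(attr(build_callable_mask(ref$masks, ref$genome), "callable_bp"),
               1e6 - sum(unc$end - unc$start))
})

test_that("zero mask fraction leaves the whole genome callable", {
  cfg <- sim_config(seed = 2, genome_length = 5e4, mask_fraction = 0,
                    n_genes = 0)
  ref <- sim_reference(cfg)
  expect_equal(nrow(ref$masks), 0)
  expect_equal(attr(ref$callable, "callable_bp"), 2 * 25000)
})

test_that("observed GC tracks the configured fraction", {
  cfg <- sim_config(seed = 9, genome_length = 1e6, n_chromosomes = 1,
                    gc_fraction = 0.5, mask_fraction = 0, n_genes = 0)
  ref <- sim_reference(cfg)
  f <- Biostrings::letterFrequency(ref$genome, "GC", as.prob = TRUE)
  expect_gt(f[1], 0.49)
  expect_lt(f[1], 0.51)
})

test_that("identical seeds give byte-identical FASTA, BED and VCF outputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- sim_config(seed = 77, genome_length = 5e4, n_genes = 2,
                    n_mut_lines = 2, mean_induced_snv = 20,
                    mean_induced_indel = 5, n_parent_diffs = 20,
                    n_landrace_segsites = 50)
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("gene models translate cleanly on both strands", {
  st <- small_study()
  strands <- vapply(unclass(st$genes), `[[`, character(1), "strand")
  expect_true(all(c("+", "-") %in% strands))
  for (g in unclass(st$genes)) {
    cds <- gene_cds_seq(g, st$genome)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
    # canonical splice dinucleotides around every intron
    if (nrow(g$cds) > 1) {
      chrom <- as.character(st$genome[[g$chrom]])
      for (e in seq_len(nrow(g$cds) - 1)) {
        intron <- substr(chrom, g$cds$end[e] + 1, g$cds$start[e + 1] - 1)
        if (g$strand == "-") {
          intron <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(intron)))
        }
        expect_equal(substr(intron, 1, 2), "GT")
        expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
      }
    }
  }
})

test_that("zero genes gives an empty annotation set", {
  cfg <- sim_config(seed = 4, genome_length = 5e4, n_genes = 0)
  out <- sim_genes(cfg, sim_reference(cfg))
  expect_length(out$genes, 0)
  expect_equal(nrow(as.data.frame(out$genes)), 0)
})

test_that("parent diffs sit on matching reference bases at distinct positions", {
  cfg <- sim_config(seed = 13, genome_length = 1e6, n_chromosomes = 1,
                    n_parent_diffs = 500, n_genes = 0)
  ref <- sim_reference(cfg)
  pd <- sim_parent_diffs(cfg, ref)
  expect_equal(nrow(pd), 500)
  expect_equal(anyDuplicated(paste(pd$chrom, pd$pos)), 0)
  chrom <- as.character(ref$genome[[1]])
  expect_true(all(substring(chrom, pd$pos, pd$pos) == substr(pd$ref, 1, 1)))
  # zero requested -> empty set
  cfg0 <- sim_config(seed = 13, genome_length = 5e4, n_parent_diffs = 0,
                     n_genes = 0)
  expect_equal(nrow(sim_parent_diffs(cfg0, sim_reference(cfg0))), 0)
})

test_that("induced spectrum and CC placement follow the configuration", {
  st <- small_study()
  tr <- st$truth[st$truth$origin == "induced" & st$truth$vtype == "SNV", ]
  sp <- collapse_spectrum(ref = tr$ref, alt = tr$alt)
  n <- sp$total
  p <- small_cfg()$spectrum_probs[["C>T*"]]
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(sp$fractions[6] - p), 3 * se)
  # with enrichment 1, the +1=C fraction of forward C>T equals the
  # genome-wide conditional frequency of C after a callable C
  cfg <- sim_config(seed = 21, genome_length = 4e5, n_chromosomes = 1,
                    n_mut_lines = 6, mean_induced_snv = 400,
                    mean_induced_indel = 0, n_parent_diffs = 0,
                    n_genes = 0, cc_context_enrichment = 1,
                    het_fraction_induced = 0)
  ref <- sim_reference(cfg)
  ml <- sim_mutant_lines(cfg, ref)
  fwd <- ml$truth[ml$truth$ref == "C" & ml$truth$alt == "T", ]
  chrom <- as.character(ref$genome[[1]])
  nxt <- substring(chrom, fwd$pos + 1, fwd$pos + 1)
  obs <- mean(nxt == "C")
  # independent oracle: dinucleotide count on the same sequence
  km <- count_kmers(ref$genome, 2)
  cond <- km$counts[["CC"]] /
    sum(km$counts[c("CA", "CC", "CG", "CT")])
  se <- sqrt(cond * (1 - cond) / nrow(fwd))
  expect_lt(abs(obs - cond), 3 * se + 0.02)
})

test_that("lines contain only spontaneous/heterogeneity when induced means are zero", {
  cfg <- sim_config(seed = 31, genome_length = 5e4, n_mut_lines = 2,
                    mean_induced_snv = 0, mean_induced_indel = 0,
                    n_parent_diffs = 10, n_genes = 0)
  ref <- sim_reference(cfg)
  ml <- sim_mutant_lines(cfg, ref, sim_parent_diffs(cfg, ref))
  expect_false(any(ml$truth$origin == "induced"))
  expect_true(all(ml$truth$origin %in% c("spontaneous", "heterogeneity")))
})

test_that("truth table and emitted variants are set-equal", {
  st <- small_study()
  expect_setequal(vkey(st$lines), vkey(st$truth))
  # and survives a VCF round trip per line
  d <- withr::local_tempdir()
  s <- unique(st$lines$sample)[1]
  write_vcf(st$lines[st$lines$sample == s, ], st$genome,
            file.path(d, "line.vcf"))
  back <- read_vcf(file.path(d, "line.vcf"))
  expect_setequal(skey(back), skey(st$truth[st$truth$sample == s, ]))
})

test_that("no variant is placed in uncallable regions unless contamination is on", {
  st <- small_study()
  call_gr <- azidemut:::intervals_to_gr(st$callable)
  for (tab in list(st$parent, st$lines, st$landraces)) {
    gr <- azidemut:::variants_to_gr(tab)
    expect_true(all(IRanges::overlapsAny(gr, call_gr, type = "within")))
  }
  cfg <- sim_config(seed = 8, genome_length = 2e5, n_chromosomes = 1,
                    mask_fraction = 0.4, n_mut_lines = 2,
                    mean_induced_snv = 300, mean_induced_indel = 0,
                    n_parent_diffs = 0, n_genes = 0, contaminate_masks = TRUE)
  ref <- sim_reference(cfg)
  ml <- sim_mutant_lines(cfg, ref)
  unc <- azidemut:::intervals_to_gr(ref$masks)
  hit <- IRanges::overlapsAny(azidemut:::variants_to_gr(ml$variants), unc)
  expect_gt(sum(hit), 0)
})

test_that("landrace allele counts follow the 1/i spectrum", {
  cfg <- sim_config(seed = 15, genome_length = 1e6, n_chromosomes = 1,
                    n_landrace_segsites = 10000, n_genes = 0)
  ref <- sim_reference(cfg)
  lr <- sim_landraces(cfg, ref)
  expect_equal(nrow(lr$sites), 10000)
  n_hap <- 2 * cfg$n_landraces
  p1 <- 1 / sum(1 / seq_len(n_hap - 1))
  obs <- mean(lr$sites$allele_count == 1)
  se <- sqrt(p1 * (1 - p1) / 10000)
  expect_lt(abs(obs - p1), 3 * se)
  # both strata populated
  lab <- classify_rare_common(lr$variants)
  expect_gt(sum(lab$label == "rare"), 0)
  expect_gt(sum(lab$label == "common"), 0)
})

test_that("degenerate landrace configurations behave", {
  cfg <- sim_config(seed = 3, genome_length = 5e4, n_landrace_segsites = 0,
                    n_genes = 0)
  ref <- sim_reference(cfg)
  expect_equal(nrow(sim_landraces(cfg, ref)$variants), 0)
  cfg2 <- sim_config(seed = 3, genome_length = 5e4, n_landraces = 1,
                     n_genes = 0)
  expect_error(sim_landraces(cfg2, sim_reference(cfg2)), "n_landraces")
})
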