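# Consequence classification against hand-built gene models, the CC/GG
# codon motif flag, amino-acid tables, Bonferroni labels, and load
# summaries.

# chr1 carries a single-exon plus-strand gene with CDS
# ATG GGA CAA CCT TGC TAA at positions 21-38
plus_gene_fixture <- function() {
  cds <- "ATGGGACAACCTTGCTAA"
  chr1 <- paste0(strrep("A", 20), cds, strrep("A", 6000 - 20 - nchar(cds)))
  genome <- mk_genome(chr1)
  genes <- mk_gene("g1", "chr1", "+", 21, 38, 21, 38)
  list(genome = genome, genes = genes)
}

test_that("coding SNVs get codon-accurate consequences", {
  fx <- plus_gene_fixture()
  v <- rbind(
    mk_var("s", "chr1", 25, ref = "G", alt = "A"),   # GGA -> GAA missense G/E
    mk_var("s", "chr1", 27, ref = "C", alt = "T"),   # CAA -> TAA stop gained
    mk_var("s", "chr1", 32, ref = "T", alt = "A"),   # CCT -> CCA synonymous
    mk_var("s", "chr1", 22, ref = "T", alt = "C"),   # ATG -> ACG start lost
    mk_var("s", "chr1", 36, ref = "T", alt = "C"),   # TAA -> CAA stop lost
    mk_var("s", "chr1", 30, ref = "CCT", alt = "C"), # 2-bp deletion in CDS
    mk_var("s", "chr1", 10),                         # upstream
    mk_var("s", "chr1", 45),                         # downstream
    mk_var("s", "chr1", 5900))                       # beyond the 5 kb flank
  ann <- classify_effects(v, fx$genes, fx$genome)
  expect_equal(as.character(ann$consequence),
               c("missense", "stop_gained", "synonymous", "start_lost",
                 "stop_lost", "frameshift", "upstream", "downstream",
                 "intergenic"))
  expect_equal(ann$aa_change[1], "G/E")
  expect_equal(ann$ref_codon[2], "CAA")
  expect_equal(ann$alt_codon[2], "TAA")
  # consequence partition: one class per variant
  expect_equal(sum(table(ann$consequence)), nrow(v))
})

test_that("in-frame indels and CDS validation are handled", {
  fx <- plus_gene_fixture()
  v <- mk_var("s", "chr1", 30, ref = "CCTT", alt = "C")  # 3-bp deletion
  ann <- classify_effects(v, fx$genes, fx$genome)
  expect_equal(as.character(ann$consequence), "inframe_indel")
  bad <- mk_gene("gbad", "chr1", "+", 21, 24, 21, 24)
  expect_error(classify_effects(v, bad, fx$genome), "multiple of 3")
})

test_that("splice dinucleotides outrank intron calls", {
  # two-exon gene: exon1 11-19 (ATGGGACCT), intron 20-31 (GT...AG),
  # exon2 32-37 (TGCTAA)
  chr <- paste0(strrep("A", 10), "ATGGGACCT", "GTAAAAAAAAAG", "TGCTAA",
                strrep("A", 100))
  genome <- mk_genome(chr)
  genes <- mk_gene("g2", "chr1", "+", 11, 37, c(11, 32), c(19, 37))
  v <- rbind(mk_var("s", "chr1", 20, ref = "G", alt = "A"),
             mk_var("s", "chr1", 31, ref = "G", alt = "C"),
             mk_var("s", "chr1", 25))
  ann <- classify_effects(v, genes, genome)
  expect_equal(as.character(ann$consequence),
               c("splice_donor", "splice_acceptor", "intron"))
})

test_that("a minus-strand mirror of a gene yields identical calls", {
  fx <- plus_gene_fixture()
  L <- Biostrings::width(fx$genome)[1]
  rc <- Biostrings::reverseComplement(fx$genome[[1]])
  genome_rc <- mk_genome(as.character(rc))
  genes_rc <- mk_gene("g1rc", "chr1", "-", L - 38 + 1, L - 21 + 1,
                      L - 38 + 1, L - 21 + 1)
  v_plus <- rbind(mk_var("s", "chr1", 25, ref = "G", alt = "A"),
                  mk_var("s", "chr1", 27, ref = "C", alt = "T"),
                  mk_var("s", "chr1", 32, ref = "T", alt = "A"))
  v_minus <- v_plus
  v_minus$pos <- L - v_plus$pos + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_minus$ref <- unname(comp[v_plus$ref])
  v_minus$alt <- unname(comp[v_plus$alt])
  a_plus <- classify_effects(v_plus, fx$genes, fx$genome)
  a_minus <- classify_effects(v_minus, genes_rc, genome_rc)
  expect_equal(as.character(a_minus$consequence),
               as.character(a_plus$consequence))
  expect_equal(a_minus$aa_change, a_plus$aa_change)
})

test_that("CC/GG codon motif flag follows the forward-strand rule", {
  g <- mk_genome("ACCATGGA")
  v <- rbind(mk_var("s", "chr1", 2, ref = "C", alt = "T"),  # C followed by C
             mk_var("s", "chr1", 3, ref = "C", alt = "T"),  # C followed by A
             mk_var("s", "chr1", 7, ref = "G", alt = "A"))  # G preceded by G
  expect_equal(cc_motif_in_codon(v, g), c(TRUE, FALSE, TRUE))
  edge <- mk_var("s", "chr1", 1, ref = "C", alt = "T")
  expect_warning(flag <- cc_motif_in_codon(edge, mk_genome("C")), "edge")
  expect_false(flag)
})

test_that("amino-acid table reproduces printed percentages by truncation", {
  del <- c(rep("G/D", 22), rep("P/S", 20), rep("A/T", 19), rep("A/V", 10),
           rep(sprintf("X%02d/Y", 1:28), each = 3))
  tol <- c(rep("A/T", 40), rep("A/V", 33), rep("G/D", 23), rep("P/S", 23),
           rep(sprintf("Q%02d/R", 1:79), each = 2))
  ann <- data.frame(aa_change = c(del, tol),
                    label = rep(c("deleterious", "tolerated"),
                                c(length(del), length(tol))))
  tab <- amino_acid_change_table(ann)
  pick <- function(lab, ch) tab$pct[tab$label == lab & tab$aa_change == ch]
  expect_equal(pick("deleterious", "G/D"), 14.19)
  expect_equal(pick("deleterious", "P/S"), 12.90)
  expect_equal(pick("deleterious", "A/T"), 12.25)
  expect_equal(pick("deleterious", "A/V"), 6.45)
  expect_equal(pick("tolerated", "A/T"), 14.44)
  expect_equal(pick("tolerated", "A/V"), 11.91)
  expect_equal(pick("tolerated", "G/D"), 8.30)
  expect_equal(pick("tolerated", "P/S"), 8.30)
  # full-precision percentages conserve mass within each stratum
  for (lab in c("deleterious", "tolerated")) {
    expect_equal(sum(tab$pct_exact[tab$label == lab]), 100, tolerance = 1e-9)
  }
  # counts are ranked descending within stratum
  expect_equal(tab$count[tab$label == "deleterious"][1], 22L)
  # single change -> 100%
  one <- amino_acid_change_table(data.frame(aa_change = "A/T"))
  expect_equal(one$pct_exact, 100)
})

test_that("Bonferroni thresholds truncate at two significant digits", {
  expect_equal(as.numeric(bonferroni_threshold(611)), 8.1e-5)
  expect_equal(as.numeric(bonferroni_threshold(9716)), 5.1e-6)
  expect_equal(as.numeric(bonferroni_threshold(14537)), 3.4e-6)
  expect_equal(as.numeric(bonferroni_threshold(1)), 5.0e-2)
  expect_equal(attr(bonferroni_threshold(611), "exact"), 0.05 / 611)
  # strictly decreasing in the number of tests
  ns <- c(1, 10, 100, 611, 9716, 14537)
  th <- vapply(ns, function(n) attr(bonferroni_threshold(n), "exact"),
               numeric(1))
  expect_true(all(diff(th) < 0))
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("constraint labels need both the p-value and auxiliary criteria", {
  th <- bonferroni_threshold(611)
  calls <- data.frame(p = c(as.numeric(th), 1e-9, 1e-9, NA),
                      n_seqs = c(20, 20, 5, 20),
                      allele_novel = c(TRUE, TRUE, TRUE, TRUE))
  out <- label_constraint(calls, th)
  expect_equal(out$calls$label, c("tolerated", "deleterious", "tolerated", NA))
  expect_equal(out$n_skipped, 1)
  # a planted deleterious fraction is recovered exactly
  n <- 1000
  planted <- data.frame(p = c(rep(1e-9, 179), rep(0.5, n - 179)))
  expect_equal(label_constraint(planted, th)$fraction_deleterious, 0.179)
})

test_that("load windows divide counts by covered codons", {
  genome <- mk_genome(strrep("A", 20000))
  genes <- mk_gene("g", "chr1", "+", 1001, 4000, 1001, 4000)
  ann <- data.frame(chrom = "chr1", pos = c(1500, 2500, 3000),
                    label = c("deleterious", "deleterious", "tolerated"))
  w <- load_windows(ann, genes, genome, window_bp = 5000)
  expect_equal(w$codons[1], 1000)
  expect_equal(w$del_per_codon[1], 0.002)
  expect_equal(w$tol_per_codon[1], 0.001)
  expect_true(is.na(w$del_per_codon[2]))
  # anchor shift permutes windows but conserves totals
  w2 <- load_windows(ann, genes, genome, window_bp = 5000, anchor = 2500)
  expect_equal(sum(w2$n_deleterious), sum(w$n_deleterious))
  expect_equal(sum(w2$n_tolerated), sum(w$n_tolerated))
  # no annotations -> all zero counts
  w0 <- load_windows(ann[0, ], genes, genome, window_bp = 5000)
  expect_true(all(w0$n_deleterious == 0))
})

test_that("per-sample load summary counts nonsynonymous classes", {
  ann <- data.frame(sample = c("a", "a", "a", "b"),
                    consequence = factor(c("missense", "synonymous",
                                           "stop_gained", "intron"),
                                         levels = azidemut:::CONSEQUENCE_LEVELS),
                    label = c("deleterious", NA, "tolerated", NA))
  ls <- load_summary(ann)
  expect_equal(ls$nonsyn, c(2L, 0L))
  expect_equal(ls$syn, c(1L, 0L))
  expect_equal(ls$ratio_nsyn_syn[1], 2)
  expect_true(is.na(ls$ratio_nsyn_syn[2]))
  expect_equal(ls$deleterious[1], 1L)
})

test_that("load-phenotype correlations behave at the extremes", {
  x <- 1:10
  expect_equal(correlate_load_phenotype(x, rev(x))$estimate, -1)
  expect_equal(correlate_load_phenotype(x, x)$estimate, 1)
  expect_warning(r <- correlate_load_phenotype(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r$estimate))
  expect_error(correlate_load_phenotype(1:2, 2:1), "at least 3")
  set.seed(33)
  n <- 200
  a <- stats::rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * stats::rnorm(n)
  est <- correlate_load_phenotype(a, b, method = "linear")$estimate
  expect_lt(abs(est - 0.6), 3 / sqrt(n - 3))
})
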