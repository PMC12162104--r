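# De novo isolation filters: interval arithmetic, hard thresholds,
# window/privacy/panel/SV rules, and the assembled pipeline.

test_that("callable mask is the complement of merged uncallable intervals", {
  g <- mk_genome(strrep("A", 200))
  expect_equal(build_callable_mask(
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character()), g)$start, 0)
  masks <- data.frame(chrom = "chr1", start = c(0, 50), end = c(100, 150),
                      label = "repeat")
  cal <- build_callable_mask(masks, g)
  expect_equal(cal[, c("start", "end")], data.frame(start = 150, end = 200))
  expect_equal(attr(cal, "callable_bp"), 50)
  # low-complexity flag can only shrink the callable set
  masks2 <- rbind(masks, data.frame(chrom = "chr1", start = 160, end = 170,
                                    label = "low_complexity"))
  strict <- build_callable_mask(masks2, g, exclude_low_complexity = TRUE)
  loose <- build_callable_mask(masks2, g)
  expect_lte(attr(strict, "callable_bp"), attr(loose, "callable_bp"))
  expect_error(build_callable_mask(
    data.frame(chrom = "chr1", start = 150, end = 300, label = "repeat"), g),
    "bounds")
})

test_that("hard filters apply site and genotype thresholds", {
  # QUAL below 30 removes the site
  v <- mk_var("s1", "chr1", 100, qual = 29)
  expect_equal(nrow(hard_filter_snps(v)$variants), 0)
  # perfectly balanced het passes; deviation beyond 0.1 invalidates
  v2 <- rbind(mk_var("s1", "chr1", 100, gt = "het", ab = 0.5),
              mk_var("s2", "chr1", 200, gt = "het", ab = 0.35))
  out <- hard_filter_snps(v2, n_samples = 20)$variants
  expect_equal(out$pos, 100L)
  # per-sample DP bounds invalidate the genotype
  v3 <- rbind(mk_var("s1", "chr1", 100, dp = 4L),
              mk_var("s2", "chr1", 100, dp = 200L),
              mk_var("s3", "chr1", 100, dp = 30L))
  expect_equal(hard_filter_snps(v3, n_samples = 20)$variants$sample, "s3")
  # invalidated genotypes count toward site missingness
  many <- do.call(rbind, lapply(1:10, function(i)
    mk_var(sprintf("s%02d", i), "chr1", 100,
           dp = if (i <= 4) 2L else 30L)))
  expect_equal(nrow(hard_filter_snps(many, n_samples = 10)$variants), 0)
  # het-proportion rule uses the cohort denominator
  het11 <- mk_var("s1", "chr1", 100, gt = "het", ab = 0.5)
  expect_equal(nrow(hard_filter_snps(het11, n_samples = 11)$variants), 1)
  expect_equal(nrow(hard_filter_snps(het11, n_samples = 5)$variants), 0)
})

test_that("diversity windows are tumbling and drop overloaded windows", {
  v <- mk_var(rep("s1", 3), "chr1", c(10, 40, 90))
  expect_equal(nrow(diversity_window_filter(v)$variants), 0)
  v2 <- mk_var(rep("s1", 2), "chr1", c(10, 40))
  expect_equal(nrow(diversity_window_filter(v2)$variants), 2)
  # 99 and 101 fall in different windows
  v3 <- mk_var(rep("s1", 4), "chr1", c(99, 101, 150, 180))
  out <- diversity_window_filter(v3)$variants
  expect_equal(sort(out$pos), c(99L))
})

test_that("parent-difference subtraction removes intersecting spans", {
  line <- mk_var("m1", "chr1", 500)
  parent <- mk_var("parent", "chr1", 500)
  expect_equal(nrow(subtract_reference_differences(line, parent)$variants), 0)
  # identity with empty parent set and no regions
  expect_equal(subtract_reference_differences(line, parent[0, ])$variants,
               line)
  # 50-bp deletion overlapping a diff region by one base is removed
  del <- mk_var("m1", "chr1", 1000, ref = strrep("A", 51), alt = "A")
  region <- data.frame(chrom = "chr1", start = 1049, end = 1100,
                       label = "reference-difference")
  expect_equal(nrow(subtract_reference_differences(
    del, parent[0, ], region)$variants), 0)
  region2 <- data.frame(chrom = "chr1", start = 1050, end = 1100,
                        label = "reference-difference")
  expect_equal(nrow(subtract_reference_differences(
    del, parent[0, ], region2)$variants), 1)
})

test_that("privacy keeps alleles carried by exactly one line", {
  v <- rbind(mk_var("m1", "chr1", 100), mk_var("m2", "chr1", 100),
             mk_var("m3", "chr1", 200))
  out <- privacy_filter(v)$variants
  expect_equal(out$sample, "m3")
  # different alt alleles at one position are independent events
  v2 <- rbind(mk_var("m1", "chr1", 100, alt = "T"),
              mk_var("m2", "chr1", 100, alt = "G"))
  expect_equal(nrow(privacy_filter(v2)$variants), 2)
  expect_warning(privacy_filter(mk_var("m1", "chr1", 100)), "single-line")
})

test_that("panel exclusion matches anchor positions only", {
  panel <- data.frame(chrom = "chr1", pos = 100L)
  expect_equal(nrow(panel_exclusion(mk_var("m1", "chr1", 100),
                                    panel)$variants), 0)
  v <- mk_var("m1", "chr1", 300)
  expect_equal(panel_exclusion(v, panel[0, ])$variants, v)
  # deletion spanning the panel position but anchored at 98 is kept
  del <- mk_var("m1", "chr1", 98, ref = "AAAAA", alt = "A")
  expect_equal(nrow(panel_exclusion(del, panel)$variants), 1)
})

test_that("SV support and mask rules apply to supported records only", {
  svs <- rbind(mk_var("m1", "chr1", 100, ref = "A", alt = strrep("A", 60),
                      support = 4L),
               mk_var("m1", "chr1", 200, ref = "A", alt = strrep("A", 60),
                      support = 5L))
  out <- sv_support_filter(svs)$variants
  expect_equal(out$pos, 200L)
  masks <- data.frame(chrom = "chr1", start = 190, end = 260,
                      label = "repeat")
  expect_equal(nrow(sv_support_filter(svs, masks = masks)$variants), 0)
  # records without support values pass untouched
  plain <- mk_var("m1", "chr1", 195)
  expect_equal(nrow(sv_support_filter(plain, masks = masks)$variants), 1)
})

test_that("rare/common labels follow diploid allele counts", {
  v <- rbind(mk_var("a", "chr1", 10, gt = "het"),
             mk_var("a", "chr1", 20, gt = "hom_alt"),
             mk_var("a", "chr1", 30, gt = "hom_alt"),
             mk_var("b", "chr1", 30, gt = "hom_alt"),
             mk_var("a", "chr1", 40, gt = "hom_ref"))
  lab <- classify_rare_common(v)
  expect_equal(lab$label[match(c(10, 20, 30, 40), lab$pos)],
               c("rare", "rare", "common", "invariant"))
  expect_equal(lab$allele_count[match(c(10, 20, 30, 40), lab$pos)],
               c(1L, 2L, 4L, 0L))
})

test_that("every filter is a subset operation and reports conserve counts", {
  st <- small_study()
  res <- run_isolation_pipeline(st$lines, st$parent, st$masks, st$genome,
                                landraces = st$landraces)
  expect_true(all(res$report$input - res$report$removed ==
                    res$report$surviving))
  expect_true(all(vkey(res$lines) %in% vkey(st$lines)))
  # re-running on its own output is a no-op
  res2 <- run_isolation_pipeline(res$lines, res$parent_diffs, st$masks,
                                 st$genome)
  expect_setequal(vkey(res2$lines), vkey(res$lines))
})

test_that("an all-uncallable genome yields zero survivors", {
  st <- small_study()
  lens <- Biostrings::width(st$genome)
  allmask <- data.frame(chrom = names(st$genome), start = 0, end = lens,
                        label = "repeat")
  res <- run_isolation_pipeline(st$lines, st$parent, allmask, st$genome)
  expect_equal(nrow(res$lines), 0)
})

test_that("pipeline recovers induced truth and removes heterogeneity", {
  st <- small_study()
  res <- run_isolation_pipeline(st$lines, st$parent, st$masks, st$genome)
  induced <- st$truth[st$truth$origin == "induced", ]
  sens <- mean(vkey(induced) %in% vkey(res$lines))
  expect_gte(sens, 0.99)
  het <- st$truth[st$truth$origin == "heterogeneity", ]
  expect_equal(sum(vkey(res$lines) %in% vkey(het)), 0)
})
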