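# Interval conventions: interval tables (masks, callable regions) are
# BED-style 0-based half-open; variant positions are VCF-style 1-based
# with the reference span of an indel/SV covering [pos, pos+nchar(ref)-1].
# All overlap logic goes through GenomicRanges.

intervals_to_gr <- function(intervals) {
  if (!nrow(intervals)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end)
  )
}

gr_to_intervals <- function(gr, label = NA_character_) {
  if (!length(gr)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character()))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = label)
}

variants_to_gr <- function(variants) {
  if (!nrow(variants)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos,
                              end = variants$pos + nchar(variants$ref) - 1L)
  )
}

new_filter_report <- function() {
  data.frame(step = character(), input = integer(), removed = integer(),
             surviving = integer())
}

add_report <- function(report, step, input, surviving) {
  rbind(report, data.frame(step = step, input = as.integer(input),
                           removed = as.integer(input - surviving),
                           surviving = as.integer(surviving)))
}

#' Build the callable mask of a genome
#'
#' Callable regions are the per-chromosome complement of the union of
#' the uncallable masks (`repeat`, `nstretch`, `high_copy` labels, plus
#' `low_complexity` when `exclude_low_complexity = TRUE`).
#'
#' @param masks Interval table (`chrom`, `start`, `end`, `label`),
#'   0-based half-open.
#' @param genome [Biostrings::DNAStringSet]; provides chromosome bounds.
#' @param exclude_low_complexity Also subtract `low_complexity` intervals.
#' @return Interval table of callable regions with attribute
#'   `"callable_bp"` (total callable length).
#' @export
build_callable_mask <- function(masks, genome, exclude_low_complexity = FALSE) {
  lens <- Biostrings::width(genome)
  whole <- GenomicRanges::GRanges(names(genome),
                                  IRanges::IRanges(1L, lens))
  if (nrow(masks)) {
    if (any(masks$start < 0) ||
        any(masks$end > lens[match(masks$chrom, names(genome))]) ||
        any(is.na(match(masks$chrom, names(genome))))) {
      stop("mask interval outside chromosome bounds")
    }
    keep <- if (exclude_low_complexity) rep(TRUE, nrow(masks))
            else masks$label != "low_complexity"
    unc <- GenomicRanges::reduce(intervals_to_gr(masks[keep, , drop = FALSE]))
    call_gr <- GenomicRanges::setdiff(whole, unc)
  } else {
    call_gr <- whole
  }
  out <- gr_to_intervals(call_gr, label = "callable")
  attr(out, "callable_bp") <- sum(out$end - out$start)
  out
}

# keep only variants whose full reference span lies inside callable
restrict_to_callable <- function(variants, callable) {
  if (!nrow(variants)) return(variants)
  hits <- IRanges::overlapsAny(variants_to_gr(variants),
                               intervals_to_gr(callable),
                               type = "within")
  variants[hits, , drop = FALSE]
}

#' Hard genotype and site filters
#'
#' Applies the per-sample and per-site hard thresholds used after joint
#' calling. Per-sample failures (depth out of `[min_dp, max_dp]`,
#' genotype quality below `min_gq`, heterozygous allele balance deviating
#' from 0.5 by more than `ab_dev`) invalidate the genotype (set to
#' missing); site-level criteria (QUAL below `min_qual`, proportion of
#' heterozygous genotypes above `max_het_prop`, proportion missing above
#' `max_missing`) then remove the whole site. Proportions use the cohort
#' size as denominator; samples without a row at a site are
#' homozygous-reference, not missing.
#'
#' @param variants Long variant table (possibly several samples).
#' @param thresholds Named list overriding any of `ab_dev` (0.1),
#'   `max_het_prop` (0.1), `min_dp` (5), `max_dp` (158), `max_missing`
#'   (0.30), `min_qual` (30), `min_gq` (9). A linked-read profile would
#'   use `min_dp = 5, max_dp = 78, ab_dev = 0.2`.
#' @param n_samples Cohort size; defaults to the number of distinct
#'   samples present in `variants`.
#' @return List with `variants` (surviving calls) and `report`.
#' @export
hard_filter_snps <- function(variants, thresholds = list(), n_samples = NULL) {
  th <- utils::modifyList(list(ab_dev = 0.1, max_het_prop = 0.1,
                               min_dp = 5, max_dp = 158, max_missing = 0.30,
                               min_qual = 30, min_gq = 9), thresholds)
  report <- new_filter_report()
  n_in <- nrow(variants)
  if (!n_in) {
    return(list(variants = variants,
                report = add_report(report, "hard_filters", 0, 0)))
  }
  if (is.null(n_samples)) n_samples <- length(unique(variants$sample))

  bad_call <- (!is.na(variants$dp) &
                 (variants$dp < th$min_dp | variants$dp > th$max_dp)) |
              (!is.na(variants$gq) & variants$gq < th$min_gq) |
              (variants$gt == "het" & !is.na(variants$ab) &
                 abs(variants$ab - 0.5) > th$ab_dev)
  kept <- variants[!bad_call, , drop = FALSE]
  n_missing_new <- tapply(bad_call, paste(variants$chrom, variants$pos,
                                          variants$ref, variants$alt,
                                          sep = "\r"), sum)

  key <- paste(kept$chrom, kept$pos, kept$ref, kept$alt, sep = "\r")
  n_het <- tapply(kept$gt == "het", key, sum)
  site_missing <- n_missing_new[names(n_het)]
  site_missing[is.na(site_missing)] <- 0
  qual <- tapply(kept$qual, key, function(q) q[1])
  bad_site <- (!is.na(qual) & qual < th$min_qual) |
              (n_het / n_samples > th$max_het_prop) |
              (site_missing / n_samples > th$max_missing)
  out <- kept[!(key %in% names(bad_site)[bad_site]), , drop = FALSE]
  report <- add_report(report, "hard_filters", n_in, nrow(out))
  list(variants = out, report = report)
}

#' Diversity-window filter
#'
#' Partitions each chromosome into non-overlapping (tumbling) windows of
#' `window_bp` anchored at position 1 and removes every SNV lying in a
#' window containing more than `max_variants` distinct SNV positions
#' (more than 2 SNVs per 100 bp corresponds to >2% diversity, the level
#' implausible for a self-vs-self comparison). Non-SNV rows pass through.
#'
#' @param variants Long variant table.
#' @param window_bp Window width in bp.
#' @param max_variants Maximum distinct SNV positions tolerated per window.
#' @return List with `variants` and `report`.
#' @export
diversity_window_filter <- function(variants, window_bp = 100,
                                    max_variants = 2) {
  n_in <- nrow(variants)
  report <- new_filter_report()
  if (!n_in) {
    return(list(variants = variants,
                report = add_report(report, "diversity_window", 0, 0)))
  }
  is_snv <- variants$vtype == "SNV"
  win <- paste(variants$chrom, (variants$pos - 1L) %/% window_bp, sep = "\r")
  n_pos <- tapply(variants$pos[is_snv], win[is_snv],
                  function(p) length(unique(p)))
  bad_win <- names(n_pos)[n_pos > max_variants]
  drop <- is_snv & win %in% bad_win
  out <- variants[!drop, , drop = FALSE]
  list(variants = out,
       report = add_report(report, "diversity_window", n_in, nrow(out)))
}

#' Subtract parent-vs-reference differences
#'
#' Removes any line variant whose reference span intersects the span of
#' a parent variant or a supplied difference region. These positions are
#' heterogeneity between the mutagenized seed stock and the reference,
#' not induced mutations.
#'
#' @param line_variants Long variant table for the mutagenized lines.
#' @param parent_variants Parent variant table (already filtered).
#' @param diff_regions Optional interval table of additional
#'   difference-from-reference regions (0-based half-open).
#' @return List with `variants` and `report`.
#' @export
subtract_reference_differences <- function(line_variants, parent_variants,
                                           diff_regions = NULL) {
  n_in <- nrow(line_variants)
  report <- new_filter_report()
  if (!n_in) {
    return(list(variants = line_variants,
                report = add_report(report, "subtract_parent_diffs", 0, 0)))
  }
  diff_gr <- variants_to_gr(parent_variants)
  if (!is.null(diff_regions) && nrow(diff_regions)) {
    diff_gr <- c(diff_gr, intervals_to_gr(diff_regions))
  }
  hit <- IRanges::overlapsAny(variants_to_gr(line_variants), diff_gr)
  out <- line_variants[!hit, , drop = FALSE]
  list(variants = out,
       report = add_report(report, "subtract_parent_diffs", n_in, nrow(out)))
}

#' Privacy filter
#'
#' Keeps a variant only when its (chrom, pos, ref, alt) key is carried by
#' exactly one sample of the cohort. Induced mutations arise after
#' treatment and should be unique to a line; shared variants reflect
#' heterogeneity. Two lines carrying different alternate alleles at the
#' same position are independent events and both survive.
#'
#' @param variants Long variant table for >= 2 lines (a single-line
#'   cohort is returned unchanged with a warning).
#' @return List with `variants` and `report`.
#' @export
privacy_filter <- function(variants) {
  n_in <- nrow(variants)
  report <- new_filter_report()
  if (!n_in) {
    return(list(variants = variants,
                report = add_report(report, "privacy", 0, 0)))
  }
  if (length(unique(variants$sample)) < 2) {
    warning("privacy filter applied to a single-line cohort; all variants retained")
    return(list(variants = variants,
                report = add_report(report, "privacy", n_in, n_in)))
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  n_carriers <- tapply(variants$sample, key,
                       function(s) length(unique(s)))
  out <- variants[n_carriers[key] == 1, , drop = FALSE]
  list(variants = out,
       report = add_report(report, "privacy", n_in, nrow(out)))
}

#' Genotyping-panel exclusion
#'
#' Removes variants whose anchor position exactly matches a known
#' genotyping-panel position (assay-designed sites are standing
#' variation, not induced mutations). An indel spanning a panel position
#' but anchored elsewhere is kept.
#'
#' @param variants Long variant table.
#' @param panel Data frame with `chrom` and `pos` (1-based).
#' @return List with `variants` and `report`.
#' @export
panel_exclusion <- function(variants, panel) {
  n_in <- nrow(variants)
  report <- new_filter_report()
  if (!n_in || is.null(panel) || !nrow(panel)) {
    return(list(variants = variants,
                report = add_report(report, "panel_exclusion", n_in, n_in)))
  }
  hit <- paste(variants$chrom, variants$pos) %in% paste(panel$chrom, panel$pos)
  out <- variants[!hit, , drop = FALSE]
  list(variants = out,
       report = add_report(report, "panel_exclusion", n_in, nrow(out)))
}

#' Structural-variant read-support filter
#'
#' Keeps SVs with at least `min_support` supporting reads and drops SVs
#' overlapping uncallable (and low-complexity) masks.
#'
#' @param svs Long variant table with a `support` column.
#' @param min_support Minimum supporting reads.
#' @param masks Optional interval table of uncallable/low-complexity
#'   regions.
#' @return List with `variants` and `report`.
#' @export
sv_support_filter <- function(svs, min_support = 5, masks = NULL) {
  n_in <- nrow(svs)
  report <- new_filter_report()
  if (!n_in) {
    return(list(variants = svs,
                report = add_report(report, "sv_support", 0, 0)))
  }
  is_sv <- !is.na(svs$support)
  keep <- !is_sv | svs$support >= min_support
  if (!is.null(masks) && nrow(masks)) {
    keep <- keep & (!is_sv | !IRanges::overlapsAny(variants_to_gr(svs),
                                                   intervals_to_gr(masks)))
  }
  out <- svs[keep, , drop = FALSE]
  list(variants = out,
       report = add_report(report, "sv_support", n_in, nrow(out)))
}

#' Rare/common classification of multi-sample variants
#'
#' Computes the non-reference allele count per site over diploid
#' genotypes (het = 1, hom-alt = 2; missing genotypes excluded) and
#' labels sites `rare` (count <= 2), `common` (count >= 3), or
#' `invariant` (count 0, excluded from both strata).
#'
#' @param variants Long multi-sample variant table.
#' @return Data frame with one row per site: `chrom`, `pos`, `ref`,
#'   `alt`, `allele_count`, `label`.
#' @export
classify_rare_common <- function(variants) {
  if (!nrow(variants)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      allele_count = integer(), label = character()))
  }
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  copies <- ifelse(variants$gt == "hom_alt", 2L,
                   ifelse(variants$gt == "het", 1L, 0L))
  ac <- tapply(copies, key, sum)
  first <- !duplicated(key)
  out <- data.frame(chrom = variants$chrom[first], pos = variants$pos[first],
                    ref = variants$ref[first], alt = variants$alt[first])
  out$allele_count <- as.integer(ac[key[first]])
  out$label <- ifelse(out$allele_count == 0, "invariant",
                      ifelse(out$allele_count <= 2, "rare", "common"))
  out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
}

#' Two-part de novo variant isolation pipeline
#'
#' Executes, in order: callable-region masking (part 1 and 2), hard
#' genotype/site filters (parent, then the line cohort jointly),
#' SV read-support filtering, the diversity-window filter on the parent,
#' subtraction of the surviving parent differences (plus any extra
#' difference regions), genotyping-panel exclusion, the privacy filter,
#' and — when a landrace set is supplied — rare/common classification.
#'
#' @param lines Long variant table of the mutagenized line cohort.
#' @param parent Parent-vs-reference variant table.
#' @param masks Uncallable interval table (0-based half-open, labelled).
#' @param genome [Biostrings::DNAStringSet].
#' @param panel Optional panel positions (`chrom`, `pos`).
#' @param landraces Optional long multi-sample landrace variant table.
#' @param thresholds Passed to [hard_filter_snps()].
#' @param window_bp,max_per_window Passed to [diversity_window_filter()].
#' @param min_support Passed to [sv_support_filter()].
#' @param exclude_low_complexity Use the stricter callable set.
#' @return List with `lines` (surviving per-line de novo calls),
#'   `parent_diffs` (the filtered parent difference set), `callable`,
#'   `report` (audit table over all stages), and `landrace_labels`.
#' @export
run_isolation_pipeline <- function(lines, parent, masks, genome,
                                   panel = NULL, landraces = NULL,
                                   thresholds = list(),
                                   window_bp = 100, max_per_window = 2,
                                   min_support = 5,
                                   exclude_low_complexity = FALSE) {
  callable <- build_callable_mask(masks, genome, exclude_low_complexity)
  report <- new_filter_report()

  # Part 1: the parent difference set
  p <- restrict_to_callable(parent, callable)
  report <- add_report(report, "parent_callable", nrow(parent), nrow(p))
  hf <- hard_filter_snps(p, thresholds, n_samples = 1)
  hf$report$step <- "parent_hard_filters"
  report <- rbind(report, hf$report)
  sv <- sv_support_filter(hf$variants, min_support, masks)
  sv$report$step <- "parent_sv_support"
  report <- rbind(report, sv$report)
  dw <- diversity_window_filter(sv$variants, window_bp, max_per_window)
  dw$report$step <- "parent_diversity_window"
  report <- rbind(report, dw$report)
  parent_diffs <- dw$variants

  # Part 2: the mutagenized lines
  l <- restrict_to_callable(lines, callable)
  report <- add_report(report, "lines_callable", nrow(lines), nrow(l))
  hf2 <- hard_filter_snps(l, thresholds)
  hf2$report$step <- "lines_hard_filters"
  report <- rbind(report, hf2$report)
  sv2 <- sv_support_filter(hf2$variants, min_support, masks)
  sv2$report$step <- "lines_sv_support"
  report <- rbind(report, sv2$report)
  sub <- subtract_reference_differences(sv2$variants, parent_diffs)
  report <- rbind(report, sub$report)
  pe <- panel_exclusion(sub$variants, panel)
  report <- rbind(report, pe$report)
  pv <- privacy_filter(pe$variants)
  report <- rbind(report, pv$report)

  landrace_labels <- if (!is.null(landraces)) {
    classify_rare_common(landraces)
  }
  rownames(report) <- NULL
  list(lines = pv$variants, parent_diffs = parent_diffs,
       callable = callable, report = report,
       landrace_labels = landrace_labels)
}
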