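CONSEQUENCE_LEVELS <- c("splice_donor", "splice_acceptor", "stop_gained",
                        "stop_lost", "start_lost", "frameshift",
                        "inframe_indel", "missense", "synonymous",
                        "intron", "upstream", "downstream", "intergenic")

NONSYN_CLASSES <- c("missense", "start_lost", "stop_gained", "stop_lost")

# per-gene lookup: CDS genomic positions in translation order and the
# coding-strand CDS sequence
gene_cds_map <- function(gene, genome) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    gene$cds$start[i]:gene$cds$end[i]))
  if (gene$strand == "-") pos <- rev(pos)
  list(pos = pos, seq = gene_cds_seq(gene, genome))
}

translate_codon <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

#' Classify variant consequences against gene models
#'
#' Assigns each variant a single consequence by precedence: splice
#' donor/acceptor > stop-gained/stop-lost/start-lost > frameshift/
#' inframe-indel > missense/synonymous > intron > upstream/downstream >
#' intergenic. Minus-strand genes are evaluated on the reverse
#' complement; codon and amino-acid changes are reported on the coding
#' strand. Indels inside CDS are frameshift when their length is not a
#' multiple of 3, otherwise inframe.
#'
#' @param variants Variant table (`chrom`, `pos`, `ref`, `alt`; extra
#'   columns carried through).
#' @param genes A `gene_models` object.
#' @param genome [Biostrings::DNAStringSet] (the stamped genome the gene
#'   models refer to).
#' @param flank_bp Up/downstream flank distance.
#' @return `variants` with added columns `consequence`, `gene_id`,
#'   `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `aa_change` (e.g.
#'   `"G/D"`, NA unless coding SNV), `cc_motif`.
#' @export
classify_effects <- function(variants, genes, genome, flank_bp = 5000) {
  genes <- unclass(genes)
  for (g in genes) {
    len <- sum(g$cds$end - g$cds$start + 1L)
    if (len %% 3 != 0) {
      stop("CDS length of ", g$gene_id, " is not a multiple of 3")
    }
  }
  maps <- lapply(genes, gene_cds_map, genome = genome)
  n <- nrow(variants)
  cons <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  ref_codon <- alt_codon <- ref_aa <- alt_aa <- rep(NA_character_, n)

  rank_of <- function(x) match(x, CONSEQUENCE_LEVELS)
  for (i in seq_len(n)) {
    p <- variants$pos[i]
    pe <- p + nchar(variants$ref[i]) - 1L  # reference span end
    is_snv <- nchar(variants$ref[i]) == 1 && nchar(variants$alt[i]) == 1
    best <- "intergenic"
    best_gene <- NA_character_
    best_detail <- NULL
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      if (g$chrom != variants$chrom[i]) next
      res <- classify_one(variants$ref[i], variants$alt[i], p, pe, is_snv,
                          g, maps[[gi]], flank_bp)
      if (is.null(res)) next
      if (rank_of(res$consequence) < rank_of(best)) {
        best <- res$consequence
        best_gene <- g$gene_id
        best_detail <- res
      }
    }
    cons[i] <- best
    gene_id[i] <- best_gene
    if (!is.null(best_detail$ref_codon)) {
      ref_codon[i] <- best_detail$ref_codon
      alt_codon[i] <- best_detail$alt_codon
      ref_aa[i] <- best_detail$ref_aa
      alt_aa[i] <- best_detail$alt_aa
    }
  }
  out <- variants
  out$consequence <- factor(cons, levels = CONSEQUENCE_LEVELS)
  out$gene_id <- gene_id
  out$ref_codon <- ref_codon
  out$alt_codon <- alt_codon
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$aa_change <- ifelse(is.na(ref_aa), NA_character_,
                          paste(ref_aa, alt_aa, sep = "/"))
  out$cc_motif <- cc_motif_in_codon(out, genome)
  out
}

# consequence of one variant against one gene; NULL if unrelated
classify_one <- function(ref, alt, p, pe, is_snv, g, map, flank_bp) {
  in_span <- pe >= g$start && p <= g$end
  if (!in_span) {
    if (pe >= g$start - flank_bp && p < g$start) {
      side <- if (g$strand == "+") "upstream" else "downstream"
      return(list(consequence = side))
    }
    if (p <= g$end + flank_bp && pe > g$end) {
      side <- if (g$strand == "+") "downstream" else "upstream"
      return(list(consequence = side))
    }
    return(NULL)
  }
  # CDS overlap?
  in_cds <- any(p <= g$cds$end & pe >= g$cds$start)
  if (in_cds) {
    if (!is_snv) {
      len <- nchar(alt) - nchar(ref)
      return(list(consequence = if (len %% 3 != 0) "frameshift"
                  else "inframe_indel"))
    }
    t <- match(p, map$pos)
    if (is.na(t)) return(list(consequence = "intron"))  # should not happen
    ci <- (t - 1L) %/% 3L
    within <- (t - 1L) %% 3L
    codon <- substr(map$seq, 3L * ci + 1L, 3L * ci + 3L)
    base <- if (g$strand == "+") alt else comp_base(alt)
    altc <- codon
    substr(altc, within + 1L, within + 1L) <- base
    raa <- translate_codon(codon)
    aaa <- translate_codon(altc)
    consequence <- if (ci == 0L && raa == "M" && aaa != "M") "start_lost"
      else if (raa == "*" && aaa != "*") "stop_lost"
      else if (aaa == "*" && raa != "*") "stop_gained"
      else if (raa == aaa) "synonymous" else "missense"
    return(list(consequence = consequence, ref_codon = codon,
                alt_codon = altc, ref_aa = raa, alt_aa = aaa))
  }
  # intronic: splice dinucleotides first (strand-aware)
  if (nrow(g$cds) > 1) {
    for (e in seq_len(nrow(g$cds) - 1L)) {
      int_start <- g$cds$end[e] + 1L
      int_end <- g$cds$start[e + 1L] - 1L
      if (pe < int_start || p > int_end) next
      lo2 <- c(int_start, int_start + 1L)
      hi2 <- c(int_end - 1L, int_end)
      donor <- if (g$strand == "+") lo2 else hi2
      acceptor <- if (g$strand == "+") hi2 else lo2
      if (any(p:pe %in% donor)) return(list(consequence = "splice_donor"))
      if (any(p:pe %in% acceptor)) return(list(consequence = "splice_acceptor"))
    }
  }
  list(consequence = "intron")
}

#' Flag coding SNVs whose codon sits in a CC (or GG) mutagen motif
#'
#' TRUE when the reference base at the variant and its immediate 3'
#' neighbor on the forward strand read CC, or the variant base and its
#' immediate 5' neighbor read GG (the reverse-complement motif).
#' Variants at a sequence edge return FALSE with a warning.
#'
#' @param variants Variant table (`chrom`, `pos`).
#' @param genome [Biostrings::DNAStringSet].
#' @return Logical vector.
#' @export
cc_motif_in_codon <- function(variants, genome) {
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  n <- nrow(variants)
  out <- logical(n)
  edge <- FALSE
  for (i in seq_len(n)) {
    cs <- chars[[variants$chrom[i]]]
    p <- variants$pos[i]
    if (p < 1 || p > length(cs)) next
    b <- cs[p]
    nxt <- if (p < length(cs)) cs[p + 1L] else { edge <- TRUE; "X" }
    prv <- if (p > 1) cs[p - 1L] else { edge <- TRUE; "X" }
    out[i] <- (b == "C" && nxt == "C") || (b == "G" && prv == "G")
  }
  if (edge) warning("variant at sequence edge; motif flag set to FALSE")
  out
}

# truncate toward zero at `digits` decimals (guarding float representation)
trunc_decimal <- function(x, digits = 2) {
  trunc(x * 10^digits + 1e-9) / 10^digits
}

#' Ranked amino-acid-change table
#'
#' Tabulates amino-acid changes (e.g. `"G/D"`), optionally stratified by
#' constraint label and variant stratum, with per-stratum percentages.
#' The displayed percentage column is truncated toward zero at two
#' decimals (the convention of the published tables); `pct_exact` keeps
#' full precision and sums to 100 within each stratum.
#'
#' @param annotations Data frame with `aa_change` and optionally `label`
#'   and/or `stratum` columns; rows with missing `aa_change` are dropped.
#' @return Data frame with grouping columns, `aa_change`, `count`, `pct`
#'   (truncated display), `pct_exact`, sorted by descending count within
#'   group.
#' @export
amino_acid_change_table <- function(annotations) {
  df <- annotations[!is.na(annotations$aa_change), , drop = FALSE]
  groups <- intersect(c("stratum", "label"), names(df))
  if (!nrow(df)) {
    return(data.frame(aa_change = character(), count = integer(),
                      pct = numeric(), pct_exact = numeric()))
  }
  gkey <- if (length(groups)) {
    interaction(df[groups], drop = TRUE, sep = "\r")
  } else factor(rep("all", nrow(df)))
  out <- do.call(rbind, lapply(levels(gkey), function(lv) {
    sub <- df[gkey == lv, , drop = FALSE]
    tab <- sort(table(sub$aa_change), decreasing = TRUE)
    res <- data.frame(aa_change = names(tab), count = as.integer(tab))
    res$pct_exact <- 100 * res$count / sum(res$count)
    res$pct <- trunc_decimal(res$pct_exact, 2)
    if (length(groups)) {
      for (gcol in rev(groups)) res[[gcol]] <- sub[[gcol]][1]
      res <- res[, c(groups, "aa_change", "count", "pct", "pct_exact")]
    }
    res
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni threshold with two-significant-digit truncation
#'
#' Returns `alpha / n_tests` truncated toward zero at two significant
#' digits — the display convention that reproduces quoted thresholds
#' such as 0.05/611 = 8.18e-5 -> 8.1e-5. The full-precision value is
#' attached as attribute `"exact"`.
#'
#' @param n_tests Number of tests (codons tested); must be >= 1.
#' @param alpha Family-wise error rate.
#' @return Truncated threshold with attribute `exact`.
#' @examples
#' bonferroni_threshold(611)   # 8.1e-5
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  t <- alpha / n_tests
  e <- floor(log10(t))
  m <- t / 10^e
  disp <- (trunc(m * 10 + 1e-9) / 10) * 10^e
  structure(disp, exact = t)
}

#' Label constraint-test calls deleterious or tolerated
#'
#' A variant is deleterious iff its constraint p-value is strictly below
#' the Bonferroni threshold and all auxiliary criteria pass (alignment
#' of at least `min_seqs` sequences; neither allele observed in the
#' other species). Everything else, including boundary p-values, is
#' tolerated. Calls with a missing p-value are skipped and counted.
#'
#' @param calls Data frame with `p` and optionally `n_seqs`,
#'   `allele_novel` (logical; both default to passing when absent).
#' @param threshold P-value threshold (e.g. [bonferroni_threshold()]).
#' @param min_seqs Minimum alignment depth.
#' @return List with `calls` (input plus `label` column), `n_skipped`,
#'   `fraction_deleterious` (among labelled calls).
#' @export
label_constraint <- function(calls, threshold, min_seqs = 10) {
  n_seqs <- calls$n_seqs %||% rep(min_seqs, nrow(calls))
  novel <- calls$allele_novel %||% rep(TRUE, nrow(calls))
  skipped <- is.na(calls$p)
  lab <- ifelse(skipped, NA_character_,
                ifelse(calls$p < as.numeric(threshold) &
                         n_seqs >= min_seqs & novel,
                       "deleterious", "tolerated"))
  calls$label <- lab
  list(calls = calls, n_skipped = sum(skipped),
       fraction_deleterious = mean(lab[!skipped] == "deleterious"))
}

#' Per-sample nonsynonymous/synonymous load summary
#'
#' @param annotations Output of [classify_effects()] with a `sample`
#'   column and optionally a `label` column from [label_constraint()].
#' @return Data frame per sample: `nonsyn`, `syn`, `ratio_nsyn_syn` (NA
#'   when no synonymous calls), and when labels are present
#'   `deleterious` and `tolerated`.
#' @export
load_summary <- function(annotations) {
  samples <- sort(unique(annotations$sample))
  out <- do.call(rbind, lapply(samples, function(s) {
    a <- annotations[annotations$sample == s, ]
    nonsyn <- sum(a$consequence %in% NONSYN_CLASSES)
    syn <- sum(a$consequence == "synonymous")
    row <- data.frame(sample = s, nonsyn = nonsyn, syn = syn,
                      ratio_nsyn_syn = if (syn > 0) nonsyn / syn else NA_real_)
    if (!is.null(a$label)) {
      row$deleterious <- sum(a$label == "deleterious", na.rm = TRUE)
      row$tolerated <- sum(a$label == "tolerated", na.rm = TRUE)
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Deleterious load per covered codon in genomic windows
#'
#' Counts deleterious and tolerated nonsynonymous variants in tumbling
#' windows and divides by the number of codons of (callable) CDS covered
#' by each window. Windows without covered codons are flagged NA.
#'
#' @param annotations Labelled annotations (`chrom`, `pos`, `label`).
#' @param genes A `gene_models` object supplying CDS intervals.
#' @param genome [Biostrings::DNAStringSet] for chromosome lengths.
#' @param window_bp Window width (default 10 Mb).
#' @param callable Optional callable interval table; CDS is intersected
#'   with it before codon counting.
#' @param anchor 0-based offset of the first window boundary.
#' @return Data frame per window: `chrom`, `start`, `end` (0-based
#'   half-open), `n_deleterious`, `n_tolerated`, `codons`,
#'   `del_per_codon`, `tol_per_codon`.
#' @export
load_windows <- function(annotations, genes, genome, window_bp = 1e7,
                         callable = NULL, anchor = 0) {
  stopifnot(window_bp > 0)
  cds <- do.call(rbind, lapply(unclass(genes), function(g)
    data.frame(chrom = g$chrom, start = g$cds$start - 1L, end = g$cds$end)))
  cds_gr <- GenomicRanges::reduce(intervals_to_gr(cds))
  if (!is.null(callable)) {
    cds_gr <- GenomicRanges::intersect(cds_gr, intervals_to_gr(callable))
  }
  rows <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    L <- Biostrings::width(genome)[ci]
    bounds <- seq(anchor %% window_bp, L, by = window_bp)
    if (!length(bounds) || bounds[1] > 0) bounds <- c(0, bounds)
    if (bounds[length(bounds)] < L) bounds <- c(bounds, L)
    bounds <- unique(bounds)
    for (bi in seq_len(length(bounds) - 1)) {
      s <- bounds[bi]
      e <- bounds[bi + 1]
      win_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e))
      cds_bp <- sum(IRanges::width(GenomicRanges::intersect(cds_gr, win_gr)))
      in_win <- annotations$chrom == chrom & annotations$pos > s &
        annotations$pos <= e
      nd <- sum(in_win & annotations$label == "deleterious", na.rm = TRUE)
      nt <- sum(in_win & annotations$label == "tolerated", na.rm = TRUE)
      codons <- floor(cds_bp / 3)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = s, end = e,
        n_deleterious = nd, n_tolerated = nt, codons = codons,
        del_per_codon = if (codons > 0) nd / codons else NA_real_,
        tol_per_codon = if (codons > 0) nt / codons else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate per-line deleterious load with a phenotype
#'
#' @param load Numeric vector of per-line load (e.g. deleterious counts).
#' @param phenotype Numeric vector of per-line phenotype values (e.g.
#'   yield), same order.
#' @param method `"rank"` (Spearman) or `"linear"` (Pearson).
#' @return List with `estimate`, `p_value`, `method`, `n`.
#' @export
correlate_load_phenotype <- function(load, phenotype,
                                     method = c("rank", "linear")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(load, phenotype)
  if (sum(ok) < 3) stop("need at least 3 paired observations")
  if (stats::sd(load[ok]) == 0 || stats::sd(phenotype[ok]) == 0) {
    warning("constant vector; correlation undefined")
    return(list(estimate = NA_real_, p_value = NA_real_,
                method = method, n = sum(ok)))
  }
  ct <- suppressWarnings(cor.test(
    load[ok], phenotype[ok],
    method = if (method == "rank") "spearman" else "pearson"))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = sum(ok))
}
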