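#' Collapse SNVs into the six reverse-complement-pooled classes
#'
#' Each of the 12 raw single-base substitutions is mapped to the
#' representative whose reference base is A or C, so e.g. G>A counts as
#' C>T* and T>C as A>G*. Records with non-ACGT alleles are skipped and
#' counted.
#'
#' @param snvs Either a variant table with `ref`/`alt` columns or a pair
#'   of character vectors via `ref=`/`alt=`.
#' @param ref,alt Optional explicit allele vectors (used when `snvs` is
#'   missing).
#' @return Object of class `mutation_spectrum`: list with `counts`
#'   (named length-6 integer), `total`, `fractions`, `n_skipped`.
#' @examples
#' collapse_spectrum(ref = c("G", "C", "T"), alt = c("A", "T", "C"))
#' @export
collapse_spectrum <- function(snvs = NULL, ref = NULL, alt = NULL) {
  if (!is.null(snvs)) {
    if (!is.null(snvs$vtype)) snvs <- snvs[snvs$vtype == "SNV", ]
    ref <- snvs$ref
    alt <- snvs$alt
  }
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt &
    nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!ok)
  if (n_skipped) warning(n_skipped, " record(s) with non-ACGT alleles skipped")
  ref <- ref[ok]
  alt <- alt[ok]
  flip <- ref %in% c("G", "T")
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  cls <- factor(paste0(ref, ">", alt, "*"), levels = SPECTRUM_CLASSES)
  counts <- table(cls)
  total <- sum(counts)
  structure(list(
    counts = stats::setNames(as.integer(counts), SPECTRUM_CLASSES),
    total = total,
    fractions = if (total > 0) as.numeric(counts) / total else
      rep(NA_real_, 6),
    n_skipped = n_skipped
  ), class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("Collapsed mutation spectrum (", x$total, " SNVs)\n", sep = "")
  df <- data.frame(class = SPECTRUM_CLASSES, count = x$counts,
                   fraction = round(x$fractions, 4))
  print(df, row.names = FALSE)
  if (x$n_skipped) cat("  skipped:", x$n_skipped, "\n")
  invisible(x)
}

#' @export
plot.mutation_spectrum <- function(x, ...) {
  barplot(x$fractions, names.arg = SPECTRUM_CLASSES,
          ylab = "Fraction of SNVs", ...)
  invisible(x)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#'
#' @inheritParams collapse_spectrum
#' @return List with `ts`, `tv`, and `ratio` (NA with a warning when no
#'   transversions are present).
#' @export
ts_tv <- function(snvs = NULL, ref = NULL, alt = NULL) {
  if (!is.null(snvs)) {
    if (!is.null(snvs$vtype)) snvs <- snvs[snvs$vtype == "SNV", ]
    ref <- snvs$ref
    alt <- snvs$alt
  }
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  ref <- ref[ok]
  alt <- alt[ok]
  is_ts <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
           (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ts <- sum(is_ts)
  tv <- sum(!is_ts)
  if (tv == 0) {
    warning("no transversions observed; Ts/Tv undefined")
    return(list(ts = ts, tv = 0L, ratio = NA_real_))
  }
  list(ts = ts, tv = tv, ratio = ts / tv)
}

#' Signed indel length histogram
#'
#' Tabulates signed indel lengths (insertions positive, deletions
#' negative) over `[-max_len, -1]` and `[1, max_len]` with overflow bins
#' for longer events, and reports the fraction of 1-bp events among
#' insertions and among deletions separately.
#'
#' @param indels Variant table with a signed `length` column, or a bare
#'   numeric vector of signed lengths.
#' @param max_len Largest length shown per side.
#' @return List with `histogram` (data frame `length`, `count`; overflow
#'   rows labelled by `<=-(max_len+1)` / `>=(max_len+1)`),
#'   `frac_ins_1bp`, `frac_del_1bp` (NA when the respective side is
#'   empty), `n_insertions`, `n_deletions`.
#' @export
indel_length_histogram <- function(indels, max_len = 20) {
  len <- if (is.data.frame(indels)) indels$length else indels
  if (any(len == 0)) stop("indel records must have non-zero signed length")
  lv <- c(paste0("<=", -(max_len + 1)), as.character(c(-(max_len:1), 1:max_len)),
          paste0(">=", max_len + 1))
  binned <- ifelse(len < -max_len, lv[1],
                   ifelse(len > max_len, lv[length(lv)], as.character(len)))
  counts <- table(factor(binned, levels = lv))
  n_ins <- sum(len > 0)
  n_del <- sum(len < 0)
  if (n_ins + n_del == 0) {
    warning("empty indel set; 1-bp fractions undefined")
  }
  list(histogram = data.frame(length = lv, count = as.integer(counts)),
       frac_ins_1bp = if (n_ins > 0) sum(len == 1) / n_ins else NA_real_,
       frac_del_1bp = if (n_del > 0) sum(len == -1) / n_del else NA_real_,
       n_insertions = n_ins, n_deletions = n_del)
}

#' Genome k-mer composition
#'
#' Counts overlapping k-mers on the forward strand of a sequence set.
#' Windows containing a non-ACGT character (e.g. N) are excluded from
#' both the counts and the window total.
#'
#' @param seqs [Biostrings::DNAStringSet], a character vector of
#'   sequences, or a single string.
#' @param k Word size (>= 1).
#' @return Object of class `kmer_composition`: list with `k`, `counts`
#'   (named over the 4^k ACGT words), `total_windows`, `fractions`.
#' @examples
#' count_kmers("ACGT", 2)$counts[c("AC", "CG", "GT")]
#' @export
count_kmers <- function(seqs, k) {
  stopifnot(k >= 1)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (all(Biostrings::width(seqs) < k)) {
    warning("k exceeds every sequence length; empty composition")
    counts <- integer(4^k)
  } else {
    counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  }
  total <- sum(counts)
  structure(list(k = k, counts = counts, total_windows = total,
                 fractions = if (total > 0) counts / total else
                   rep(NA_real_, length(counts))),
            class = "kmer_composition")
}

#' @export
print.kmer_composition <- function(x, ...) {
  cat(sprintf("k-mer composition (k = %d, %d windows)\n", x$k,
              x$total_windows))
  top <- sort(x$counts, decreasing = TRUE)
  top <- top[top > 0]
  show <- head(top, 12)
  df <- data.frame(kmer = names(show), count = as.integer(show),
                   fraction = round(show / max(1, x$total_windows), 4))
  print(df, row.names = FALSE)
  if (length(top) > 12) cat("  ...\n")
  invisible(x)
}
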