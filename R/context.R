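# Sequence-context statistics around mutated sites: each mutation is
# paired with a control position carrying the same reference base drawn
# near the mutation, and per-flanking-position base frequencies are
# compared by relative entropy (KL divergence) and a G-test deviance.

#' Sample matched-base control positions near mutations
#'
#' For every SNV, draws one position uniformly from within
#' `+/- window` bp on the same chromosome that carries the same
#' reference base as the mutated site, excluding the focal position
#' itself. Mutations with no eligible position are excluded from the
#' context analysis and counted.
#'
#' @param snvs Variant table (`chrom`, `pos`, `ref`).
#' @param genome [Biostrings::DNAStringSet].
#' @param window Search radius in bp.
#' @param seed Optional integer seed for reproducible sampling.
#' @return List with `controls` (data frame `chrom`, `pos`, matched row
#'   index `mutation_row`) and `n_excluded`.
#' @export
sample_controls <- function(snvs, genome, window = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  n <- nrow(snvs)
  ctrl_pos <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    cs <- chars[[snvs$chrom[i]]]
    p <- snvs$pos[i]
    lo <- max(1L, p - window)
    hi <- min(length(cs), p + window)
    cand <- lo - 1L + which(cs[lo:hi] == snvs$ref[i])
    cand <- cand[cand != p]
    if (length(cand)) {
      ctrl_pos[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      ok[i] <- TRUE
    }
  }
  list(controls = data.frame(chrom = snvs$chrom[ok], pos = ctrl_pos[ok],
                             mutation_row = which(ok)),
       n_excluded = sum(!ok))
}

base_counts_at <- function(chars, chrom, pos, offset) {
  b <- vapply(seq_along(chrom), function(i) {
    cs <- chars[[chrom[i]]]
    j <- pos[i] + offset
    if (j >= 1 && j <= length(cs)) cs[j] else "X"
  }, character(1))
  counts <- table(factor(b, levels = DNA_BASES))
  stats::setNames(as.integer(counts), DNA_BASES)
}

#' Flanking-context profile of a focal substitution
#'
#' Compares base composition at each flanking position (default
#' `-flank..-1, +1..+flank`) between mutations of one focal change (all
#' sharing the same forward-strand ref/alt) and their matched controls.
#' Per position, the relative-entropy term for base `b` is
#' `p_m(b) * log2(p_m(b)/p_c(b))` (0 where `p_m(b) = 0`; an optional
#' pseudocount guards small samples), and the position's RE is the sum of
#' terms — a KL divergence, non-negative. Term signs mark over-
#' (positive) versus under-representation for logo rendering.
#'
#' @param snvs Variant table of the focal change (e.g. all C>T rows).
#' @param genome [Biostrings::DNAStringSet].
#' @param controls Result of [sample_controls()] on the same rows.
#' @param flank Flank radius in bp (2 gives 5-bp neighborhoods).
#' @param pseudocount Added to every base count before frequencies.
#' @return Object of class `context_profile`: list with `focal_change`,
#'   `flank`, `n`, `positions` (offsets), `mut_counts` / `ctrl_counts`
#'   (4 x positions matrices), `re_terms` (per-base signed terms),
#'   `re` (per-position totals).
#' @export
context_profile <- function(snvs, genome, controls, flank = 2,
                            pseudocount = 0) {
  focal <- unique(paste0(snvs$ref, ">", snvs$alt))
  if (length(focal) != 1) {
    stop("all SNVs must share one forward-strand focal change; got: ",
         paste(focal, collapse = ", "))
  }
  mut <- snvs[controls$controls$mutation_row, , drop = FALSE]
  ctl <- controls$controls
  if (nrow(mut) != nrow(ctl)) stop("controls are not paired 1:1 with mutations")
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  offsets <- setdiff(-flank:flank, 0)
  mut_counts <- ctrl_counts <- matrix(0L, nrow = 4, ncol = length(offsets),
                                      dimnames = list(DNA_BASES, offsets))
  for (j in seq_along(offsets)) {
    mut_counts[, j] <- base_counts_at(chars, mut$chrom, mut$pos, offsets[j])
    ctrl_counts[, j] <- base_counts_at(chars, ctl$chrom, ctl$pos, offsets[j])
  }
  re_terms <- matrix(0, nrow = 4, ncol = length(offsets),
                     dimnames = list(DNA_BASES, offsets))
  for (j in seq_along(offsets)) {
    re_terms[, j] <- re_position(mut_counts[, j], ctrl_counts[, j],
                                 pseudocount)
  }
  structure(list(focal_change = focal, flank = flank, n = nrow(mut),
                 positions = offsets, mut_counts = mut_counts,
                 ctrl_counts = ctrl_counts, re_terms = re_terms,
                 re = colSums(re_terms)),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("Context profile for %s (n = %d, flank %d)\n",
              x$focal_change, x$n, x$flank))
  cat("Per-position relative entropy (bits):\n")
  print(round(x$re, 4))
  invisible(x)
}

#' @export
plot.context_profile <- function(x, ...) {
  barplot(x$re, names.arg = x$positions,
          xlab = "Position relative to mutated base",
          ylab = "Relative entropy (bits)", ...)
  invisible(x)
}

#' Per-position G-test deviance of a context profile
#'
#' For each flanking position, tests independence of base composition
#' from set membership (mutation vs control) in the 2 x 4 contingency
#' table via the likelihood-ratio statistic
#' `G = 2 * sum O * ln(O/E)` (zero cells contribute 0), with 3 degrees
#' of freedom and an upper-tail chi-squared p-value. This equals the
#' position-effect deviance of a single-position log-linear model.
#'
#' @param profile A `context_profile` object.
#' @return Data frame with `position`, `G`, `df`, `p`.
#' @export
position_deviance <- function(profile) {
  out <- data.frame(position = profile$positions,
                    G = NA_real_, df = 3L, p = NA_real_)
  for (j in seq_along(profile$positions)) {
    tab <- rbind(mutation = profile$mut_counts[, j],
                 control = profile$ctrl_counts[, j])
    if (any(rowSums(tab) == 0)) {
      warning("a set has zero total at position ", profile$positions[j])
      next
    }
    out$G[j] <- g_statistic(tab)
    out$p[j] <- pchisq(out$G[j], df = 3, lower.tail = FALSE)
  }
  out
}

# per-base relative-entropy terms at one flanking position:
# p_m(b) * log2(p_m(b)/p_c(b)), with zero-frequency mutation bases
# contributing 0
re_position <- function(mut_counts, ctrl_counts, pseudocount = 0) {
  pm <- (mut_counts + pseudocount) / sum(mut_counts + pseudocount)
  pc <- (ctrl_counts + pseudocount) / sum(ctrl_counts + pseudocount)
  ifelse(pm == 0, 0, pm * log2(pm / pc))
}

# likelihood-ratio statistic for an r x c contingency table
g_statistic <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab == 0, 0, tab * log(tab / E))
  2 * sum(terms)
}
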