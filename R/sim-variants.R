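# Internal index over the simulated genome used by the variant
# generators: per-position base, callable flag and context-specific site
# pools (CC / CpG and their reverse-complement mirrors). Positions are
# encoded globally (1..sum of chromosome lengths) so pools can be drawn
# from in one step.
build_site_index <- function(ref, contaminate_masks = FALSE) {
  chr_names <- names(ref$genome)
  lens <- Biostrings::width(ref$genome)
  offsets <- cumsum(c(0L, lens))[seq_along(lens)]
  chars <- unlist(lapply(as.character(ref$genome),
                         function(s) strsplit(s, "")[[1]]), use.names = FALSE)
  G <- length(chars)
  callable <- rep(TRUE, G)
  if (!contaminate_masks && nrow(ref$masks)) {
    keep <- ref$masks$label != "low_complexity"
    m <- ref$masks[keep, , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      off <- offsets[match(m$chrom[j], chr_names)]
      callable[(off + m$start[j] + 1):(off + m$end[j])] <- FALSE
    }
  }
  callable[chars == "N"] <- FALSE

  # neighbours within chromosomes only
  nxt <- c(chars[-1], "X")
  prv <- c("X", chars[-G])
  ends <- offsets + lens
  nxt[ends] <- "X"            # last base of each chromosome
  prv[offsets + 1L] <- "X"    # first base of each chromosome

  ic <- which(callable)
  bc <- chars[ic]
  nx <- nxt[ic]
  pv <- prv[ic]
  pools <- list(ALL = ic)
  for (b in DNA_BASES) pools[[b]] <- ic[bc == b]
  isC <- bc == "C"
  isG <- bc == "G"
  pools[["C_nextC"]] <- ic[isC & nx == "C"]
  pools[["C_notC"]]  <- ic[isC & nx != "C" & nx != "X"]
  pools[["G_prevG"]] <- ic[isG & pv == "G"]
  pools[["G_notG"]]  <- ic[isG & pv != "G" & pv != "X"]
  pools[["C_nextG"]] <- ic[isC & nx == "G"]
  pools[["C_notG"]]  <- ic[isC & nx != "G" & nx != "X"]
  pools[["G_prevC"]] <- ic[isG & pv == "C"]
  pools[["G_notC"]]  <- ic[isG & pv != "C" & pv != "X"]

  list(chars = chars, callable = callable, pools = pools,
       chr_names = chr_names, lens = lens, offsets = offsets, G = G)
}

gpos_to_chrom <- function(idx, gpos) {
  ci <- findInterval(gpos, idx$offsets + 1L)
  list(chrom = idx$chr_names[ci], pos = gpos - idx$offsets[ci], ci = ci)
}

# draw n distinct untaken positions from a pool (global coordinates);
# marks them taken in env$taken. Rejection sampling keeps each draw O(1);
# a full scan is the fallback when the pool is nearly exhausted.
draw_positions <- function(pool, n, env) {
  if (n == 0) return(integer())
  if (!length(pool)) {
    stop("no eligible sites in pool; enlarge the genome or reduce variant counts")
  }
  out <- integer(0)
  for (t in 1:50) {
    need <- n - length(out)
    if (need == 0) break
    cand <- pool[sample.int(length(pool), need, replace = TRUE)]
    cand <- unique(cand[!env$taken[cand]])
    env$taken[cand] <- TRUE
    out <- c(out, cand)
  }
  if (length(out) < n) {
    avail <- pool[!env$taken[pool]]
    need <- n - length(out)
    if (length(avail) < need) {
      stop("not enough eligible sites in pool (", length(avail),
           " still available, ", need, " more requested); ",
           "enlarge the genome or reduce variant counts")
    }
    extra <- if (length(avail) == 1) avail else sample(avail, need)
    env$taken[extra] <- TRUE
    out <- c(out, extra)
  }
  out
}

empty_variants <- function() {
  data.frame(sample = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), vtype = character(),
             length = integer(), gt = character(), dp = integer(),
             gq = integer(), ab = numeric(), qual = numeric(),
             support = integer())
}

variant_row <- function(sample, chrom, pos, ref, alt, gt,
                        dp = 30L, gq = 99L, qual = 100) {
  vtype <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                  ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  data.frame(sample = sample, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, vtype = vtype,
             length = nchar(alt) - nchar(ref), gt = gt,
             dp = dp, gq = gq,
             ab = ifelse(gt == "het", 0.5, NA_real_),
             qual = qual, support = NA_integer_)
}

# classify the immediate context of a SNV for the truth table
context_flag <- function(idx, gpos, ref_base) {
  nxt <- if (gpos < idx$G) idx$chars[gpos + 1L] else "X"
  prv <- if (gpos > 1) idx$chars[gpos - 1L] else "X"
  if (ref_base == "C" && nxt == "C") return("CC")
  if (ref_base == "G" && prv == "G") return("CC")
  if (ref_base == "C" && nxt == "G") return("CpG")
  if (ref_base == "G" && prv == "C") return("CpG")
  "other"
}

#' Simulate parent-vs-reference heterogeneity variants
#'
#' Places `n_parent_diffs` variants (82% SNVs, 18% 1-bp indels) at
#' distinct callable positions. These represent residual differences
#' between the seed stock actually mutagenized and the reference
#' assembly; every mutagenized line inherits them, and the isolation
#' pipeline must remove them.
#'
#' @param config A [sim_config()] object.
#' @param ref Result of [sim_reference()] (or the gene-stamped genome in
#'   the same structure).
#' @param idx Optional precomputed site index (internal reuse).
#' @return Data frame of variant calls for sample `"parent"`.
#' @export
sim_parent_diffs <- function(config, ref, idx = NULL) {
  set.seed(config$seed + 2L)
  n <- config$n_parent_diffs
  if (n == 0) return(empty_variants())
  if (is.null(idx)) idx <- build_site_index(ref, config$contaminate_masks)
  env <- new.env()
  env$taken <- logical(idx$G)
  gpos <- draw_positions(idx$pools$ALL, n, env)
  loc <- gpos_to_chrom(idx, gpos)
  b <- idx$chars[gpos]
  gt <- ifelse(runif(n) < 0.7, "hom_alt", "het")
  is_snv <- runif(n) < 0.82
  nxt_ok <- gpos < idx$G & loc$pos < idx$lens[loc$ci]
  nxt_base <- rep("N", n)
  nxt_base[nxt_ok] <- idx$chars[gpos[nxt_ok] + 1L]
  is_del <- !is_snv & runif(n) < 0.5 & nxt_ok & nxt_base != "N"

  ref <- b
  alt <- b
  # SNVs: shift to another base
  shift <- sample.int(3, n, replace = TRUE)
  alt[is_snv] <- vapply(which(is_snv), function(i)
    setdiff(DNA_BASES, b[i])[shift[i]], character(1))
  # 1-bp deletions (left-anchored) and insertions
  ref[is_del] <- paste0(b[is_del], nxt_base[is_del])
  ins <- !is_snv & !is_del
  alt[ins] <- paste0(b[ins], sample(DNA_BASES, sum(ins), replace = TRUE))

  out <- variant_row("parent", loc$chrom, loc$pos, ref, alt, gt)
  rownames(out) <- NULL
  out
}

# draw collapsed-class assignments and realized (strand-resolved)
# ref/alt bases for n SNVs
draw_snv_classes <- function(n, probs) {
  cls <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = probs[SPECTRUM_CLASSES])
  fwd <- runif(n) < 0.5
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  ref[!fwd] <- comp_base(ref[!fwd])
  alt[!fwd] <- comp_base(alt[!fwd])
  data.frame(class = cls, ref = ref, alt = alt, forward = fwd)
}

# weighted two-pool choice used for context enrichment: returns TRUE when
# the enriched pool should be used, with odds multiplied by `w`
enriched_pool_draw <- function(n, n_enriched, n_other, w) {
  p <- (w * n_enriched) / (w * n_enriched + n_other)
  runif(n) < p
}

# batch-draw positions for a set of classed SNVs: C>T* draws choose
# between an enriched context pool and its complement (odds multiplied
# by w); every other class draws from its reference-base pool
draw_context_weighted <- function(cl, idx, env, w, enriched, plain) {
  n <- nrow(cl)
  pool_name <- cl$ref
  for (b in c("C", "G")) {
    rows <- which(cl$class == "C>T*" & cl$ref == b)
    if (!length(rows)) next
    use <- enriched_pool_draw(length(rows),
                              length(idx$pools[[enriched[[b]]]]),
                              length(idx$pools[[plain[[b]]]]), w)
    pool_name[rows] <- ifelse(use, enriched[[b]], plain[[b]])
  }
  gpos <- integer(n)
  for (pn in unique(pool_name)) {
    rows <- which(pool_name == pn)
    gpos[rows] <- draw_positions(idx$pools[[pn]], length(rows), env)
  }
  gpos
}

#' Simulate induced and spontaneous variants in mutagenized lines
#'
#' For each of `n_mut_lines` lines: a Poisson number of induced SNVs with
#' collapsed class drawn from `spectrum_probs` (C>T* draws are placed
#' preferentially at C-followed-by-C sites — or G-preceded-by-G for the
#' reverse-complement realization — with odds multiplied by
#' `cc_context_enrichment`); a Poisson number of induced small indels
#' with the configured 1-bp mass and deletion fraction; a Poisson number
#' of spontaneous variants whose mean comes from [selfing_expectation()]
#' at the configured rates; plus the inherited parent heterogeneity
#' variants. Induced and spontaneous variants are globally private (no
#' two lines share one), and the truth table records every emitted call.
#'
#' @inheritParams sim_parent_diffs
#' @param parent_diffs Output of [sim_parent_diffs()]; inherited by every
#'   line and recorded as heterogeneity.
#' @return List with `variants` (long data frame of per-sample calls) and
#'   `truth` (data frame: `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `vtype`, `class`, `context`, `origin`).
#' @export
sim_mutant_lines <- function(config, ref, parent_diffs = empty_variants(),
                             idx = NULL) {
  set.seed(config$seed + 3L)
  if (is.null(idx)) idx <- build_site_index(ref, config$contaminate_masks)
  env <- new.env()
  env$taken <- logical(idx$G)
  # reserve parent positions so induced mutations never collide with them
  if (nrow(parent_diffs)) {
    off <- idx$offsets[match(parent_diffs$chrom, idx$chr_names)]
    env$taken[off + parent_diffs$pos] <- TRUE
  }

  spont_fit <- selfing_expectation(2 * sum(idx$lens), config$spont_snv_rate,
                                   config$generations)
  spont_snv_mean <- spont_fit$total
  spont_het_frac <- if (spont_fit$total > 0) {
    spont_fit$total_het / spont_fit$total
  } else 0.5
  spont_indel_mean <- selfing_expectation(2 * sum(idx$lens),
                                          config$spont_indel_rate,
                                          config$generations)$total

  all_var <- list()
  all_truth <- list()
  w <- config$cc_context_enrichment
  for (li in seq_len(config$n_mut_lines)) {
    sample_id <- sprintf("M%02d", li)
    n_ind <- rpois(1, config$mean_induced_snv)
    n_sp <- rpois(1, spont_snv_mean)
    n_spi <- rpois(1, spont_indel_mean)

    if (n_ind > 0) {
      cl <- draw_snv_classes(n_ind, config$spectrum_probs)
      gpos <- draw_context_weighted(cl, idx, env, w,
                                    enriched = c(C = "C_nextC", G = "G_prevG"),
                                    plain = c(C = "C_notC", G = "G_notG"))
      loc <- gpos_to_chrom(idx, gpos)
      gt <- ifelse(runif(n_ind) < config$het_fraction_induced, "het", "hom_alt")
      v <- variant_row(sample_id, loc$chrom, loc$pos, cl$ref, cl$alt, gt)
      ctx <- vapply(seq_len(n_ind),
                    function(i) context_flag(idx, gpos[i], cl$ref[i]),
                    character(1))
      t <- data.frame(sample = sample_id, chrom = loc$chrom, pos = loc$pos,
                      ref = cl$ref, alt = cl$alt, vtype = "SNV",
                      class = cl$class, context = ctx, origin = "induced")
      all_var[[length(all_var) + 1]] <- v
      all_truth[[length(all_truth) + 1]] <- t
    }

    n_idl <- rpois(1, config$mean_induced_indel)
    if (n_idl > 0) {
      iv <- sim_indels(config, idx, env, sample_id, n_idl, origin = "induced")
      all_var[[length(all_var) + 1]] <- iv$variants
      all_truth[[length(all_truth) + 1]] <- iv$truth
    }

    if (n_sp > 0) {
      cl <- draw_snv_classes(n_sp, config$landrace_spectrum_probs)
      gpos <- integer(n_sp)
      for (b in unique(cl$ref)) {
        rows <- which(cl$ref == b)
        gpos[rows] <- draw_positions(idx$pools[[b]], length(rows), env)
      }
      loc <- gpos_to_chrom(idx, gpos)
      gt <- ifelse(runif(n_sp) < spont_het_frac, "het", "hom_alt")
      all_var[[length(all_var) + 1]] <-
        variant_row(sample_id, loc$chrom, loc$pos, cl$ref, cl$alt, gt)
      all_truth[[length(all_truth) + 1]] <-
        data.frame(sample = sample_id, chrom = loc$chrom, pos = loc$pos,
                   ref = cl$ref, alt = cl$alt, vtype = "SNV",
                   class = cl$class,
                   context = vapply(seq_len(n_sp), function(i)
                     context_flag(idx, gpos[i], cl$ref[i]), character(1)),
                   origin = "spontaneous")
    }
    if (n_spi > 0) {
      iv <- sim_indels(config, idx, env, sample_id, n_spi,
                       origin = "spontaneous")
      all_var[[length(all_var) + 1]] <- iv$variants
      all_truth[[length(all_truth) + 1]] <- iv$truth
    }

    # inherited heterogeneity: the parent's variants, same genotypes
    if (nrow(parent_diffs)) {
      h <- parent_diffs
      h$sample <- sample_id
      all_var[[length(all_var) + 1]] <- h
      all_truth[[length(all_truth) + 1]] <-
        data.frame(sample = sample_id, chrom = h$chrom, pos = h$pos,
                   ref = h$ref, alt = h$alt, vtype = h$vtype,
                   class = NA_character_, context = NA_character_,
                   origin = "heterogeneity")
    }
  }
  variants <- do.call(rbind, c(all_var, list(empty_variants())))
  truth <- do.call(rbind, all_truth)
  if (is.null(truth)) {
    truth <- data.frame(sample = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), vtype = character(),
                        class = character(), context = character(),
                        origin = character())
  }
  rownames(variants) <- rownames(truth) <- NULL
  list(variants = variants, truth = truth)
}

# small-indel generator: left-anchored VCF alleles, lengths 1..20 with
# the 1-bp mass set by config and a geometric-like tail
sim_indels <- function(config, idx, env, sample_id, n, origin) {
  is_del <- runif(n) < config$deletion_fraction
  frac1 <- ifelse(is_del, config$indel_1bp_fraction_del,
                  config$indel_1bp_fraction_ins)
  tail_lens <- 2:20
  tail_p <- 0.65^(tail_lens - 2)
  len <- ifelse(runif(n) < frac1, 1L,
                sample(tail_lens, n, replace = TRUE, prob = tail_p))
  gpos <- draw_positions(idx$pools$ALL, n, env)
  # deletions must fit inside the chromosome with a fully callable span;
  # redraw the few anchors that do not
  for (i in which(is_del)) {
    repeat {
      loc_i <- gpos_to_chrom(idx, gpos[i])
      span <- gpos[i] + seq_len(len[i])
      if (loc_i$pos + len[i] <= idx$lens[loc_i$ci] &&
          all(idx$callable[span])) break
      gpos[i] <- draw_positions(idx$pools$ALL, 1, env)
    }
  }
  loc <- gpos_to_chrom(idx, gpos)
  anchor <- idx$chars[gpos]
  ref <- anchor
  alt <- anchor
  for (i in seq_len(n)) {
    if (is_del[i]) {
      ref[i] <- paste(idx$chars[gpos[i] + 0:len[i]], collapse = "")
    } else {
      alt[i] <- paste0(anchor[i],
                       paste(sample(DNA_BASES, len[i], replace = TRUE),
                             collapse = ""))
    }
  }
  gt <- ifelse(runif(n) < config$het_fraction_induced, "het", "hom_alt")
  v <- variant_row(sample_id, loc$chrom, loc$pos, ref, alt, gt)
  truth <- data.frame(sample = sample_id, chrom = loc$chrom, pos = loc$pos,
                      ref = ref, alt = alt, vtype = v$vtype,
                      class = NA_character_, context = NA_character_,
                      origin = origin)
  list(variants = v, truth = truth)
}

#' Simulate standing variation in untreated landrace samples
#'
#' Each segregating site receives a non-reference allele count drawn from
#' a neutral-like 1/i site-frequency spectrum over `1..2n-1` haplotypes,
#' a collapsed substitution class from `landrace_spectrum_probs`, and —
#' for C>T* draws — a CpG placement bias with odds multiplied by
#' `cpg_enrichment`. Allele copies are assigned to random haplotypes, so
#' both rare (count <= 2) and common (count >= 3) strata are populated.
#'
#' @inheritParams sim_parent_diffs
#' @return List with `variants` (long data frame: one row per carrier
#'   sample per site) and `sites` (per-site data frame with `class`,
#'   `context`, `allele_count`).
#' @export
sim_landraces <- function(config, ref, idx = NULL) {
  set.seed(config$seed + 4L)
  if (config$n_landraces < 2) stop("n_landraces must be >= 2")
  n_sites <- config$n_landrace_segsites
  if (n_sites == 0) {
    return(list(variants = empty_variants(),
                sites = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   class = character(), context = character(),
                                   allele_count = integer())))
  }
  if (is.null(idx)) idx <- build_site_index(ref, config$contaminate_masks)
  env <- new.env()
  env$taken <- logical(idx$G)
  w <- config$cpg_enrichment

  cl <- draw_snv_classes(n_sites, config$landrace_spectrum_probs)
  gpos <- draw_context_weighted(cl, idx, env, w,
                                enriched = c(C = "C_nextG", G = "G_prevC"),
                                plain = c(C = "C_notG", G = "G_notC"))
  loc <- gpos_to_chrom(idx, gpos)
  n_hap <- 2L * config$n_landraces
  k <- sample.int(n_hap - 1L, n_sites, replace = TRUE,
                  prob = 1 / seq_len(n_hap - 1L))
  samples <- sprintf("L%02d", seq_len(config$n_landraces))

  site_idx <- vector("list", n_sites)
  carrier_s <- vector("list", n_sites)
  carrier_gt <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    hap <- sample.int(n_hap, k[i])
    copies <- tabulate(ceiling(hap / 2), nbins = config$n_landraces)
    carriers <- which(copies > 0)
    site_idx[[i]] <- rep.int(i, length(carriers))
    carrier_s[[i]] <- samples[carriers]
    carrier_gt[[i]] <- ifelse(copies[carriers] == 2, "hom_alt", "het")
  }
  si <- unlist(site_idx)
  variants <- variant_row(unlist(carrier_s), loc$chrom[si], loc$pos[si],
                          cl$ref[si], cl$alt[si], unlist(carrier_gt))
  rownames(variants) <- NULL
  sites <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = cl$ref,
                      alt = cl$alt, class = cl$class,
                      context = vapply(seq_len(n_sites), function(i)
                        context_flag(idx, gpos[i], cl$ref[i]), character(1)),
                      allele_count = k)
  list(variants = variants, sites = sites)
}

#' Simulate a complete synthetic mutagenesis study
#'
#' Runs the full generator stack — reference and masks, gene models,
#' parent-vs-reference heterogeneity, mutagenized lines with truth table,
#' and landrace standing variation — and optionally writes all artifacts
#' to disk (FASTA, BED, per-sample VCF v4.2, multi-sample landrace VCF,
#' GFF3, tab-separated truth table).
#'
#' @param config A [sim_config()] object.
#' @param outdir Optional directory; created if missing.
#' @return List with `config`, `genome`, `masks`, `callable`, `genes`,
#'   `parent`, `lines`, `truth`, `landraces`, `landrace_sites`.
#' @export
simulate_study <- function(config, outdir = NULL) {
  ref <- sim_reference(config)
  stamped <- sim_genes(config, ref)
  ref$genome <- stamped$genome
  idx <- build_site_index(ref, config$contaminate_masks)
  parent <- sim_parent_diffs(config, ref, idx = idx)
  ml <- sim_mutant_lines(config, ref, parent, idx = idx)
  lr <- sim_landraces(config, ref, idx = idx)

  out <- list(config = config, genome = ref$genome, masks = ref$masks,
              callable = ref$callable, genes = stamped$genes,
              parent = parent, lines = ml$variants, truth = ml$truth,
              landraces = lr$variants, landrace_sites = lr$sites)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(out$genome, file.path(outdir, "reference.fa"))
    write_bed(out$masks, file.path(outdir, "masks.bed"))
    write_bed(out$callable, file.path(outdir, "callable.bed"))
    write_vcf(parent, out$genome, file.path(outdir, "parent.vcf"))
    for (s in unique(ml$variants$sample)) {
      write_vcf(ml$variants[ml$variants$sample == s, ], out$genome,
                file.path(outdir, paste0(s, ".vcf")))
    }
    if (nrow(lr$variants)) {
      write_vcf(lr$variants, out$genome, file.path(outdir, "landraces.vcf"),
                multi_sample = TRUE)
    }
    write_gff3(stamped$genes, file.path(outdir, "genes.gff3"))
    write.table(ml$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
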