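#' Simulate a reference genome with callable and uncallable masks
#'
#' Generates random chromosome sequences at the configured GC content and
#' overlays uncallable masks (labelled `repeat`, `high_copy`, `nstretch`)
#' covering `mask_fraction` of each chromosome, plus a small separate
#' `low_complexity` mask. Bases under `nstretch` intervals are set to N,
#' mirroring assembly gaps.
#'
#' @param config A [sim_config()] object.
#' @return List with:
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] of chromosomes `chr1..`}
#'     \item{masks}{data frame of uncallable intervals: `chrom`, `start`
#'       (0-based), `end` (exclusive), `label`.}
#'     \item{callable}{data frame of callable intervals (complement of
#'       the non-low-complexity masks), same coordinate convention.}
#'   }
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  chr_len <- floor(config$genome_length / n_chr)
  gc <- config$gc_fraction
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  seqs <- character(n_chr)
  mask_rows <- list()
  for (i in seq_len(n_chr)) {
    chrom <- paste0("chr", i)
    bases <- sample(DNA_BASES, chr_len, replace = TRUE, prob = base_probs)
    m <- place_mask_intervals(chr_len, config$mask_fraction)
    if (nrow(m)) {
      m$chrom <- chrom
      m$label <- sample(c("repeat", "high_copy", "nstretch"), nrow(m),
                        replace = TRUE, prob = c(0.7, 0.2, 0.1))
      for (j in which(m$label == "nstretch")) {
        bases[(m$start[j] + 1):m$end[j]] <- "N"
      }
    }
    lc <- place_mask_intervals(chr_len, min(0.02, config$mask_fraction))
    if (nrow(lc)) {
      lc$chrom <- chrom
      lc$label <- "low_complexity"
    }
    mask_rows[[i]] <- rbind(m, lc)
    seqs[i] <- paste(bases, collapse = "")
  }
  masks <- do.call(rbind, mask_rows)
  if (is.null(masks) || !nrow(masks)) {
    masks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), label = character())
  }
  masks <- masks[, c("chrom", "start", "end", "label")]
  rownames(masks) <- NULL

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(n_chr))
  callable <- build_callable_mask(masks, genome, exclude_low_complexity = FALSE)
  list(genome = genome, masks = masks, callable = callable)
}

# Deterministically place non-overlapping intervals covering ~fraction of a
# chromosome: the chromosome is cut into equal slots, one interval per slot
# at a random offset. Total masked bp lands within +/-2% of target.
place_mask_intervals <- function(chr_len, fraction) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character())
  if (fraction <= 0) return(empty)
  target <- round(chr_len * fraction)
  if (target < 1) return(empty)
  n_int <- max(1L, round(target / 2000))
  len_i <- round(target / n_int)
  slot <- floor(chr_len / n_int)
  if (len_i >= slot) {
    stop("genome too small to host the requested mask fraction; ",
         "increase genome_length or lower mask_fraction")
  }
  offs <- floor(runif(n_int, 0, slot - len_i))
  start <- (seq_len(n_int) - 1L) * slot + offs
  data.frame(chrom = NA_character_, start = as.integer(start),
             end = as.integer(start + len_i), label = NA_character_)
}

#' Simulate gene models stamped onto a reference genome
#'
#' Designs `n_genes` toy protein-coding genes (1-3 exons, CDS length a
#' multiple of 3, ATG start, single terminal stop, no internal stops,
#' canonical GT/AG splice dinucleotides) and writes their sequences into
#' callable regions of the genome, on either strand. Stamping the
#' designed sequence into the reference guarantees that every emitted CDS
#' translates cleanly, so consequence calls can be verified against the
#' construction.
#'
#' @param config A [sim_config()] object.
#' @param ref Result of [sim_reference()].
#' @return List with `genes` (a `gene_models` object, see
#'   [gene_models()]) and `genome` (the modified [Biostrings::DNAStringSet]).
#' @export
sim_genes <- function(config, ref) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_genes <- config$n_genes
  chars <- lapply(as.character(ref$genome), function(s) strsplit(s, "")[[1]])
  chr_names <- names(ref$genome)
  occupied <- lapply(chars, function(x) logical(length(x)))
  # forbid placement over masked bases
  for (j in seq_len(nrow(ref$masks))) {
    ci <- match(ref$masks$chrom[j], chr_names)
    occupied[[ci]][(ref$masks$start[j] + 1):ref$masks$end[j]] <- TRUE
  }

  genes <- vector("list", n_genes)
  if (n_genes > 0) {
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                    collapse = "")
    sense_codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    for (g in seq_len(n_genes)) {
      n_aa <- sample(40:150, 1)
      cds_seq <- paste0("ATG",
                        paste(sample(sense_codons, n_aa - 2, replace = TRUE),
                              collapse = ""),
                        sample(c("TAA", "TAG", "TGA"), 1))
      cds_len <- nchar(cds_seq)
      n_exons <- sample(1:3, 1)
      exon_lens <- cut_lengths(cds_len, n_exons, min_len = 30)
      intron_lens <- if (n_exons > 1) sample(60:200, n_exons - 1, replace = TRUE) else integer()
      span_len <- cds_len + sum(intron_lens)

      placed <- FALSE
      for (try in seq_len(200)) {
        ci <- sample(seq_along(chars), 1)
        L <- length(chars[[ci]])
        if (span_len + 2 >= L) next
        start <- sample.int(L - span_len - 1L, 1)
        if (any(occupied[[ci]][start:(start + span_len - 1L)])) next
        strand <- sample(c("+", "-"), 1)
        # assemble pre-mRNA on the coding strand
        pieces <- character(2 * n_exons - 1)
        cpos <- 1L
        for (e in seq_len(n_exons)) {
          pieces[2 * e - 1] <- substr(cds_seq, cpos, cpos + exon_lens[e] - 1L)
          cpos <- cpos + exon_lens[e]
          if (e < n_exons) {
            core_len <- intron_lens[e] - 4L
            core <- paste(sample(DNA_BASES, core_len, replace = TRUE),
                          collapse = "")
            pieces[2 * e] <- paste0("GT", core, "AG")
          }
        }
        premrna <- paste(pieces, collapse = "")
        stamped <- if (strand == "+") premrna else revcomp(premrna)
        chars[[ci]][start:(start + span_len - 1L)] <- strsplit(stamped, "")[[1]]
        occupied[[ci]][max(1, start - 10):min(L, start + span_len + 9)] <- TRUE

        # genomic CDS coordinates (ascending)
        exon_starts_tx <- cumsum(c(1L, head(exon_lens, -1) + intron_lens))
        cds_tx <- data.frame(start = exon_starts_tx,
                             end = exon_starts_tx + exon_lens - 1L)
        if (strand == "+") {
          cds_gen <- data.frame(start = start + cds_tx$start - 1L,
                                end = start + cds_tx$end - 1L)
        } else {
          gend <- start + span_len - 1L
          cds_gen <- data.frame(start = gend - cds_tx$end + 1L,
                                end = gend - cds_tx$start + 1L)
          cds_gen <- cds_gen[rev(seq_len(nrow(cds_gen))), , drop = FALSE]
          rownames(cds_gen) <- NULL
        }
        # phase: bases to skip at the 5' end of each CDS piece
        lens_tx <- exon_lens
        phase_tx <- c(0L, cumsum(head(lens_tx, -1))) %% 3L
        phase <- if (strand == "+") phase_tx else rev(phase_tx)
        cds_gen$phase <- phase
        genes[[g]] <- list(gene_id = sprintf("gene%03d", g),
                           chrom = chr_names[ci], strand = strand,
                           start = start, end = start + span_len - 1L,
                           cds = cds_gen)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place gene ", g,
             " without overlap; reduce n_genes or enlarge the genome")
      }
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- chr_names
  list(genes = gene_models(genes), genome = genome)
}

# split `total` into n parts each >= min_len
cut_lengths <- function(total, n, min_len = 30) {
  if (n == 1) return(total)
  repeat {
    cuts <- sort(sample.int(total - 1L, n - 1L))
    lens <- diff(c(0L, cuts, total))
    if (all(lens >= min_len)) return(lens)
  }
}

#' Gene model container
#'
#' @param genes List of gene descriptions, each with `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive span) and `cds` (data
#'   frame `start`, `end`, `phase`, ascending genomic coordinates).
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes = list()) {
  genes <- Filter(Negate(is.null), genes)
  structure(genes, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s)\n", length(x)))
  if (length(x)) {
    df <- as.data.frame(x)
    print(head(df, 10), row.names = FALSE)
    if (nrow(df) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.gene_models <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_exons = integer(),
                      cds_len = integer()))
  }
  do.call(rbind, lapply(unclass(x), function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$start, end = g$end, n_exons = nrow(g$cds),
               cds_len = sum(g$cds$end - g$cds$start + 1L))
  }))
}

#' Extract the spliced CDS sequence of a gene
#'
#' @param gene One element of a `gene_models` object.
#' @param genome [Biostrings::DNAStringSet] holding the stamped genome.
#' @return Character scalar: the CDS on the coding strand (starts ATG).
#' @export
gene_cds_seq <- function(gene, genome) {
  chrom <- as.character(genome[[gene$chrom]])
  parts <- substring(chrom, gene$cds$start, gene$cds$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}
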