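# Variant tables use a long layout throughout the package: one row per
# called genotype of one sample at one site, with columns
#   sample, chrom, pos (1-based), ref, alt, vtype, length, gt
#   ("het"/"hom_alt"), dp, gq, ab, qual, support
# BED-style interval tables are 0-based half-open (chrom, start, end[,
# label]); VCF coordinates are 1-based.

#' Write variant calls to a VCF v4.2 file
#'
#' @param variants Long variant data frame (see [sim_mutant_lines()]).
#' @param genome [Biostrings::DNAStringSet] used for contig headers.
#' @param path Output path.
#' @param multi_sample If TRUE, all samples share one file with per-sample
#'   genotype columns (absent calls written as `0/0`); otherwise the
#'   table must contain a single sample.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genome, path, multi_sample = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   Biostrings::width(genome)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">")
  gt_code <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0", missing = "./.")
  fmt_call <- function(gt, dp, gq, ab) {
    sprintf("%s:%d:%d:%s", gt_code[gt], dp, gq,
            ifelse(is.na(ab), ".", format(ab, digits = 3)))
  }
  if (multi_sample) {
    samples <- sort(unique(variants$sample))
    key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt,
                 sep = "\r")
    sites <- variants[!duplicated(key), c("chrom", "pos", "ref", "alt", "qual")]
    skey <- key[!duplicated(key)]
    ord <- order(match(sites$chrom, names(genome)), sites$pos)
    sites <- sites[ord, ]
    skey <- skey[ord]
    cols <- matrix("0/0:30:99:.", nrow = nrow(sites), ncol = length(samples),
                   dimnames = list(NULL, samples))
    ridx <- match(key, skey)
    cidx <- match(variants$sample, samples)
    cols[cbind(ridx, cidx)] <- fmt_call(variants$gt, variants$dp,
                                        variants$gq, variants$ab)
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                  sites$qual, "PASS", ".", "GT:DP:GQ:AB",
                  apply(cols, 1, paste, collapse = "\t"), sep = "\t")
    head_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", samples),
                       collapse = "\t")
  } else {
    if (length(unique(variants$sample)) > 1) {
      stop("single-sample VCF requested but multiple samples present")
    }
    sn <- if (nrow(variants)) variants$sample[1] else "sample"
    ord <- order(match(variants$chrom, names(genome)), variants$pos)
    v <- variants[ord, ]
    body <- if (nrow(v)) {
      paste(v$chrom, v$pos, ".", v$ref, v$alt, v$qual, "PASS", ".",
            "GT:DP:GQ:AB", fmt_call(v$gt, v$dp, v$gq, v$ab), sep = "\t")
    } else character()
    head_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", sn), collapse = "\t")
  }
  writeLines(c(hdr, head_line, body), path)
  invisible(path)
}

#' Read a VCF file into the package's long variant table
#'
#' Parses with [vcfR::read.vcfR()] and expands genotype columns into one
#' row per non-reference call. Missing (`./.`) and homozygous-reference
#' genotypes are dropped.
#'
#' @param path VCF file path.
#' @return Long variant data frame.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(empty_variants())
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  ab <- suppressWarnings(vcfR::extract.gt(v, element = "AB", as.numeric = TRUE))
  rows <- list()
  for (s in colnames(gt)) {
    g <- gsub("\\|", "/", gt[, s])
    lab <- rep(NA_character_, length(g))
    lab[g %in% c("0/1", "1/0")] <- "het"
    lab[g == "1/1"] <- "hom_alt"
    keep <- !is.na(lab)
    if (!any(keep)) next
    rows[[s]] <- data.frame(
      sample = s, chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
      ref = fix$REF[keep], alt = fix$ALT[keep],
      vtype = ifelse(nchar(fix$REF[keep]) == 1 & nchar(fix$ALT[keep]) == 1,
                     "SNV",
                     ifelse(nchar(fix$ALT[keep]) > nchar(fix$REF[keep]),
                            "insertion", "deletion")),
      length = nchar(fix$ALT[keep]) - nchar(fix$REF[keep]),
      gt = lab[keep],
      dp = if (is.null(dp)) NA_integer_ else as.integer(dp[keep, s]),
      gq = if (is.null(gq)) NA_integer_ else as.integer(gq[keep, s]),
      ab = if (is.null(ab)) NA_real_ else ab[keep, s],
      qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
      support = NA_integer_)
  }
  out <- do.call(rbind, c(rows, list(empty_variants())))
  rownames(out) <- NULL
  out
}

#' Write an interval table as BED
#'
#' @param intervals Data frame with `chrom`, `start` (0-based), `end`
#'   (exclusive) and optionally `label` (written as the BED name column).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "label"), names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval table
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `start`, `end` and, when the file has
#'   a name column, `label`.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  df[, intersect(c("chrom", "start", "end", "label"), names(df))]
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features with phase, one mRNA per gene.
#'
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in unclass(genes)) {
    lines <- c(lines,
      paste(g$chrom, "azidemut", "gene", g$start, g$end, ".", g$strand, ".",
            sprintf("ID=%s", g$gene_id), sep = "\t"),
      paste(g$chrom, "azidemut", "mRNA", g$start, g$end, ".", g$strand, ".",
            sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id), sep = "\t"),
      paste(g$chrom, "azidemut", "CDS", g$cds$start, g$cds$end, ".",
            g$strand, g$cds$phase,
            sprintf("ID=%s.cds;Parent=%s.t1", g$gene_id, g$gene_id),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports via [rtracklayer::import()] and reassembles the package's
#' `gene_models` structure from `gene` and `CDS` features (CDS grouped by
#' Parent transcript, one transcript per gene expected).
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  cds <- df[df$type == "CDS", ]
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    tx_id <- paste0(gid, ".t1")
    cc <- cds[vapply(cds$Parent, function(p) tx_id %in% p, logical(1)), ]
    cc <- cc[order(cc$start), ]
    list(gene_id = gid, chrom = as.character(genes$seqnames[i]),
         strand = as.character(genes$strand[i]),
         start = genes$start[i], end = genes$end[i],
         cds = data.frame(start = cc$start, end = cc$end,
                          phase = as.integer(as.character(cc$phase))))
  })
  gene_models(out)
}

#' Read a genotyping-panel position list
#'
#' Accepts either a two-column tab-separated file (`chrom`, `pos`) or a
#' VCF, returning the positions used by [panel_exclusion()].
#'
#' @param path Input path.
#' @return Data frame with `chrom` and `pos` (1-based).
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- read_vcf(path)
    unique(v[, c("chrom", "pos")])
  } else {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                     col.names = c("chrom", "pos"))
    df$pos <- as.integer(df$pos)
    df
  }
}
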