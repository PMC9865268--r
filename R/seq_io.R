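# FASTA / GFF3 input-output and sequence extraction.
#
# Conventions: genomic coordinates are 1-based inclusive (GFF3 native);
# intervals are stored sorted ascending regardless of strand; minus-strand
# sequences are reverse-complemented on extraction, never on storage.

#' Construct a gene model
#'
#' The coordinate backbone used by promoter extraction, gene-structure
#' statistics and duplication geometry. Intervals are 1-based inclusive
#' genome coordinates, stored sorted ascending on the plus strand
#' irrespective of the gene's own strand.
#'
#' @param gene_id gene (locus) identifier.
#' @param chromosome chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals two-column matrix (start, end) of CDS intervals.
#' @param exon_intervals two-column matrix of exon intervals; defaults to the
#'   CDS intervals when the annotation carries no separate exon features.
#' @param transcript_id optional transcript identifier (isoform label).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, cds_intervals,
                       exon_intervals = cds_intervals, transcript_id = gene_id) {
  cds_intervals <- normalize_intervals(cds_intervals, gene_id, "CDS")
  exon_intervals <- normalize_intervals(exon_intervals, gene_id, "exon")
  if (!strand %in% c("+", "-")) {
    stop("gene ", gene_id, ": strand must be '+' or '-', got '", strand, "'")
  }
  if (sum(cds_intervals[, 2] - cds_intervals[, 1] + 1) <= 0) {
    stop("gene ", gene_id, ": total CDS length must be positive")
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         chromosome = chromosome, strand = strand,
         cds_intervals = cds_intervals, exon_intervals = exon_intervals),
    class = "gene_model"
  )
}

normalize_intervals <- function(x, gene_id, what) {
  x <- matrix(as.integer(as.matrix(x)), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (any(x[, 1] > x[, 2])) {
    stop("gene ", gene_id, ": ", what, " interval with start > end")
  }
  x <- x[order(x[, 1]), , drop = FALSE]
  if (nrow(x) > 1L && any(x[-1L, 1] <= x[-nrow(x), 2])) {
    stop("gene ", gene_id, ": overlapping ", what, " intervals")
  }
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d [%s], %d CDS / %d exon interval(s)\n",
              x$gene_id, x$transcript_id, x$chromosome,
              min(x$cds_intervals[, 1]), max(x$cds_intervals[, 2]),
              x$strand, nrow(x$cds_intervals), nrow(x$exon_intervals)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] and enforces the package's record
#' invariants: identifiers are the first whitespace-delimited token of the
#' header, must be non-empty and unique; sequences are upper-cased.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA record with empty identifier in '", path, "' (record ",
         which(is.na(ids) | !nzchar(ids))[1L], ")")
  }
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA identifier(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[!nzchar(seqs)][1L], "' in '", path, "'")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS/exon features via [rtracklayer::import()]. One
#' `gene_model` is returned per mRNA; mRNAs without CDS features are skipped
#' with a warning. CDS/exon features must carry a `Parent` attribute linking
#' them to their transcript.
#'
#' @param path path to a GFF3 file.
#' @param longest_per_gene if `TRUE`, keep only the transcript with the
#'   longest total CDS per gene (the standard convention for gene-family
#'   surveys); ties broken by transcript id.
#' @return list of [gene_model] objects.
#' @export
read_gff3 <- function(path, longest_per_gene = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)

  mrna <- gr[type %in% c("mRNA", "transcript")]
  if (length(mrna) == 0L) stop("no mRNA/transcript features in '", path, "'")
  mrna_id <- as.character(S4Vectors::mcols(mrna)$ID)
  parent_of <- function(x) {
    p <- S4Vectors::mcols(x)$Parent
    vapply(seq_along(x), function(i) {
      pi <- p[[i]]
      if (length(pi) == 0L) NA_character_ else as.character(pi[[1L]])
    }, character(1))
  }
  mrna_gene <- parent_of(mrna)
  mrna_gene[is.na(mrna_gene)] <- mrna_id[is.na(mrna_gene)]

  sub <- gr[type %in% c("CDS", "exon")]
  if (length(sub) > 0L) {
    sub_parent <- parent_of(sub)
    if (anyNA(sub_parent)) {
      bad <- which(is.na(sub_parent))[1L]
      stop("GFF3 feature without Parent attribute in '", path, "': ",
           as.character(S4Vectors::mcols(sub)$type)[bad], " at ",
           as.character(GenomicRanges::seqnames(sub))[bad], ":",
           GenomicRanges::start(sub)[bad])
    }
  } else {
    sub_parent <- character(0)
  }
  sub_type <- as.character(S4Vectors::mcols(sub)$type)

  models <- list()
  for (i in seq_along(mrna)) {
    tid <- mrna_id[i]
    sel <- sub_parent == tid
    cds_sel <- sel & sub_type == "CDS"
    if (!any(cds_sel)) {
      warning("transcript '", tid, "' has no CDS features; skipped")
      next
    }
    exon_sel <- sel & sub_type == "exon"
    cds_iv <- cbind(GenomicRanges::start(sub)[cds_sel],
                    GenomicRanges::end(sub)[cds_sel])
    exon_iv <- if (any(exon_sel)) {
      cbind(GenomicRanges::start(sub)[exon_sel],
            GenomicRanges::end(sub)[exon_sel])
    } else cds_iv
    models[[length(models) + 1L]] <- gene_model(
      gene_id = mrna_gene[i], transcript_id = tid,
      chromosome = as.character(GenomicRanges::seqnames(mrna))[i],
      strand = as.character(BiocGenerics::strand(mrna))[i],
      cds_intervals = cds_iv, exon_intervals = exon_iv
    )
  }
  if (longest_per_gene) models <- longest_isoform(models)
  models
}

#' Keep the longest-CDS isoform per gene
#'
#' @param models list of [gene_model] objects.
#' @return filtered list, one model per `gene_id`, ordered by gene id.
#' @export
longest_isoform <- function(models) {
  if (length(models) == 0L) return(models)
  cds_len <- vapply(models, function(m) sum(m$cds_intervals[, 2] - m$cds_intervals[, 1] + 1L), numeric(1))
  gid <- vapply(models, `[[`, character(1), "gene_id")
  tid <- vapply(models, `[[`, character(1), "transcript_id")
  keep <- unlist(lapply(split(seq_along(models), gid), function(idx) {
    idx[order(-cds_len[idx], tid[idx])][1L]
  }))
  models[keep[order(gid[keep])]]
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent linkage, suitable
#' for round-tripping through [read_gff3()].
#'
#' @param models list of [gene_model] objects.
#' @param path output path.
#' @param source value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "genefamkit") {
  rows <- lapply(models, function(m) {
    span <- range(c(m$cds_intervals, m$exon_intervals))
    g <- data.frame(seqnames = m$chromosome, start = span[1], end = span[2],
                    strand = m$strand, type = "gene",
                    ID = m$gene_id, Parent = NA_character_)
    t <- data.frame(seqnames = m$chromosome, start = span[1], end = span[2],
                    strand = m$strand, type = "mRNA",
                    ID = m$transcript_id, Parent = m$gene_id)
    e <- data.frame(seqnames = m$chromosome,
                    start = m$exon_intervals[, 1], end = m$exon_intervals[, 2],
                    strand = m$strand, type = "exon",
                    ID = NA_character_, Parent = m$transcript_id)
    # phase: offset to the first complete codon, in transcription order
    iv <- m$cds_intervals
    lens <- iv[, 2] - iv[, 1] + 1L
    if (m$strand == "-") lens <- rev(lens)
    phase <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
    if (m$strand == "-") phase <- rev(phase)
    cc <- data.frame(seqnames = m$chromosome,
                     start = iv[, 1], end = iv[, 2],
                     strand = m$strand, type = "CDS",
                     ID = NA_character_, Parent = m$transcript_id)
    out <- rbind(g, t, e, cc)
    out$phase <- c(rep(NA_integer_, nrow(g) + nrow(t) + nrow(e)), phase)
    out
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Extract the coding sequence of a gene model
#'
#' Concatenates the CDS intervals in transcription order; minus-strand genes
#' are reverse-complemented.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gm a [gene_model].
#' @return nucleotide string.
#' @export
extract_cds <- function(genome, gm) {
  if (!gm$chromosome %in% names(genome)) {
    stop("chromosome '", gm$chromosome, "' not in genome")
  }
  chrom <- genome[[gm$chromosome]]
  if (max(gm$cds_intervals[, 2]) > nchar(chrom) || min(gm$cds_intervals[, 1]) < 1L) {
    stop("gene ", gm$gene_id, ": CDS interval out of chromosome bounds")
  }
  pieces <- substring(chrom, gm$cds_intervals[, 1], gm$cds_intervals[, 2])
  s <- paste(pieces, collapse = "")
  if (gm$strand == "-") s <- revcomp(s)
  s
}

#' Translate a coding sequence
#'
#' Standard genetic code; a trailing stop codon is removed; codons containing
#' characters outside A/C/G/T translate to `X`.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @param internal_stop `"error"` (default) to fail on premature stop codons,
#'   `"X"` to translate them as `X`.
#' @return protein string.
#' @export
translate_cds <- function(cds, internal_stop = c("error", "X")) {
  internal_stop <- match.arg(internal_stop)
  codons <- codon_split(toupper(cds))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    if (internal_stop == "error") {
      stop("internal stop codon at codon ", which(aa == "*")[1L])
    }
    aa[aa == "*"] <- "X"
  }
  paste(aa, collapse = "")
}

#' Extract a promoter sequence
#'
#' Returns the `length` bases immediately 5' of the CDS start codon,
#' strand-aware: for minus-strand genes this is the reverse complement of the
#' bases 3' of the CDS end in genome coordinates. The promoter is truncated
#' (with a warning) at the contig edge.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gm a [gene_model].
#' @param length promoter length in bp (default 2000, the conventional
#'   upstream window for plant cis-element surveys).
#' @return nucleotide string, 5'->3' reading toward the start codon.
#' @export
extract_promoter <- function(genome, gm, length = 2000L) {
  if (!gm$chromosome %in% names(genome)) {
    stop("chromosome '", gm$chromosome, "' not in genome")
  }
  chrom <- genome[[gm$chromosome]]
  n <- nchar(chrom)
  if (gm$strand == "+") {
    atg <- min(gm$cds_intervals[, 1])
    from <- atg - length
    if (from < 1L) {
      warning("gene ", gm$gene_id, ": promoter truncated to ", atg - 1L,
              " bp at contig start")
      from <- 1L
    }
    if (atg == 1L) return("")
    substring(chrom, from, atg - 1L)
  } else {
    cds_end <- max(gm$cds_intervals[, 2])
    to <- cds_end + length
    if (to > n) {
      warning("gene ", gm$gene_id, ": promoter truncated to ", n - cds_end,
              " bp at contig end")
      to <- n
    }
    if (cds_end == n) return("")
    revcomp(substring(chrom, cds_end + 1L, to))
  }
}
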