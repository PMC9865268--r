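# Promoter cis-regulatory element scanning against an IUPAC consensus
# catalogue, with per-gene functional-category summaries.
#
# Matching is exact-IUPAC against published consensus strings (deterministic
# and auditable, sufficient for presence/absence claims); no matrix models.
# `N` in a promoter never matches anything.

IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(consensus) {
  ch <- seq_chars(toupper(consensus))
  bad <- setdiff(unique(ch), names(IUPAC_CLASS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC symbol(s) in consensus '", consensus, "': ",
         paste(bad, collapse = ", "))
  }
  paste(IUPAC_CLASS[ch], collapse = "")
}

#' Load a cis-element catalogue
#'
#' With no arguments, returns the built-in catalogue of plant promoter
#' elements (published PlantCARE-style consensus strings) covering the four
#' conventional functional categories: light, hormone, stress and
#' growth/metabolic. The stress set includes the drought-diagnostic
#' elements ABRE (ABA-responsive) and MBS (MYB drought-binding site), plus
#' low-temperature (LTR), anaerobic-induction (ARE) and defense (W-box)
#' elements.
#'
#' @param path optional path to a TSV with columns `name`, `consensus`,
#'   `category` overriding the built-in catalogue.
#' @return data.frame with columns `name`, `consensus`, `category`.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    cat_df <- data.frame(
      name = c("ABRE", "MBS", "LTR", "ARE", "W-box",
               "CGTCA-motif", "TGACG-motif", "TCA-element", "GARE-motif",
               "TGA-element", "G-box", "Box4", "CAT-box", "O2-site"),
      consensus = c("ACGTG", "CAACTG", "CCGAAA", "AAACCA", "TTGACC",
                    "CGTCA", "TGACG", "CCATCTTTTT", "TCTGTTG",
                    "AACGAC", "CACGTG", "ATTAAT", "GCCACT", "GATGACATGG"),
      category = c("stress", "stress", "stress", "stress", "stress",
                   "hormone", "hormone", "hormone", "hormone",
                   "hormone", "light", "light",
                   "growth/metabolic", "growth/metabolic"),
      stringsAsFactors = FALSE
    )
  } else {
    cat_df <- read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
    need <- c("name", "consensus", "category")
    if (!all(need %in% names(cat_df))) {
      stop("catalogue must have columns: ", paste(need, collapse = ", "))
    }
  }
  cat_df$consensus <- toupper(cat_df$consensus)
  if (any(nchar(cat_df$consensus) < 4L)) {
    stop("catalogue consensus shorter than 4 bases: ",
         paste(cat_df$name[nchar(cat_df$consensus) < 4L], collapse = ", "))
  }
  invisible(lapply(cat_df$consensus, iupac_to_regex))  # validates IUPAC
  cat_df
}

# all (overlapping) start positions of an IUPAC consensus on a plus-strand
# sequence; N in the subject never matches
iupac_match_starts <- function(seq, consensus) {
  re <- paste0("(?=", iupac_to_regex(consensus), ")")
  m <- gregexpr(re, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-elements
#'
#' Reports every IUPAC-compatible match of every catalogue element on both
#' strands. Minus-strand hits (matches of the reverse complement of the
#' consensus) are reported at plus-strand coordinates with strand `"-"`.
#' Overlapping hits are all reported. Positions are 1-based from the
#' promoter 5' end; `dist_to_atg` is the distance from the element's last
#' base to the start codon (`promoter length - start - element length + 1`).
#'
#' @param promoter promoter sequence over A/C/G/T/N, 5'->3' toward the
#'   start codon (as produced by [extract_promoter()]).
#' @param catalog cis-element catalogue from [load_catalog()].
#' @param gene_id id recorded in the output.
#' @return data.frame with columns `gene_id`, `element`, `category`,
#'   `start`, `strand`, `match`, `dist_to_atg`.
#' @export
scan_promoter <- function(promoter, catalog = load_catalog(), gene_id = "promoter") {
  promoter <- toupper(promoter)
  plen <- nchar(promoter)
  rows <- lapply(seq_len(nrow(catalog)), function(k) {
    cons <- catalog$consensus[k]
    L <- nchar(cons)
    plus <- iupac_match_starts(promoter, cons)
    minus <- iupac_match_starts(promoter, revcomp(cons))
    # drop palindromic double counting? no: a minus-strand hit is a genuine
    # distinct orientation even at the same position; report both.
    starts <- c(plus, minus)
    strands <- c(rep("+", length(plus)), rep("-", length(minus)))
    if (length(starts) == 0L) return(NULL)
    data.frame(gene_id = gene_id, element = catalog$name[k],
               category = catalog$category[k],
               start = starts, strand = strands,
               match = substring(promoter, starts, starts + L - 1L),
               dist_to_atg = plen - starts - L + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), element = character(0),
                      category = character(0), start = integer(0),
                      strand = character(0), match = character(0),
                      dist_to_atg = integer(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$element, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize cis-element hits by functional category
#'
#' Counts hits per gene and category and flags promoters carrying at least
#' one drought-diagnostic element (MBS or ABRE).
#'
#' @param hits data.frame of hits from [scan_promoter()] (possibly several
#'   genes row-bound together).
#' @param genes optional character vector of gene ids to include (genes
#'   without hits get zero rows and a `FALSE` flag).
#' @param categories category columns to tabulate.
#' @param drought_elements element names that raise the drought flag.
#' @return data.frame with one row per gene: counts per category and
#'   logical `drought_flag`.
#' @export
summarize_categories <- function(hits, genes = NULL,
                                 categories = c("light", "hormone", "stress",
                                                "growth/metabolic"),
                                 drought_elements = c("MBS", "ABRE")) {
  if (is.null(genes)) genes <- sort(unique(hits$gene_id))
  rows <- lapply(genes, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    counts <- vapply(categories, function(cc) sum(h$category == cc), numeric(1))
    df <- as.data.frame(as.list(counts), check.names = FALSE)
    names(df) <- categories
    cbind(data.frame(gene_id = g, stringsAsFactors = FALSE), df,
          data.frame(drought_flag = any(h$element %in% drought_elements)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analytic per-window match probability of an IUPAC consensus
#'
#' Probability that a uniform i.i.d. A/C/G/T window matches the consensus
#' on a fixed strand; used by the scan-statistics checks.
#'
#' @param consensus IUPAC consensus string.
#' @return probability in (0, 1\].
#' @export
iupac_match_prob <- function(consensus) {
  ch <- seq_chars(toupper(consensus))
  widths <- nchar(gsub("\\[|\\]", "", vapply(ch, function(c) IUPAC_CLASS[[c]], character(1))))
  prod(widths / 4)
}
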