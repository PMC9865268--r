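# Duplicate-pair detection, duplication-type classification, Nei-Gojobori
# Ka/Ks estimation and molecular-clock divergence dating.
#
# The Ka/Ks estimator is Nei & Gojobori (1986): per-codon synonymous site
# fractions by enumeration of all nine single-base changes (stop-producing
# changes excluded from the per-position denominator, so N + S = 3 per
# codon holds exactly), pathway-averaged difference counting for multi-hit
# codons with stop-traversing pathways excluded, and a Jukes-Cantor
# multiple-hit correction applied to pN and pS separately.

#' Global protein alignment with identity and coverage
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' (BLOSUM62 by default; a gap of length k costs
#' `gap_open + k * gap_extend`). Identity is the percentage of identical
#' columns among columns where both sequences are aligned (non-gap);
#' coverage is the fraction of such columns relative to the longer input.
#'
#' @param protein_a,protein_b protein strings.
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return list with `identity` (percent), `coverage` (fraction), `score`,
#'   and `aligned` (named character vector of the two gapped rows).
#' @export
global_align <- function(protein_a, protein_b,
                         substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(nzchar(protein_a), nzchar(protein_b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  row_a <- as.character(Biostrings::alignedPattern(pa))
  row_b <- as.character(Biostrings::alignedSubject(pa))
  a <- seq_chars(row_a); b <- seq_chars(row_b)
  both <- a != "-" & b != "-"
  n_both <- sum(both)
  identity <- if (n_both > 0) 100 * sum(a[both] == b[both]) / n_both else 0
  coverage <- n_both / max(nchar(protein_a), nchar(protein_b))
  list(identity = identity, coverage = coverage,
       score = Biostrings::score(pa),
       aligned = c(a = unname(row_a), b = unname(row_b)))
}

#' Find duplicate gene pairs
#'
#' All unordered pairs of members passing both thresholds strictly
#' (`identity > identity_min` and `coverage > coverage_min`, matching the
#' conventional >85% / >0.75 duplicate definition).
#'
#' @param proteins named character vector of member protein sequences.
#' @param identity_min identity threshold in percent (strict).
#' @param coverage_min coverage threshold as a fraction (strict).
#' @param ... passed to [global_align()].
#' @return data.frame with columns `gene_a`, `gene_b`, `identity`,
#'   `coverage`, ordered by (gene_a, gene_b).
#' @export
find_duplicates <- function(proteins, identity_min = 85, coverage_min = 0.75, ...) {
  stopifnot(!is.null(names(proteins)))
  ids <- sort(names(proteins))
  if (length(ids) < 2L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage = numeric(0)))
  }
  pairs <- combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    al <- global_align(proteins[[a]], proteins[[b]], ...)
    if (al$identity > identity_min && al$coverage > coverage_min) {
      data.frame(gene_a = a, gene_b = b, identity = al$identity,
                 coverage = al$coverage, stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage = numeric(0))
  }
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

gene_span <- function(gm) {
  range(c(gm$cds_intervals, gm$exon_intervals))
}

#' Classify a duplication as tandem or segmental
#'
#' A pair is tandem iff both genes lie on the same chromosome AND (their
#' spans are within `tandem_window` bp of each other OR at most
#' `tandem_max_intervening` annotated genes lie strictly between them);
#' otherwise segmental. The intervening-gene rule is only evaluated when
#' `all_models` is supplied.
#'
#' @param gm_a,gm_b [gene_model] objects for the two genes.
#' @param all_models optional list of all annotated gene models, used to
#'   count intervening genes.
#' @param tandem_window maximum gap in bp for the distance rule (default
#'   100 kb).
#' @param tandem_max_intervening maximum intervening gene count (default 5).
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(gm_a, gm_b, all_models = NULL,
                                 tandem_window = 1e5, tandem_max_intervening = 5) {
  if (gm_a$chromosome != gm_b$chromosome) return("segmental")
  sa <- gene_span(gm_a); sb <- gene_span(gm_b)
  gap <- max(0, max(sa[1], sb[1]) - min(sa[2], sb[2]) - 1)
  if (gap <= tandem_window) return("tandem")
  if (!is.null(all_models)) {
    lo <- min(sa[2], sb[2]); hi <- max(sa[1], sb[1])
    between <- vapply(all_models, function(m) {
      if (m$chromosome != gm_a$chromosome) return(FALSE)
      if (m$gene_id %in% c(gm_a$gene_id, gm_b$gene_id)) return(FALSE)
      sp <- gene_span(m)
      sp[1] > lo && sp[2] < hi
    }, logical(1))
    n_between <- length(unique(vapply(all_models[between], `[[`, character(1), "gene_id")))
    if (n_between <= tandem_max_intervening) return("tandem")
  }
  "segmental"
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each aligned residue column is expanded to its source codon; columns with
#' a gap in either row are dropped, so the result is gap-free, equal-length
#' and stop-free. A terminal stop codon on either CDS is removed before
#' expansion. The CDSs must translate to the degapped protein rows.
#'
#' @param cds_a,cds_b coding sequences.
#' @param aligned_a,aligned_b gap-aligned protein rows (as from
#'   [global_align()]'s `aligned` element).
#' @return object of class `codon_alignment` with `seq_a`, `seq_b`,
#'   `n_codons`.
#' @export
codon_align <- function(cds_a, cds_b, aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned rows have different lengths")
  }
  expand <- function(cds, row, label) {
    codons <- codon_split(toupper(cds))
    if (length(codons) > 0L &&
        !is.na(Biostrings::GENETIC_CODE[codons[length(codons)]]) &&
        Biostrings::GENETIC_CODE[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    prot <- gsub("-", "", row, fixed = TRUE)
    trans <- paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
    if (trans != prot) {
      stop("CDS/protein mismatch for sequence ", label,
           ": CDS translates to a different residue string than the alignment row")
    }
    codons
  }
  cod_a <- expand(cds_a, aligned_a, "a")
  cod_b <- expand(cds_b, aligned_b, "b")
  a <- seq_chars(aligned_a); b <- seq_chars(aligned_b)
  ia <- cumsum(a != "-"); ib <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  structure(
    list(seq_a = paste(cod_a[ia[both]], collapse = ""),
         seq_b = paste(cod_b[ib[both]], collapse = ""),
         n_codons = sum(both)),
    class = "codon_alignment"
  )
}

# ---- Nei-Gojobori machinery -------------------------------------------------

.ng_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# synonymous site count per sense codon: at each position the fraction of
# non-stop single-base changes that are synonymous
ng_site_table <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache$sites)
  gc <- Biostrings::GENETIC_CODE
  cods <- sense_codons()
  s <- vapply(cods, function(cod) {
    ch <- seq_chars(cod)
    total <- 0
    for (pos in 1:3) {
      syn <- 0L; valid <- 0L
      for (b in setdiff(BASES, ch[pos])) {
        mut <- ch; mut[pos] <- b
        mc <- paste(mut, collapse = "")
        if (gc[mc] == "*") next
        valid <- valid + 1L
        if (gc[mc] == gc[cod]) syn <- syn + 1L
      }
      if (valid > 0L) total <- total + syn / valid
    }
    total
  }, numeric(1))
  .ng_cache$sites <- s
  s
}

PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# pathway-averaged (syn, nonsyn) difference counts between two sense codons;
# pathways through stop codons are excluded (all-stop fallback: include them)
ng_codon_diff <- function(cod_a, cod_b) {
  gc <- Biostrings::GENETIC_CODE
  a <- seq_chars(cod_a); b <- seq_chars(cod_b)
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  count_path <- function(order) {
    cur <- a
    syn <- 0; nonsyn <- 0
    for (pos in diff_pos[order]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      if (aa_nxt == "*") return(NULL)
      if (aa_cur == aa_nxt) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  perms <- PERMS[[nd]]
  res <- lapply(perms, count_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # every ordering traverses a stop: fall back to counting steps through
    # stops as nonsynonymous
    res <- lapply(perms, function(order) {
      cur <- a; syn <- 0; nonsyn <- 0
      for (pos in diff_pos[order]) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa_cur <- gc[paste(cur, collapse = "")]
        aa_nxt <- gc[paste(nxt, collapse = "")]
        if (!is.na(aa_cur) && !is.na(aa_nxt) && aa_cur == aa_nxt) {
          syn <- syn + 1
        } else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn, nonsyn)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# 61 x 61 lookup matrices of pathway-averaged difference counts
ng_diff_tables <- function() {
  if (!is.null(.ng_cache$sd)) {
    return(list(sd = .ng_cache$sd, nd = .ng_cache$nd))
  }
  cods <- sense_codons()
  n <- length(cods)
  sd <- matrix(0, n, n, dimnames = list(cods, cods))
  ndm <- matrix(0, n, n, dimnames = list(cods, cods))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- ng_codon_diff(cods[i], cods[j])
      sd[i, j] <- sd[j, i] <- d[["syn"]]
      ndm[i, j] <- ndm[j, i] <- d[["nonsyn"]]
    }
  }
  .ng_cache$sd <- sd
  .ng_cache$nd <- ndm
  list(sd = sd, nd = ndm)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * ln(1 - (4/3) * p)`; proportions at or beyond the 3/4
#' saturation bound return `NA`.
#'
#' @param p proportion of differing sites.
#' @return corrected distance (NA where saturated).
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori Ka/Ks estimation
#'
#' Implements the Nei & Gojobori (1986) unweighted-pathway method on a
#' gap-free codon alignment: synonymous/nonsynonymous site counts averaged
#' over the two sequences, pathway-averaged difference counts, and separate
#' Jukes-Cantor corrections of pN and pS. `pS` or `pN` at or above 3/4 is
#' reported as saturated (`NA` for the corrected rate).
#'
#' @param aln a `codon_alignment` (see [codon_align()]), or a list with
#'   `seq_a` and `seq_b` equal-length stop-free codon strings.
#' @return list with `N`, `S` (site counts), `Nd`, `Sd` (difference counts),
#'   `pN`, `pS`, `Ka`, `Ks`, `omega` (Ka/Ks; NA when Ks is 0 or saturated)
#'   and logical `saturated`.
#' @export
nei_gojobori <- function(aln) {
  cod_a <- codon_split(aln$seq_a)
  cod_b <- codon_split(aln$seq_b)
  if (length(cod_a) != length(cod_b)) stop("codon rows differ in length")
  sites <- ng_site_table()
  sa <- sites[cod_a]; sb <- sites[cod_b]
  if (anyNA(sa) || anyNA(sb)) stop("stop codon or invalid codon in alignment")
  n_codons <- length(cod_a)
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * n_codons - S
  tabs <- ng_diff_tables()
  idx <- cbind(match(cod_a, rownames(tabs$sd)), match(cod_b, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       Ka = Ka, Ks = Ks, omega = omega,
       saturated = c(pN = pN >= 0.75, pS = pS >= 0.75))
}

#' Ka/Ks ratio
#'
#' @param ka,ks per-site substitution rates.
#' @return `ka / ks` (NA where `ks` is 0).
#' @export
kaks_ratio <- function(ka, ks) {
  stopifnot(all(ka >= 0, na.rm = TRUE), all(ks >= 0, na.rm = TRUE))
  ifelse(ks > 0, ka / ks, NA_real_)
}

#' Selection class from a Ka/Ks ratio
#'
#' @param omega Ka/Ks ratio(s).
#' @return `"purifying"` (< 1), `"positive"` (> 1) or `"neutral"` (= 1).
#' @export
selection_class <- function(omega) {
  ifelse(is.na(omega), NA_character_,
         ifelse(omega < 1, "purifying",
                ifelse(omega > 1, "positive", "neutral")))
}

#' Divergence time from synonymous divergence
#'
#' Molecular-clock dating `T = Ks / (2 * lambda)`, reported in million
#' years. Pairs with `Ks > ks_max` are discarded (`NA`) to avoid
#' substitution saturation.
#'
#' @param ks synonymous substitutions per synonymous site.
#' @param lambda clock rate in substitutions/site/year (default `1.5e-8`,
#'   the standard grass synonymous rate).
#' @param ks_max saturation cutoff (default 2.0).
#' @return divergence time in Mya (`NA` where discarded).
#' @export
#' @examples
#' divergence_time(0.014907323)  # 0.496910767 Mya
divergence_time <- function(ks, lambda = 1.5e-8, ks_max = 2.0) {
  stopifnot(all(ks >= 0, na.rm = TRUE), lambda > 0)
  t <- ks / (2 * lambda) / 1e6
  t[!is.na(ks) & ks > ks_max] <- NA_real_
  t
}

#' Full duplicate-pair analysis table
#'
#' For each duplicate pair found at the identity/coverage thresholds,
#' computes the codon alignment, Nei-Gojobori Ka and Ks, Ka/Ks, selection
#' class, divergence time and (when gene models are given) the
#' tandem/segmental call — the shape of a published paralogous-pair table.
#'
#' @param proteins named character vector of member proteins.
#' @param cds named character vector of matching coding sequences.
#' @param models optional named list of [gene_model] objects (names = gene
#'   ids) for duplication-type classification.
#' @param identity_min,coverage_min duplicate thresholds (strict).
#' @param lambda,ks_max dating parameters, see [divergence_time()].
#' @return data.frame, one row per duplicate pair.
#' @export
kaks_pairs <- function(proteins, cds, models = NULL,
                       identity_min = 85, coverage_min = 0.75,
                       lambda = 1.5e-8, ks_max = 2.0) {
  dup <- find_duplicates(proteins, identity_min, coverage_min)
  if (nrow(dup) == 0L) {
    return(cbind(dup, ka = numeric(0), ks = numeric(0), omega = numeric(0),
                 selection = character(0), divergence_mya = numeric(0),
                 dup_type = character(0)))
  }
  rows <- lapply(seq_len(nrow(dup)), function(k) {
    a <- dup$gene_a[k]; b <- dup$gene_b[k]
    al <- global_align(proteins[[a]], proteins[[b]])
    ca <- codon_align(cds[[a]], cds[[b]], al$aligned[["a"]], al$aligned[["b"]])
    ng <- nei_gojobori(ca)
    dt <- if (!is.na(ng$Ks)) divergence_time(ng$Ks, lambda, ks_max) else NA_real_
    type <- if (!is.null(models) && a %in% names(models) && b %in% names(models)) {
      classify_duplication(models[[a]], models[[b]], all_models = models)
    } else NA_character_
    data.frame(gene_a = a, gene_b = b,
               identity = dup$identity[k], coverage = dup$coverage[k],
               ka = ng$Ka, ks = ng$Ks, omega = ng$omega,
               selection = selection_class(ng$omega),
               divergence_mya = dt, dup_type = type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
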