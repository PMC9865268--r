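# Family-member selection from domain-search evidence.
#
# Accepts hmmsearch --domtblout and BLAST -outfmt 6 tables from external
# searches, and additionally ships a self-contained position-specific
# scoring-matrix (PSSM) scanner with an empirical E-value calibration so the
# whole pipeline can run with no external tool.

#' Parse a tabular domain-search file
#'
#' Supported dialects:
#' \describe{
#'   \item{`hmmsearch_domtbl`}{HMMER3 `--domtblout`: whitespace-delimited,
#'     `#` comments; per-domain independent E-value (column 13) is used.}
#'   \item{`blast_tab`}{BLAST `-outfmt 6` (12 columns); the subject
#'     (database protein) is taken as the hit, E-value from column 11.}
#' }
#'
#' @param path path to the table.
#' @param dialect `"hmmsearch_domtbl"` or `"blast_tab"`.
#' @return data.frame with columns `protein_id`, `domain_name`, `evalue`,
#'   `ali_start`, `ali_end`, `score`.
#' @export
parse_domain_table <- function(path, dialect = c("hmmsearch_domtbl", "blast_tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(0), domain_name = character(0),
                      evalue = numeric(0), ali_start = integer(0),
                      ali_end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  if (dialect == "hmmsearch_domtbl") {
    need <- 22L
    get <- function(f, i) f[[i]]
    rows <- lapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      if (length(f) < need) {
        stop("domtblout row ", k, " has ", length(f), " fields (need >= ", need, ")")
      }
      ev <- suppressWarnings(as.numeric(f[13]))
      if (is.na(ev)) stop("non-numeric E-value '", f[13], "' on domtblout row ", k)
      data.frame(protein_id = f[1], domain_name = f[4], evalue = ev,
                 ali_start = as.integer(f[18]), ali_end = as.integer(f[19]),
                 score = as.numeric(f[14]), stringsAsFactors = FALSE)
    })
  } else {
    rows <- lapply(seq_along(fields), function(k) {
      f <- fields[[k]]
      if (length(f) < 12L) {
        stop("blast_tab row ", k, " has ", length(f), " fields (need 12)")
      }
      ev <- suppressWarnings(as.numeric(f[11]))
      if (is.na(ev)) stop("non-numeric E-value '", f[11], "' on blast_tab row ", k)
      data.frame(protein_id = f[2], domain_name = f[1], evalue = ev,
                 ali_start = as.integer(f[9]), ali_end = as.integer(f[10]),
                 score = as.numeric(f[12]), stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a position-specific scoring profile from a seed alignment
#'
#' Per-column log-odds scores `log2((f + pc*bg) / ((1 + pc) * bg))` where `f`
#' is the observed residue frequency among non-gap characters, `bg` the
#' background frequency and `pc` the pseudocount weight. Columns with more
#' than 50% gaps are dropped. With `pseudocount = 0`, unobserved residues
#' would score `-Inf`; their score is clamped at `score_floor`.
#'
#' @param seed_alignment character vector of equal-length gap-aligned
#'   protein strings (gaps as `-`), at least 2 sequences.
#' @param pseudocount non-negative pseudocount weight (default 1).
#' @param background named amino-acid frequency vector summing to 1
#'   (default uniform).
#' @param name profile name.
#' @param score_floor lower clamp for log-odds scores, in bits.
#' @return object of class `scoring_profile` with a `scores` matrix
#'   (20 amino acids x positions).
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL, name = "profile",
                          score_floor = -10) {
  if (length(seed_alignment) < 2L) stop("need >= 2 seed sequences")
  L <- unique(nchar(seed_alignment))
  if (length(L) != 1L) stop("seed sequences have unequal aligned lengths")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA20)
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  mat <- do.call(rbind, strsplit(toupper(seed_alignment), ""))
  keep <- colMeans(mat == "-") <= 0.5
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) < 6L) stop("profile has fewer than 6 usable columns")
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-" & col %in% AA20]
    f <- table(factor(col, levels = AA20)) / max(length(col), 1L)
    s <- log2((as.numeric(f) + pseudocount * background[AA20]) /
                ((1 + pseudocount) * background[AA20]))
    pmax(s, score_floor)
  }, numeric(20))
  rownames(scores) <- AA20
  structure(list(name = name, scores = scores, background = background,
                 pseudocount = pseudocount, score_floor = score_floor),
            class = "scoring_profile")
}

#' @export
print.scoring_profile <- function(x, ...) {
  cat(sprintf("<scoring_profile> %s: %d positions, pseudocount %.3g\n",
              x$name, ncol(x$scores), x$pseudocount))
  invisible(x)
}

# summed log-odds of every window of profile width; X/unknown scores 0
window_scores <- function(protein, profile) {
  aa <- seq_chars(toupper(protein))
  L <- ncol(profile$scores)
  n <- length(aa)
  if (n < L) return(numeric(0))
  idx <- match(aa, AA20)
  sc <- profile$scores
  out <- numeric(n - L + 1L)
  # accumulate column by column to stay O(n*L) with vectorized gather
  for (j in seq_len(L)) {
    pos <- seq.int(j, j + n - L)
    col <- sc[, j]
    v <- col[idx[pos]]
    v[is.na(v)] <- 0
    out <- out + v
  }
  out
}

#' Scan a protein with a scoring profile
#'
#' Reports every window whose summed log-odds meets `score_threshold`,
#' greedily merged so that no two reported hits overlap by more than 50% of
#' the window width (the better-scoring window wins). If a `calibration`
#' (see [calibrate_profile()]) is supplied, each hit also carries an
#' empirical E-value.
#'
#' @param protein protein string.
#' @param profile a `scoring_profile`.
#' @param score_threshold minimum window score in bits.
#' @param calibration optional result of [calibrate_profile()].
#' @param protein_id id recorded in the output.
#' @return data.frame with columns `protein_id`, `domain_name`, `evalue`,
#'   `ali_start`, `ali_end`, `score` (empty if the protein is shorter than
#'   the profile).
#' @export
profile_scan <- function(protein, profile, score_threshold,
                         calibration = NULL, protein_id = "query") {
  L <- ncol(profile$scores)
  ws <- window_scores(protein, profile)
  empty <- data.frame(protein_id = character(0), domain_name = character(0),
                      evalue = numeric(0), ali_start = integer(0),
                      ali_end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  hit <- which(ws >= score_threshold)
  if (length(hit) == 0L) return(empty)
  ord <- hit[order(-ws[hit], hit)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(p - kept) > L / 2)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  ev <- if (is.null(calibration)) NA_real_ else profile_evalue(ws[kept], calibration)
  data.frame(protein_id = protein_id, domain_name = profile$name,
             evalue = ev, ali_start = kept, ali_end = kept + L - 1L,
             score = ws[kept], stringsAsFactors = FALSE)
}

#' Calibrate empirical E-values for the profile scanner
#'
#' Karlin-Altschul-style calibration: residues of each query protein are
#' shuffled `n_shuffles` times, the maximum window score per shuffle is
#' recorded, and a Gumbel (extreme-value) distribution is fitted by the
#' method of moments. The E-value of a score `S` in a search over `n_db`
#' sequences is `n_db * P(max score >= S)` under that null. This is an
#' approximation (documented as such): scores are not length-normalized
#' beyond the per-sequence maximum.
#'
#' @param profile a `scoring_profile`.
#' @param proteins named character vector used to build the shuffle null
#'   (composition source).
#' @param n_shuffles shuffles per protein (default 1000 overall draws are
#'   accumulated across proteins).
#' @param seed RNG seed.
#' @return object of class `profile_calibration` (Gumbel `loc`, `scale`,
#'   `n_db`).
#' @export
calibrate_profile <- function(profile, proteins, n_shuffles = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  L <- ncol(profile$scores)
  proteins <- proteins[nchar(proteins) >= L]
  if (length(proteins) == 0L) stop("no protein long enough for the profile")
  draws <- numeric(n_shuffles)
  src <- sample(proteins, n_shuffles, replace = TRUE)
  for (i in seq_len(n_shuffles)) {
    aa <- sample(seq_chars(src[[i]]))
    draws[i] <- max(window_scores(paste(aa, collapse = ""), profile))
  }
  beta <- sd(draws) * sqrt(6) / pi
  mu <- mean(draws) - 0.5772156649 * beta
  structure(list(loc = mu, scale = beta, n_db = length(proteins),
                 n_shuffles = n_shuffles),
            class = "profile_calibration")
}

# per-sequence tail probability under the fitted Gumbel, times database size
profile_evalue <- function(score, calibration) {
  z <- (score - calibration$loc) / calibration$scale
  p <- 1 - exp(-exp(-z))
  # numerically stable tail for large scores
  small <- exp(-z) < 1e-8
  p[small] <- exp(-z[small])
  p * calibration$n_db
}

#' Score threshold corresponding to a target E-value
#'
#' Inverts the calibration of [calibrate_profile()].
#'
#' @param calibration a `profile_calibration`.
#' @param evalue target E-value.
#' @return score in bits.
#' @export
score_at_evalue <- function(calibration, evalue) {
  p <- evalue / calibration$n_db
  calibration$loc - calibration$scale * log(p)
}

#' Select family members from domain hits
#'
#' Keeps protein ids with at least one hit at `evalue <= evalue_max`. When
#' hits carry a `source` column and `require_sources = "all"`, a protein
#' must qualify in every source present in the table; the default `"any"`
#' takes the union of evidence sources (the usual combined HMM+BLAST
#' candidate pool). Redundancy is removed by collapsing isoforms to one
#' representative per locus when an isoform map is given.
#'
#' @param hits data.frame of domain hits (as from [parse_domain_table()] or
#'   [profile_scan()]), optionally with a `source` column.
#' @param evalue_max inclusion threshold (default `1e-10`, the conventional
#'   stringency for family surveys).
#' @param require_sources `"any"` or `"all"`.
#' @param isoform_map optional named character vector protein_id -> gene id.
#' @param protein_lengths optional named numeric vector used to pick the
#'   longest isoform per gene; defaults to lexicographic choice.
#' @return sorted character vector of member ids (protein ids, or one
#'   representative per gene when `isoform_map` is given).
#' @export
select_members <- function(hits, evalue_max = 1e-10,
                           require_sources = c("any", "all"),
                           isoform_map = NULL, protein_lengths = NULL) {
  require_sources <- match.arg(require_sources)
  if (nrow(hits) == 0L) return(character(0))
  pass <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(pass) == 0L) return(character(0))
  if (require_sources == "all" && "source" %in% names(hits)) {
    sources <- unique(hits$source)
    tab <- unique(pass[, c("protein_id", "source")])
    cnt <- table(tab$protein_id)
    ids <- names(cnt)[cnt == length(sources)]
  } else {
    ids <- unique(pass$protein_id)
  }
  if (!is.null(isoform_map)) {
    genes <- isoform_map[ids]
    genes[is.na(genes)] <- ids[is.na(genes)]
    pick <- vapply(split(ids, genes), function(iso) {
      if (!is.null(protein_lengths)) {
        iso[order(-protein_lengths[iso], iso)][1L]
      } else sort(iso)[1L]
    }, character(1))
    ids <- unname(pick)
  }
  sort(ids)
}
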