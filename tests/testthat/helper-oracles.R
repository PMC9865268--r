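# Independent oracles used by the test suite. Each re-derives an expected
# value by a brute-force route that shares no code with the implementation
# it checks.

# --- exhaustive affine-gap Needleman-Wunsch (three-state DP) ----------------
# Scoring convention matches the package contract: a gap of length k costs
# gap_open + k * gap_extend.
oracle_global_score <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(neg, n + 1, m + 1)  # ends in gap in b (a aligned to '-')
  Y <- matrix(neg, n + 1, m + 1)  # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -gap_open - i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- -gap_open - j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive pathway enumeration for codon difference counting -----------
# Depth-first enumeration of every ordering of the differing positions,
# dropping orderings that pass through a stop codon; equal weights.
oracle_codon_diff <- function(cod_a, cod_b) {
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(cod_a, "")[[1]]; b <- strsplit(cod_b, "")[[1]]
  diff <- which(a != b)
  if (length(diff) == 0L) return(c(syn = 0, nonsyn = 0))
  acc <- list()
  walk <- function(cur, remaining, syn, nonsyn) {
    if (length(remaining) == 0L) {
      acc[[length(acc) + 1L]] <<- c(syn, nonsyn)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- b[pos]
      if (gc[paste(nxt, collapse = "")] == "*") next
      step_syn <- gc[paste(cur, collapse = "")] == gc[paste(nxt, collapse = "")]
      walk(nxt, setdiff(remaining, pos),
           syn + as.numeric(step_syn), nonsyn + as.numeric(!step_syn))
    }
  }
  walk(a, diff, 0, 0)
  if (length(acc) == 0L) return(NULL)  # all orderings hit a stop
  m <- do.call(rbind, acc)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

oracle_pair_diffs <- function(cds_a, cds_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(cds_a); cb <- split3(cds_b)
  tot <- c(syn = 0, nonsyn = 0)
  for (k in seq_along(ca)) {
    d <- oracle_codon_diff(ca[k], cb[k])
    if (!is.null(d)) tot <- tot + d
  }
  tot
}

# --- dense grid search for the isoelectric point ----------------------------
oracle_pi_grid <- function(protein, step = 1e-4, pka_set = "bjellqvist") {
  ph <- seq(0, 14, by = step)
  q <- net_charge(protein, ph, pka_set)
  ph[which.min(abs(q))]
}

# --- naive double-loop instability index ------------------------------------
oracle_instability <- function(protein) {
  diwv <- genefamkit:::DIWV
  aa <- strsplit(protein, "")[[1]]
  total <- 0
  for (i in seq_len(length(aa) - 1)) {
    for (j in seq_along(aa)) {
      if (j == i + 1) total <- total + diwv[aa[i], aa[j]]
    }
  }
  10 * total / length(aa)
}

# --- small random peptide/protein helpers -----------------------------------
random_peptide <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}
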