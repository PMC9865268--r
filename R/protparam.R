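# Physicochemical profiling of proteins from sequence alone: molecular
# weight, theoretical pI, instability index, aliphatic index, GRAVY.
# All constant tables are the published ones used by the standard web
# calculators (average residue masses, Bjellqvist/EMBOSS pKa sets, the
# Guruprasad dipeptide instability weights, Kyte-Doolittle hydropathy).

# ExPASy average (isotope-averaged) residue masses, Da
AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Kyte & Doolittle (1982) hydropathy values
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# pKa sets for the charge model. "bjellqvist" is the ExPASy/Compute-pI set:
# side chains plus residue-specific N-terminal pKa values; "emboss" is the
# EMBOSS iep set.
PKA_SETS <- list(
  bjellqvist = list(
    cterm = 3.55,
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70),
    pos = c(H = 5.98, K = 10.00, R = 12.00),
    neg = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  ),
  emboss = list(
    cterm = 3.6,
    nterm_default = 8.6,
    nterm = c(),
    pos = c(H = 6.5, K = 10.8, R = 12.5),
    neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
)

check_protein <- function(protein, min_len = 1L) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    stop("protein must be a non-empty string")
  }
  aa <- seq_chars(toupper(protein))
  bad <- setdiff(unique(aa), c(names(AA_MASS), "X"))
  if (length(bad) > 0L) {
    stop("invalid amino-acid character(s): ", paste(bad, collapse = ", "))
  }
  if (length(aa) < min_len) {
    stop("protein shorter than ", min_len, " residue(s)")
  }
  aa
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water. `X` contributes the
#' unweighted mean residue mass of the 20 standard amino acids.
#'
#' @param protein amino-acid string.
#' @return mass in Daltons.
#' @export
molecular_weight <- function(protein) {
  aa <- check_protein(protein)
  m <- AA_MASS[aa]
  m[is.na(m)] <- mean(AA_MASS)
  sum(m) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over the N-terminus, C-terminus and the ionizable
#' side chains (D, E, C, Y, H, K, R).
#'
#' @param protein amino-acid string.
#' @param pH pH value(s); vectorized.
#' @param pka_set `"bjellqvist"` (ExPASy) or `"emboss"`.
#' @return net charge at each pH.
#' @export
net_charge <- function(protein, pH, pka_set = c("bjellqvist", "emboss")) {
  pka_set <- match.arg(pka_set)
  aa <- check_protein(protein)
  pk <- PKA_SETS[[pka_set]]
  nterm_pk <- pk$nterm[aa[1L]]
  if (is.na(nterm_pk) || is.null(nterm_pk)) nterm_pk <- pk$nterm_default
  pos_pk <- c(unname(nterm_pk), unname(pk$pos[aa[aa %in% names(pk$pos)]]))
  neg_pk <- c(pk$cterm, unname(pk$neg[aa[aa %in% names(pk$neg)]]))
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pk))) - sum(1 / (1 + 10^(neg_pk - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH at which the net charge vanishes, found by bisection on \[0, 14\].
#' The charge is strictly decreasing in pH, so the root is unique.
#'
#' @param protein amino-acid string.
#' @param tol bisection tolerance in pH units.
#' @param pka_set `"bjellqvist"` (ExPASy, default) or `"emboss"`.
#' @return pI in pH units.
#' @export
theoretical_pi <- function(protein, tol = 1e-3, pka_set = c("bjellqvist", "emboss")) {
  pka_set <- match.arg(pka_set)
  check_protein(protein)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(protein, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' Guruprasad et al. dipeptide-weight statistic:
#' `II = (10 / L) * sum(DIWV(x_i, x_{i+1}))` over consecutive residue pairs.
#' Dipeptides containing `X` contribute 0. Values above 40 conventionally
#' predict an unstable protein in vitro.
#'
#' @param protein amino-acid string, length >= 2.
#' @return dimensionless instability index.
#' @export
instability_index <- function(protein) {
  aa <- check_protein(protein, min_len = 2L)
  L <- length(aa)
  i1 <- match(aa[-L], DIWV_AA)
  i2 <- match(aa[-1L], DIWV_AA)
  w <- ifelse(is.na(i1) | is.na(i2), 0, DIWV[cbind(i1, i2)])
  (10 / L) * sum(w)
}

#' Aliphatic index
#'
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with `X` the mole
#' percent of each residue over the full sequence length.
#'
#' @param protein amino-acid string.
#' @return dimensionless aliphatic index.
#' @export
aliphatic_index <- function(protein) {
  aa <- check_protein(protein)
  L <- length(aa)
  molpct <- function(r) 100 * sum(aa == r) / L
  molpct("A") + 2.9 * molpct("V") + 3.9 * (molpct("I") + molpct("L"))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over residues; `X` is ignored in both the
#' numerator and the denominator.
#'
#' @param protein amino-acid string.
#' @return dimensionless GRAVY score; negative values indicate hydrophilic
#'   proteins.
#' @export
gravy <- function(protein) {
  aa <- check_protein(protein)
  h <- KYTE_DOOLITTLE[aa]
  h <- h[!is.na(h)]
  if (length(h) == 0L) stop("no standard residues in sequence")
  mean(h)
}

#' Classify hydropathy from a GRAVY score
#'
#' Strictly negative GRAVY is hydrophilic, otherwise hydrophobic (the strict
#' zero threshold is the only reading consistent with a clean
#' negative/positive dichotomy of printed GRAVY values).
#'
#' @param gravy numeric GRAVY value(s).
#' @return character vector, `"hydrophilic"` or `"hydrophobic"`.
#' @export
classify_hydropathy <- function(gravy) {
  stopifnot(is.numeric(gravy), all(is.finite(gravy)))
  ifelse(gravy < 0, "hydrophilic", "hydrophobic")
}

#' Physicochemical profile table
#'
#' Computes, per protein, the columns of a standard family-characterization
#' table: length, molecular weight, theoretical pI, instability index (with
#' stable/unstable call at II > 40), aliphatic index, GRAVY and the
#' hydrophilic/hydrophobic call.
#'
#' @param proteins named character vector of protein sequences.
#' @param pka_set pKa set for the pI calculation.
#' @return data.frame, one row per protein.
#' @export
physicochemical_profile <- function(proteins, pka_set = "bjellqvist") {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    p <- proteins[[id]]
    g <- gravy(p)
    ii <- instability_index(p)
    data.frame(
      protein_id = id,
      length = nchar(p),
      mw = molecular_weight(p),
      pi = theoretical_pi(p, pka_set = pka_set),
      instability_index = ii,
      stability_class = if (ii > 40) "unstable" else "stable",
      aliphatic_index = aliphatic_index(p),
      gravy = g,
      hydropathy_class = classify_hydropathy(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
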