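# Seeded synthetic-data generators with planted ground truth for every
# pipeline stage: a multi-chromosome genome carrying a protein family with a
# shared domain, duplicate pairs evolved at known omega and Ks, promoters
# with planted cis-elements, and FPKM/Ct/phenotype tables with known
# effects. Every generator is a pure function of (parameters, seed).

# 60-residue consensus of the planted family domain. The sequence is an
# invented subtilase-flavoured motif (Asp...Gly-Thr-His...Gly-Thr-Ser core);
# only its conservation, not its biology, matters to the generators.
FAMILY_DOMAIN <- paste0(
  "AVIDTGIDASHPDLKGKVIGWRDFVNGKDTPYDDNGHGTHVAGTIAALDNGVGVVGVAPG"
)

aa_alphabet <- function() AA20

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute residues at the given per-site rate (always to a different one)
mutate_protein <- function(protein, rate) {
  aa <- seq_chars(protein)
  hit <- runif(length(aa)) < rate
  aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1L), character(1))
  paste(aa, collapse = "")
}

# codons for each amino acid under the standard code (sense codons only)
codons_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

# back-translate a protein with uniformly random synonymous codons
back_translate <- function(protein) {
  tab <- codons_for_aa()
  aa <- seq_chars(protein)
  paste(vapply(aa, function(a) {
    opts <- tab[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Random stop-free coding sequence
#'
#' @param n_codons number of sense codons.
#' @param seed optional RNG seed.
#' @return nucleotide string of length `3 * n_codons` with no stop codons.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  cods <- sense_codons()
  paste(sample(cods, n_codons, replace = TRUE), collapse = "")
}

#' Plant cis-elements into a random promoter
#'
#' Writes catalogue elements at the requested positions (reverse-
#' complemented for minus-strand plants) on an i.i.d. random background.
#' With `scrub = TRUE`, background windows that spuriously match any
#' catalogue element and do not overlap a planted element are mutated away,
#' so a scan recovers the planted hits cleanly.
#'
#' @param length promoter length in bp.
#' @param plants data.frame with columns `element`, `position` (1-based
#'   start on the promoter), `strand` (`"+"`/`"-"`); positions must be in
#'   bounds and non-overlapping.
#' @param catalog cis-element catalogue (see [load_catalog()]).
#' @param scrub mutate spurious background matches away (default TRUE).
#' @param seed optional RNG seed.
#' @return list with `promoter` (string) and `truth` (the `plants` table
#'   with the element category and written sequence added).
#' @export
plant_cis_elements <- function(length = 2000L, plants = NULL,
                               catalog = load_catalog(), scrub = TRUE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(plants) || nrow(plants) == 0L) {
    plants <- data.frame(element = character(0), position = integer(0),
                         strand = character(0), stringsAsFactors = FALSE)
  }
  idx <- match(plants$element, catalog$name)
  if (anyNA(idx)) {
    stop("element(s) not in catalogue: ",
         paste(plants$element[is.na(idx)], collapse = ", "))
  }
  cons <- catalog$consensus[idx]
  len_el <- nchar(cons)
  if (any(plants$position < 1L | plants$position + len_el - 1L > length)) {
    stop("planted element out of promoter bounds")
  }
  if (nrow(plants) > 1L) {
    ord <- order(plants$position)
    starts <- plants$position[ord]; ends <- starts + len_el[ord] - 1L
    if (any(starts[-1L] <= ends[-base::length(starts)])) {
      stop("planted elements overlap")
    }
  }
  seq <- seq_chars(random_dna(length))
  written <- character(nrow(plants))
  spans <- cbind(plants$position, plants$position + len_el - 1L)
  for (k in seq_len(nrow(plants))) {
    w <- if (plants$strand[k] == "-") revcomp(cons[k]) else cons[k]
    seq[spans[k, 1]:spans[k, 2]] <- seq_chars(w)
    written[k] <- w
  }
  promoter <- paste(seq, collapse = "")
  if (scrub) {
    in_planted <- function(pos) {
      nrow(plants) > 0L && any(pos >= spans[, 1] & pos <= spans[, 2])
    }
    for (round in 1:100) {
      hits <- scan_promoter(promoter, catalog)
      el_len <- nchar(catalog$consensus[match(hits$element, catalog$name)])
      truth_key <- paste(plants$element, plants$position, plants$strand)
      spurious <- !(paste(hits$element, hits$start, hits$strand) %in% truth_key)
      if (!any(spurious)) break
      changed <- FALSE
      seq <- seq_chars(promoter)
      for (h in which(spurious)) {
        window <- hits$start[h]:(hits$start[h] + el_len[h] - 1L)
        free <- window[!vapply(window, in_planted, logical(1))]
        if (length(free) == 0L) next  # unavoidable overlap with a plant
        pos <- free[1L]
        seq[pos] <- sample(setdiff(BASES, seq[pos]), 1L)
        changed <- TRUE
      }
      promoter <- paste(seq, collapse = "")
      if (!changed) break
    }
  }
  truth <- cbind(plants,
                 data.frame(category = catalog$category[idx],
                            written = written, stringsAsFactors = FALSE))
  list(promoter = promoter, truth = truth)
}

# split a CDS body into n_exons exon pieces with random intron lengths;
# returns local (1-based) exon intervals within the assembled body and the
# assembled body sequence
lay_out_exons <- function(cds, n_exons, intron_range = c(60L, 200L)) {
  nc <- nchar(cds)
  stopifnot(n_exons >= 1L, n_exons <= nc)
  cuts <- if (n_exons > 1L) sort(sample.int(nc - 1L, n_exons - 1L)) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nc)
  body <- ""
  iv <- matrix(0L, nrow = n_exons, ncol = 2L)
  pos <- 0L
  for (e in seq_len(n_exons)) {
    piece <- substring(cds, starts[e], ends[e])
    iv[e, ] <- c(pos + 1L, pos + nchar(piece))
    body <- paste0(body, piece)
    pos <- pos + nchar(piece)
    if (e < n_exons) {
      intron <- random_dna(sample(intron_range[1]:intron_range[2], 1L))
      body <- paste0(body, intron)
      pos <- pos + nchar(intron)
    }
  }
  list(body = body, exon_intervals = iv)
}

#' Simulate a genome carrying a planted gene family
#'
#' Generates a small multi-chromosome genome in which `n_members` genes
#' share a planted, conserved protein domain and fall into well-separated
#' phylogenetic classes, while `n_decoys` genes lack the domain. Member
#' proteins are equal-length so they double as a multiple alignment. One
#' class is a tight cluster of near-identical paralogs, planting duplicate
#' pairs above the conventional >85% identity / >0.75 coverage thresholds.
#' Member promoters carry planted cis-elements (every member gets at least
#' one drought-diagnostic ABRE or MBS). Exon counts span 1-34, so intron
#' counts span 0-33.
#'
#' All coordinates and sequences round-trip exactly through [write_gff3()] /
#' [read_gff3()] and [extract_cds()] / [extract_promoter()].
#'
#' @param n_chromosomes number of chromosomes (default 7).
#' @param n_members planted family size (default 18).
#' @param n_decoys non-family genes (default 50).
#' @param seed RNG seed; same seed, same output, byte for byte.
#' @param class_sizes member count per planted class (sums to `n_members`).
#' @param member_length member protein length in residues.
#' @param promoter_length planted promoter length in bp.
#' @param catalog cis-element catalogue for promoter planting.
#' @param dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `proteome.fa`, `cds.fa` there.
#' @return list with `genome`, `models` (named list of [gene_model]),
#'   `proteins`, `cds`, `alignment` (member proteins),
#'   `seed_domain_alignment` (domain seed set for [build_profile()]) and
#'   `truth` (members, decoys, classes, dup_pairs, cis, domain window,
#'   seed).
#' @export
simulate_family_genome <- function(n_chromosomes = 7L, n_members = 18L,
                                   n_decoys = 50L, seed = 1L,
                                   class_sizes = c(9L, 6L, 3L),
                                   member_length = 300L,
                                   promoter_length = 2000L,
                                   catalog = load_catalog(),
                                   dir = NULL) {
  stopifnot(n_members >= 2L, sum(class_sizes) == n_members,
            member_length >= nchar(FAMILY_DOMAIN) + 40L)
  set.seed(as.integer(seed))

  dom_len <- nchar(FAMILY_DOMAIN)
  dom_start <- 101L
  dom_span <- dom_start:(dom_start + dom_len - 1L)

  # root family protein with the domain planted at a fixed offset
  root <- seq_chars(random_protein(member_length))
  root[dom_span] <- seq_chars(FAMILY_DOMAIN)
  root <- paste(root, collapse = "")

  mutate_member <- function(protein, rate_out, rate_dom) {
    aa <- seq_chars(protein)
    out <- paste(aa[-dom_span], collapse = "")
    dom <- paste(aa[dom_span], collapse = "")
    out <- seq_chars(mutate_protein(out, rate_out))
    dom <- seq_chars(mutate_protein(dom, rate_dom))
    res <- character(member_length)
    res[dom_span] <- dom
    res[-dom_span] <- out
    paste(res, collapse = "")
  }

  # class ancestors diverge strongly; members within a class moderately;
  # the last class is a tight paralog cluster planting duplicate pairs
  n_classes <- length(class_sizes)
  ancestors <- replicate(n_classes, mutate_member(root, 0.35, 0.08))
  member_prot <- character(0)
  member_class <- integer(0)
  for (ci in seq_len(n_classes)) {
    tight <- ci == n_classes
    for (m in seq_len(class_sizes[ci])) {
      p <- if (tight) mutate_member(ancestors[ci], 0.015, 0.010)
           else mutate_member(ancestors[ci], 0.18, 0.02)
      member_prot <- c(member_prot, p)
      member_class <- c(member_class, ci)
    }
  }

  decoy_prot <- vapply(seq_len(n_decoys),
                       function(i) random_protein(sample(200:400, 1L)),
                       character(1))

  n_genes <- n_members + n_decoys
  ids <- sprintf("gene%03d", seq_len(n_genes))
  member_idx <- sort(sample.int(n_genes, n_members))
  member_ids <- ids[member_idx]
  decoy_ids <- setdiff(ids, member_ids)

  proteins <- character(n_genes)
  names(proteins) <- ids
  proteins[member_ids] <- member_prot
  proteins[decoy_ids] <- decoy_prot
  classes <- setNames(member_class, member_ids)

  exon_counts <- setNames(integer(n_genes), ids)
  exon_counts[member_ids] <- sample(1:34, n_members, replace = TRUE)
  exon_counts[decoy_ids] <- sample(1:10, n_decoys, replace = TRUE)

  # promoter planting: every member carries ABRE or MBS plus extras
  extra_pool <- c("LTR", "ARE", "TGACG-motif", "G-box", "Box4", "CAT-box")
  cis_truth <- list()
  promoters <- setNames(character(n_genes), ids)
  for (i in seq_len(n_genes)) {
    id <- ids[i]
    if (id %in% member_ids) {
      core <- if (match(id, member_ids) %% 2L == 1L) "ABRE" else "MBS"
      extras <- sample(extra_pool, sample(1:2, 1L))
      els <- c(core, extras)
      # well-spaced slots keep plants non-overlapping
      slots <- sort(sample(seq(50L, promoter_length - 60L, by = 30L), length(els)))
      plants <- data.frame(element = els, position = slots,
                           strand = sample(c("+", "-"), length(els), replace = TRUE),
                           stringsAsFactors = FALSE)
      pc <- plant_cis_elements(promoter_length, plants, catalog, scrub = TRUE)
      promoters[id] <- pc$promoter
      pc$truth$gene_id <- id
      cis_truth[[length(cis_truth) + 1L]] <- pc$truth
    } else {
      promoters[id] <- random_dna(promoter_length)
    }
  }
  cis_truth <- do.call(rbind, cis_truth)

  # assemble chromosomes
  cds <- setNames(vapply(ids, function(id) {
    paste0(back_translate(proteins[[id]]),
           sample(c("TAA", "TGA", "TAG"), 1L))
  }, character(1)), ids)

  chrom_of <- setNames(sample.int(n_chromosomes, n_genes, replace = TRUE), ids)
  strand_of <- setNames(sample(c("+", "-"), n_genes, replace = TRUE), ids)
  chrom_seq <- setNames(rep("", n_chromosomes),
                        sprintf("chr%d", seq_len(n_chromosomes)))
  models <- list()

  for (ci in seq_len(n_chromosomes)) {
    cname <- sprintf("chr%d", ci)
    here <- ids[chrom_of == ci]
    cursor <- 0L
    pieces <- character(0)
    for (id in here) {
      spacer <- random_dna(sample(300:800, 1L))
      lay <- lay_out_exons(cds[[id]], exon_counts[[id]])
      local <- paste0(promoters[[id]], lay$body)
      llen <- nchar(local)
      s <- cursor + nchar(spacer) + 1L  # genome start of the gene block
      if (strand_of[[id]] == "+") {
        iv <- lay$exon_intervals + promoter_length + (s - 1L)
        block <- local
      } else {
        # local position p maps to genome position s + llen - p
        iv0 <- lay$exon_intervals + promoter_length
        iv <- cbind(s + llen - iv0[, 2], s + llen - iv0[, 1])
        iv <- iv[order(iv[, 1]), , drop = FALSE]
        block <- revcomp(local)
      }
      models[[id]] <- gene_model(
        gene_id = id, transcript_id = paste0(id, ".t1"),
        chromosome = cname, strand = strand_of[[id]],
        cds_intervals = iv, exon_intervals = iv
      )
      pieces <- c(pieces, spacer, block)
      cursor <- cursor + nchar(spacer) + llen
    }
    pieces <- c(pieces, random_dna(500L))
    chrom_seq[cname] <- paste(pieces, collapse = "")
  }

  # planted duplicate pairs: all pairs within the tight class
  tight_ids <- member_ids[member_class == n_classes]
  dup_pairs <- if (length(tight_ids) >= 2L) {
    cmb <- combn(sort(tight_ids), 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0))
  }

  # seed alignment emulating a curated domain seed set
  seed_domain_alignment <- vapply(seq_len(8L),
                                  function(i) mutate_protein(FAMILY_DOMAIN, 0.05),
                                  character(1))

  alignment <- setNames(proteins[member_ids], member_ids)

  out <- list(
    genome = chrom_seq,
    models = models[ids],
    proteins = proteins,
    cds = cds,
    alignment = alignment,
    seed_domain_alignment = seed_domain_alignment,
    truth = list(
      members = member_ids, decoys = decoy_ids, classes = classes,
      dup_pairs = dup_pairs, cis = cis_truth,
      domain_start = dom_start, domain_length = dom_len,
      promoter_length = promoter_length, seed = as.integer(seed)
    )
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(out$genome, file.path(dir, "genome.fa"))
    write_fasta(out$proteins, file.path(dir, "proteome.fa"))
    write_fasta(out$cds, file.path(dir, "cds.fa"))
    write_gff3(out$models, file.path(dir, "annotation.gff3"))
  }
  out
}

#' Evolve a duplicate coding-sequence pair at known Ks and omega
#'
#' Applies a Jukes-Cantor-style substitution process independently down two
#' lineages from a common ancestral CDS. Proposals are uniform over sites
#' and alternative bases; stop-creating changes are rejected; for
#' `omega <= 1` nonsynonymous proposals are accepted with probability
#' `omega`, for `omega > 1` synonymous proposals are thinned by `1/omega`.
#' Each lineage realizes a Poisson number of synonymous events with mean
#' `target_ks * S / 2` (S = Nei-Gojobori synonymous sites of the ancestor),
#' so the expected pairwise synonymous divergence is `target_ks`. The model
#' deliberately matches the Nei-Gojobori estimator's assumptions, so
#' recovery tests probe the estimator rather than model mismatch.
#'
#' @param ancestral_cds stop-free CDS (length divisible by 3).
#' @param target_ks target pairwise synonymous substitutions per site.
#' @param omega target Ka/Ks (>= 0).
#' @param seed RNG seed.
#' @return list with `cds_a`, `cds_b`, and realized per-lineage event
#'   counts `n_syn`, `n_nonsyn`.
#' @export
evolve_codon_pair <- function(ancestral_cds, target_ks, omega, seed = 1L) {
  set.seed(as.integer(seed))
  stopifnot(target_ks >= 0, omega >= 0)
  cods <- codon_split(toupper(ancestral_cds))
  gc <- Biostrings::GENETIC_CODE
  if (any(is.na(gc[cods])) || any(gc[cods] == "*")) {
    stop("ancestral CDS must be stop-free standard codons")
  }
  if (target_ks > 2) {
    warning("target Ks ", target_ks, " is beyond the usual saturation cutoff (2.0)")
  }
  S0 <- sum(ng_site_table()[cods])
  evolve_lineage <- function(codons) {
    m <- rpois(1L, target_ks * S0 / 2)
    n_syn <- 0L; n_nonsyn <- 0L
    guard <- 0L
    while (n_syn < m) {
      guard <- guard + 1L
      if (guard > 1e6) stop("substitution process failed to reach target")
      ci <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      cur <- seq_chars(codons[ci])
      b <- sample(setdiff(BASES, cur[pos]), 1L)
      nxt <- cur; nxt[pos] <- b
      nxt_cod <- paste(nxt, collapse = "")
      if (gc[nxt_cod] == "*") next
      syn <- gc[nxt_cod] == gc[codons[ci]]
      if (syn) {
        if (omega > 1 && runif(1) > 1 / omega) next
        codons[ci] <- nxt_cod
        n_syn <- n_syn + 1L
      } else {
        if (omega <= 1) {
          if (runif(1) > omega) next
        }
        codons[ci] <- nxt_cod
        n_nonsyn <- n_nonsyn + 1L
      }
    }
    list(codons = codons, n_syn = n_syn, n_nonsyn = n_nonsyn)
  }
  a <- evolve_lineage(cods)
  b <- evolve_lineage(cods)
  list(cds_a = paste(a$codons, collapse = ""),
       cds_b = paste(b$codons, collapse = ""),
       n_syn = c(a = a$n_syn, b = b$n_syn),
       n_nonsyn = c(a = a$n_nonsyn, b = b$n_nonsyn))
}

#' Simulate FPKM, qPCR Ct and phenotype tables with known effects
#'
#' Generates the three tabular inputs of a drought-response expression
#' study: a genes x tissues FPKM matrix (log-normal around per-gene means),
#' a long-format qPCR Ct table whose 2^-ddCt fold changes follow a planted
#' truth array, and a phenotype table (fresh/turgid/dry weights consistent
#' with a declining relative-water-content trajectory, plus survival
#' counts).
#'
#' @param design list with elements `lines` (character), `timepoints`
#'   (numeric, first = control), `genes` (character), `true_fold` (array
#'   gene x line x timepoint of planted fold changes relative to the first
#'   line at the first timepoint), and optional `reference_gene`,
#'   `replicates`, `ct_sd`, `n_tissues`, `fpkm_meanlog`, `fpkm_sdlog`,
#'   `wilt_rate` (per-line RWC decline per day), `survival_p` (per-line
#'   water-stress survival probability), `n_plants`.
#' @param seed RNG seed.
#' @return list with `fpkm`, `ct`, `phenotype`, `truth`.
#' @export
simulate_tables <- function(design = default_table_design(), seed = 1L) {
  set.seed(as.integer(seed))
  lines <- design$lines
  tps <- design$timepoints
  genes <- design$genes
  fold <- design$true_fold
  stopifnot(identical(dim(fold), c(length(genes), length(lines), length(tps))))
  reference_gene <- design$reference_gene %||% "actin"
  reps <- design$replicates %||% 3L
  ct_sd <- design$ct_sd %||% 0.15
  if (ct_sd < 0) stop("negative Ct noise SD")
  n_tissues <- design$n_tissues %||% 23L
  meanlog <- design$fpkm_meanlog %||% setNames(runif(length(genes), 0, 4), genes)
  sdlog <- design$fpkm_sdlog %||% 0.5
  if (sdlog < 0) stop("negative FPKM noise SD")

  fpkm <- matrix(stats::rlnorm(length(genes) * n_tissues,
                               meanlog = rep(meanlog, n_tissues),
                               sdlog = sdlog),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("tissue%02d", seq_len(n_tissues))))

  ct_base <- 26; ct_ref <- 20
  rows <- list()
  for (li in seq_along(lines)) for (ti in seq_along(tps)) {
    sample_id <- paste0(lines[li], "_d", tps[ti])
    for (gi in seq_along(genes)) {
      ct_t <- ct_base - log2(fold[gi, li, ti]) + rnorm(reps, 0, ct_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, gene = genes[gi], ct = ct_t,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample_id, gene = reference_gene,
      ct = ct_ref + rnorm(reps, 0, ct_sd), stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, rows)

  wilt <- design$wilt_rate %||% setNames(seq(2.0, 4.5, length.out = length(lines)), lines)
  surv_p <- design$survival_p %||% setNames(seq(0.65, 0.2, length.out = length(lines)), lines)
  n_plants <- design$n_plants %||% 16L
  ph <- list()
  for (li in seq_along(lines)) for (trt in c("WW", "WS")) for (tp in tps) {
    rwc <- if (trt == "WW") 95 else max(95 - wilt[[lines[li]]] * tp, 20)
    dw <- 0.9 + rnorm(1, 0, 0.03)
    tw <- dw + 2.0 + rnorm(1, 0, 0.05)
    fw <- dw + (rwc / 100) * (tw - dw)
    surv <- if (trt == "WW") n_plants else rbinom(1, n_plants, surv_p[[lines[li]]])
    ph[[length(ph) + 1L]] <- data.frame(
      line = lines[li], treatment = trt, day = tp,
      fresh_weight = fw, turgid_weight = tw, dry_weight = dw,
      survived = surv, total = n_plants, stringsAsFactors = FALSE)
  }
  phenotype <- do.call(rbind, ph)

  list(fpkm = fpkm, ct = ct, phenotype = phenotype,
       truth = list(true_fold = fold, design = design, seed = as.integer(seed),
                    calibrator_sample = paste0(lines[1], "_d", tps[1]),
                    reference_gene = reference_gene))
}

#' Default design for [simulate_tables()]
#'
#' Three inbred lines (one drought-tolerant, one intermediate, one
#' sensitive), five drought timepoints, six family genes. Four genes are
#' planted with drought-induced folds ordered tolerant > intermediate >
#' sensitive; two genes with the opposite ordering.
#'
#' @return design list, see [simulate_tables()].
#' @export
default_table_design <- function() {
  lines <- c("tolerant", "intermediate", "sensitive")
  tps <- c(0, 3, 7, 10, 14)
  genes <- sprintf("fam%d", 1:6)
  fold <- array(1, dim = c(length(genes), length(lines), length(tps)),
                dimnames = list(genes, lines, tps))
  induction <- c(8, 4, 1.5)     # tolerant > intermediate > sensitive
  repression <- c(0.25, 0.5, 1) # mirrored for negatively correlated genes
  ramp <- c(0, 0.5, 1, 1, 0.75) # induction profile over the time course
  for (ti in seq_along(tps)) {
    for (li in seq_along(lines)) {
      fold[1:4, li, ti] <- 1 * (induction[li] / 1)^ramp[ti]
      fold[5:6, li, ti] <- 1 * (repression[li] / 1)^ramp[ti]
    }
  }
  list(lines = lines, timepoints = tps, genes = genes, true_fold = fold,
       reference_gene = "actin", replicates = 3L, ct_sd = 0.15)
}
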