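# Duplicate detection, codon alignment, Nei-Gojobori estimation and
# divergence dating.

test_that("global_align reports identity, coverage and the optimal affine-gap score", {
  al <- global_align("MKVLAW", "MKVLAW")
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 1.0)

  # a 3-residue tail against a 6-residue sequence: coverage 1/2 by definition
  al2 <- global_align("ACD", "ACDEEE")
  expect_equal(al2$coverage, 0.5)

  # score equals the exhaustive three-state DP oracle on short pairs
  set.seed(7)
  for (i in 1:15) {
    a <- random_peptide(sample(3:8, 1))
    b <- random_peptide(sample(3:8, 1))
    expect_equal(global_align(a, b)$score, oracle_global_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("find_duplicates applies strict thresholds and pins the boundary", {
  # identical 20-mers except 3 mismatches: identity exactly 85% -> excluded
  a <- "MKVLAWDDEEFFGGHHIIKK"
  b <- "MKVLAWDDEEFFGGHHIAAA"
  al <- global_align(a, b)
  expect_equal(al$identity, 85)
  dup <- find_duplicates(c(x = a, y = b), identity_min = 85, coverage_min = 0.5)
  expect_equal(nrow(dup), 0L)
  # one mismatch fewer crosses the strict boundary
  b2 <- "MKVLAWDDEEFFGGHHIIAA"
  dup2 <- find_duplicates(c(x = a, y = b2), identity_min = 85, coverage_min = 0.5)
  expect_equal(nrow(dup2), 1L)

  # all-dissimilar set
  set.seed(9)
  rand <- setNames(vapply(1:4, function(i) random_peptide(60), character(1)),
                   paste0("r", 1:4))
  expect_equal(nrow(find_duplicates(rand)), 0L)
})

test_that("a planted duplication in a synthetic trio is found exactly once", {
  set.seed(10)
  base <- random_peptide(120)
  twin <- local({
    aa <- strsplit(base, "")[[1]]
    idx <- sample(120, 4)
    for (i in idx) aa[i] <- sample(setdiff(genefamkit:::AA20, aa[i]), 1)
    paste(aa, collapse = "")
  })
  other <- random_peptide(120)
  dup <- find_duplicates(c(g1 = base, g2 = twin, g3 = other))
  expect_equal(nrow(dup), 1L)
  expect_identical(c(dup$gene_a, dup$gene_b), c("g1", "g2"))
})

test_that("classify_duplication distinguishes tandem from segmental", {
  gm <- function(id, chr, start, end) gene_model(id, chr, "+", cbind(start, end))
  a <- gm("a", "chr5", 1e6, 1.01e6)
  far <- gm("b", "chr5", 6e6, 6.01e6)
  near <- gm("c", "chr5", 1.03e6, 1.04e6)
  other_chr <- gm("d", "chr2", 1e6, 1.01e6)
  fillers <- lapply(1:8, function(i) gm(paste0("f", i), "chr5", 2e6 + i * 3e5,
                                        2e6 + i * 3e5 + 1e4))

  expect_identical(classify_duplication(a, far, all_models = c(list(a, far), fillers)),
                   "segmental")  # 5 Mb apart, > 5 intervening genes
  expect_identical(classify_duplication(a, other_chr), "segmental")
  expect_identical(classify_duplication(a, near), "tandem")  # 20 kb apart
})

test_that("codon_align back-translates through the protein alignment", {
  cds_a <- "ATGGCTTGCTAA"  # MAC + stop
  cds_b <- "ATGTGC"        # MC
  al <- global_align("MAC", "MC")
  ca <- codon_align(cds_a, cds_b, al$aligned[["a"]], al$aligned[["b"]])
  expect_equal(ca$n_codons, 2L)
  # the one gapped column (A) is dropped; both rows translate to the kept
  # residues and stay in frame
  expect_identical(translate_cds(ca$seq_a), "MC")
  expect_identical(translate_cds(ca$seq_b), "MC")

  # ungapped identical pair: both CDS unchanged (minus the stop)
  ci <- codon_align("ATGGCT", "ATGGCT", "MA", "MA")
  expect_identical(ci$seq_a, "ATGGCT")
  expect_identical(ci$seq_b, "ATGGCT")

  expect_error(codon_align("ATGGCT", "ATGTGC", "MW", "MC"), "mismatch")
})

test_that("Nei-Gojobori site counts follow codon degeneracy with N+S=3 per codon", {
  sites <- genefamkit:::ng_site_table()
  expect_equal(unname(sites[["TTT"]]), 1 / 3)   # Phe: third-position C only
  expect_equal(unname(sites[["TGG"]]), 0)       # Trp: no synonymous change
  # fourfold-degenerate third position
  expect_equal(unname(sites[["GGG"]]), 1)
  # over any alignment, N + S = 3 * n_codons exactly
  set.seed(11)
  for (i in 1:5) {
    cds <- random_cds(30)
    ng <- nei_gojobori(list(seq_a = cds, seq_b = cds))
    expect_equal(ng$N + ng$S, 3 * 30, tolerance = 1e-12)
    expect_equal(ng$Ka, 0)
    expect_equal(ng$Ks, 0)
  }
})

test_that("pathway-averaged difference counts equal the exhaustive enumeration oracle", {
  set.seed(12)
  for (i in 1:20) {
    anc <- random_cds(10)
    ev <- evolve_codon_pair(anc, target_ks = runif(1, 0.1, 0.8),
                            omega = runif(1, 0.2, 2), seed = i)
    ng <- nei_gojobori(list(seq_a = ev$cds_a, seq_b = ev$cds_b))
    orc <- oracle_pair_diffs(ev$cds_a, ev$cds_b)
    expect_equal(ng$Sd, unname(orc["syn"]), tolerance = 1e-9)
    expect_equal(ng$Nd, unname(orc["nonsyn"]), tolerance = 1e-9)
  }
})

test_that("nei_gojobori is symmetric and flags saturation", {
  set.seed(13)
  ev <- evolve_codon_pair(random_cds(100), 0.6, 0.5, seed = 2)
  ab <- nei_gojobori(list(seq_a = ev$cds_a, seq_b = ev$cds_b))
  ba <- nei_gojobori(list(seq_a = ev$cds_b, seq_b = ev$cds_a))
  expect_equal(ab$Ka, ba$Ka)
  expect_equal(ab$Ks, ba$Ks)
  expect_equal(ab$S, ba$S)

  # a hand-built saturated case: pS >= 3/4 undefined under Jukes-Cantor
  expect_true(is.na(jukes_cantor(0.8)))
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
})

test_that("divergence dating reproduces the published pair table and discards saturated Ks", {
  pairs <- maize_sps8_pairs()
  t_mya <- divergence_time(pairs$ks)
  expect_equal(t_mya, c(0.496910767, 1.269308133, 26.76781127), tolerance = 1e-7)
  expect_equal(divergence_time(0), 0)
  expect_true(is.na(divergence_time(2.5)))
  expect_error(divergence_time(-0.1))

  omega <- kaks_ratio(pairs$ka, pairs$ks)
  expect_equal(omega, c(0.32315386, 1.639529208, 0.696005187), tolerance = 1e-7)
  expect_identical(selection_class(omega), c("purifying", "positive", "purifying"))
})

test_that("kaks_pairs produces a coherent pair table on planted duplicates", {
  sim <- simulate_family_genome(n_members = 6, n_decoys = 0, seed = 31,
                                class_sizes = c(2, 1, 3))
  members <- sim$truth$members
  tab <- kaks_pairs(sim$proteins[members],
                    vapply(members, function(id) sim$cds[[id]], character(1)),
                    models = sim$models[members])
  expect_equal(nrow(tab), nrow(sim$truth$dup_pairs))
  expect_setequal(paste(tab$gene_a, tab$gene_b),
                  paste(sim$truth$dup_pairs$gene_a, sim$truth$dup_pairs$gene_b))
  expect_true(all(tab$ka >= 0 & tab$ks >= 0, na.rm = TRUE))
  expect_true(all(tab$dup_type %in% c("tandem", "segmental")))
})
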