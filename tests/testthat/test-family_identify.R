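# Domain-evidence parsing, PSSM profile building/scanning and member
# selection.

domtbl_fixture <- function() {
  f <- tempfile(fileext = ".domtblout")
  writeLines(c(
    "# --- full sequence --- -------------- this domain -------------",
    "#target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias from to from to from to acc description",
    paste("prot1 - 420 Peptidase_S8 PF00082.24 280 1.2e-50 170.1 0.0 1 1 3e-52 1.5e-48 168.0 0.0 1 278 25 300 20 310 0.97 -"),
    paste("prot2 - 350 Peptidase_S8 PF00082.24 280 4.0e-12 44.0 0.1 1 1 8e-13 2.0e-09 42.1 0.1 5 270 30 290 25 300 0.90 -"),
    paste("prot3 - 512 Peptidase_S8 PF00082.24 280 2.2e-30 104.2 0.0 1 1 5e-31 1.1e-27 102.0 0.0 2 279 100 380 95 390 0.95 -")
  ), f)
  f
}

test_that("parse_domain_table reads hmmsearch domtblout rows with domain E-values", {
  hits <- parse_domain_table(domtbl_fixture(), "hmmsearch_domtbl")
  expect_equal(nrow(hits), 3L)
  expect_identical(hits$protein_id, c("prot1", "prot2", "prot3"))
  expect_equal(hits$evalue, c(1.5e-48, 2.0e-09, 1.1e-27))
  expect_equal(hits$ali_start, c(25L, 30L, 100L))
  expect_equal(hits$ali_end, c(300L, 290L, 380L))
})

test_that("parse_domain_table reads blast -outfmt 6 and handles degenerate files", {
  f <- tempfile()
  writeLines(c(
    "query1\tsubjA\t98.5\t250\t3\t0\t1\t250\t10\t259\t3e-120\t356",
    "query1\tsubjB\t45.0\t200\t90\t5\t20\t210\t1\t195\t2.5e-08\t88"
  ), f)
  hits <- parse_domain_table(f, "blast_tab")
  expect_identical(hits$protein_id, c("subjA", "subjB"))
  expect_equal(hits$evalue, c(3e-120, 2.5e-08))
  expect_equal(hits$score, c(356, 88))

  only_comments <- tempfile()
  writeLines(c("# nothing", "# here"), only_comments)
  expect_equal(nrow(parse_domain_table(only_comments, "hmmsearch_domtbl")), 0L)

  bad <- tempfile()
  writeLines("q\ts\t90\t100\t1\t0\t1\t100\t1\t100\tNOTANUMBER\t50", bad)
  expect_error(parse_domain_table(bad, "blast_tab"), "non-numeric")
})

test_that("build_profile computes log-odds columns and drops gappy columns", {
  # two identical sequences: the observed letter maximizes every column
  prof <- build_profile(c("ACDEFG", "ACDEFG"), pseudocount = 1)
  top <- rownames(prof$scores)[apply(prof$scores, 2, which.max)]
  expect_identical(top, c("A", "C", "D", "E", "F", "G"))

  # a column with > 50% gaps is dropped
  prof2 <- build_profile(c("A-CDEFG", "A-CDEFG", "AACDEFG"), pseudocount = 1)
  expect_equal(ncol(prof2$scores), 6L)

  # hand-computed log-odds: single column observed "A", pc = 0, uniform bg
  prof3 <- build_profile(c("AAAAAA", "AAAAAA"), pseudocount = 0)
  expect_equal(unname(prof3$scores["A", 1]), log2(20), tolerance = 1e-12)
  expect_equal(unname(prof3$scores["C", 1]), prof3$score_floor)

  expect_error(build_profile(c("AAA", "AAAA")), "unequal")
  expect_error(build_profile("AAAA"), ">= 2")
})

test_that("profile_scan finds a planted consensus and only the planted site", {
  set.seed(5)
  prof <- build_profile(rep(genefamkit:::FAMILY_DOMAIN, 3), pseudocount = 1)
  dom <- genefamkit:::FAMILY_DOMAIN
  flank1 <- random_peptide(90)
  flank2 <- random_peptide(150)
  protein <- paste0(flank1, dom, flank2)
  hits <- profile_scan(protein, prof, score_threshold = 50)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ali_start, 91L)
  expect_equal(hits$ali_end, 90L + nchar(dom))

  # the consensus itself: hit at position 1 with the maximal possible score
  self <- profile_scan(dom, prof, score_threshold = 0)
  expect_equal(self$ali_start, 1L)
  expect_equal(self$score, sum(apply(prof$scores, 2, max)))

  # protein shorter than the profile: empty result, not an error
  expect_equal(nrow(profile_scan("MKV", prof, 0)), 0L)
})

test_that("calibrated null yields ~0 hits on random sequences at the 1e-3 level", {
  set.seed(6)
  prof <- build_profile(rep(genefamkit:::FAMILY_DOMAIN, 3), pseudocount = 1)
  pool <- vapply(1:30, function(i) random_peptide(250), character(1))
  names(pool) <- paste0("r", 1:30)
  cal <- calibrate_profile(prof, pool, n_shuffles = 400, seed = 6)
  thr <- score_at_evalue(cal, 1e-3)
  n_hits <- sum(vapply(1:200, function(i) {
    nrow(profile_scan(random_peptide(250), prof, thr))
  }, numeric(1)))
  # expected false positives over 200 random sequences at E = 1e-3 per
  # database of 30: well below 1; allow a little calibration slack
  expect_lte(n_hits, 2)
})

test_that("select_members applies the E-value cutoff, merges sources and dedupes isoforms", {
  hits <- data.frame(
    protein_id = c("a", "b", "c1", "c2"),
    domain_name = "dom",
    evalue = c(1e-12, 1e-8, 1e-15, 1e-20),
    ali_start = 1L, ali_end = 50L, score = 100,
    stringsAsFactors = FALSE
  )
  # strict threshold keeps only hits at <= 1e-10
  expect_identical(select_members(hits, evalue_max = 1e-10), c("a", "c1", "c2"))

  # two isoforms of one gene collapse to the longest
  iso <- c(c1 = "geneC", c2 = "geneC")
  lens <- c(a = 100, c1 = 200, c2 = 300)
  expect_identical(select_members(hits, 1e-10, isoform_map = iso,
                                  protein_lengths = lens), c("a", "c2"))

  expect_identical(select_members(hits[0, ]), character(0))

  # require_sources = "all" demands qualifying evidence in every source
  hits$source <- c("hmm", "hmm", "hmm", "blast")
  both <- rbind(hits, within(hits[1, ], source <- "blast"))
  expect_identical(select_members(both, 1e-10, require_sources = "all"), "a")
})

test_that("select_members is monotone in the E-value threshold", {
  set.seed(8)
  ev <- 10^-runif(40, 0, 20)
  hits <- data.frame(protein_id = paste0("p", 1:40), domain_name = "d",
                     evalue = ev, ali_start = 1L, ali_end = 10L, score = 1,
                     stringsAsFactors = FALSE)
  thresholds <- 10^seq(-15, -2, by = 1)
  prev <- character(0)
  for (t in thresholds) {
    cur <- select_members(hits, evalue_max = t)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("planted members are recovered exactly on a synthetic proteome", {
  sim <- simulate_family_genome(n_members = 8, n_decoys = 15, seed = 21,
                                class_sizes = c(4, 2, 2))
  prof <- build_profile(sim$seed_domain_alignment, name = "FamDomain")
  cal <- calibrate_profile(prof, sim$proteins, n_shuffles = 300, seed = 21)
  thr <- score_at_evalue(cal, 1e-3)
  hits <- do.call(rbind, lapply(names(sim$proteins), function(id) {
    profile_scan(sim$proteins[[id]], prof, thr, cal, protein_id = id)
  }))
  members <- select_members(hits, evalue_max = 1e-10)
  expect_setequal(members, sim$truth$members)
})
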