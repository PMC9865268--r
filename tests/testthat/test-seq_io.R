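# FASTA/GFF3 IO, sequence extraction and coordinate conventions.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records, preserves order and enforces invariants", {
  f <- write_tmp(c(">a", "ACGT"), ".fa")
  expect_identical(read_fasta(f), c(a = "ACGT"))

  f2 <- write_tmp(c(">b desc text", "acgt", "ACGT", ">a", "TTTT"), ".fa")
  got <- read_fasta(f2)
  expect_identical(names(got), c("b", "a"))       # order preserved
  expect_identical(unname(got[1]), "ACGTACGT")    # wrapped + upper-cased

  dup <- write_tmp(c(">x", "AA", ">x", "CC"), ".fa")
  expect_error(read_fasta(dup), "duplicated")
  empty <- write_tmp(character(0), ".fa")
  expect_error(read_fasta(empty), "empty|malformed")
  expect_error(read_fasta(tempfile()), "no such file")
})

minimal_gff <- function() {
  write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t100\t200\t.\t+\t0\tParent=g1.t1",
    "chr1\tsrc\tCDS\t301\t400\t.\t+\t1\tParent=g1.t1",
    "chr2\tsrc\tgene\t50\t130\t.\t-\t.\tID=g2",
    "chr2\tsrc\tmRNA\t50\t130\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\tsrc\tCDS\t90\t130\t.\t-\t0\tParent=g2.t1",
    "chr2\tsrc\tCDS\t50\t70\t.\t-\t1\tParent=g2.t1",
    "chr3\tsrc\tgene\t10\t90\t.\t+\t.\tID=nc1",
    "chr3\tsrc\tmRNA\t10\t90\t.\t+\t.\tID=nc1.t1;Parent=nc1",
    "chr3\tsrc\texon\t10\t90\t.\t+\t.\tParent=nc1.t1"
  ), ".gff3")
}

test_that("read_gff3 builds gene models with sorted intervals and skips CDS-less transcripts", {
  models <- suppressWarnings(read_gff3(minimal_gff()))
  expect_length(models, 2L)  # ncRNA skipped
  expect_warning(read_gff3(minimal_gff()), "no CDS")

  g1 <- models[[1]]
  expect_s3_class(g1, "gene_model")
  expect_identical(g1$gene_id, "g1")
  expect_equal(nrow(g1$cds_intervals), 2L)
  expect_equal(g1$cds_intervals[, 1], c(100L, 301L))

  g2 <- models[[2]]
  expect_identical(g2$strand, "-")
  # minus-strand intervals still stored ascending
  expect_true(all(diff(g2$cds_intervals[, 1]) > 0))
})

test_that("gene_model rejects malformed intervals and strands", {
  expect_error(gene_model("g", "chr1", "*", cbind(1, 10)), "strand")
  expect_error(gene_model("g", "chr1", "+", cbind(10, 1)), "start > end")
  expect_error(gene_model("g", "chr1", "+", rbind(c(1, 10), c(5, 20))), "overlap")
})

test_that("extract_cds concatenates intervals, splices introns and honors strand", {
  genome <- c(chr1 = "AAATGAAACCCGGGTTT")
  plus <- gene_model("p", "chr1", "+", cbind(3, 8))
  expect_identical(extract_cds(genome, plus), "ATGAAA")

  minus <- gene_model("m", "chr1", "-", cbind(3, 8))
  expect_identical(extract_cds(genome, minus), "TTTCAT")

  spliced <- gene_model("s", "chr1", "+", rbind(c(3, 5), c(12, 14)))
  expect_identical(extract_cds(genome, spliced), "ATGGGG")  # intron absent

  oob <- gene_model("o", "chr1", "+", cbind(10, 100))
  expect_error(extract_cds(genome, oob), "out of")
  expect_error(extract_cds(genome, gene_model("x", "chrZ", "+", cbind(1, 3))),
               "not in genome")
})

test_that("translate_cds follows the standard code and handles stops and ambiguity", {
  expect_identical(translate_cds("ATGGCTTAA"), "MA")   # trailing stop removed
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
  expect_identical(translate_cds("ATGTAAGCT", internal_stop = "X"), "MXA")
  expect_identical(translate_cds("ATGNNN"), "MX")
  expect_error(translate_cds("ATGA"), "divisible by 3")
})

test_that("extract_promoter is strand-aware and truncates at contig edges", {
  set.seed(1)
  chr <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  genome <- c(chr1 = chr)

  plus <- gene_model("p", "chr1", "+", cbind(3001, 3300))
  expect_identical(extract_promoter(genome, plus, 2000), substring(chr, 1001, 3000))

  near_edge <- gene_model("e", "chr1", "+", cbind(500, 800))
  expect_warning(prom <- extract_promoter(genome, near_edge, 2000), "truncated")
  expect_identical(nchar(prom), 499L)

  minus <- gene_model("m", "chr1", "-", cbind(1001, 1300))
  expect_identical(extract_promoter(genome, minus, 2000),
                   revcomp(substring(chr, 1301, 3300)))
})

test_that("revcomp is an involution and promoter never overlaps its own CDS", {
  set.seed(42)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
  # promoter/CDS disjointness on the synthetic genome
  sim <- simulate_family_genome(n_members = 4, n_decoys = 2, seed = 11,
                                class_sizes = c(2, 1, 1))
  for (id in names(sim$models)) {
    m <- sim$models[[id]]
    cds_span <- range(m$cds_intervals)
    if (m$strand == "+") {
      prom_span <- c(min(m$cds_intervals[, 1]) - 2000, min(m$cds_intervals[, 1]) - 1)
    } else {
      prom_span <- c(max(m$cds_intervals[, 2]) + 1, max(m$cds_intervals[, 2]) + 2000)
    }
    expect_true(prom_span[2] < cds_span[1] || prom_span[1] > cds_span[2])
  }
})

test_that("write_gff3/read_gff3 and write_fasta/read_fasta round-trip the synthetic genome", {
  sim <- simulate_family_genome(n_members = 6, n_decoys = 4, seed = 3,
                                class_sizes = c(3, 2, 1), dir = (d <- tempfile()))
  genome <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(genome, sim$genome)
  models <- read_gff3(file.path(d, "annotation.gff3"), longest_per_gene = TRUE)
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  expect_setequal(names(models), names(sim$models))
  for (id in names(models)) {
    expect_identical(extract_cds(genome, models[[id]]), sim$cds[[id]])
    expect_equal(models[[id]]$cds_intervals, sim$models[[id]]$cds_intervals)
  }
})

test_that("longest_isoform keeps one transcript per gene by CDS length", {
  m1 <- gene_model("g1", "chr1", "+", cbind(1, 30), transcript_id = "g1.t1")
  m2 <- gene_model("g1", "chr1", "+", cbind(1, 90), transcript_id = "g1.t2")
  m3 <- gene_model("g2", "chr1", "+", cbind(200, 250), transcript_id = "g2.t1")
  kept <- longest_isoform(list(m1, m2, m3))
  expect_length(kept, 2L)
  expect_identical(vapply(kept, `[[`, character(1), "transcript_id"),
                   c("g1.t2", "g2.t1"))
})
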