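test_that("CX report reading maps fields and keeps zero-coverage sites", {
  f <- tempfile(fileext = ".cx")
  writeLines(c("Chr1\t10\t+\t5\t5\tCG\tCGA",
               "Chr1\t20\t+\t0\t10\tCHG\tCAG",
               "Chr1\t30\t-\t10\t0\tCHH\tCTT"), f)
  s <- read_cx_report(f, genotype = "wt", replicate = "r1")
  expect_s3_class(s, "methylome_sample")
  expect_equal(nrow(s$sites), 3L)
  expect_equal(s$sites$count_meth + s$sites$count_unmeth, c(10L, 10L, 10L))
  expect_equal(s$genotype, "wt")

  # zero-coverage rows are retained as positions
  writeLines(c("Chr1\t10\t+\t0\t0\tCG\tCGA"), f)
  s0 <- read_cx_report(f)
  expect_equal(nrow(s0$sites), 1L)
  expect_true(is.na(site_frequency(s0$sites$count_meth, s0$sites$count_unmeth)))
})

test_that("malformed CX rows raise parse errors naming the line", {
  f <- tempfile(fileext = ".cx")
  writeLines(c("Chr1\t10\t+\t5\t5\tCG\tCGA",
               "Chr1\t20\t+\t1\t2\tCXX\tCAA"), f)
  expect_error(read_cx_report(f), "CXX.*line 2|line 2")
  writeLines(c("Chr1\tnope\t+\t5\t5\tCG\tCGA"), f)
  expect_error(read_cx_report(f), "line 1")
})

test_that("unsorted CX input is sorted with a notice", {
  f <- tempfile(fileext = ".cx")
  writeLines(c("Chr1\t30\t+\t1\t1\tCHH\tCAA",
               "Chr1\t10\t+\t1\t1\tCHH\tCAA"), f)
  expect_message(s <- read_cx_report(f), "unsorted")
  expect_equal(s$sites$pos, c(10L, 30L))
})

test_that("CX report round-trips byte-identically on sorted input", {
  sites <- random_sites(1000, seed = 11)
  s <- methylome_sample(sites, "wt", "r1")
  f1 <- tempfile(fileext = ".cx")
  f2 <- tempfile(fileext = ".cx")
  write_cx_report(s, f1)
  write_cx_report(read_cx_report(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("gzip CX input is accepted", {
  sites <- random_sites(50, seed = 2)
  s <- methylome_sample(sites, "wt", "r1")
  f <- tempfile(fileext = ".cx.gz")
  write_cx_report(s, f)
  s2 <- read_cx_report(f, genotype = "wt", replicate = "r1")
  expect_equal(as.data.frame(s2$sites), as.data.frame(s$sites))
})

test_that("trinucleotide/context consistency is enforced", {
  bad <- make_sites(10, list(c(1, 1)), context = "CG")
  bad$trinucleotide <- "CAA"  # CHH trinucleotide labelled CG
  expect_error(methylome_sample(bad), "inconsistent")
  expect_equal(context_of_trinucleotide(c("CGA", "CTG", "CAT")),
               c("CG", "CHG", "CHH"))
})

test_that("duplicate sites and out-of-bounds positions are rejected", {
  dup <- rbind(make_sites(10, list(c(1, 1))), make_sites(10, list(c(2, 2))))
  expect_error(methylome_sample(dup), "duplicate")
  expect_error(methylome_sample(make_sites(500, list(c(1, 1))),
                                genome = c(Chr1 = 100L)),
               "beyond")
})

test_that("GFF3 genes span first to last exon with resolvable parents", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Chr1\ttest\tgene\t101\t600\t.\t+\t.\tID=g1",
    "Chr1\ttest\tmRNA\t101\t600\t.\t+\t.\tID=g1.1;Parent=g1",
    "Chr1\ttest\texon\t101\t200\t.\t+\t.\tParent=g1.1",
    "Chr1\ttest\texon\t401\t500\t.\t+\t.\tParent=g1.1"), f)
  g <- read_gff3(f)
  expect_equal(length(g), 1L)
  expect_equal(GenomicRanges::start(g), 101L)
  expect_equal(GenomicRanges::end(g), 500L)  # last exon end, not gene record end
  expect_equal(g$id, "g1")
})

test_that("GFF3 degenerate records warn and fall back", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Chr1\ttest\tgene\t101\t500\t.\t+\t.\tID=g1",
    "Chr1\ttest\texon\t101\t200\t.\t+\t.\tParent=g1",
    "Chr1\ttest\tgene\t1000\t1500\t.\t-\t.\tID=g2",
    "Chr1\ttest\texon\t2000\t2100\t.\t+\t.\tParent=ghost"), f)
  expect_warning(expect_warning(g <- read_gff3(f), "without resolvable"),
                 "without exons")
  expect_equal(GenomicRanges::end(g[g$id == "g1"]), 200L)
  expect_equal(GenomicRanges::start(g[g$id == "g2"]), 1000L)  # gene-record span
})

test_that("promoters are the 200 bp upstream of the first exon, clipped", {
  plus <- gr(101, 500, "+"); plus$id <- "gp"
  minus <- gr(101, 500, "-"); minus$id <- "gm"
  pp <- gene_promoters(plus)
  expect_equal(c(GenomicRanges::start(pp), GenomicRanges::end(pp)), c(1L, 100L))
  pm <- gene_promoters(minus)
  expect_equal(c(GenomicRanges::start(pm), GenomicRanges::end(pm)), c(501L, 700L))
  # clip at chromosome start: first exon at 51 leaves only 50 bp upstream
  near <- gr(51, 500, "+"); near$id <- "gn"
  pn <- gene_promoters(near)
  expect_equal(c(GenomicRanges::start(pn), GenomicRanges::end(pn)), c(1L, 50L))
  # clip at chromosome end for a minus-strand gene
  pe <- gene_promoters(minus, genome = c(Chr1 = 600L))
  expect_equal(GenomicRanges::end(pe), 600L)
})

test_that("TE annotation converts coordinates and validates records", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("AT1TE0001\t+\t1001\t1500\tATCOPIA1\tLTR/Copia",
               "AT2TE0002\t-\t200\t800\tATGP1\tLTR/Gypsy"), f)
  tes <- read_te_annotation(f)
  te1 <- tes[tes$id == "AT1TE0001"]
  expect_equal(GenomicRanges::width(te1), 500L)
  expect_equal(as.character(GenomeInfoDb::seqnames(te1)), "Chr1")
  expect_equal(as.character(GenomeInfoDb::seqnames(tes[tes$id == "AT2TE0002"])), "Chr2")

  writeLines(c("AT1TE0001\t+\t1001\t1500\tF1\tLTR/Copia",
               "AT1TE0001\t+\t2001\t2500\tF1\tLTR/Copia"), f)
  expect_error(read_te_annotation(f), "duplicate")

  writeLines(c("AT1TE0001\t+\t1500\t1001\tF1\tLTR/Copia",
               "AT1TE0002\t+\t2001\t2500\tF1\tLTR/Copia"), f)
  expect_warning(ok <- read_te_annotation(f), "rejected")
  expect_equal(ok$id, "AT1TE0002")
})

test_that("TE tables round-trip through the writer", {
  set.seed(7)
  n <- 100L
  start <- sample.int(100000L, n)
  sf <- sample(c("LTR/Gypsy", "DNA/MuDR", "RC/Helitron"), n, replace = TRUE)
  dt <- data.table::data.table(
    name = sprintf("AT1TE%05d", seq_len(n)),
    chrom = "Chr1",
    orientation = sample(c("+", "-"), n, replace = TRUE),
    start = start, end = start + sample.int(5000L, n),
    family = paste0(gsub("[^A-Za-z]", "", sf), "_F1"),
    superfamily = sf)
  f1 <- tempfile(); f2 <- tempfile()
  data.table::fwrite(dt, f1, sep = "\t", col.names = FALSE, quote = FALSE)
  write_te_annotation(read_te_annotation(f1), f2)
  t1 <- data.table::fread(f1, header = FALSE)[order(V4)]
  t2 <- data.table::fread(f2, header = FALSE)[order(V4)]
  expect_equal(t1, t2)
})

test_that("feature_set interval queries agree with a linear scan", {
  set.seed(21)
  n <- 400L
  starts <- sample.int(200000L, n)
  tes <- gr(starts, starts + sample.int(3000L, n))
  tes$id <- sprintf("AT1TE%04d", seq_len(n))
  tes$family <- "F"; tes$superfamily <- "LTR/Gypsy"
  fs <- tiny_feature_set(te_iv = tes, genome_len = 300000L)
  for (q in 1:20) {
    qs <- sample.int(200000L, 1L); qe <- qs + sample.int(5000L, 1L)
    hits <- sort(S4Vectors::subjectHits(GenomicRanges::findOverlaps(
      gr(qs, qe), fs$tes, ignore.strand = TRUE)))
    brute <- which(GenomicRanges::start(fs$tes) <= qe &
                     GenomicRanges::end(fs$tes) >= qs)
    expect_equal(hits, brute)
  }
})

test_that("DMR BED output follows the BED6+ convention", {
  dmrs <- data.table::data.table(
    chrom = "Chr1", start = 1001L, end = 1150L, length = 150L,
    context = "CHH", direction = "hypo", wt_level = 0.6, mut_level = 0.1,
    diff = -0.5, n_sites = 30L, p_value = 0.0005,
    wt_meth = 1L, wt_unmeth = 1L, mut_meth = 1L, mut_unmeth = 1L)
  f <- tempfile(fileext = ".bed")
  write_dmr_bed(dmrs, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(fields[1:6], c("Chr1", "1000", "1150", "CHH:hypo", "33", "."))
  expect_equal(as.integer(fields[9]), 30L)

  dmrs$p_value <- 1e-300
  write_dmr_bed(dmrs, f)
  expect_equal(strsplit(readLines(f), "\t")[[1]][5], "1000")

  write_dmr_bed(dmrs[0], f)
  expect_equal(file.size(f), 0)
})
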