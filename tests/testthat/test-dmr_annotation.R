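dmr_row <- function(start, end, direction = "hyper", context = "CHH") {
  data.table::data.table(chrom = "Chr1", start = start, end = end,
                         context = context, direction = direction)
}

test_that("DMRs are assigned by the 50% overlap rule", {
  # gene body covering exactly half of a 100-nt DMR -> gene_body
  # (minus strand puts the promoter downstream, away from the DMR)
  fs <- tiny_feature_set(gene_iv = gr(151, 500, "-"))
  a <- assign_dmrs(dmr_row(101, 200), fs)
  expect_equal(a$category, "gene_body")
  expect_equal(a$gene_ids, fs$genes$id)

  # TE covering 51% -> te; adding a gene body at >= 50% -> both
  fs_te <- tiny_feature_set(te_iv = gr(150, 500))
  expect_equal(assign_dmrs(dmr_row(101, 200), fs_te)$category, "te")
  fs_both <- tiny_feature_set(gene_iv = gr(151, 500, "-"), te_iv = gr(150, 500))
  expect_equal(assign_dmrs(dmr_row(101, 200), fs_both)$category,
               "gene_element_and_te")

  # 49-nt overlaps only -> other
  fs49 <- tiny_feature_set(gene_iv = gr(152, 500, "-"), te_iv = gr(152, 500))
  expect_equal(assign_dmrs(dmr_row(101, 200), fs49)$category, "other")
})

test_that("promoter matches take precedence and are strand-aware", {
  g <- gr(1001, 3000, "+")
  fs <- tiny_feature_set(gene_iv = g)
  # promoter is [801, 1000]; DMR [801, 900] sits fully inside it
  a <- assign_dmrs(dmr_row(801, 900), fs)
  expect_equal(a$category, "promoter")
  # a DMR straddling the promoter/body boundary with both >= 50%:
  # 100 nt with 50 in the promoter and 50 in the body
  a2 <- assign_dmrs(dmr_row(951, 1050), fs)
  expect_equal(a2$category, "promoter")
  expect_equal(a2$gene_side, "promoter")
})

test_that("a DMR in a TE nested inside a gene matches both", {
  fs <- tiny_feature_set(gene_iv = gr(1000, 9000), te_iv = gr(4000, 5000))
  a <- assign_dmrs(dmr_row(4200, 4400), fs)
  expect_equal(a$category, "gene_element_and_te")
  expect_equal(a$gene_side, "gene_body")
  expect_equal(a$te_ids, fs$tes$id)
})

test_that("category tabulation reproduces the published row arithmetic", {
  # a genotype's hypermethylated CHH set: 231 DMRs of which 57 match gene
  # elements (6 promoter, 51 body), 155 match TEs, 15 match both, 34 neither
  n_both <- 15L
  a <- data.table::data.table(
    direction = "hyper",
    category = c(rep("promoter", 6L), rep("gene_body", 51L - n_both),
                 rep("gene_element_and_te", n_both), rep("te", 155L - n_both),
                 rep("other", 34L)),
    gene_side = c(rep("promoter", 6L), rep("gene_body", 51L - n_both),
                  rep("gene_body", n_both), rep(NA, 155L - n_both),
                  rep(NA, 34L)))
  tab <- tabulate_categories(a, direction_split = FALSE)
  expect_equal(tab$total, 231L)
  expect_equal(tab$gene_elements, 57L)
  expect_equal(tab$gene_elements_pct, 24.7)
  expect_equal(tab$promoter_pct, 2.6)
  expect_equal(tab$gene_body_pct, 22.1)
  expect_equal(tab$te, 155L)
  expect_equal(tab$te_pct, 67.1)
  expect_equal(tab$gene_element_and_te_pct, 6.5)
  expect_equal(tab$other_pct, 14.7)
  # the column identity: gene elements + TEs - both + others = total
  expect_equal(tab$gene_elements + tab$te - tab$gene_element_and_te + tab$other,
               tab$total)
})

test_that("category percentages of disjoint classes sum to ~100", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(50:400, 1)
    cat <- sample(c("promoter", "gene_body", "te", "gene_element_and_te", "other"),
                  n, replace = TRUE)
    a <- data.table::data.table(
      direction = sample(c("hyper", "hypo"), n, replace = TRUE),
      category = cat,
      gene_side = ifelse(cat %in% c("promoter"), "promoter",
                         ifelse(cat %in% c("gene_body", "gene_element_and_te"),
                                "gene_body", NA)))
    tab <- tabulate_categories(a)
    tot <- tab[direction == "Total"]
    s <- tot$promoter_pct + tot$gene_body_pct + tot$te_pct + tot$other_pct -
      tot$gene_element_and_te_pct
    expect_lt(abs(s - 100), 0.3)
    # direction rows partition the total
    expect_equal(sum(tab$total[1:2]), tot$total)
  }
})

test_that("empty assignments give an all-zero table", {
  a <- data.table::data.table(direction = character(0), category = character(0),
                              gene_side = character(0))
  tab <- tabulate_categories(a, direction_split = FALSE)
  expect_equal(tab$total, 0L)
  expect_true(is.na(tab$te_pct))
})

test_that("superfamily summaries count distinct targeted TEs", {
  tes <- gr(seq(1000, 10000, by = 1000), seq(1400, 10400, by = 1000))
  tes$id <- sprintf("TE%02d", 1:10)
  tes$family <- paste0("F", rep(1:5, each = 2))
  tes$superfamily <- rep(c("LTR/Gypsy", "LTR/Gypsy", "DNA/MuDR", "RC/Helitron",
                           "SINE"), each = 2)
  fs <- tiny_feature_set(te_iv = tes, genome_len = 20000L)
  a <- data.table::data.table(
    direction = c("hyper", "hyper", "hypo", "hypo"),
    te_ids = c("TE01,TE02", "TE03", "TE05", "TE01"))
  sf <- superfamily_summary(a, fs)
  expect_equal(sf[superfamily == "LTR/Gypsy"]$n_tes, 3L)  # TE01 counted once
  expect_equal(sf[superfamily == "LTR/Gypsy"]$proportion, 3 / 4)

  # direction subsets partition the targeted multiset
  all_ids <- targeted <- NULL
  hypo <- superfamily_summary(a, fs, "hypo")
  hyper <- superfamily_summary(a, fs, "hyper")
  expect_equal(sum(hypo$n_tes) + sum(hyper$n_tes) -
                 1L,  # TE01 targeted in both directions, distinct in "all"
               sum(sf$n_tes))
  expect_error(superfamily_summary(
    data.table::data.table(direction = "hyper", te_ids = "ghost"), fs),
    "not in feature set")
})

test_that("family representation uses a strict >10% member threshold", {
  tes <- gr(seq(1000, 40000, by = 1000), seq(1200, 40200, by = 1000))
  n <- length(tes)
  tes$id <- sprintf("TE%02d", seq_len(n))
  tes$family <- c(rep("F20", 20L), rep("F10", 10L), rep("FX", n - 30L))
  tes$superfamily <- "LTR/Gypsy"
  fs <- tiny_feature_set(te_iv = tes, genome_len = 60000L)
  a <- data.table::data.table(
    direction = "hyper",
    te_ids = c("TE01,TE02,TE03",   # 3/20 = 15% -> included
               "TE21,TE22"))      # 2/10 = 20% -> included
  rep1 <- family_representation(a, fs)
  expect_setequal(rep1$family, c("F20", "F10"))
  # exactly 10% is excluded (strict inequality)
  a2 <- data.table::data.table(direction = "hyper", te_ids = "TE01,TE02")
  expect_false("F20" %in% family_representation(a2, fs)$family)
  # order of assignments does not matter
  rep2 <- family_representation(a[2:1], fs)
  expect_equal(rep1[order(family)], rep2[order(family)])
})

test_that("overlap summaries enumerate disjoint Venn cells", {
  sets <- list(A = c("1", "2", "3"), B = c("3", "4"), C = c("4", "5"))
  ov <- overlap_summary(sets)
  pg <- ov$per_genotype
  expect_equal(pg[genotype == "A"]$unique, 2L)
  expect_equal(pg[genotype == "A"]$unique_pct, 66.67)
  expect_equal(pg[genotype == "A"]$formatted, "66.67% (2/3)")
  expect_equal(ov$cells[combo == "A+B"]$n, 1L)   # element 3
  expect_equal(ov$cells[combo == "A+B+C"]$n, 0L)

  ident <- overlap_summary(list(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b")))
  expect_true(all(ident$per_genotype$unique == 0L))
  expect_equal(ident$cells[combo == "X+Y+Z"]$n, 2L)
})

test_that("Venn cells satisfy inclusion-exclusion on random sets", {
  set.seed(31)
  for (i in 1:10) {
    sets <- list(a = as.character(sample(100, 40)),
                 b = as.character(sample(100, 30)),
                 c = as.character(sample(100, 50)))
    ov <- overlap_summary(sets)
    expect_equal(sum(ov$cells$n), length(unique(unlist(sets))))
    # per set: cells containing the set sum to the set size
    for (g in names(sets)) {
      in_g <- vapply(strsplit(ov$cells$combo, "+", fixed = TRUE),
                     function(x) g %in% x, TRUE)
      expect_equal(sum(ov$cells$n[in_g]), length(sets[[g]]))
    }
  }
  # empty set is tolerated
  ov0 <- overlap_summary(list(a = "x", b = character(0)))
  expect_true(is.na(ov0$per_genotype[genotype == "b"]$formatted))
})
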