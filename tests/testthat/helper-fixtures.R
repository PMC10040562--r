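library(data.table)

# --- small site-table builders -----------------------------------------------

# a site table row; counts given as list of c(meth, unmeth)
make_sites <- function(pos, counts, context = "CHH", chrom = "Chr1",
                       strand = "+") {
  data.table(chrom = chrom, pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             count_meth = vapply(counts, `[`, 0, 1L),
             count_unmeth = vapply(counts, `[`, 0, 2L),
             context = rep_len(context, length(pos)),
             trinucleotide = NA_character_)
}

# sample with n sites of one context at uniform counts, evenly spaced
uniform_sample <- function(n, meth, unmeth, context = "CHH", spacing = 10L,
                           genotype = "wt", replicate = "r1") {
  sites <- make_sites(seq_len(n) * spacing,
                      rep(list(c(meth, unmeth)), n), context = context)
  methylome_sample(sites, genotype, replicate)
}

# random well-formed site table across contexts (for IO round-trips etc.)
random_sites <- function(n, seed, chrom = "Chr1", max_pos = 50L * n) {
  set.seed(seed)
  tri <- list(CG = c("CGA", "CGT", "CGC", "CGG"),
              CHG = c("CAG", "CTG", "CCG"),
              CHH = c("CAA", "CAT", "CTA", "CTT"))
  pos <- sort(sample.int(max_pos, n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ctx <- sample(names(tri), n, replace = TRUE)
  dup <- duplicated(data.table(pos, strand))
  pos <- pos[!dup]; strand <- strand[!dup]; ctx <- ctx[!dup]
  n <- length(pos)
  data.table(chrom = chrom, pos = pos, strand = strand,
             count_meth = sample(0:30, n, replace = TRUE),
             count_unmeth = sample(0:30, n, replace = TRUE),
             context = ctx,
             trinucleotide = vapply(ctx, function(c) sample(tri[[c]], 1L), ""))
}

# a binomially sampled methylome at a single true level
binomial_sample <- function(n_sites, level, coverage, context = "CHH",
                            seed = 1L, spacing = 5L) {
  set.seed(seed)
  cov <- rpois(n_sites, coverage)
  meth <- rbinom(n_sites, cov, level)
  sites <- data.table(chrom = "Chr1", pos = seq_len(n_sites) * spacing,
                      strand = "+", count_meth = meth,
                      count_unmeth = cov - meth, context = context,
                      trinucleotide = NA_character_)
  methylome_sample(sites, "sim", "r1")
}

# --- tiny annotation builders ------------------------------------------------

gr <- function(start, end, strand = "+", chrom = "Chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

tiny_feature_set <- function(gene_iv = NULL, te_iv = NULL, genome_len = 100000L) {
  genes <- if (is.null(gene_iv)) GenomicRanges::GRanges() else gene_iv
  tes <- if (is.null(te_iv)) GenomicRanges::GRanges() else te_iv
  if (length(genes) && is.null(genes$id)) {
    genes$id <- sprintf("At1g%05d", seq_along(genes) * 10L)
  }
  if (length(tes)) {
    if (is.null(tes$id)) tes$id <- sprintf("AT1TE%04d", seq_along(tes))
    if (is.null(tes$family)) tes$family <- "FAM1"
    if (is.null(tes$superfamily)) tes$superfamily <- "LTR/Gypsy"
  }
  feature_set(genes, tes, genome = c(Chr1 = genome_len))
}

# --- independent oracles -----------------------------------------------------

# two-sided Fisher p by direct enumeration with choose() arithmetic
# (independent of dhyper and of fisher_exact_2x2)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-07)]))
}

# brute-force metaprofile: enumerate (feature, offset) pairs one by one
oracle_metaprofile <- function(sample, features, context, anchor,
                               flank = 5000L, interval_size = 100L,
                               discard = 0L) {
  n_bins <- 2L * flank / interval_size
  tm <- integer(n_bins); tc <- integer(n_bins)
  s <- as.data.frame(sample$sites)
  s <- s[s$context == context & (s$count_meth + s$count_unmeth) > 0L, ]
  for (i in seq_along(features)) {
    fs <- GenomicRanges::start(features)[i]
    fe <- GenomicRanges::end(features)[i]
    minus <- as.character(GenomicRanges::strand(features))[i] == "-"
    chrom <- as.character(GenomeInfoDb::seqnames(features))[i]
    for (off in seq.int(-flank, flank - 1L)) {
      gpos <- if (!minus) {
        (if (anchor == "five_prime") fs else fe) + off
      } else {
        (if (anchor == "five_prime") fe else fs) - off
      }
      # discard rule: in-body positions within `discard` of the opposite end
      if (discard > 0L && gpos >= fs && gpos <= fe) {
        opp_at_right <- (anchor == "five_prime") != minus
        d_opp <- if (opp_at_right) fe - gpos else gpos - fs
        if (d_opp < discard) next
      }
      rows <- s[s$chrom == chrom & s$pos == gpos, ]
      if (nrow(rows) == 0L) next
      bin <- (off + flank) %/% interval_size + 1L
      tm[bin] <- tm[bin] + sum(rows$count_meth)
      tc[bin] <- tc[bin] + sum(rows$count_meth + rows$count_unmeth)
    }
  }
  data.frame(bin = seq_len(n_bins) - 1L, total_meth = tm, total_c = tc,
             level = ifelse(tc > 0, tm / tc, NA_real_))
}

# brute-force per-window level recount
oracle_window_levels <- function(sample, context, window) {
  s <- as.data.frame(sample$sites)
  s <- s[s$context == context & (s$count_meth + s$count_unmeth) > 0L, ]
  if (nrow(s) == 0L) return(data.frame())
  out <- list()
  for (w in sort(unique((s$pos - 1L) %/% window))) {
    rows <- s[(s$pos - 1L) %/% window == w, ]
    out[[length(out) + 1L]] <- data.frame(
      wstart = w * window + 1L,
      level = sum(rows$count_meth) / sum(rows$count_meth + rows$count_unmeth),
      n = nrow(rows))
  }
  do.call(rbind, out)
}
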