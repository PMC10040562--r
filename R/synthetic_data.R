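#' Compartment model for methylome simulation
#'
#' Describes the ground truth a simulated methylome is drawn from: a true
#' methylation level per genomic compartment (gene body, short TE, long
#' TE, intergenic) and context, a beta-binomial overdispersion parameter
#' shared across sites, a mean read coverage, and the expected cytosine
#' density per context. The default levels follow the qualitative ordering
#' of plant methylomes — TEs heavily methylated in CG and CHG with low
#' CHH, gene bodies carrying moderate CG-only methylation, intergenic
#' background near zero — and the default densities approximate the
#' per-context cytosine densities of a 36%-GC plant genome counting both
#' strands.
#'
#' @param levels numeric matrix, rows `gene_body`, `te_short`, `te_long`,
#'   `intergenic`; columns `CG`, `CHG`, `CHH`; entries in `[0, 1]`.
#' @param dispersion beta-binomial overdispersion rho in `[0, 1)`; 0 gives
#'   pure binomial counts.
#' @param coverage_mean expected reads per site (Poisson).
#' @param cytosine_density named expected cytosines per nt per context
#'   (both strands combined).
#' @return a list of class `compartment_model`.
#' @export
compartment_model <- function(levels = NULL, dispersion = 0.02,
                              coverage_mean = 20,
                              cytosine_density = c(CG = 0.04, CHG = 0.04,
                                                   CHH = 0.15)) {
  if (is.null(levels)) {
    levels <- rbind(gene_body  = c(CG = 0.25, CHG = 0.03, CHH = 0.02),
                    te_short   = c(CG = 0.75, CHG = 0.45, CHH = 0.10),
                    te_long    = c(CG = 0.85, CHG = 0.55, CHH = 0.10),
                    intergenic = c(CG = 0.05, CHG = 0.03, CHH = 0.02))
  }
  stopifnot(is.matrix(levels), all(levels >= 0 & levels <= 1),
            all(METH_CONTEXTS %in% colnames(levels)),
            all(c("gene_body", "te_short", "te_long", "intergenic") %in%
                  rownames(levels)),
            dispersion >= 0, dispersion < 1, coverage_mean > 0,
            all(METH_CONTEXTS %in% names(cytosine_density)),
            all(cytosine_density > 0))
  structure(list(levels = levels, dispersion = dispersion,
                 coverage_mean = coverage_mean,
                 cytosine_density = cytosine_density),
            class = "compartment_model")
}

default_superfamily_weights <- function() {
  c("LTR/Gypsy" = 0.25, "RC/Helitron" = 0.20, "DNA/MuDR" = 0.15,
    "LTR/Copia" = 0.12, "DNA/Harbinger" = 0.10, "DNA/Tc1" = 0.08,
    "SINE" = 0.05, "LINE/L1" = 0.05)
}

# place n non-overlapping intervals of the given widths on [1, len];
# returns a data.table(start, end) or errors when density is infeasible
place_nonoverlapping <- function(len, widths, existing = NULL, max_tries = 200L) {
  placed_s <- if (is.null(existing)) integer(0) else existing$start
  placed_e <- if (is.null(existing)) integer(0) else existing$end
  out_s <- integer(length(widths)); out_e <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(len - w + 1L, 1L)
      e <- s + w - 1L
      if (!any(s <= placed_e & e >= placed_s)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place feature ", i, " without overlap; density infeasible")
    out_s[i] <- s; out_e[i] <- e
    placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
  }
  data.table(start = out_s, end = out_e)
}

#' Simulate a genome annotation with genes and TEs
#'
#' Places `n_genes` gene bodies (1-4 kb) and `n_tes` TEs (bimodal lengths:
#' short 200-800 nt, long 3-8 kb) uniformly and without overlap on a
#' single chromosome, drawing TE superfamilies from `superfamily_weights`
#' and assigning each TE to one of three families within its superfamily.
#' Deterministic given the seed.
#'
#' @param length chromosome length in nt.
#' @param n_genes,n_tes feature counts.
#' @param superfamily_weights named sampling weights (default: a
#'   Gypsy/Helitron/MuDR-dominated mix).
#' @param seed integer seed.
#' @param p_long probability that a TE is long (default 0.3).
#' @param chrom chromosome name (default `"Chr1"`).
#' @return a [feature_set()].
#' @export
simulate_genome <- function(length, n_genes, n_tes,
                            superfamily_weights = default_superfamily_weights(),
                            seed = 1L, p_long = 0.3, chrom = "Chr1") {
  set.seed(child_seed(seed, "genome"))
  genome <- setNames(as.integer(length), chrom)

  gene_w <- if (n_genes > 0L) sample(1000:4000, n_genes, replace = TRUE) else integer(0)
  long <- if (n_tes > 0L) runif(n_tes) < p_long else logical(0)
  te_w <- integer(n_tes)
  te_w[long] <- sample(3000:8000, sum(long), replace = TRUE)
  te_w[!long] <- sample(200:800, sum(!long), replace = TRUE)

  placed <- place_nonoverlapping(as.integer(length), c(gene_w, te_w))
  gene_iv <- placed[seq_len(n_genes)]
  te_iv <- placed[n_genes + seq_len(n_tes)]

  genes <- GenomicRanges::GRanges(
    rep(chrom, n_genes), IRanges::IRanges(gene_iv$start, gene_iv$end),
    strand = if (n_genes) sample(c("+", "-"), n_genes, replace = TRUE) else character(0))
  genes$id <- sprintf("At1g%05d", seq_len(n_genes) * 10L)

  sf <- if (n_tes) sample(names(superfamily_weights), n_tes, replace = TRUE,
                          prob = superfamily_weights) else character(0)
  fam <- if (n_tes) paste0(gsub("[^A-Za-z0-9]", "", sf), "_FAM",
                           sample.int(3L, n_tes, replace = TRUE)) else character(0)
  tes <- GenomicRanges::GRanges(
    rep(chrom, n_tes), IRanges::IRanges(te_iv$start, te_iv$end),
    strand = if (n_tes) sample(c("+", "-"), n_tes, replace = TRUE) else character(0))
  tes$id <- sprintf("AT1TE%05d", seq_len(n_tes))
  tes$family <- fam
  tes$superfamily <- sf

  feature_set(genes, tes, genome = genome)
}

#' Plant differentially methylated regions of known effect
#'
#' Chooses non-overlapping target regions — preferentially inside TEs —
#' and assigns each a context and a signed methylation-level shift to be
#' applied in the mutant methylome. Hypermethylating shifts raise the
#' compartment baseline (the regime of RdDM mutants whose CHH DMRs are
#' predominantly hypermethylated); hypomethylating shifts are supported
#' where the baseline leaves room. Regions are kept at least
#' `min_separation` nt apart so that window merging cannot fuse two
#' planted regions. Deterministic given the seed.
#'
#' @param features a [feature_set()].
#' @param n_regions number of regions to plant.
#' @param contexts context(s) sampled per region (default `"CHH"`).
#' @param effect_range magnitude range of the level shift (default
#'   0.3-0.6).
#' @param length_range region length range in nt (default 250-600).
#' @param te_fraction fraction of regions placed inside TEs, the rest
#'   intergenic (default 0.8).
#' @param direction `"hyper"`, `"hypo"` or `"both"` (sign of the shift;
#'   default `"hyper"`).
#' @param min_separation minimum nt between planted regions (default
#'   1000).
#' @param seed integer seed.
#' @return an object of class `synthetic_truth`: a list with `regions`
#'   (a `data.table` with `chrom`, `start`, `end`, `context`, `effect`,
#'   `direction`, `host`) and `seed`.
#' @export
plant_dmrs <- function(features, n_regions, contexts = "CHH",
                       effect_range = c(0.3, 0.6), length_range = c(250L, 600L),
                       te_fraction = 0.8, direction = "hyper",
                       min_separation = 1000L, seed = 1L) {
  stopifnot(inherits(features, "feature_set"), n_regions >= 0L,
            all(contexts %in% METH_CONTEXTS),
            direction %in% c("hyper", "hypo", "both"))
  set.seed(child_seed(seed, "plant"))
  empty <- data.table(chrom = character(0), start = integer(0), end = integer(0),
                      context = character(0), effect = numeric(0),
                      direction = character(0), host = character(0))
  if (n_regions == 0L) {
    return(structure(list(regions = empty, seed = seed), class = "synthetic_truth"))
  }
  tes <- features$tes
  te_dt <- data.table(chrom = as.character(GenomeInfoDb::seqnames(tes)),
                      start = GenomicRanges::start(tes),
                      end = GenomicRanges::end(tes),
                      width = GenomicRanges::width(tes))
  occupied <- data.table(chrom = c(as.character(GenomeInfoDb::seqnames(features$genes)),
                                   te_dt$chrom),
                         start = c(GenomicRanges::start(features$genes), te_dt$start),
                         end = c(GenomicRanges::end(features$genes), te_dt$end))
  chroms <- names(features$genome)

  regions <- empty
  in_te <- runif(n_regions) < te_fraction
  for (i in seq_len(n_regions)) {
    w <- sample(length_range[1L]:length_range[2L], 1L)
    placed <- FALSE
    for (try in seq_len(400L)) {
      if (in_te[i]) {
        cands <- te_dt[width >= w]
        if (nrow(cands) == 0L) break
        host <- cands[sample.int(nrow(cands), 1L, prob = cands$width)]
        s <- host$start + sample.int(host$width - w + 1L, 1L) - 1L
        ch <- host$chrom; host_lab <- "te"
      } else {
        ch <- sample(chroms, 1L)
        s <- sample.int(features$genome[[ch]] - w + 1L, 1L)
        host_lab <- "intergenic"
        # intergenic regions must not touch any annotated feature
        if (nrow(occupied[chrom == ch & start <= s + w - 1L & end >= s])) next
      }
      e <- s + w - 1L
      near <- regions[chrom == ch &
                        start <= e + min_separation & end >= s - min_separation]
      if (nrow(near) == 0L) {
        sgn <- switch(direction, hyper = 1, hypo = -1,
                      both = sample(c(-1, 1), 1L))
        eff <- sgn * runif(1L, effect_range[1L], effect_range[2L])
        regions <- rbind(regions, data.table(
          chrom = ch, start = s, end = e,
          context = sample(contexts, 1L),
          effect = eff,
          direction = if (eff < 0) "hypo" else "hyper",
          host = host_lab))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not plant region ", i, "; layout infeasible")
  }
  setkey(regions, chrom, start)
  structure(list(regions = regions[], seed = seed), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d planted region(s), seed %s\n",
              nrow(x$regions), format(x$seed)))
  invisible(x)
}

# trinucleotides compatible with each context (second base G <=> CG, etc.)
context_trinucleotides <- list(
  CG = c("CGA", "CGT", "CGC", "CGG"),
  CHG = c("CAG", "CTG", "CCG"),
  CHH = c("CAA", "CAT", "CAC", "CTA", "CTT", "CTC", "CCA", "CCT", "CCC"))

#' Simulate cytosine positions for a feature set
#'
#' Draws strand-resolved cytosine positions per context at the densities
#' of a [compartment_model()], with context-consistent trinucleotides.
#' Positions are simulated once per scenario and shared by every
#' replicate and genotype (the genome sequence does not change between
#' samples); counts are drawn separately per sample.
#'
#' @param features a [feature_set()] (provides chromosome lengths).
#' @param model a [compartment_model()].
#' @param seed integer seed.
#' @return a `data.table` with `chrom`, `pos`, `strand`, `context`,
#'   `trinucleotide`, sorted with no duplicate (chrom, pos, strand).
#' @export
simulate_cytosine_positions <- function(features, model, seed = 1L) {
  set.seed(child_seed(seed, "positions"))
  out <- rbindlist(lapply(names(features$genome), function(ch) {
    len <- features$genome[[ch]]
    rbindlist(lapply(METH_CONTEXTS, function(ctx) {
      n <- round(len * model$cytosine_density[[ctx]])
      if (n == 0L) return(NULL)
      data.table(chrom = ch,
                 pos = sample.int(len, n, replace = TRUE),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 context = ctx,
                 trinucleotide = sample(context_trinucleotides[[ctx]], n,
                                        replace = TRUE))
    }))
  }))
  out <- out[!duplicated(out, by = c("chrom", "pos", "strand"))]
  setkey(out, chrom, pos, strand)
  out[]
}

# compartment of each position: TE beats gene body (a TE inside a gene is
# still TE chromatin); long TEs are those of at least `long_te_min` nt
classify_compartment <- function(positions, features, long_te_min = 1500L) {
  comp <- rep("intergenic", nrow(positions))
  pos_gr <- GenomicRanges::GRanges(positions$chrom,
                                   IRanges::IRanges(positions$pos, positions$pos))
  if (length(features$genes)) {
    hit <- IRanges::overlapsAny(pos_gr, features$genes, ignore.strand = TRUE)
    comp[hit] <- "gene_body"
  }
  if (length(features$tes)) {
    short_te <- features$tes[GenomicRanges::width(features$tes) < long_te_min]
    long_te <- features$tes[GenomicRanges::width(features$tes) >= long_te_min]
    comp[IRanges::overlapsAny(pos_gr, short_te, ignore.strand = TRUE)] <- "te_short"
    comp[IRanges::overlapsAny(pos_gr, long_te, ignore.strand = TRUE)] <- "te_long"
  }
  comp
}

#' Simulate one replicate methylome
#'
#' Draws per-site coverage from a Poisson distribution and methylated
#' counts from a beta-binomial whose mean is the compartment baseline of
#' the site, shifted (and clipped to `[0, 1]`) by any planted region of
#' the same context containing the site. Pass `truth = NULL` for the
#' wild-type and the [plant_dmrs()] truth for the mutant. Replicates share
#' cytosine positions and differ only in counts; everything is
#' deterministic given `(seed, genotype, replicate)`.
#'
#' @param features a [feature_set()].
#' @param model a [compartment_model()].
#' @param genotype,replicate labels; the count RNG stream is derived from
#'   them, so replicates differ while remaining reproducible.
#' @param truth a `synthetic_truth` whose effects apply to this sample,
#'   or `NULL`.
#' @param seed scenario seed (shared across the samples of one scenario).
#' @param positions optional precomputed [simulate_cytosine_positions()]
#'   table; computed from `seed` when `NULL`.
#' @return a [methylome_sample()].
#' @export
simulate_methylome <- function(features, model, genotype = "wt",
                               replicate = "r1", truth = NULL, seed = 1L,
                               positions = NULL) {
  stopifnot(inherits(features, "feature_set"), inherits(model, "compartment_model"))
  if (is.null(positions)) {
    positions <- simulate_cytosine_positions(features, model, seed)
  }
  pos <- copy(positions)
  comp <- classify_compartment(pos, features)
  lvl <- model$levels[cbind(comp, pos$context)]

  if (!is.null(truth) && nrow(truth$regions)) {
    tr <- truth$regions
    hits <- pos[, .(row = .I, chrom, pos, context)][
      tr, on = .(chrom, context, pos >= start, pos <= end),
      .(row = x.row, effect = i.effect), nomatch = NULL]
    if (nrow(hits)) {
      lvl[hits$row] <- pmin(1, pmax(0, lvl[hits$row] + hits$effect))
    }
  }

  set.seed(child_seed(seed, paste("counts", genotype, replicate)))
  n <- nrow(pos)
  coverage <- rpois(n, model$coverage_mean)
  rho <- model$dispersion
  if (rho > 0) {
    p <- lvl
    mid <- lvl > 0 & lvl < 1
    shape <- (1 - rho) / rho
    p[mid] <- rbeta(sum(mid), lvl[mid] * shape, (1 - lvl[mid]) * shape)
  } else {
    p <- lvl
  }
  meth <- rbinom(n, coverage, p)
  pos[, `:=`(count_meth = meth, count_unmeth = coverage - meth)]
  setcolorder(pos, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                     "context", "trinucleotide"))
  methylome_sample(pos, genotype = genotype, replicate = replicate,
                   genome = features$genome)
}

#' Simulate a complete two-genotype scenario
#'
#' The default validation scenario: a 1-Mb chromosome carrying 40 genes
#' and 80 TEs, 60 planted CHH regions of effect magnitude 0.3-0.6 inside
#' TEs (80%) or intergenic space, 20x mean coverage and two replicates per
#' genotype. The wild-type draws from the compartment baselines; the
#' mutant additionally carries the planted shifts.
#'
#' @param genome_length,n_genes,n_tes genome layout.
#' @param n_dmrs number of planted regions.
#' @param contexts,effect_range,length_range,te_fraction,direction passed
#'   to [plant_dmrs()].
#' @param model a [compartment_model()] (defaults).
#' @param n_replicates replicates per genotype (default 2).
#' @param seed scenario seed.
#' @return a list with `features`, `truth`, `model`, `positions`, and the
#'   sample lists `wt` and `mut`.
#' @export
simulate_scenario <- function(genome_length = 1e6, n_genes = 40L, n_tes = 80L,
                              n_dmrs = 60L, contexts = "CHH",
                              effect_range = c(0.3, 0.6),
                              length_range = c(250L, 600L),
                              te_fraction = 0.8, direction = "hyper",
                              model = compartment_model(),
                              n_replicates = 2L, seed = 1L) {
  features <- simulate_genome(genome_length, n_genes, n_tes, seed = seed)
  truth <- plant_dmrs(features, n_dmrs, contexts = contexts,
                      effect_range = effect_range, length_range = length_range,
                      te_fraction = te_fraction, direction = direction,
                      seed = seed)
  positions <- simulate_cytosine_positions(features, model, seed)
  reps <- paste0("r", seq_len(n_replicates))
  wt <- lapply(reps, function(r) simulate_methylome(
    features, model, genotype = "wt", replicate = r, truth = NULL,
    seed = seed, positions = positions))
  mut <- lapply(reps, function(r) simulate_methylome(
    features, model, genotype = "mutant", replicate = r, truth = truth,
    seed = seed, positions = positions))
  names(wt) <- names(mut) <- reps
  list(features = features, truth = truth, model = model,
       positions = positions, wt = wt, mut = mut)
}

#' Score called DMRs against planted truth
#'
#' A planted region is recovered when some called DMR of the same context
#' and direction overlaps it reciprocally by at least
#' `min_reciprocal_overlap` (intersection at least that fraction of both
#' lengths). Sensitivity is the recovered fraction of planted regions;
#' the false-discovery proportion (FDP) is the fraction of called DMRs
#' matching no planted region (`NA` when nothing was called).
#'
#' @param called DMR table from [call_dmrs()].
#' @param truth a `synthetic_truth` from [plant_dmrs()].
#' @param min_reciprocal_overlap reciprocal overlap threshold (default
#'   0.5).
#' @return a list with `sensitivity`, `fdp`, `n_called`, `n_planted`,
#'   `recovered` (logical per planted region) and `called_matched`
#'   (logical per called DMR).
#' @export
evaluate_calls <- function(called, truth, min_reciprocal_overlap = 0.5) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tr <- truth$regions
  n_called <- if (is.null(called)) 0L else nrow(called)
  recovered <- rep(FALSE, nrow(tr))
  called_matched <- rep(FALSE, n_called)
  if (n_called > 0L && nrow(tr) > 0L) {
    for (i in seq_len(nrow(tr))) {
      ov_lo <- pmax(called$start, tr$start[i])
      ov_hi <- pmin(called$end, tr$end[i])
      ov <- pmax(0L, ov_hi - ov_lo + 1L)
      len_c <- called$end - called$start + 1L
      len_t <- tr$end[i] - tr$start[i] + 1L
      match_i <- called$chrom == tr$chrom[i] &
        called$context == tr$context[i] &
        called$direction == tr$direction[i] &
        ov >= min_reciprocal_overlap * len_c &
        ov >= min_reciprocal_overlap * len_t
      if (any(match_i)) {
        recovered[i] <- TRUE
        called_matched <- called_matched | match_i
      }
    }
  }
  list(sensitivity = if (nrow(tr)) mean(recovered) else NA_real_,
       fdp = if (n_called) mean(!called_matched) else NA_real_,
       n_called = n_called, n_planted = nrow(tr),
       recovered = recovered, called_matched = called_matched)
}
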