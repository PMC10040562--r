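#' Parameters of the window-based DMR caller
#'
#' Defaults follow the standard plant WGBS recipe: a 50-nt window scan,
#' candidate windows closer than 100 nt merged into one region, regions of
#' at least 100 nt containing at least 20 covered cytosine positions,
#' per-context minimum methylation differences of 10% (CHH), 20% (CHG) and
#' 40% (CG), and a two-sided Fisher's exact test at p < 0.001 without
#' multiple-testing correction.
#'
#' @param window scan window width in nt.
#' @param max_gap largest gap (nt) between candidate windows that still
#'   merges them; two windows separated by more than this are independent
#'   regions.
#' @param min_length minimum region length in nt.
#' @param min_sites minimum number of cytosine positions covered in both
#'   samples within the region.
#' @param min_diff named per-context minimum absolute level difference.
#' @param alpha p-value bound for the Fisher test.
#' @return a named list of class `dmr_params`.
#' @export
dmr_params <- function(window = 50L, max_gap = 100L, min_length = 100L,
                       min_sites = 20L,
                       min_diff = c(CG = 0.40, CHG = 0.20, CHH = 0.10),
                       alpha = 0.001) {
  stopifnot(window >= 1L, max_gap >= 0L, min_length >= 1L, min_sites >= 1L,
            alpha > 0, all(METH_CONTEXTS %in% names(min_diff)),
            all(min_diff > 0))
  structure(list(window = as.integer(window), max_gap = as.integer(max_gap),
                 min_length = as.integer(min_length),
                 min_sites = as.integer(min_sites),
                 min_diff = min_diff[METH_CONTEXTS], alpha = alpha),
            class = "dmr_params")
}

#' Pool replicate methylomes of one genotype by count summation
#'
#' Read counts are summed per (chrom, pos, strand) across replicates, so
#' the pooled weighted level of any region equals the count-weighted
#' combination of the replicate levels. Sites present in only some
#' replicates keep the counts they have; the context recorded at a shared
#' position must agree across replicates.
#'
#' @param samples a list of [methylome_sample()] objects sharing a genome.
#' @return a [methylome_sample()] with replicate label `"pooled"`.
#' @export
pool_replicates <- function(samples) {
  stopifnot(length(samples) >= 1L,
            all(vapply(samples, inherits, TRUE, "methylome_sample")))
  if (length(samples) == 1L) return(samples[[1L]])
  all_sites <- rbindlist(lapply(samples, `[[`, "sites"))
  ctx <- all_sites[, .(n_ctx = uniqueN(context)), by = .(chrom, pos, strand)]
  if (any(ctx$n_ctx > 1L)) {
    bad <- ctx[n_ctx > 1L][1L]
    stop("context disagreement across replicates at ", bad$chrom, ":", bad$pos,
         " (", bad$strand, ")")
  }
  pooled <- all_sites[, .(count_meth = sum(count_meth),
                          count_unmeth = sum(count_unmeth),
                          context = context[1L],
                          trinucleotide = trinucleotide[1L]),
                      by = .(chrom, pos, strand)]
  setkey(pooled, chrom, pos, strand)
  genome_lens <- Reduce(function(a, b) {
    chroms <- union(names(a), names(b))
    setNames(pmax(a[chroms], b[chroms], na.rm = TRUE), chroms)
  }, lapply(samples, `[[`, "genome"))
  methylome_sample(pooled, genotype = samples[[1L]]$genotype,
                   replicate = "pooled", genome = genome_lens)
}

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Exact two-sided p-value for independence in the table
#' `rbind(c(a, b), c(c, d))`, computed by summing, over all tables with the
#' observed margins, the hypergeometric probabilities that do not exceed
#' the probability of the observed table (the minimum-likelihood
#' definition of "as or more extreme"). Vectorised over tables. A zero row
#' or column margin gives p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer counts; in the DMR caller these are
#'   wild-type methylated/unmethylated and mutant methylated/unmethylated
#'   read totals of a region.
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(a + b + c + d)) || any(c(a, b, c, d) < 0)) {
    stop("counts must be non-negative and finite")
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]          # row 1 margin
    nn <- c[i] + d[i]         # row 2 margin
    k <- a[i] + c[i]          # column 1 margin
    if (m == 0 || nn == 0 || k == 0 || (b[i] + d[i]) == 0) return(1)
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    obs <- dhyper(a[i], m, nn, k)
    min(1, sum(probs[probs <= obs * (1 + 1e-07)]))
  }, numeric(1))
}

#' Scan tiling windows for candidate methylation differences
#'
#' Tiles each chromosome with non-overlapping windows (50 nt) and flags a
#' window as a candidate when both samples have at least one covered
#' cytosine of the context in it and the absolute difference of the pooled
#' window levels reaches the per-context minimum difference.
#'
#' @param wt,mut single (pooled) [methylome_sample()] objects.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params a [dmr_params()].
#' @return a `data.table` of candidate windows sorted by (chrom, start)
#'   with 1-based inclusive `start`/`end`, per-sample counts and levels,
#'   and `diff = mut_level - wt_level`.
#' @export
scan_windows <- function(wt, mut, context, params = dmr_params()) {
  match_context(context)
  stopifnot(inherits(wt, "methylome_sample"), inherits(mut, "methylome_sample"))
  w <- params$window
  win_counts <- function(sample) {
    s <- sample$sites[context, on = "context", nomatch = NULL]
    s <- s[count_meth + count_unmeth > 0L]
    s[, .(meth = sum(count_meth), unmeth = sum(count_unmeth), n = .N),
      by = .(chrom, wstart = as.integer((pos - 1L) %/% w) * w + 1L)]
  }
  cw <- win_counts(wt)
  cm <- win_counts(mut)
  both <- cw[cm, on = .(chrom, wstart), nomatch = NULL]
  if (nrow(both) == 0L) {
    return(data.table(chrom = character(0), start = integer(0), end = integer(0),
                      wt_meth = integer(0), wt_unmeth = integer(0),
                      mut_meth = integer(0), mut_unmeth = integer(0),
                      wt_level = numeric(0), mut_level = numeric(0),
                      diff = numeric(0)))
  }
  setnames(both, c("meth", "unmeth", "n", "i.meth", "i.unmeth", "i.n"),
           c("wt_meth", "wt_unmeth", "wt_n", "mut_meth", "mut_unmeth", "mut_n"))
  both[, `:=`(wt_level = wt_meth / (wt_meth + wt_unmeth),
              mut_level = mut_meth / (mut_meth + mut_unmeth))]
  both[, diff := mut_level - wt_level]
  cand <- both[abs(diff) >= params$min_diff[[context]]]
  cand[, `:=`(start = wstart, end = wstart + w - 1L,
              wstart = NULL, wt_n = NULL, mut_n = NULL)]
  setcolorder(cand, c("chrom", "start", "end"))
  setkey(cand, chrom, start)
  cand[]
}

#' Merge candidate windows into candidate regions
#'
#' Consecutive candidate windows on the same chromosome whose gap is at
#' most `max_gap` nt belong to the same region; windows separated by more
#' than `max_gap` start independent regions. Merging is idempotent.
#'
#' @param windows candidate windows from [scan_windows()] (1-based
#'   inclusive `start`/`end`).
#' @param max_gap largest mergeable gap in nt (default 100).
#' @return a `data.table` of regions (`chrom`, `start`, `end`,
#'   `n_windows`).
#' @export
merge_candidates <- function(windows, max_gap = 100L) {
  if (nrow(windows) == 0L) {
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0)))
  }
  w <- copy(windows)[order(chrom, start)]
  w[, gap := start - shift(end) - 1L, by = chrom]
  w[, new_region := is.na(gap) | gap > max_gap]
  w[, region := cumsum(new_region)]
  w[, .(chrom = chrom[1L], start = min(start), end = max(end),
        n_windows = .N), by = region][, region := NULL][]
}

#' Call differentially methylated regions between two methylomes
#'
#' The full caller for one context: scan 50-nt tiling windows for
#' candidate differences, merge candidates separated by at most 100 nt,
#' recompute pooled counts and levels over every covered cytosine of the
#' context in each merged region, and keep regions that (i) span at least
#' `min_length` nt, (ii) contain at least `min_sites` cytosine positions
#' covered in both samples, (iii) show an absolute region-level difference
#' of at least the per-context minimum, and (iv) reach p < `alpha` in a
#' two-sided Fisher's exact test on the pooled 2x2 count table
#' (wt meth/unmeth vs mutant meth/unmeth). Direction is `hypo` when the
#' mutant level is below wild-type, `hyper` otherwise.
#'
#' @inheritParams scan_windows
#' @return a `data.table` sorted by (chrom, start), one row per DMR:
#'   `chrom`, `start`, `end` (1-based inclusive), `length`, `context`,
#'   `direction`, `wt_level`, `mut_level`, `diff`, `n_sites`, `p_value`
#'   and the pooled counts `wt_meth`, `wt_unmeth`, `mut_meth`,
#'   `mut_unmeth`.
#' @export
call_dmrs <- function(wt, mut, context, params = dmr_params()) {
  match_context(context)
  if (nrow(wt$sites) == 0L || nrow(mut$sites) == 0L) {
    warning("empty input sample; no DMRs called")
    return(empty_dmr_table())
  }
  cand <- scan_windows(wt, mut, context, params)
  regions <- merge_candidates(cand, params$max_gap)
  regions <- regions[end - start + 1L >= params$min_length]
  if (nrow(regions) == 0L) return(empty_dmr_table())

  covered <- function(sample) {
    s <- sample$sites[context, on = "context", nomatch = NULL]
    s[count_meth + count_unmeth > 0L,
      .(chrom, pos, strand, count_meth, count_unmeth)]
  }
  sw <- covered(wt)
  sm <- covered(mut)
  regions[, rid := .I]
  pool_region <- function(s) {
    s[regions, on = .(chrom, pos >= start, pos <= end),
      .(rid = i.rid, strand = x.strand, gpos = x.pos,
        count_meth = x.count_meth, count_unmeth = x.count_unmeth),
      nomatch = NULL]
  }
  hw <- pool_region(sw)
  hm <- pool_region(sm)
  aw <- hw[, .(wt_meth = sum(count_meth), wt_unmeth = sum(count_unmeth)), by = rid]
  am <- hm[, .(mut_meth = sum(count_meth), mut_unmeth = sum(count_unmeth)), by = rid]
  shared <- merge(hw[, .(rid, gpos, strand)], hm[, .(rid, gpos, strand)],
                  by = c("rid", "gpos", "strand"))[, .(n_sites = .N), by = rid]

  out <- regions[, .(rid, chrom, start, end)]
  out <- Reduce(function(x, y) merge(x, y, by = "rid", all.x = TRUE),
                list(out, aw, am, shared))
  for (col in c("wt_meth", "wt_unmeth", "mut_meth", "mut_unmeth", "n_sites")) {
    out[is.na(get(col)), (col) := 0L]
  }
  out[, `:=`(wt_level = ifelse(wt_meth + wt_unmeth > 0,
                               wt_meth / (wt_meth + wt_unmeth), NA_real_),
             mut_level = ifelse(mut_meth + mut_unmeth > 0,
                                mut_meth / (mut_meth + mut_unmeth), NA_real_))]
  out[, diff := mut_level - wt_level]
  out <- out[n_sites >= params$min_sites &
               !is.na(diff) & abs(diff) >= params$min_diff[[context]]]
  if (nrow(out) == 0L) return(empty_dmr_table())
  out[, p_value := fisher_exact_2x2(wt_meth, wt_unmeth, mut_meth, mut_unmeth)]
  out <- out[p_value < params$alpha]
  if (nrow(out) == 0L) return(empty_dmr_table())
  out[, `:=`(length = end - start + 1L,
             context = context,
             direction = ifelse(diff < 0, "hypo", "hyper"),
             rid = NULL)]
  setcolorder(out, c("chrom", "start", "end", "length", "context", "direction",
                     "wt_level", "mut_level", "diff", "n_sites", "p_value",
                     "wt_meth", "wt_unmeth", "mut_meth", "mut_unmeth"))
  setkey(out, chrom, start)
  out[]
}

empty_dmr_table <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             length = integer(0), context = character(0),
             direction = character(0), wt_level = numeric(0),
             mut_level = numeric(0), diff = numeric(0), n_sites = integer(0),
             p_value = numeric(0), wt_meth = integer(0), wt_unmeth = integer(0),
             mut_meth = integer(0), mut_unmeth = integer(0))
}

#' Per-context DMR count and coverage summary
#'
#' The per-genotype report structure: number of DMRs and kilobases covered
#' per context with a total row, plus each context's share of all DMRs as
#' a percentage (1 decimal).
#'
#' @param dmrs a DMR table from [call_dmrs()] (contexts may be mixed).
#' @return a `data.table` with rows CG, CHG, CHH and `Total` and columns
#'   `n_dmrs`, `kb_covered`, `pct_of_total`.
#' @export
tabulate_dmr_totals <- function(dmrs) {
  base <- data.table(context = METH_CONTEXTS)
  agg <- dmrs[, .(n_dmrs = .N, kb_covered = round(sum(end - start + 1L) / 1000, 2)),
              by = context]
  out <- merge(base, agg, by = "context", all.x = TRUE, sort = FALSE)
  out[is.na(n_dmrs), `:=`(n_dmrs = 0L, kb_covered = 0)]
  total <- data.table(context = "Total", n_dmrs = sum(out$n_dmrs),
                      kb_covered = round(sum(out$kb_covered), 2))
  out[, pct_of_total := percent_of(n_dmrs, total$n_dmrs, 1)]
  total[, pct_of_total := ifelse(n_dmrs > 0, 100, NA_real_)]
  rbind(out, total)[]
}
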