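#' Per-site methylation frequency
#'
#' The single-nucleotide methylation frequency: methylated reads over total
#' reads at the site (the count of cytosines over cytosines plus thymines
#' in bisulfite space). Vectorised; zero-coverage sites yield `NA`, never 0.
#'
#' @param count_meth,count_unmeth non-negative integer vectors.
#' @return numeric vector of frequencies in `[0, 1]` with `NA` at
#'   zero-coverage sites.
#' @export
site_frequency <- function(count_meth, count_unmeth) {
  cov <- count_meth + count_unmeth
  ifelse(cov > 0, count_meth / cov, NA_real_)
}

#' Binned weighted methylation levels
#'
#' Tiles each chromosome with non-overlapping bins (50 nt by default) and
#' computes the weighted methylation level of each bin: the total number of
#' methylated read calls divided by the total number of read calls over all
#' cytosines of the requested context in the bin. This is count pooling,
#' not a mean of per-site frequencies, so deeply covered sites weigh more.
#'
#' @param sample a [methylome_sample()].
#' @param bin_size bin width in nt (default 50).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`; with `"all"` a level
#'   is reported per (bin, context) present.
#' @return a `data.table` with columns `chrom`, `bin_start` (1-based start
#'   of the bin), `context`, `total_meth`, `total_c`, `level`. Bins that
#'   contain cytosines of the context but no covered one carry `level = NA`;
#'   bins without any cytosine are omitted.
#' @export
bin_levels <- function(sample, bin_size = 50L, context = "all") {
  stopifnot(inherits(sample, "methylome_sample"), bin_size >= 1L)
  context <- match_context(context, allow_all = TRUE)
  s <- sample$sites
  if (context != "all") s <- s[context, on = "context"]
  if (nrow(s) == 0L) {
    return(data.table(chrom = character(0), bin_start = integer(0),
                      context = character(0), total_meth = integer(0),
                      total_c = integer(0), level = numeric(0)))
  }
  out <- s[, .(total_meth = sum(count_meth),
               total_c = sum(count_meth + count_unmeth)),
           by = .(chrom, bin_start = as.integer((pos - 1L) %/% bin_size) * bin_size + 1L,
                  context)]
  out[, level := ifelse(total_c > 0, total_meth / total_c, NA_real_)]
  setkey(out, chrom, bin_start, context)
  out[]
}

#' Genome-wide weighted methylation levels per context
#'
#' Pools methylated and total read calls over every covered cytosine of
#' each context across the whole genome and reports the weighted level
#' (and the same number as a percentage rounded to 2 decimals, the
#' precision used for genome-wide summaries).
#'
#' @param sample a [methylome_sample()].
#' @return a `data.table` keyed by `context` with columns `total_meth`,
#'   `total_c`, `n_sites` (covered sites), `level` and `percent`. Contexts
#'   with no covered site carry `NA` levels.
#' @export
global_levels <- function(sample) {
  stopifnot(inherits(sample, "methylome_sample"))
  agg <- sample$sites[, .(total_meth = sum(count_meth),
                          total_c = sum(count_meth + count_unmeth),
                          n_sites = sum(count_meth + count_unmeth > 0L)),
                      by = context]
  out <- data.table(context = METH_CONTEXTS)[agg, on = "context",
    `:=`(total_meth = i.total_meth, total_c = i.total_c, n_sites = i.n_sites)]
  out[is.na(total_c), `:=`(total_meth = 0L, total_c = 0L, n_sites = 0L)]
  out[, level := ifelse(total_c > 0, total_meth / total_c, NA_real_)]
  out[, percent := round(100 * level, 2)]
  setkey(out, context)
  out[]
}

#' Relative reduction of a global methylation level
#'
#' Percentage loss of the test sample relative to the reference:
#' `100 * (reference - test) / reference`, the convention used to report
#' how much overall methylation a mutant has lost in a given context.
#'
#' @param reference,test `data.table`s from [global_levels()], or bare
#'   numeric levels.
#' @param context context to compare when tables are given.
#' @param digits decimals kept in the result (default 2).
#' @return a single percentage (positive = loss in `test`).
#' @export
relative_reduction <- function(reference, test, context = "CHH", digits = 2) {
  lv <- function(x) {
    if (is.numeric(x) && length(x) == 1L) return(x)
    match_context(context)
    x[context, on = "context"]$level
  }
  ref <- lv(reference); tst <- lv(test)
  if (is.na(ref) || ref <= 0) {
    stop("reference level is zero or missing in context ", context)
  }
  round(100 * (ref - tst) / ref, digits)
}
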