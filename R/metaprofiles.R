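#' Oriented coordinate frames for end-anchored profiles
#'
#' For each feature, builds the frame that maps genomic positions to
#' offsets relative to one feature end (the anchor), so that methylation
#' can be averaged across features aligned at their 5' or 3' ends.
#' Minus-strand features are flipped: `five_prime` always means the
#' biological 5' end and offsets increase in the direction of
#' transcription. Positions inside the feature that lie within `discard`
#' nt of the end opposite to the anchor are masked, i.e. excluded from all
#' interval sums; features shorter than `discard` keep their flanks but
#' have the whole body masked.
#'
#' @param features a `GRanges` (strand `*` is treated as `+`).
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param flank profile half-width in nt (default 5000).
#' @param discard nt to mask at the opposite end (1500 for genes, 250 for
#'   TEs by convention).
#' @return a `data.table` with one row per feature: `chrom`, `fstart`,
#'   `fend`, `sgn` (+1/-1 orientation), `anchor_pos`, `win_lo`/`win_hi`
#'   (genomic extent of the profile window) and `mask_lo`/`mask_hi`
#'   (genomic extent of the masked body segment, `NA` when `discard = 0`).
#' @export
feature_frames <- function(features, anchor = c("five_prime", "three_prime"),
                           flank = 5000L, discard = 0L) {
  anchor <- match.arg(anchor)
  stopifnot(methods::is(features, "GRanges"))
  w <- GenomicRanges::width(features)
  if (any(w < 1L)) stop("feature with non-positive length")
  fr <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(features)),
    fstart = GenomicRanges::start(features),
    fend = GenomicRanges::end(features),
    sgn = ifelse(as.character(GenomicRanges::strand(features)) == "-", -1L, 1L))
  at_five <- (anchor == "five_prime")
  fr[, anchor_pos := ifelse(sgn == 1L, if (at_five) fstart else fend,
                            if (at_five) fend else fstart)]
  # genomic window giving offsets in [-flank, flank)
  fr[, win_lo := ifelse(sgn == 1L, anchor_pos - flank, anchor_pos - flank + 1L)]
  fr[, win_hi := ifelse(sgn == 1L, anchor_pos + flank - 1L, anchor_pos + flank)]
  # mask `discard` nt of the body at the end opposite the anchor
  if (discard > 0L) {
    opp_right <- (fr$sgn == 1L) == at_five   # mask sits at the right genomic end
    fr[, mask_lo := ifelse(opp_right, pmax(fstart, fend - discard + 1L), fstart)]
    fr[, mask_hi := ifelse(opp_right, fend, pmin(fend, fstart + discard - 1L))]
  } else {
    fr[, `:=`(mask_lo = NA_integer_, mask_hi = NA_integer_)]
  }
  fr[]
}

#' End-anchored average methylation profile over a feature class
#'
#' Pools methylated and total read calls into fixed-width offset intervals
#' (100 nt by default) spanning `flank` nt on both sides of the anchored
#' feature end, over all features of a class, then divides per interval.
#' A cytosine overlapped by the windows of several features contributes
#' once per feature frame. Body positions within `discard` nt of the end
#' opposite the anchor are excluded (see [feature_frames()]).
#'
#' @param sample a [methylome_sample()].
#' @param features a `GRanges`, or a [feature_set()] from which the class
#'   is picked.
#' @param feature_class `"gene"` or `"TE"`; sets the default `discard`
#'   (1500 and 250 nt respectively).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param anchor `"five_prime"` or `"three_prime"`.
#' @param flank half-width in nt (default 5000).
#' @param interval_size averaging interval in nt (default 100).
#' @param discard override of the class default mask length.
#' @return an object of class `meta_profile`: a `data.table` with columns
#'   `offset_start` (interval start relative to the anchor; upstream
#'   negative), `total_meth`, `total_c`, `level` (`NA` where no covered
#'   cytosine falls in the interval), with the geometry stored in
#'   attributes.
#' @export
compute_metaprofile <- function(sample, features,
                                feature_class = c("gene", "TE"),
                                context = "CHH",
                                anchor = c("five_prime", "three_prime"),
                                flank = 5000L, interval_size = 100L,
                                discard = NULL) {
  feature_class <- match.arg(feature_class)
  anchor <- match.arg(anchor)
  match_context(context)
  stopifnot(inherits(sample, "methylome_sample"))
  if (inherits(features, "feature_set")) {
    features <- if (feature_class == "gene") features$genes else features$tes
  }
  if (length(features) == 0L) stop("no features to profile")
  if (is.null(discard)) discard <- if (feature_class == "gene") 1500L else 250L
  if (2L * flank %% interval_size != 0L) {
    stop("2 * flank must be a multiple of interval_size")
  }

  fr <- feature_frames(features, anchor = anchor, flank = flank, discard = discard)
  sites <- sample$sites[context, on = "context", nomatch = NULL]
  sites <- sites[count_meth + count_unmeth > 0L]

  n_bins <- as.integer(2L * flank / interval_size)
  prof <- data.table(bin = seq_len(n_bins) - 1L)
  prof[, offset_start := -flank + bin * interval_size]
  prof[, `:=`(total_meth = 0L, total_c = 0L)]

  if (nrow(sites)) {
    hits <- sites[fr, on = .(chrom, pos >= win_lo, pos <= win_hi),
                  .(gpos = x.pos, count_meth = x.count_meth,
                    count_unmeth = x.count_unmeth,
                    sgn = i.sgn, anchor_pos = i.anchor_pos,
                    mask_lo = i.mask_lo, mask_hi = i.mask_hi),
                  nomatch = NULL]
    if (nrow(hits)) {
      hits <- hits[is.na(mask_lo) | gpos < mask_lo | gpos > mask_hi]
    }
    if (nrow(hits)) {
      hits[, offset := sgn * (gpos - anchor_pos)]
      agg <- hits[, .(total_meth = sum(count_meth),
                      total_c = sum(count_meth + count_unmeth)),
                  by = .(bin = as.integer((offset + flank) %/% interval_size))]
      prof[agg, on = "bin", `:=`(total_meth = i.total_meth, total_c = i.total_c)]
    }
  }
  prof[, level := ifelse(total_c > 0, total_meth / total_c, NA_real_)]
  if (all(prof$total_c == 0L)) warning("no covered cytosine in any interval")
  setattr(prof, "sample", paste(sample$genotype, sample$replicate, sep = "_"))
  setattr(prof, "feature_class", feature_class)
  setattr(prof, "context", context)
  setattr(prof, "anchor", anchor)
  setattr(prof, "flank", as.integer(flank))
  setattr(prof, "interval_size", as.integer(interval_size))
  setattr(prof, "class", c("meta_profile", class(prof)))
  prof[]
}

#' Difference between two metaprofiles
#'
#' Elementwise `b - a` over profiles with identical geometry, with `NA`
#' propagation; the summary statistics ignore intervals missing in either
#' profile.
#'
#' @param a,b `meta_profile` objects sharing feature class, context,
#'   anchor, flank and interval size.
#' @return a list with `table` (`offset_start`, `level_a`, `level_b`,
#'   `diff`), `mean_diff` and `mean_abs_diff`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "meta_profile"), inherits(b, "meta_profile"))
  for (at in c("feature_class", "context", "anchor", "flank", "interval_size")) {
    if (!identical(attr(a, at), attr(b, at))) {
      stop("profile geometry mismatch on '", at, "'")
    }
  }
  tab <- data.table(offset_start = a$offset_start,
                    level_a = a$level, level_b = b$level)
  tab[, diff := level_b - level_a]
  ok <- !is.na(tab$diff)
  list(table = tab[],
       mean_diff = if (any(ok)) mean(tab$diff[ok]) else NA_real_,
       mean_abs_diff = if (any(ok)) mean(abs(tab$diff[ok])) else NA_real_)
}
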