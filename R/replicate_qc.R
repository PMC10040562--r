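#' Site-frequency matrix over cytosines covered in every sample
#'
#' Extracts the (chrom, pos, strand) cytosine sites of one context that
#' reach the minimum coverage in every sample and returns their
#' methylation frequencies as a samples x sites matrix with no missing
#' entries — the input for replicate-reproducibility PCA.
#'
#' @param samples a named list (>= 2) of [methylome_sample()] objects;
#'   unnamed lists are labelled `genotype_replicate`.
#' @param context context of the sites (default `"CG"`).
#' @param min_coverage minimum reads for a site to count as covered
#'   (default 1).
#' @return a numeric matrix, rows = samples, columns = shared sites named
#'   `chrom:pos:strand`, entries in `[0, 1]`.
#' @export
shared_sites <- function(samples, context = "CG", min_coverage = 1L) {
  stopifnot(length(samples) >= 2L,
            all(vapply(samples, inherits, TRUE, "methylome_sample")))
  match_context(context)
  if (is.null(names(samples))) {
    names(samples) <- vapply(samples, function(s)
      paste(s$genotype, s$replicate, sep = "_"), "")
  }
  covered <- lapply(samples, function(s) {
    x <- s$sites[context, on = "context", nomatch = NULL]
    x[count_meth + count_unmeth >= min_coverage,
      .(chrom, pos, strand, freq = count_meth / (count_meth + count_unmeth))]
  })
  n_cov <- vapply(covered, nrow, 0L)
  shared <- Reduce(function(a, b) a[b[, .(chrom, pos, strand)],
                                    on = .(chrom, pos, strand), nomatch = NULL],
                   covered[-1L], init = covered[[1L]][, .(chrom, pos, strand)])
  if (nrow(shared) == 0L) {
    stop("no ", context, " site covered in all samples (covered per sample: ",
         paste(sprintf("%s=%d", names(samples), n_cov), collapse = ", "), ")")
  }
  setkey(shared, chrom, pos, strand)
  mat <- do.call(rbind, lapply(covered, function(x) {
    x[shared, on = .(chrom, pos, strand)]$freq
  }))
  colnames(mat) <- shared[, paste(chrom, pos, strand, sep = ":")]
  rownames(mat) <- names(samples)
  mat
}

#' Principal component analysis of a shared-site frequency matrix
#'
#' Column-centered PCA without unit-variance scaling (frequencies already
#' share the `[0, 1]` scale), computed with a deterministic eigen
#' decomposition. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are reproducible across
#' column orderings.
#'
#' @param mat samples x sites matrix from [shared_sites()].
#' @param n_components number of components to return (default
#'   `nrow(mat) - 1`, the maximum meaningful rank).
#' @return a list of class `pca_result` with `coordinates` (samples x
#'   components), `var_explained` (all non-trivial variance fractions,
#'   non-increasing, summing to 1 for full rank) and `sdev`.
#' @export
pca_samples <- function(mat, n_components = nrow(mat) - 1L) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (n_components >= nrow(mat)) {
    stop("n_components must be smaller than the number of samples")
  }
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  var_explained <- if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  # fixed sign convention: largest |loading| of each kept component positive
  keep <- seq_len(min(n_components, ncol(p$x)))
  for (j in keep) {
    flip <- sign(p$rotation[which.max(abs(p$rotation[, j])), j])
    if (flip < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(coordinates = p$x[, keep, drop = FALSE],
                 var_explained = var_explained,
                 sdev = p$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- round(100 * x$var_explained, 1)
  cat("pca_result:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "components kept\n")
  cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  invisible(x)
}
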