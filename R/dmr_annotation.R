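#' Assign DMRs to promoters, gene bodies and transposable elements
#'
#' A DMR maps to a feature class when at least half of the DMR's length
#' (by default) overlaps a feature of that class: the 200-bp promoter, the
#' first-to-last-exon gene body, or an annotated TE. A DMR with both a
#' gene-element match and a TE match is categorised `gene_element_and_te`;
#' with neither it is `other`. When both the promoter and the gene body of
#' some gene reach the threshold, the promoter takes precedence for the
#' gene-side label.
#'
#' @param dmrs a DMR table from [call_dmrs()] (columns `chrom`, `start`,
#'   `end`, optionally `context`/`direction`, 1-based inclusive).
#' @param features a [feature_set()].
#' @param min_overlap minimum fraction of the DMR length that must overlap
#'   (default 0.5).
#' @return a `data.table`, one row per DMR, with `category` in
#'   `{promoter, gene_body, te, gene_element_and_te, other}`, `gene_side`
#'   (`promoter`/`gene_body`/`NA`), and comma-separated `gene_ids` and
#'   `te_ids` of every matched feature.
#' @export
assign_dmrs <- function(dmrs, features, min_overlap = 0.5) {
  stopifnot(inherits(features, "feature_set"))
  n <- nrow(dmrs)
  if (n == 0L) {
    return(data.table(dmr_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      context = character(0), direction = character(0),
                      category = character(0), gene_side = character(0),
                      gene_ids = character(0), te_ids = character(0)))
  }
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(dmrs$start, dmrs$end))
  dmr_len <- GenomicRanges::width(dmr_gr)

  match_ids <- function(feat_gr, ids) {
    out <- vector("list", n)
    if (length(feat_gr) == 0L) return(out)
    hits <- GenomicRanges::findOverlaps(dmr_gr, feat_gr, ignore.strand = TRUE)
    if (length(hits) == 0L) return(out)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(dmr_gr)[q], GenomicRanges::ranges(feat_gr)[s]))
    keep <- ov >= min_overlap * dmr_len[q]
    if (!any(keep)) return(out)
    sp <- split(ids[s[keep]], q[keep])
    out[as.integer(names(sp))] <- lapply(sp, unique)
    out
  }

  prom_ids <- match_ids(features$promoters, features$genes$id)
  body_ids <- match_ids(features$genes, features$genes$id)
  te_ids <- match_ids(features$tes, features$tes$id)

  has_prom <- lengths(prom_ids) > 0L
  has_body <- lengths(body_ids) > 0L
  has_te <- lengths(te_ids) > 0L
  has_gene <- has_prom | has_body
  gene_side <- ifelse(has_prom, "promoter",
                      ifelse(has_body, "gene_body", NA_character_))
  category <- ifelse(has_gene & has_te, "gene_element_and_te",
                     ifelse(has_te, "te",
                            ifelse(has_prom, "promoter",
                                   ifelse(has_body, "gene_body", "other"))))
  collapse <- function(a, b) {
    vapply(seq_len(n), function(i) {
      ids <- unique(c(a[[i]], b[[i]]))
      if (length(ids)) paste(ids, collapse = ",") else NA_character_
    }, "")
  }
  data.table(dmr_id = seq_len(n),
             chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
             context = if ("context" %in% names(dmrs)) dmrs$context else NA_character_,
             direction = if ("direction" %in% names(dmrs)) dmrs$direction else NA_character_,
             category = category, gene_side = gene_side,
             gene_ids = collapse(prom_ids, body_ids),
             te_ids = collapse(te_ids, vector("list", n)))
}

#' Category table of DMR assignments
#'
#' Counts and percentages (1 decimal) of DMRs per genomic category, split
#' by direction with a total row. `gene_elements` counts every DMR with a
#' gene-element match (promoter + gene body, including those that also
#' match a TE); `te` likewise includes the dual matches; the dual matches
#' are additionally tallied in their own `gene_element_and_te` column, so
#' `gene_elements + te - gene_element_and_te + other = total`.
#'
#' @param assignments output of [assign_dmrs()] for one genotype/context.
#' @param direction_split when `FALSE`, only the total row is returned.
#' @return a `data.table` with one row per direction plus `Total`, and
#'   `n`/`pct` column pairs per category.
#' @export
tabulate_categories <- function(assignments, direction_split = TRUE) {
  one_row <- function(a, label) {
    total <- nrow(a)
    both <- a$category == "gene_element_and_te"
    n_prom <- sum(a$category == "promoter" | (both & a$gene_side == "promoter"))
    n_body <- sum(a$category == "gene_body" | (both & a$gene_side == "gene_body"))
    n_te <- sum(a$category == "te" | both)
    n_other <- sum(a$category == "other")
    data.table(direction = label, total = total,
               gene_elements = n_prom + n_body,
               gene_elements_pct = percent_of(n_prom + n_body, total),
               promoter = n_prom, promoter_pct = percent_of(n_prom, total),
               gene_body = n_body, gene_body_pct = percent_of(n_body, total),
               te = n_te, te_pct = percent_of(n_te, total),
               gene_element_and_te = sum(both),
               gene_element_and_te_pct = percent_of(sum(both), total),
               other = n_other, other_pct = percent_of(n_other, total))
  }
  rows <- list()
  if (direction_split) {
    for (d in c("hyper", "hypo")) {
      rows[[d]] <- one_row(assignments[direction == d],
                           c(hyper = "Hypermethylated", hypo = "Hypomethylated")[[d]])
    }
  }
  rows$total <- one_row(assignments, "Total")
  rbindlist(rows)
}

# distinct TE ids matched by a set of assignments, optionally by direction
targeted_tes <- function(assignments, direction = "all") {
  a <- assignments[!is.na(te_ids)]
  if (direction != "all") {
    keep <- which(a$direction == direction)  # 'direction' is also a column name
    a <- a[keep]
  }
  unique(unlist(strsplit(a$te_ids, ",", fixed = TRUE)))
}

#' TE superfamily representation among DMR-targeted TEs
#'
#' Counts the distinct TEs targeted by DMRs per superfamily and their
#' share of all targeted TEs. Superfamilies below `fold_below` are folded
#' into an `"Others"` group.
#'
#' @param assignments output of [assign_dmrs()].
#' @param features the [feature_set()] the assignments were made against.
#' @param direction `"hypo"`, `"hyper"` or `"all"`.
#' @param fold_below proportion under which a superfamily is folded into
#'   `"Others"` (default 0, no folding).
#' @return a `data.table` with `superfamily`, `n_tes`, `proportion`,
#'   sorted by decreasing count.
#' @export
superfamily_summary <- function(assignments, features, direction = "all",
                                fold_below = 0) {
  ids <- targeted_tes(assignments, direction)
  if (length(ids) == 0L) {
    return(data.table(superfamily = character(0), n_tes = integer(0),
                      proportion = numeric(0)))
  }
  idx <- match(ids, features$tes$id)
  if (anyNA(idx)) {
    stop("TE id(s) not in feature set: ", paste(head(ids[is.na(idx)], 3L), collapse = ", "))
  }
  tab <- data.table(superfamily = features$tes$superfamily[idx])[
    , .(n_tes = .N), by = superfamily]
  tab[, proportion := n_tes / sum(n_tes)]
  if (fold_below > 0 && any(tab$proportion < fold_below)) {
    small <- tab[proportion < fold_below]
    tab <- rbind(tab[proportion >= fold_below],
                 data.table(superfamily = "Others", n_tes = sum(small$n_tes),
                            proportion = sum(small$proportion)))
  }
  tab[order(-n_tes)][]
}

#' TE families with a large targeted share of their members
#'
#' Families whose fraction of members targeted by DMRs of the requested
#' direction strictly exceeds `min_fraction` (default: more than 10% of
#' members targeted by hypermethylated DMRs).
#'
#' @inheritParams superfamily_summary
#' @param min_fraction strict lower bound on targeted-member fraction.
#' @return a `data.table` with `family`, `superfamily`, `n_targeted`,
#'   `family_size`, `fraction`, sorted by decreasing fraction.
#' @export
family_representation <- function(assignments, features, direction = "hyper",
                                  min_fraction = 0.10) {
  sizes <- data.table(family = features$tes$family,
                      superfamily = features$tes$superfamily)[
    , .(family_size = .N, superfamily = superfamily[1L]), by = family]
  ids <- targeted_tes(assignments, direction)
  if (length(ids) == 0L) {
    return(data.table(family = character(0), superfamily = character(0),
                      n_targeted = integer(0), family_size = integer(0),
                      fraction = numeric(0)))
  }
  idx <- match(ids, features$tes$id)
  if (anyNA(idx)) stop("TE id(s) not in feature set")
  hit <- data.table(family = features$tes$family[idx])[, .(n_targeted = .N), by = family]
  out <- sizes[hit, on = "family"]
  out <- out[family_size > 0L]
  out[, fraction := n_targeted / family_size]
  out <- out[fraction > min_fraction]
  setcolorder(out, c("family", "superfamily", "n_targeted", "family_size", "fraction"))
  out[order(-fraction)][]
}

#' Cross-genotype overlap (Venn) summary of targeted feature sets
#'
#' Given the sets of feature ids (TEs or genes) targeted in each genotype,
#' computes every disjoint intersection cell, the count and formatted
#' fraction of ids unique to each genotype, and the pairwise shared
#' fraction over the union of each pair. Fractions are reported as
#' `"NN.NN% (num/den)"` (2 decimals).
#'
#' @param sets a named list (>= 2 entries) of character vectors of ids.
#' @return an object of class `overlap_summary`: a list with `cells`
#'   (disjoint Venn cells keyed by `+`-joined genotype combinations),
#'   `per_genotype` (total, unique count, unique percentage and formatted
#'   fraction; `NA` for empty sets) and `pairwise` (shared count over
#'   pair union).
#' @export
overlap_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  labels <- names(sets)
  k <- length(sets)
  universe <- unique(unlist(sets))
  if (length(universe) == 0L) {
    combo <- character(0)
  } else {
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                                 dimnames = list(NULL, labels))
    combo <- apply(member, 1L, function(r) paste(labels[r], collapse = "+"))
  }
  cells <- data.table(combo = combo)[, .(n = .N), by = combo]
  # ensure all 2^k - 1 cells appear, empty ones with n = 0
  all_combos <- unlist(lapply(seq_len(k), function(m) {
    apply(utils::combn(labels, m), 2L, paste, collapse = "+")
  }))
  cells <- merge(data.table(combo = all_combos), cells, by = "combo", all.x = TRUE)
  cells[is.na(n), n := 0L]

  per_genotype <- rbindlist(lapply(labels, function(g) {
    total <- length(sets[[g]])
    uniq <- cells[combo == g]$n
    data.table(genotype = g, total = total, unique = uniq,
               unique_pct = percent_of(uniq, total, 2),
               formatted = if (total == 0L) NA_character_ else
                 format_fraction(uniq, total))
  }))

  pairs <- utils::combn(labels, 2L)
  pairwise <- rbindlist(lapply(seq_len(ncol(pairs)), function(j) {
    a <- sets[[pairs[1L, j]]]; b <- sets[[pairs[2L, j]]]
    shared <- length(intersect(a, b)); uni <- length(union(a, b))
    data.table(pair = paste(pairs[, j], collapse = "+"),
               shared = shared, union = uni,
               shared_pct = percent_of(shared, uni, 2),
               formatted = format_fraction(shared, uni))
  }))

  structure(list(cells = cells[], per_genotype = per_genotype,
                 pairwise = pairwise, labels = labels),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("overlap_summary over", length(x$labels), "sets:",
      paste(x$labels, collapse = ", "), "\n")
  cat("unique per set:\n")
  for (i in seq_len(nrow(x$per_genotype))) {
    cat(sprintf("  %s: %s\n", x$per_genotype$genotype[i], x$per_genotype$formatted[i]))
  }
  invisible(x)
}
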