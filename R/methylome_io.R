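#' Construct a methylome sample from a per-cytosine site table
#'
#' A `methylome_sample` bundles a full per-cytosine methylation call table
#' (one strand-resolved cytosine per row, with methylated and unmethylated
#' read counts and sequence context) with its genotype/replicate labels and
#' the chromosome lengths of the genome it lives on. All internal genomic
#' coordinates in this package are 1-based and inclusive, matching the
#' cytosine-report convention on disk; BED output is converted to 0-based
#' half-open at the boundary.
#'
#' @param sites a `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (1-based), `strand` (`+`/`-`), `count_meth`, `count_unmeth`, `context`
#'   (`CG`, `CHG` or `CHH`) and optionally `trinucleotide`.
#' @param genotype,replicate sample labels (e.g. `"wt"`, `"r1"`).
#' @param genome named integer vector of chromosome lengths; inferred from
#'   the largest observed position per chromosome when `NULL`.
#' @return an object of class `methylome_sample`: a list with elements
#'   `sites` (a keyed `data.table` sorted by chrom, pos, strand),
#'   `genotype`, `replicate` and `genome`.
#' @details Zero-coverage cytosines are retained: they record that a
#'   cytosine position exists even though it contributes no counts to any
#'   level. Rows are sorted on construction; duplicate (chrom, pos, strand)
#'   entries are an error. CG sites on opposite strands are kept as two
#'   independent sites (no strand symmetrisation).
#' @export
methylome_sample <- function(sites, genotype = NA_character_,
                             replicate = NA_character_, genome = NULL) {
  sites <- as.data.table(sites)
  required <- c("chrom", "pos", "strand", "count_meth", "count_unmeth", "context")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"trinucleotide" %in% names(sites)) sites[, trinucleotide := NA_character_]
  sites <- sites[, c(required, "trinucleotide"), with = FALSE]
  sites[, chrom := as.character(chrom)]
  sites[, pos := as.integer(pos)]
  sites[, count_meth := as.integer(count_meth)]
  sites[, count_unmeth := as.integer(count_unmeth)]

  if (anyNA(sites$pos) || any(sites$pos < 1L)) stop("positions must be 1-based positive integers")
  if (any(sites$count_meth < 0L) || any(sites$count_unmeth < 0L)) {
    stop("read counts must be non-negative")
  }
  bad_ctx <- !sites$context %in% METH_CONTEXTS
  if (any(bad_ctx)) {
    stop("unknown context token(s): ",
         paste(unique(sites$context[bad_ctx]), collapse = ", "))
  }
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  check_trinucleotide_context(sites)

  ord <- order(sites$chrom, sites$pos, sites$strand, method = "radix")
  if (!identical(ord, seq_len(nrow(sites)))) {
    message("site table was unsorted; sorted on load")
  }
  setkey(sites, chrom, pos, strand)
  if (anyDuplicated(sites, by = c("chrom", "pos", "strand"))) {
    stop("duplicate (chrom, pos, strand) entries in site table")
  }

  observed <- sites[, .(len = max(pos)), by = chrom]
  if (is.null(genome)) {
    genome <- setNames(observed$len, observed$chrom)
  } else {
    genome <- setNames(as.integer(genome), names(genome))
    over <- observed[len > genome[chrom] | is.na(genome[chrom])]
    if (nrow(over)) {
      stop("sites beyond declared chromosome length on: ",
           paste(over$chrom, collapse = ", "))
    }
  }

  structure(list(sites = sites, genotype = as.character(genotype),
                 replicate = as.character(replicate), genome = genome),
            class = "methylome_sample")
}

# context must agree with the trinucleotide when one is given:
# CG <=> 2nd base G; CHG <=> 3rd base G and 2nd base not G; else CHH
check_trinucleotide_context <- function(sites) {
  has_tri <- !is.na(sites$trinucleotide) & nzchar(sites$trinucleotide)
  if (!any(has_tri)) return(invisible(TRUE))
  tri <- sites$trinucleotide[has_tri]
  if (any(nchar(tri) != 3L)) stop("trinucleotide strings must have length 3")
  expected <- context_of_trinucleotide(tri)
  bad <- expected != sites$context[has_tri]
  if (any(bad)) {
    stop("context inconsistent with trinucleotide for ", sum(bad), " site(s), e.g. ",
         tri[bad][1L], " labelled ", sites$context[has_tri][bad][1L])
  }
  invisible(TRUE)
}

#' Derive the methylation context of a cytosine trinucleotide
#'
#' @param tri character vector of 3-letter trinucleotides starting with C.
#' @return `"CG"`, `"CHG"` or `"CHH"` per element.
#' @export
context_of_trinucleotide <- function(tri) {
  second <- substr(tri, 2L, 2L)
  third <- substr(tri, 3L, 3L)
  ifelse(second == "G", "CG", ifelse(third == "G", "CHG", "CHH"))
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("methylome_sample: genotype=%s replicate=%s\n", x$genotype, x$replicate))
  cat(sprintf("  %d sites on %d chromosome(s)\n", nrow(x$sites), length(x$genome)))
  tab <- x$sites[, .N, by = context]
  cat("  sites per context:",
      paste(sprintf("%s=%d", tab$context, tab$N), collapse = ", "), "\n")
  invisible(x)
}

#' Read a Bismark-style cytosine (CX) report
#'
#' Ingests the per-cytosine output tier of a bisulfite methylation
#' extractor: a tab-separated file with one row per strand-resolved
#' cytosine and columns chromosome, position (1-based), strand, methylated
#' count, unmethylated count, context and trinucleotide. Gzip-compressed
#' input is accepted. Zero-coverage rows are kept (see
#' [methylome_sample()]); unsorted input is sorted with a notice.
#'
#' @param path file path (plain or `.gz`).
#' @inheritParams methylome_sample
#' @return a [methylome_sample()].
#' @export
read_cx_report <- function(path, genotype = NA_character_,
                           replicate = NA_character_, genome = NULL) {
  dt <- fread_maybe_gz(path, sep = "\t", header = FALSE,
                       colClasses = "character", fill = TRUE, na.strings = NULL)
  if (ncol(dt) != 7L) {
    stop("CX report must have 7 tab-separated columns, found ", ncol(dt),
         " in ", path)
  }
  setnames(dt, c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                 "context", "trinucleotide"))
  for (col in c("pos", "count_meth", "count_unmeth")) {
    v <- suppressWarnings(as.integer(dt[[col]]))
    bad <- which(is.na(v) | v < 0L)
    if (length(bad)) {
      stop("malformed ", col, " at line ", bad[1L], " of ", path, ": '",
           dt[[col]][bad[1L]], "'")
    }
    set(dt, j = col, value = v)
  }
  bad_ctx <- which(!dt$context %in% METH_CONTEXTS)
  if (length(bad_ctx)) {
    stop("unknown context token '", dt$context[bad_ctx[1L]], "' at line ",
         bad_ctx[1L], " of ", path)
  }
  bad_strand <- which(!dt$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop("malformed strand at line ", bad_strand[1L], " of ", path)
  }
  methylome_sample(dt, genotype = genotype, replicate = replicate, genome = genome)
}

#' Write a methylome sample as a CX report
#'
#' Inverse of [read_cx_report()]: writing a sample read from a sorted,
#' well-formed report reproduces the file byte for byte.
#'
#' @param sample a [methylome_sample()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sample, path) {
  stopifnot(inherits(sample, "methylome_sample"))
  out <- sample$sites[, .(chrom, pos, strand, count_meth, count_unmeth,
                          context, trinucleotide)]
  out[is.na(trinucleotide), trinucleotide := ""]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` records and returns one range per gene spanning
#' its first to last exon (the transcriptional unit used for gene-body
#' overlap and promoter definition). Exon `Parent` attributes are resolved
#' either directly to a gene or through an intermediate transcript record.
#'
#' @param path GFF3 file (plain or gzip).
#' @return a [GenomicRanges::GRanges] with one range per gene, metadata
#'   column `id`, and strand from the gene record.
#' @details Exons whose `Parent` cannot be resolved to a gene are skipped
#'   with a warning; genes without any exon fall back to the gene record's
#'   own span, also with a warning.
#' @export
read_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gff$type)
  genes <- gff[types == "gene"]
  if (length(genes) == 0L) stop("no gene records in ", path)
  gene_ids <- as.character(genes$ID)

  # transcripts (any non-gene, non-exon feature with an ID and a gene Parent)
  mid <- gff[!types %in% c("gene", "exon")]
  tx2gene <- character(0)
  if (length(mid)) {
    tx_ids <- as.character(mid$ID)
    tx_parent <- vapply(mid$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    keep <- !is.na(tx_ids) & tx_parent %in% gene_ids
    tx2gene <- setNames(tx_parent[keep], tx_ids[keep])
  }

  exons <- gff[types == "exon"]
  exon_parent <- vapply(exons$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  resolved <- ifelse(exon_parent %in% gene_ids, exon_parent,
                     unname(tx2gene[exon_parent]))
  if (anyNA(resolved)) {
    warning(sum(is.na(resolved)), " exon(s) without resolvable gene parent skipped")
    exons <- exons[!is.na(resolved)]
    resolved <- resolved[!is.na(resolved)]
  }

  if (length(exons)) {
    ex <- data.table(gene = resolved,
                     start = GenomicRanges::start(exons),
                     end = GenomicRanges::end(exons))
    span <- ex[, .(start = min(start), end = max(end)), by = gene]
  } else {
    span <- data.table(gene = character(0), start = integer(0), end = integer(0))
  }
  idx <- match(gene_ids, span$gene)
  no_exon <- is.na(idx)
  if (any(no_exon)) {
    warning(sum(no_exon), " gene(s) without exons; using the gene record span")
  }
  starts <- ifelse(no_exon, GenomicRanges::start(genes), span$start[idx])
  ends <- ifelse(no_exon, GenomicRanges::end(genes), span$end[idx])

  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genes),
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = GenomicRanges::strand(genes))
  out$id <- gene_ids
  sort(out)
}

#' Promoter intervals of a set of genes
#'
#' The promoter is the fixed-width interval immediately upstream of the
#' first exon on the gene's strand (200 bp by default), clipped at
#' chromosome bounds rather than rejected.
#'
#' @param genes a `GRanges` of gene bodies (as from [read_gff3()]).
#' @param upstream promoter width in nt (default 200).
#' @param genome optional named vector of chromosome lengths for clipping
#'   at the right-hand end.
#' @return a `GRanges` parallel to `genes` (zero-width ranges possible when
#'   a gene starts at a chromosome end).
#' @export
gene_promoters <- function(genes, upstream = 200L, genome = NULL) {
  prom <- GenomicRanges::promoters(genes, upstream = upstream, downstream = 0L)
  # clip to [1, chrom length]
  st <- pmax(GenomicRanges::start(prom), 1L)
  en <- GenomicRanges::end(prom)
  if (!is.null(genome)) {
    lens <- genome[as.character(GenomeInfoDb::seqnames(prom))]
    en <- pmin(en, as.integer(lens))
  }
  en <- pmax(en, st - 1L)  # allow zero-width when fully clipped
  GenomicRanges::ranges(prom) <- IRanges::IRanges(start = st, end = en)
  prom
}

#' Read a transposable-element annotation table
#'
#' Reads a TAIR10-style TE table: tab-separated columns TE name,
#' orientation, start, end (1-based inclusive), family and superfamily.
#' The chromosome is taken from a `chrom` column when present, otherwise
#' derived from the AGI-style TE name (`AT1TE...` is chromosome `Chr1`).
#' A header line is detected and skipped automatically.
#'
#' @param path TSV file (plain or gzip).
#' @return a `GRanges` with metadata columns `id`, `family`, `superfamily`.
#' @details Rows with `end < start` are rejected with a warning; a
#'   duplicated TE name is an error; a family mapping to two superfamilies
#'   is an error.
#' @export
read_te_annotation <- function(path) {
  dt <- fread_maybe_gz(path, sep = "\t", header = "auto",
                       colClasses = "character")
  if (!all(c("name", "start", "end") %in% names(dt))) {
    # positional layout
    if (ncol(dt) == 6L) {
      setnames(dt, c("name", "orientation", "start", "end", "family", "superfamily"))
    } else if (ncol(dt) == 7L) {
      setnames(dt, c("name", "chrom", "orientation", "start", "end", "family",
                     "superfamily"))
    } else {
      stop("TE annotation must have 6 or 7 tab-separated columns, found ", ncol(dt))
    }
  }
  dt[, start := suppressWarnings(as.integer(start))]
  dt[, end := suppressWarnings(as.integer(end))]
  if (anyNA(dt$start) || anyNA(dt$end)) stop("non-numeric TE coordinates in ", path)
  if (!"chrom" %in% names(dt)) {
    m <- regmatches(dt$name, regexec("^AT([0-9CM]+)TE", toupper(dt$name)))
    chr <- vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
    if (anyNA(chr)) {
      stop("cannot derive chromosome from TE name(s): ",
           paste(head(dt$name[is.na(chr)], 3L), collapse = ", "))
    }
    dt[, chrom := paste0("Chr", chr)]
  }
  bad <- dt$end < dt$start
  if (any(bad)) {
    warning(sum(bad), " TE record(s) with end < start rejected")
    dt <- dt[!bad]
  }
  if (anyDuplicated(dt$name)) {
    stop("duplicate TE name(s): ", paste(unique(dt$name[duplicated(dt$name)]), collapse = ", "))
  }
  dt[, orientation := c("true" = "+", "false" = "-")[tolower(orientation)] %??% orientation]
  dt[!orientation %in% c("+", "-"), orientation := "*"]
  out <- GenomicRanges::GRanges(dt$chrom,
                                IRanges::IRanges(dt$start, dt$end),
                                strand = dt$orientation)
  out$id <- dt$name
  out$family <- dt$family
  out$superfamily <- dt$superfamily
  check_family_map(out)
  sort(out)
}

`%??%` <- function(a, b) ifelse(is.na(a), b, a)

# fread with transparent gzip support through a connection (no extra deps)
fread_maybe_gz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    fread(text = readLines(con), ...)
  } else {
    fread(path, ...)
  }
}

check_family_map <- function(tes) {
  map <- unique(data.table(family = tes$family, superfamily = tes$superfamily))
  dup <- map$family[duplicated(map$family)]
  if (length(dup)) {
    stop("TE family mapping to more than one superfamily: ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(tes$superfamily))) stop("empty TE superfamily label")
  invisible(TRUE)
}

#' Write a TE annotation table
#'
#' Positional 7-column layout (name, chrom, orientation, start, end,
#' family, superfamily), 1-based inclusive; round-trips through
#' [read_te_annotation()].
#'
#' @param tes a `GRanges` as returned by [read_te_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_te_annotation <- function(tes, path) {
  out <- data.table(name = tes$id,
                    chrom = as.character(GenomeInfoDb::seqnames(tes)),
                    orientation = as.character(GenomicRanges::strand(tes)),
                    start = GenomicRanges::start(tes),
                    end = GenomicRanges::end(tes),
                    family = tes$family,
                    superfamily = tes$superfamily)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle genes and transposable elements into an annotated feature set
#'
#' @param genes `GRanges` of gene bodies with metadata column `id`.
#' @param tes `GRanges` of TEs with metadata columns `id`, `family`,
#'   `superfamily`.
#' @param genome named integer vector of chromosome lengths; inferred from
#'   feature extents when `NULL`.
#' @param promoter_width promoter size in nt upstream of the first exon.
#' @return an object of class `feature_set` with elements `genes`, `tes`,
#'   `promoters` and `genome`.
#' @export
feature_set <- function(genes, tes, genome = NULL, promoter_width = 200L) {
  stopifnot(methods::is(genes, "GRanges"), methods::is(tes, "GRanges"))
  if (length(tes)) check_family_map(tes)
  if (is.null(genome)) {
    all_feats <- c(GenomicRanges::granges(genes), GenomicRanges::granges(tes))
    if (length(all_feats)) {
      ends <- data.table(chrom = as.character(GenomeInfoDb::seqnames(all_feats)),
                         end = GenomicRanges::end(all_feats))
      mx <- ends[, .(len = max(end)), by = chrom]
      genome <- setNames(mx$len, mx$chrom)
    } else {
      genome <- integer(0)
    }
  }
  for (gr in list(genes, tes)) {
    if (!length(gr)) next
    lens <- genome[as.character(GenomeInfoDb::seqnames(gr))]
    if (anyNA(lens) || any(GenomicRanges::end(gr) > lens) ||
        any(GenomicRanges::start(gr) < 1L)) {
      stop("feature outside genome bounds")
    }
  }
  structure(list(genes = genes, tes = tes,
                 promoters = gene_promoters(genes, promoter_width, genome),
                 genome = genome),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d genes, %d TEs on %d chromosome(s) (%s nt)\n",
              length(x$genes), length(x$tes), length(x$genome),
              format(sum(as.numeric(x$genome)), big.mark = ",")))
  invisible(x)
}

#' Write called DMRs as BED6+
#'
#' One line per DMR: chrom, 0-based start, end, name `context:direction`,
#' score `round(-10 * log10(p))` capped at 1000, strand `"."`, then three
#' extra columns: wild-type level, mutant level and covered-site count.
#'
#' @param dmrs a DMR table as returned by [call_dmrs()] (possibly empty).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (is.null(dmrs) || nrow(dmrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- ifelse(dmrs$p_value <= 0, 1000,
                  pmin(round(-10 * log10(dmrs$p_value)), 1000))
  out <- data.table(chrom = dmrs$chrom,
                    start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = paste0(dmrs$context, ":", dmrs$direction),
                    score = as.integer(score),
                    strand = ".",
                    wt_level = round(dmrs$wt_level, 6),
                    mut_level = round(dmrs$mut_level, 6),
                    n_sites = dmrs$n_sites)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
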