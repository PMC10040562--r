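#' @import data.table
#' @importFrom stats dhyper prcomp rbeta rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# the three plant methylation contexts, in conventional order
METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Percentage of a fraction, rounded to a fixed number of decimals
#'
#' Convenience used throughout the summary tables: `100 * num / den`
#' rounded to `digits` decimals. Returns `NA` when the denominator is zero.
#'
#' @param num numerator (vectorised).
#' @param den denominator (vectorised).
#' @param digits decimals to keep (default 1, the precision used in the
#'   category tables; overlap summaries use 2).
#' @return numeric vector of percentages.
#' @export
percent_of <- function(num, den, digits = 1) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n); den <- rep_len(den, n)
  p <- ifelse(den == 0, NA_real_, 100 * num / den)
  round(p, digits)
}

#' Format a count fraction as "NN.NN% (num/den)"
#'
#' The reporting convention used for set-overlap summaries, e.g.
#' `format_fraction(485, 814)` gives `"59.58% (485/814)"`.
#'
#' @inheritParams percent_of
#' @param digits decimals in the percentage (default 2).
#' @return character vector; `"NA (0/0)"`-style when the denominator is 0.
#' @export
format_fraction <- function(num, den, digits = 2) {
  pct <- percent_of(num, den, digits)
  ifelse(is.na(pct),
         sprintf("NA (%d/%d)", num, den),
         sprintf("%.*f%% (%d/%d)", digits, pct, num, den))
}

# validate a context argument; "all" optionally allowed
match_context <- function(context, allow_all = FALSE) {
  choices <- if (allow_all) c(METH_CONTEXTS, "all") else METH_CONTEXTS
  if (length(context) != 1L || !context %in% choices) {
    stop("'context' must be one of: ", paste(choices, collapse = ", "),
         call. = FALSE)
  }
  context
}

# deterministic child seed derived from a parent seed and a stage label,
# kept below 2^31 so set.seed() accepts it on all platforms
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
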