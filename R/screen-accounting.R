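# The screen's published library and meta-analysis bookkeeping. The shipped
# count tables are inputs (the numbers the screen reports for its own
# library and for the literature datasets); the functions below recompute
# the derived quantities from them.

#' Load the screen's count tables
#'
#' @param which `"library"` (deletion-library accounting) or `"meta"`
#'   (multi-study regulator counts).
#' @return named integer vector of counts.
#' @export
load_screen_counts <- function(which = c("library", "meta")) {
  which <- match.arg(which)
  file <- system.file("extdata",
                      if (which == "library") "library_accounting.tsv"
                      else "meta_overlap_counts.tsv",
                      package = "peroxiscreen")
  df <- read.delim(file, stringsAsFactors = FALSE)
  setNames(as.integer(df$count), df$quantity)
}

#' Deletion-library accounting
#'
#' Recomputes the library summary from the raw counts: unique strains
#' (arrayed positions minus duplicates) and the percentage of the unique
#' library for which data were acquired.
#'
#' @param counts counts as from `load_screen_counts("library")`.
#' @return list: `n_arrayed`, `n_unique`, `n_analyzed`, `pct_analyzed`.
#' @export
library_summary <- function(counts = load_screen_counts("library")) {
  n_unique <- counts[["strains_arrayed"]] - counts[["duplicate_positions"]]
  list(n_arrayed = counts[["strains_arrayed"]],
       n_unique = n_unique,
       n_analyzed = counts[["strains_with_data"]],
       pct_analyzed = round(100 * counts[["strains_with_data"]] / n_unique))
}

#' Meta-analysis overlap summary
#'
#' Reconstructs synthetic gene-identifier sets with the reported
#' cardinalities (the identifiers themselves are placeholders; only the set
#' sizes and intersections carry information) and recomputes the overlap
#' percentages through [overlap_stats()], together with the total number of
#' regulators contributed by the current screen.
#'
#' @param counts counts as from `load_screen_counts("meta")`.
#' @return list: `pct_prior_recovered`, `pct_fatty_acid_only`,
#'   `n_regulators_this_study`, plus the underlying [overlap_stats()] lists.
#' @export
meta_summary <- function(counts = load_screen_counts("meta")) {
  prior <- sprintf("PRIOR%04d", seq_len(counts[["prior_regulators"]]))
  this_study <- c(head(prior, counts[["prior_recovered_by_this_study"]]),
                  sprintf("NOVEL%04d",
                          seq_len(counts[["novel_validated_this_study"]])))
  fa <- sprintf("FA%04d", seq_len(counts[["fatty_acid_study_regulators"]]))
  fa_only <- head(fa, counts[["fatty_acid_only_this_study"]])

  prior_overlap <- overlap_stats(this_study, prior)
  fa_overlap <- overlap_stats(fa_only, fa)
  list(pct_prior_recovered = prior_overlap$pct_of_b_in_a,
       pct_fatty_acid_only = fa_overlap$pct_of_b_in_a,
       n_regulators_this_study = length(this_study),
       prior_overlap = prior_overlap, fa_overlap = fa_overlap)
}
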