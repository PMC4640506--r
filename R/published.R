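# The published differential-expression table for well-fed vs 12-hr
# starved early L4 larvae, shipped as a plain TSV, plus the small
# arithmetic helpers used to reproduce its derived columns and the
# study-level summary counts.

#' Published starvation DE table
#'
#' The reported differentially expressed miRNAs and miRNA hairpins of
#' the well-fed vs 12-hr starved L4 comparison: normalised counts per
#' million for both libraries, log2 fold change, p-value, BH FDR and the
#' signed fold change, as printed (CPMs at 1 decimal place, p/FDR at two
#' significant figures).  A `seq_class` column is derived from the
#' miRBase naming convention via [mirna_name_class()].
#'
#' @return Data frame with columns `feature_id`, `seq_class`, `cpm_fed`,
#'   `cpm_starved`, `log2fc`, `p_value`, `fdr`, `fold_change`.
#' @export
published_de_table <- function() {
  path <- system.file("extdata", "starved_l4_mirna_de.tsv",
                      package = "mirstarve", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$seq_class <- mirna_name_class(d$feature_id)
  d[, c("feature_id", "seq_class", "cpm_fed", "cpm_starved", "log2fc",
        "p_value", "fdr", "fold_change")]
}

#' Mature vs hairpin from miRBase-style names
#'
#' miRBase names matures `miR-` (capital R) and hairpin precursor genes
#' `mir-` (lower case); `let-`/`lin-` legacy stems stay lower case, so
#' an arm suffix (`-5p`/`-3p`) also marks a mature.
#'
#' @param ids Character vector of miRBase-style identifiers.
#' @return Character vector: `"mature"` or `"hairpin"`.
#' @export
mirna_name_class <- function(ids) {
  out <- rep(NA_character_, length(ids))
  out[grepl("(^|-)miR-", ids)] <- "mature"
  # let-7-family matures keep a lower-case stem but carry an arm suffix
  out[is.na(out) & grepl("-(5p|3p)$", ids)] <- "mature"
  out[is.na(out) & grepl("(^|-)(mir|let)-", ids)] <- "hairpin"
  if (anyNA(out))
    stop("cannot classify ids: ", paste(ids[is.na(out)], collapse = ", "))
  out
}

#' Count up/down-regulated matures and hairpins
#'
#' Classifies DE rows by the sign of their fold change and by
#' mature-vs-hairpin naming.
#'
#' @param de Data frame with `feature_id` and a signed `fold_change` (or
#'   `log2fc`) column; defaults to [published_de_table()].
#' @return Named list: `up_mature`, `down_mature`, `up_hairpin`,
#'   `down_hairpin`.
#' @export
count_regulation <- function(de = published_de_table()) {
  fc <- de$fold_change %||% de$log2fc
  cls <- de$seq_class %||% mirna_name_class(de$feature_id)
  up <- fc > 0
  list(up_mature = sum(up & cls == "mature"),
       down_mature = sum(!up & cls == "mature"),
       up_hairpin = sum(up & cls == "hairpin"),
       down_hairpin = sum(!up & cls == "hairpin"))
}

#' Percent change between two printed means
#'
#' `100 * (to - from) / from`; negative values are decreases.
#'
#' @param from,to The baseline and comparison values.
#' @return Signed percent change.
#' @examples
#' percent_change(123, 27)    # -78% brood size
#' percent_change(12.4, 16.9) # +36% lifespan
#' @export
percent_change <- function(from, to) {
  stopifnot(from != 0)
  100 * (to - from) / from
}
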