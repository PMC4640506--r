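# Efficiency-corrected relative quantification from crossing-point (Ct)
# values: ratio = E_t^(dCt_t) / E_r^(dCt_r) with dCt = Ct(control) -
# Ct(treated), E the per-cycle amplification factor (2 = perfect
# doubling).  With E = 2 for both assays this reduces to 2^(-ddCt).

#' Construct a qPCR assay record
#'
#' @param name Assay name (e.g. the miRNA or mRNA it measures).
#' @param ct_control,ct_treated Crossing-point values; vectors are
#'   treated as technical replicates and averaged.
#' @param efficiency Per-cycle amplification factor, in `[1, 2.2]`
#'   (slight super-efficiency tolerated); default perfect doubling.
#' @return A list of class `qpcr_assay`.
#' @export
qpcr_assay <- function(name, ct_control, ct_treated, efficiency = 2) {
  stopifnot(efficiency >= 1, efficiency <= 2.2,
            all(ct_control > 0), all(ct_treated > 0))
  structure(list(name = name,
                 ct_control = mean(ct_control),
                 ct_treated = mean(ct_treated),
                 efficiency = efficiency,
                 replicate_cts = list(control = ct_control,
                                      treated = ct_treated)),
            class = "qpcr_assay")
}

#' Efficiency-corrected relative expression ratio
#'
#' @param target,reference `qpcr_assay` objects for the gene of interest
#'   and the endogenous control.
#' @return The relative expression ratio (treated vs control, target
#'   normalised to reference).
#' @examples
#' t <- qpcr_assay("miR-35-3p", ct_control = 25, ct_treated = 22)
#' r <- qpcr_assay("miR-58-3p", ct_control = 18, ct_treated = 17)
#' pfaffl_ratio(t, r)  # 2^3 / 2^1 = 4
#' @export
pfaffl_ratio <- function(target, reference) {
  stopifnot(inherits(target, "qpcr_assay"), inherits(reference, "qpcr_assay"))
  dct_t <- target$ct_control - target$ct_treated
  dct_r <- reference$ct_control - reference$ct_treated
  if ((target$efficiency <= 1 && dct_t != 0) ||
      (reference$efficiency <= 1 && dct_r != 0))
    warning("amplification efficiency <= 1 cannot discriminate a Ct shift")
  target$efficiency^dct_t / reference$efficiency^dct_r
}

#' Summarise Pfaffl ratios across biological replicates
#'
#' One ratio per biological replicate (each computed from its
#' replicate-mean Cts), then mean, standard error of the mean and a
#' direction flag versus no change.
#'
#' @param targets,references Lists of `qpcr_assay` objects of equal
#'   length, one pair per biological replicate.
#' @return List: `ratios`, `mean`, `sem` (`NA` with fewer than two
#'   replicates), `n`, `direction` (`"up"`, `"down"` or `"unchanged"`).
#' @export
replicate_summary <- function(targets, references) {
  stopifnot(length(targets) == length(references), length(targets) >= 1L)
  ratios <- mapply(pfaffl_ratio, targets, references)
  m <- mean(ratios)
  sem <- if (length(ratios) >= 2L) sd(ratios) / sqrt(length(ratios))
         else NA_real_
  list(ratios = ratios, mean = m, sem = sem, n = length(ratios),
       direction = if (m > 1) "up" else if (m < 1) "down" else "unchanged")
}

#' Relative expression from a tidy Ct table
#'
#' Expects columns `assay`, `condition` (`"control"` / `"treated"`),
#' `replicate`, `ct` and optionally `efficiency`; technical replicates
#' (repeated rows per assay/condition/replicate) are averaged before the
#' per-replicate Pfaffl ratio is formed.
#'
#' @param data Data frame of Ct values, or a TSV path.
#' @param target,reference Assay names.
#' @return One-row data frame: `target`, `reference`, `ratio`, `sem`,
#'   `n`, `direction`.
#' @export
qpcr_relative_expression <- function(data, target, reference) {
  if (is.character(data)) data <- read.delim(data, stringsAsFactors = FALSE)
  need <- c("assay", "condition", "replicate", "ct")
  if (!all(need %in% names(data)))
    stop("need columns ", paste(need, collapse = ", "))
  if (is.null(data$efficiency)) data$efficiency <- 2
  reps <- sort(unique(data$replicate))
  mk <- function(a, rep) {
    d <- data[data$assay == a & data$replicate == rep, ]
    if (!nrow(d)) stop("no Ct values for assay ", a, " replicate ", rep)
    qpcr_assay(a,
               ct_control = d$ct[d$condition == "control"],
               ct_treated = d$ct[d$condition == "treated"],
               efficiency = d$efficiency[1L])
  }
  s <- replicate_summary(lapply(reps, function(r) mk(target, r)),
                         lapply(reps, function(r) mk(reference, r)))
  data.frame(target = target, reference = reference, ratio = s$mean,
             sem = s$sem, n = s$n, direction = s$direction,
             stringsAsFactors = FALSE)
}
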