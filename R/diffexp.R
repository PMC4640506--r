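# No-replicate differential expression for a two-library design:
# counts-per-million with a >=1 CPM expression filter, TMM
# normalisation, a negative-binomial conditional exact test at a fixed
# common dispersion (there are no replicates to estimate one from),
# Benjamini-Hochberg FDR, and the signed fold-change convention used in
# reporting (higher CPM over lower, carrying the sign of the log2FC).

#' Differential-expression configuration
#'
#' @param common_dispersion Negative-binomial dispersion phi shared by
#'   all features (variance = mu + phi * mu^2).  With no replicates it
#'   cannot be estimated and is fixed, default 0.1.
#' @param cpm_threshold Expression filter: keep features with at least
#'   this CPM in at least one library (inclusive).
#' @param fdr_threshold Significance cut-off on the BH-adjusted p.
#' @param tmm_logratio_trim,tmm_abs_trim Two-sided trim fractions on the
#'   log-ratios (M) and average log-expression (A) in TMM.
#' @param prior_count Proportional prior (per library-size-scaled unit)
#'   added when forming log2 fold changes, taming zeros.
#' @param zero_cpm CPM substituted for an exactly-zero side when forming
#'   the reported fold change (half the smallest displayable 1-d.p. CPM).
#' @return A list of class `de_config`.
#' @export
de_config <- function(common_dispersion = 0.1, cpm_threshold = 1,
                      fdr_threshold = 0.05, tmm_logratio_trim = 0.30,
                      tmm_abs_trim = 0.05, prior_count = 0.125,
                      zero_cpm = 0.05) {
  stopifnot(common_dispersion >= 0,
            tmm_logratio_trim >= 0, tmm_logratio_trim < 0.5,
            tmm_abs_trim >= 0, tmm_abs_trim < 0.5,
            fdr_threshold > 0, fdr_threshold <= 1,
            prior_count >= 0, zero_cpm > 0)
  structure(list(common_dispersion = common_dispersion,
                 cpm_threshold = cpm_threshold,
                 fdr_threshold = fdr_threshold,
                 tmm_logratio_trim = tmm_logratio_trim,
                 tmm_abs_trim = tmm_abs_trim,
                 prior_count = prior_count,
                 zero_cpm = zero_cpm),
            class = "de_config")
}

#' Counts per million
#'
#' `count / (library_total * norm_factor) * 1e6`, where the library
#' total is the column sum of the tested count matrix.
#'
#' @param counts Numeric matrix, features x libraries.
#' @param norm_factors Optional per-library TMM factors (default 1).
#' @param lib_sizes Optional explicit library totals (default column
#'   sums); must be positive.
#' @return Matrix of CPM values, same shape as `counts`.
#' @export
cpm <- function(counts, norm_factors = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library total")
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  sweep(counts, 2L, lib_sizes * norm_factors, "/") * 1e6
}

#' Expression filter on CPM
#'
#' @param cpm_table CPM matrix from [cpm()].
#' @param threshold Keep features with CPM at or above this value in at
#'   least one library.
#' @return Logical vector over features.
#' @export
filter_expressed <- function(cpm_table, threshold = 1) {
  apply(as.matrix(cpm_table) >= threshold, 1L, any)
}

# Weighted trimmed mean of M-values between one library and the
# reference library; the textbook TMM recipe.
#' @noRd
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) {
    warning("no features nonzero in both libraries; TMM factor set to 1")
    return(1)
  }
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method variance of M; weights are its inverse (precision)
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalisation factors
#'
#' Weighted trimmed mean of M-values: per-library scaling factors from
#' the doubly trimmed (30% on M, 5% on A by default), precision-weighted
#' mean of log2 relative-proportion ratios against a reference library,
#' computed over features nonzero in both libraries and normalised so
#' the factors have geometric mean 1.
#'
#' @param counts Count matrix, features x libraries (>= 2 columns).
#' @param reference_library Column name or index of the reference; by
#'   default the library whose upper quartile (of nonzero-scaled counts)
#'   is closest to the mean upper quartile.
#' @param logratio_trim,abs_trim Two-sided trim fractions.
#' @return Named vector of normalisation factors.
#' @export
tmm_factors <- function(counts, reference_library = NULL,
                        logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two libraries")
  n <- colSums(counts)
  if (is.null(reference_library)) {
    f75 <- apply(counts, 2L, function(x) quantile(x, 0.75)) / n
    reference_library <- which.min(abs(f75 - mean(f75)))
  }
  if (is.character(reference_library))
    reference_library <- match(reference_library, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == reference_library) return(1)
    .tmm_pair(counts[, j], counts[, reference_library], n[j],
              n[reference_library], logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Negative-binomial conditional exact test for two libraries
#'
#' Counts are rescaled to a common effective library size (the geometric
#' mean of the two effective sizes) and rounded to pseudo-counts.
#' Conditioning on the pseudo-count sum `s`, the two-sided p-value is
#' the total conditional probability of all splits `(k, s - k)` no more
#' likely than the observed one, where both sides are independent
#' negative binomials with equal means `s/2` and dispersion `phi`
#' (binomial `(s, 1/2)` at `phi = 0`).  The log2 fold change is the
#' size-adjusted count ratio with a small proportional prior.
#'
#' @param count_a,count_b Non-negative feature counts in libraries A, B.
#' @param eff_size_a,eff_size_b Effective library sizes (library total x
#'   TMM factor), positive.
#' @param phi Common dispersion (>= 0).
#' @param prior_count Proportional prior used only for the fold change.
#' @return List with `log2fc` (B vs A) and `p_value` in (0, 1].
#' @export
exact_test_nb <- function(count_a, count_b, eff_size_a, eff_size_b,
                          phi = 0.1, prior_count = 0.125) {
  if (count_a < 0 || count_b < 0) stop("negative counts")
  if (eff_size_a <= 0 || eff_size_b <= 0) stop("effective sizes must be > 0")
  if (phi < 0) stop("negative dispersion")
  g <- sqrt(eff_size_a * eff_size_b)
  pa <- round(count_a * g / eff_size_a)
  pb <- round(count_b * g / eff_size_b)
  s <- pa + pb

  if (s == 0) {
    p <- 1
  } else {
    k <- 0:s
    logp <- if (phi == 0) {
      dbinom(k, size = s, prob = 0.5, log = TRUE)
    } else {
      r <- 1 / phi
      lp <- dnbinom(k, size = r, mu = s / 2, log = TRUE) +
        dnbinom(s - k, size = r, mu = s / 2, log = TRUE)
      mx <- max(lp)
      lp - (mx + log(sum(exp(lp - mx))))
    }
    p <- min(1, sum(exp(logp[logp <= logp[pa + 1] + 1e-12])))
  }

  mean_eff <- (eff_size_a + eff_size_b) / 2
  pr_a <- prior_count * eff_size_a / mean_eff
  pr_b <- prior_count * eff_size_b / mean_eff
  rate_a <- (count_a + pr_a) / (eff_size_a + 2 * pr_a)
  rate_b <- (count_b + pr_b) / (eff_size_b + 2 * pr_b)
  list(log2fc = log2(rate_b / rate_a), p_value = p)
}

#' Benjamini-Hochberg step-up adjustment with an explicit test count
#'
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1 and mapped back
#' to the input order.  Supplying `m` larger than the list length models
#' additional tests with p = 1 (features tested but not listed).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param m Total number of tests, at least `length(p_values)`.
#' @return Adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in (0, 1]")
  n <- length(p_values)
  if (m < n) stop("m must be at least the number of p-values")
  o <- order(p_values)
  q <- rev(cummin(rev(p_values[o] * m / seq_len(n))))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Signed fold change from a CPM pair
#'
#' The higher CPM divided by the lower, carrying the sign of the log2
#' fold change to indicate direction; an exactly-zero side is replaced
#' by `zero_cpm` before dividing.
#'
#' @param cpm_a,cpm_b CPM values (vectors allowed).
#' @param log2fc Log2 fold changes supplying the sign (0 counts as +).
#' @param zero_cpm Substitute for a zero CPM.
#' @return Signed fold changes, |FC| >= 1.
#' @export
signed_fold_change <- function(cpm_a, cpm_b, log2fc, zero_cpm = 0.05) {
  if (any(cpm_a == 0 & cpm_b == 0))
    stop("fold change undefined when both CPMs are zero")
  hi <- pmax(cpm_a, cpm_b)
  lo <- pmin(cpm_a, cpm_b)
  lo[lo == 0] <- zero_cpm
  (hi / lo) * ifelse(log2fc < 0, -1, 1)
}

#' Run the full differential-expression pipeline
#'
#' CPM -> expression filter -> TMM -> per-feature NB conditional exact
#' test -> BH adjustment (m = number of features passing the filter) ->
#' signed fold change, plus the MA table (A = mean log2 CPM, M = log2
#' fold change) used for plotting.  Exactly two libraries are supported;
#' the second library is compared against the first (B vs A).
#'
#' @param table A `mir_count_table` (its mature + hairpin rows are
#'   tested, and their column sums are the library totals) or a plain
#'   numeric matrix with feature rownames.
#' @param config A [de_config()].
#' @param classes Classes tested when `table` is a `mir_count_table`.
#' @return List of class `mir_de`: `results` (data frame `feature_id`,
#'   `seq_class`, `cpm_a`, `cpm_b`, `log2fc`, `p_value`, `fdr`,
#'   `signed_fc`, sorted by p-value), `ma` (`feature_id`, `A`, `M`,
#'   `significant`), `norm_factors`, `lib_sizes`, `libs`, `config`.
#' @export
run_de <- function(table, config = de_config(),
                   classes = c("mature", "hairpin")) {
  if (inherits(table, "mir_count_table")) {
    sel <- table$seq_class %in% classes
    counts <- as.matrix(as.data.frame(table)[sel, attr(table, "libs"),
                                             drop = FALSE])
    rownames(counts) <- table$feature_id[sel]
    seq_class <- table$seq_class[sel]
  } else {
    counts <- as.matrix(table)
    seq_class <- rep(NA_character_, nrow(counts))
    if (is.null(rownames(counts)))
      rownames(counts) <- sprintf("f%05d", seq_len(nrow(counts)))
  }
  if (ncol(counts) != 2L)
    stop("the no-replicate design needs exactly two libraries")
  libs <- colnames(counts) %||% c("A", "B")

  lib_sizes <- colSums(counts)
  nf <- tmm_factors(counts, logratio_trim = config$tmm_logratio_trim,
                    abs_trim = config$tmm_abs_trim)
  eff <- lib_sizes * nf
  cpms <- cpm(counts, norm_factors = nf)
  keep <- filter_expressed(cpms, config$cpm_threshold)
  if (!any(keep)) {
    warning("no features pass the CPM filter")
    empty <- data.frame(feature_id = character(0), seq_class = character(0),
                        cpm_a = numeric(0), cpm_b = numeric(0),
                        log2fc = numeric(0), p_value = numeric(0),
                        fdr = numeric(0), signed_fc = numeric(0))
    return(structure(list(results = empty, ma = empty,
                          norm_factors = nf, lib_sizes = lib_sizes,
                          libs = libs, config = config),
                     class = "mir_de"))
  }
  kc <- counts[keep, , drop = FALSE]
  tests <- lapply(seq_len(nrow(kc)), function(i)
    exact_test_nb(kc[i, 1L], kc[i, 2L], eff[1L], eff[2L],
                  phi = config$common_dispersion,
                  prior_count = config$prior_count))
  log2fc <- vapply(tests, `[[`, numeric(1), "log2fc")
  p <- vapply(tests, `[[`, numeric(1), "p_value")
  fdr <- bh_adjust(p, m = sum(keep))
  kcpm <- cpms[keep, , drop = FALSE]
  sfc <- signed_fold_change(kcpm[, 1L], kcpm[, 2L], log2fc,
                            zero_cpm = config$zero_cpm)
  res <- data.frame(feature_id = rownames(kc),
                    seq_class = seq_class[keep],
                    cpm_a = kcpm[, 1L], cpm_b = kcpm[, 2L],
                    log2fc = log2fc, p_value = p, fdr = fdr,
                    signed_fc = sfc, row.names = NULL,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$feature_id), , drop = FALSE]
  rownames(res) <- NULL

  # prior-cushioned CPMs for the MA table, consistent with log2fc
  mean_eff <- mean(eff)
  pr <- config$prior_count * eff / mean_eff
  cp <- sweep(sweep(kc, 2L, pr, "+"), 2L, eff + 2 * pr, "/") * 1e6
  ma <- data.frame(feature_id = rownames(kc),
                   A = 0.5 * (log2(cp[, 1L]) + log2(cp[, 2L])),
                   M = log2fc,
                   significant = fdr < config$fdr_threshold,
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = res, ma = ma, norm_factors = nf,
                 lib_sizes = lib_sizes, libs = libs, config = config),
            class = "mir_de")
}

#' @export
print.mir_de <- function(x, ...) {
  cat("mir_de:", nrow(x$results), "features tested (",
      x$libs[2L], "vs", x$libs[1L], ")\n")
  cat("TMM factors:", paste(sprintf("%s=%.4f", x$libs, x$norm_factors),
                            collapse = ", "), "\n")
  sig <- sum(x$results$fdr < x$config$fdr_threshold)
  cat(sig, "features at FDR <", x$config$fdr_threshold, "\n")
  print(utils::head(x$results, 10L))
  invisible(x)
}
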