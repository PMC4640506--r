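test_that("CPM is scale-invariant and errors on empty libraries", {
  x <- matrix(c(5, 10, 999985, 3, 6, 999991), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("A", "B")))
  cp <- cpm(x)
  expect_equal(cp["a", "A"], 5)
  expect_equal(cpm(2 * x), cp)
  expect_error(cpm(matrix(0, 2, 2)), "zero library total")
})

test_that("the CPM expression filter is inclusive in either library", {
  cp <- rbind(c(1.2, 0), c(0.5, 0.9), c(1.0, 0), c(0, 5))
  expect_identical(filter_expressed(cp), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("TMM factors are 1 for proportion-identical libraries", {
  set.seed(21)
  a <- rnbinom(400, mu = 100, size = 10)
  expect_equal(unname(tmm_factors(cbind(A = a, B = a))), c(1, 1))
  # a pure depth difference changes no proportions
  expect_equal(unname(tmm_factors(cbind(A = a, B = 2L * a))), c(1, 1))
})

test_that("TMM matches the textbook oracle and edgeR on perturbed data", {
  set.seed(22)
  mu <- exp(runif(500, log(20), log(2000)))
  x <- cbind(A = rnbinom(500, mu = mu, size = 10),
             B = rnbinom(500, mu = mu, size = 10))
  x[1:100, "B"] <- x[1:100, "B"] * 4L  # 20% of features 4-fold up in B
  f <- tmm_factors(x, reference_library = "A")
  want_b <- oracle_tmm_pair(x[, "B"], x[, "A"])
  want <- c(1, want_b) / exp(mean(log(c(1, want_b))))
  expect_equal(unname(f), want, tolerance = 1e-9)
  # independent cross-check against edgeR's implementation
  expect_equal(unname(f),
               unname(edgeR::calcNormFactors(x, method = "TMM",
                                             refColumn = 1)),
               tolerance = 1e-9)
})

test_that("the exact test is symmetric and p = 1 at an even split", {
  r <- exact_test_nb(50, 50, 1e6, 1e6, phi = 0.1)
  expect_equal(r$p_value, 1)
  expect_equal(r$log2fc, 0)
  a <- exact_test_nb(30, 200, 2e6, 1.8e6, phi = 0.1)
  b <- exact_test_nb(200, 30, 1.8e6, 2e6, phi = 0.1)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
  expect_error(exact_test_nb(-1, 5, 1e6, 1e6), "negative")
  expect_error(exact_test_nb(1, 5, 0, 1e6), "> 0")
})

test_that("exact test equals conditional enumeration for sums <= 50", {
  for (phi in c(0, 0.1)) {
    for (s in c(2, 7, 20, 50)) {
      for (ka in unique(c(0, 1, floor(s / 3), floor(s / 2), s))) {
        got <- exact_test_nb(ka, s - ka, 1e6, 1e6, phi = phi)$p_value
        want <- oracle_cond_p(ka, s - ka, phi)
        expect_equal(got, want, tolerance = 1e-9,
                     info = sprintf("phi=%g s=%d ka=%d", phi, s, ka))
      }
    }
  }
  # and the binomial special case at phi = 0 via stats::binom.test
  for (ka in c(3, 10, 17)) {
    expect_equal(exact_test_nb(ka, 20 - ka, 1e6, 1e6, phi = 0)$p_value,
                 binom.test(ka, 20, 0.5)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches p.adjust at m = n and supports m > n", {
  set.seed(31)
  p <- runif(40)^2
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  # m > n models extra tests at p = 1
  q <- bh_adjust(p, m = 100)
  expect_equal(q, pmin(1, p.adjust(c(p, rep(1, 60)), "BH")[1:40]),
               tolerance = 1e-12)
  # single test and constant lists
  expect_equal(bh_adjust(0.04, m = 1), 0.04)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # monotone and never below the raw p
  expect_true(all(q >= p))
  expect_false(is.unsorted(q[order(p)]))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(p, m = 10), "at least")
})

test_that("signed fold change divides higher by lower with the FC sign", {
  expect_equal(round(signed_fold_change(49.9, 1008.5, 4.3), 1), 20.2)
  expect_equal(round(signed_fold_change(230.1, 4053.5, 4.1), 1), 17.6)
  expect_equal(signed_fold_change(5, 5, 0), 1)
  expect_equal(signed_fold_change(10, 2.5, -2), -4)
  # zero side substituted before dividing
  expect_equal(signed_fold_change(0, 1.2, 4.6, zero_cpm = 0.05), 24)
  expect_error(signed_fold_change(0, 0, 1), "both CPMs")
  expect_true(all(abs(signed_fold_change(c(1, 8), c(4, 2),
                                         c(2, -2))) >= 1))
})

test_that("run_de ranks a strong spike first and flags it", {
  set.seed(41)
  n <- 150
  mu <- exp(runif(n, log(50), log(1000)))
  x <- cbind(A = rnbinom(n, mu = mu, size = 10),
             B = rnbinom(n, mu = mu, size = 10))
  x[1, ] <- c(500, 8000) # ~16-fold at high counts
  rownames(x) <- sprintf("f%03d", 1:n)
  de <- run_de(x)
  expect_identical(de$results$feature_id[1], "f001")
  expect_lt(de$results$fdr[1], 0.05)
  expect_gt(de$results$log2fc[1], 3)
  # MA table mirrors the tested features
  expect_identical(sort(de$ma$feature_id),
                   sort(de$results$feature_id))
  expect_true(de$ma$significant[de$ma$feature_id == "f001"])
})

test_that("run_de recovers simulated 8-fold changes (parameter recovery)", {
  set.seed(42)
  n <- 300
  depth <- 2e6
  base_cpm <- exp(runif(n, log(20), log(3000)))
  truth <- rep(FALSE, n)
  truth[sample(which(base_cpm >= 50), 30)] <- TRUE
  mu_a <- base_cpm * depth / 1e6
  mu_b <- mu_a * ifelse(truth, 8, 1)
  x <- cbind(A = rnbinom(n, mu = mu_a, size = 10),
             B = rnbinom(n, mu = mu_b, size = 10))
  rownames(x) <- sprintf("f%03d", 1:n)
  de <- run_de(x)
  res <- de$results
  is_tp <- truth[match(res$feature_id, rownames(x))]
  # at least 80% of true positives rank above every null
  first_null <- min(which(!is_tp))
  expect_gte(first_null - 1, 0.8 * 30)
  # median |log2fc| of true positives within 0.5 of log2(8) = 3
  expect_lt(abs(median(abs(res$log2fc[is_tp])) - 3), 0.5)
})

test_that("degenerate designs are rejected or warned about", {
  x <- matrix(rpois(30, 50), ncol = 3)
  expect_error(run_de(x), "exactly two")
  low <- matrix(c(1, 1), ncol = 2,
                dimnames = list("f1", c("A", "B")))
  # single shared feature passes the CPM filter trivially; empty filter:
  tiny <- matrix(c(0L, 1e6L, 0L, 1e6L), ncol = 2,
                 dimnames = list(c("f1", "f2"), c("A", "B")))
  tiny["f1", ] <- 0L
  de <- run_de(tiny)
  expect_identical(nrow(de$results), 1L)
})
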