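test_that("tandem table construction validates and excludes correctly", {
  tt <- tandem_table("g1", c(100, 500), rbind(c(30, 10), c(10, 30)))
  expect_equal(tt$n, 80)
  expect_error(tandem_table("g", c(100), matrix(5, 2, 1)), ">= 2 sites")
  expect_error(tandem_table("g", c(500, 100), matrix(5, 2, 2)), "increasing")

  # via the site-table path: exclusion reasons
  mksites <- function(cnts1, cnts2, lens, gene = "gX") {
    s <- data.frame(chrom = "chr1", strand = "+",
                    pos = 100 + lens, total = cnts1 + cnts2,
                    n_s1 = cnts1, n_s2 = cnts2,
                    tier = "UCSC", region = "UTR3", gene_id = gene,
                    utr_length = lens, stringsAsFactors = FALSE)
    attr(s, "samples") <- c("s1", "s2")
    s
  }
  out <- build_tandem_tables(mksites(c(10, 5), c(9, 5), c(100, 400)))
  expect_equal(out$excluded$reason, "min_reads")      # n = 29
  out2 <- build_tandem_tables(mksites(c(15, 15), c(15, 15), c(100, 400)))
  expect_equal(out2$tables$gX$n, 60)
  one <- mksites(20, 20, 100)
  expect_equal(build_tandem_tables(one)$excluded$reason, "single_site")
  zero <- build_tandem_tables(mksites(c(30, 30), c(0, 0), c(100, 400)))
  expect_equal(zero$excluded$reason, "not_expressed")
})

test_that("switch index equals brute-force Pearson on expanded reads", {
  tt <- tandem_table("g", c(100, 500), rbind(c(30, 10), c(10, 30)))
  r <- tsi(tt)
  expect_gt(r, 0)
  expect_equal(r, expanded_pearson(tt), tolerance = 1e-12)
  set.seed(41)
  for (i in 1:200) {
    tab <- random_tandem_table()
    r_i <- tsi(tab)
    r_brute <- expanded_pearson(tab)
    if (is.na(r_brute)) expect_true(is.na(r_i))
    else expect_equal(r_i, r_brute, tolerance = 1e-12)
  }
})

test_that("switch index symmetries: sample swap negates, affine Y invariant", {
  set.seed(42)
  for (i in 1:50) {
    tab <- random_tandem_table()
    swapped <- tandem_table(tab$gene_id, tab$utr_lengths,
                            tab$counts[2:1, , drop = FALSE])
    expect_equal(tsi(swapped), -tsi(tab), tolerance = 1e-12)
    aff <- tandem_table(tab$gene_id, 3.5 * tab$utr_lengths + 11,
                        tab$counts)
    expect_equal(tsi(aff), tsi(tab), tolerance = 1e-9)
  }
  # identical usage proportions in both samples -> r = 0
  eq <- tandem_table("g", c(100, 400), rbind(c(20, 20), c(10, 10)))
  expect_equal(tsi(eq), 0, tolerance = 1e-12)
})

test_that("degenerate tables are excluded with reason, not dropped", {
  one_sample <- tandem_table("g", c(100, 400), rbind(c(20, 20), c(0, 0)))
  expect_true(is.na(tsi(one_sample)))
  one_site <- tandem_table("g", c(100, 400), rbind(c(40, 0), c(20, 0)))
  expect_true(is.na(tsi(one_site)))
  res <- trend_test(one_site)
  expect_equal(res$reason, "degenerate")
  fit <- apa_switch(list(a = one_site,
                         b = tandem_table("b", c(100, 400),
                                          rbind(c(30, 10), c(10, 30)))))
  expect_equal(fit$excluded$reason, "degenerate")
  expect_equal(nrow(fit$results), 1L)
})

test_that("trend statistic and chi-square p behave as defined", {
  eq <- tandem_table("g", c(100, 400), rbind(c(20, 20), c(10, 10)))
  res <- trend_test(eq)
  expect_equal(res$m2, 0)
  expect_equal(res$p, 1)
  # n = 2 table: m2 = (n-1) r^2 = r^2
  tiny <- tandem_table("g", c(100, 400), rbind(c(1, 0), c(0, 1)))
  res2 <- trend_test(tiny)
  expect_equal(res2$m2, 1 * res2$tsi^2)
  # m2 = (n-1) r^2 on a random table
  tab <- random_tandem_table()
  res3 <- trend_test(tab)
  expect_equal(res3$m2, (tab$n - 1) * tsi(tab)^2)
  expect_equal(res3$p, pchisq(res3$m2, 1, lower.tail = FALSE))
})

test_that("chi-square p agrees with a label-permutation null", {
  # the chi-square(1) reference is asymptotic, so the comparison is run at
  # read depths where it has converged (n in the hundreds-thousands); the
  # permutation p of a discrete null is bracketed by its strict and
  # inclusive tails (tie convention), widened by Monte-Carlo error
  set.seed(43)
  B <- 4000
  mc <- 3.3 * sqrt(0.25 / B) + 2 / B
  for (i in 1:5) {
    tab <- random_tandem_table(n_range = c(500, 2000))
    p_perm <- permutation_tails(tab, B)
    p_chi <- trend_test(tab)$p
    expect_gte(p_chi, p_perm["strict"] - mc)
    expect_lte(p_chi, p_perm["inclusive"] + mc)
  }
})

test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # order-preserving
  p <- c(0.04, 0.001, 0.9, 0.02)
  expect_equal(order(bh_fdr(p)), order(p))
})

test_that("switch calls respect both the index and FDR thresholds", {
  res <- data.frame(tsi = c(-0.5, -0.5, 0.05, 0.5, 0.2),
                    fdr = c(0.001, 0.5, 1e-9, 0.001, 0.02))
  expect_equal(call_switch(res),
               c("shortened", "none", "none", "lengthened", "none"))
})

test_that("apa_switch fit object carries coherent methods", {
  set.seed(44)
  tabs <- lapply(1:20, function(i) random_tandem_table(paste0("g", i)))
  names(tabs) <- paste0("g", 1:20)
  fit <- apa_switch(tabs)
  expect_s3_class(fit, "apa_switch")
  expect_equal(nrow(fit$results), 20)
  expect_named(coef(fit), paste0("g", 1:20))
  expect_equal(unname(coef(fit)), fit$results$tsi)
  expect_equal(fit$results$fdr, bh_fdr(fit$results$p))
  expect_output(print(fit), "genes tested")
  expect_output(print(summary(fit)), "quartiles")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
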