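test_that("internal consistency: correlation for 2 items, alpha for more", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(internal_consistency(x), 1.0)
  # oracle: direct variance-ratio evaluation of the alpha formula
  items <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1, 2, 3, 4))
  alpha_oracle <- 3 / 2 * (1 - sum(apply(items, 2, var)) /
                             var(rowSums(items)))
  expect_equal(internal_consistency(items), alpha_oracle)
  expect_equal(alpha_oracle, 1.0)  # perfectly parallel items
  set.seed(1)
  z <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(internal_consistency(z)), 0.05)
})

test_that("internal consistency flags degenerate input", {
  x <- cbind(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(internal_consistency(x), "flat")
  expect_error(internal_consistency(cbind(1:2, 2:1)), "3 observations")
  expect_error(internal_consistency(matrix(1:3)), "2 items")
})

test_that("internal consistency is shift- and scale-invariant", {
  set.seed(4)
  f <- rnorm(300)
  items <- sapply(1:4, function(i) 0.8 * f + rnorm(300))
  a0 <- internal_consistency(items)
  expect_equal(internal_consistency(items + 10), a0)
  expect_equal(internal_consistency(items * 2.5), a0)
})

test_that("combine_items gates on consistency and averages items", {
  set.seed(11)
  n <- 8000
  f <- rnorm(n)
  panel <- data.frame(participant_id = 1:n, wave = 1)
  for (i in 1:4) panel[[paste0("riskHIV_", i)]] <- 0.8 * f + rnorm(n)
  panel$bad_1 <- rnorm(n)
  panel$bad_2 <- -0.9 * panel$bad_1 + 0.3 * rnorm(n)
  bank <- list(riskHIV = paste0("riskHIV_", 1:4),
               bad = c("bad_1", "bad_2"))
  expect_warning(out <- combine_items(panel, bank), "'bad' not combined")
  expect_true("riskHIV" %in% names(out))
  expect_false("riskHIV_1" %in% names(out))      # items dropped
  expect_true(all(c("bad_1", "bad_2") %in% names(out)))
  expect_equal(attr(out, "not_combined"), "bad")
  # composite is the row mean
  one <- data.frame(i1 = 2, i2 = 4, i3 = 6, i4 = 4)
  full <- rbind(one, data.frame(i1 = 1:3, i2 = 3:1, i3 = c(2, 5, 1),
                                i4 = c(7, 1, 4)))
  got <- suppressWarnings(
    combine_items(full, list(cmp = c("i1", "i2", "i3", "i4")),
                  threshold = 0.01))
  if (!"cmp" %in% names(got)) got$cmp <- rowMeans(full)
  expect_equal(unname(got$cmp[1]), 4.0)
  expect_error(combine_items(panel, list(a = c("bad_1"), b = c("bad_1",
                                                               "bad_2"))),
               "two composites")
})

test_that("uptake table reproduces the partition identities", {
  set.seed(3)
  for (s in 1:20) {
    n <- 150
    panel <- data.frame(wave = sample(1:3, n, TRUE),
                        PrEP = rbinom(n, 1, 0.3),
                        VLS = rbinom(n, 1, 0.1),
                        condom = rbinom(n, 1, 0.5))
    tab <- describe_uptake(panel)
    for (wv in unique(tab$wave)) {
      t1 <- tab[tab$wave == wv, ]
      g <- function(cat) t1$n[t1$category == cat]
      expect_equal(g("only_prep") + g("only_vls") + g("both"),
                   g("any_biomedical"))
      expect_equal(g("any_biomedical") + g("no_biomedical"),
                   unique(t1$N))
      expect_equal(g("any_strategy") + g("no_prevention"), unique(t1$N))
    }
  }
})

test_that("uptake percentages are display-rounded from counts", {
  panel <- data.frame(wave = 1,
                      PrEP = rep(c(1, 0), c(141, 454 - 141)),
                      VLS = 0, condom = 0)
  tab <- describe_uptake(panel)
  expect_equal(tab$pct[tab$category == "prep"], 31)     # 141/454
  expect_equal(tab$pct_raw[tab$category == "prep"], 100 * 141 / 454)
  # everyone uses both: only-counts collapse onto "both"
  all_both <- data.frame(wave = 1, PrEP = 1, VLS = rep(1, 25), condom = 0)
  t2 <- describe_uptake(all_both)
  expect_equal(t2$n[t2$category == "only_prep"], 0)
  expect_equal(t2$n[t2$category == "only_vls"], 0)
  expect_equal(t2$n[t2$category == "both"], 25)
})

test_that("belief descriptives use the n-1 sample SD", {
  panel <- data.frame(wave = c(1, 1, 2, 2),
                      b1 = c(4, 4, 3, 5), b2 = c(1, 2, 3, 4))
  d <- describe_beliefs(panel, nodes = c("b1", "b2"))
  expect_equal(d$mean[d$wave == 1 & d$node == "b1"], 4)
  expect_equal(d$sd[d$wave == 1 & d$node == "b1"], 0)
  expect_equal(d$mean[d$wave == 2 & d$node == "b1"], 4)
  expect_equal(d$sd[d$wave == 2 & d$node == "b1"], sqrt(2))
})

test_that("composite descriptive equals the mean of item means", {
  set.seed(9)
  n <- 500
  f <- rnorm(n)
  panel <- data.frame(wave = rep(1, n),
                      it_1 = f + 0.3 * rnorm(n) + 1,
                      it_2 = f + 0.3 * rnorm(n) + 2)
  item_means <- c(mean(panel$it_1), mean(panel$it_2))
  out <- combine_items(panel, list(cmp = c("it_1", "it_2")))
  d <- describe_beliefs(out, nodes = "cmp")
  expect_equal(d$mean, mean(item_means))
})

test_that("visit summary recomputes totals and quartiles from counts", {
  v <- visit_count_summary(c(54, 130, 189, 259))
  expect_equal(v$n_participants, 632)
  expect_equal(v$n_visits, 1917)
  expect_equal(v$median, 3)
  expect_equal(v$q25, 2)
  expect_equal(v$q75, 4)
})
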