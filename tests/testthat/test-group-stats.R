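test_that("the hand-worked two-group decomposition is exact", {
  at <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(at$tss, c(1.5, 4, 5.5))
  expect_equal(at$df, c(1L, 4L, 5L))
  expect_equal(at$ms[1:2], c(1.5, 1.0))
  expect_equal(at$f[1], 1.5)
})

test_that("the balanced 19 x 6 design has df 18 / 95 / 113", {
  set.seed(2)
  groups <- replicate(19, rnorm(6), simplify = FALSE)
  at <- one_way_anova(groups)
  expect_equal(at$df, c(18L, 95L, 113L))
})

test_that("sum-of-squares and df additivity hold and match the lm oracle", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    n_i <- sample(3:9, k, replace = TRUE)
    groups <- lapply(n_i, function(n) rnorm(n, mean = runif(1, -2, 2),
                                            sd = runif(1, 0.5, 2)))
    at <- one_way_anova(groups)
    expect_equal(at$tss[1] + at$tss[2], at$tss[3], tolerance = 1e-9)
    expect_equal(at$df[1] + at$df[2], at$df[3])
    df_long <- data.frame(
      value = unlist(groups),
      group = factor(rep(seq_len(k), n_i)))
    fit <- stats::anova(stats::lm(value ~ group, df_long))
    expect_equal(at$tss[1:2], fit[["Sum Sq"]], tolerance = 1e-9)
    expect_equal(at$df[1:2], fit[["Df"]])
    expect_equal(at$f[1], fit[["F value"]][1], tolerance = 1e-9)
    expect_equal(at$p[1], fit[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("degenerate cases: identical groups give F = 0, zero residual gives NA", {
  at <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(at$f[1], 0)
  const <- one_way_anova(list(c(2, 2, 2), c(2, 2, 2)))
  expect_true(is.na(const$f[1]))
  expect_match(attr(const, "note"), "undefined")
  expect_error(one_way_anova(list(c(1, 2))), "at least 2 groups")
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 observations")
})

test_that("anova_consistency reproduces MS and F from TSS and df", {
  a <- anova_consistency(14840.249, 18, 14083.024, 95)
  expect_lt(abs(a$ms_between - 824.458), 5e-4)
  expect_lt(abs(a$ms_within - 148.242), 5e-4)
  expect_lt(abs(a$f - 5.562), 5e-4)
  expect_equal(anova_consistency(3, 1, 3, 1)$f, 1)
})

test_that("ANOVA type-I error is calibrated at the nominal 5% level", {
  set.seed(1234)
  rejections <- 0L
  n_rep <- 1000L
  for (r in seq_len(n_rep)) {
    groups <- replicate(19, rnorm(6), simplify = FALSE)
    if (one_way_anova(groups)$p[1] < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("Duncan separates far-apart groups and merges identical ones", {
  d <- duncan_mrt(list(hi = c(10, 11, 12), lo = c(1, 2, 3)))
  expect_equal(d$letters, c("a", "b"))
  d2 <- duncan_mrt(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(unique(d2$letters), "a")
  expect_error(duncan_mrt(list(c(1, 2), c(1, 2, 3))), "balanced")
})

test_that("Duncan letter blocks are contiguous over the sorted means", {
  set.seed(77)
  for (rep in 1:20) {
    groups <- replicate(6, rnorm(5, mean = sample(0:3, 1)), simplify = FALSE)
    d <- duncan_mrt(groups)
    for (lt in unique(unlist(strsplit(d$letters, "")))) {
      has <- grepl(lt, d$letters, fixed = TRUE)
      expect_equal(which(has), seq(min(which(has)), max(which(has))))
    }
  }
})

test_that("Duncan with two groups reduces to the pooled two-sample comparison", {
  set.seed(55)
  for (rep in 1:50) {
    a <- rnorm(6, 0)
    b <- rnorm(6, sample(c(0, 1.5), 1))
    d <- duncan_mrt(list(a = a, b = b))
    duncan_sig <- d$letters[1] != d$letters[2]
    t_sig <- stats::t.test(a, b, var.equal = TRUE)$p.value < 0.05
    expect_equal(duncan_sig, t_sig)
  }
})

test_that("Duncan recovers a two-block structure at close to the theoretical rate", {
  # four groups with means (0, 0, 3, 3), n = 6, unit variance: the gap is
  # always detected; each true-null pair splits falsely with probability
  # ~alpha, so the full-recovery rate is ~(1 - 0.05)^2 = 0.9
  set.seed(42)
  n_rep <- 200L
  correct <- 0L
  gap_split <- 0L
  for (r in seq_len(n_rep)) {
    g <- list(a = rnorm(6, 0), b = rnorm(6, 0), c = rnorm(6, 3), d = rnorm(6, 3))
    d <- duncan_mrt(g)
    if (d$letters[2] != d$letters[3]) gap_split <- gap_split + 1L
    if (length(unique(d$letters)) == 2 && d$letters[1] == d$letters[2] &&
        d$letters[3] == d$letters[4] && d$letters[2] != d$letters[3])
      correct <- correct + 1L
  }
  expect_equal(gap_split, n_rep)
  expect_gte(correct / n_rep, 0.84)
  expect_lte(correct / n_rep, 0.97)
})

test_that("replicate_study produces per-grade ANOVA and letters and respects nulls", {
  # constructed table: grade A has three clearly distinct indices, grade B
  # has identical value sets in every group
  set.seed(8)
  mk <- function(grade, idx, vals)
    data.frame(index = idx, image = seq_along(vals), grade = grade,
               metric = "OA", value = vals)
  tabA <- rbind(mk("A", "i1", rnorm(6, 0, 0.1)), mk("A", "i2", rnorm(6, 5, 0.1)),
                mk("A", "i3", rnorm(6, 10, 0.1)))
  base <- c(1, 2, 3, 4, 5, 6)
  tabB <- rbind(mk("B", "i1", base), mk("B", "i2", base), mk("B", "i3", base))
  rep_out <- replicate_study(rbind(tabA, tabB))
  aA <- rep_out$anova[rep_out$anova$grade == "A" &
                      rep_out$anova$source == "Between Groups", ]
  expect_lt(aA$p, 0.05)
  dA <- rep_out$duncan[rep_out$duncan$grade == "A", ]
  expect_equal(sort(unique(dA$letters)), c("a", "b", "c"))
  aB <- rep_out$anova[rep_out$anova$grade == "B" &
                      rep_out$anova$source == "Between Groups", ]
  expect_equal(aB$f, 0)
  dB <- rep_out$duncan[rep_out$duncan$grade == "B", ]
  expect_equal(unique(dB$letters), "a")
})

test_that("replicate_study is invariant to permuting images within groups", {
  set.seed(10)
  tab <- expand.grid(index = paste0("i", 1:4), image = 1:5,
                     grade = "G", metric = "OA", stringsAsFactors = FALSE)
  tab$value <- rnorm(nrow(tab), mean = match(tab$index, paste0("i", 1:4)))
  perm <- tab[sample(nrow(tab)), ]
  r1 <- replicate_study(tab)
  r2 <- replicate_study(perm)
  expect_equal(r1$anova$tss, r2$anova$tss, tolerance = 1e-12)
  expect_equal(r1$duncan$letters, r2$duncan$letters)
  # unbalanced designs are refused
  expect_error(replicate_study(tab[-1, ]), "unbalanced")
})
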