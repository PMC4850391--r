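make_amp_table <- function(cell_means, n_per_cell = 5, sd = 0.02) {
  conds <- rownames(cell_means)
  poss <- colnames(cell_means)
  rows <- expand.grid(rep = seq_len(n_per_cell), condition = conds,
                      position_id = poss, stringsAsFactors = FALSE)
  rows$peak_to_trough <- mapply(function(co, po) {
    rnorm(1, cell_means[co, po], sd)
  }, rows$condition, rows$position_id)
  rows$subject <- paste0("S", rows$rep)
  rows
}

test_that("two-way ANOVA decomposes amplitude variance correctly", {
  set.seed(51)
  # all cells identical -> all effect SS are zero
  m <- matrix(0.2, 2, 3, dimnames = list(c("5", "10"), c("A", "B", "C")))
  tab <- make_amp_table(m, sd = 0)
  res <- two_way_anova_amplitude(tab)
  expect_equal(res$table$sum_sq[1:3], rep(0, 3), tolerance = 1e-20)

  # SS identity on random balanced tables
  for (r in 1:10) {
    m <- matrix(runif(6, 0.1, 0.4), 2, 3,
                dimnames = list(c("5", "10"), c("A", "B", "C")))
    tab <- make_amp_table(m)
    res <- two_way_anova_amplitude(tab)
    y <- tab$peak_to_trough
    expect_equal(res$ss_total, sum((y - mean(y))^2), tolerance = 1e-8)
  }

  # strong frequency effect is detected
  hits <- replicate(20, {
    m <- matrix(c(0.2, 0.2, 0.2, 0.4, 0.4, 0.4), 2, 3, byrow = TRUE,
                dimnames = list(c("5", "10"), c("A", "B", "C")))
    res <- two_way_anova_amplitude(make_amp_table(m, sd = 0.02))
    res$table$p[1] < 1e-3
  })
  expect_gte(mean(hits), 0.95)

  # deficient designs rejected
  bad <- make_amp_table(m)[-1, ]
  expect_error(two_way_anova_amplitude(bad), "balanced")
  expect_error(two_way_anova_amplitude(make_amp_table(m[1, , drop = FALSE])),
               "2 levels")
})

test_that("pairwise post-hoc tests cover the requested pairs", {
  set.seed(52)
  tab <- data.frame(
    condition = rep(c("a", "b", "c"), each = 20),
    peak_to_trough = c(rnorm(20, 0.2, 0.02), rnorm(20, 0.2, 0.02),
                       rnorm(20, 0.5, 0.02)))
  res <- posthoc_pairwise(tab, group = "condition", method = "fdr")
  expect_equal(nrow(res), 3)
  # identical-distribution pair small t, separated pair significant
  expect_lt(abs(res$statistic[res$group_a == "a" & res$group_b == "b"]), 3)
  expect_lt(res$p_adj[res$group_a == "a" & res$group_b == "c"], 0.01)
  expect_lt(res$p_adj[res$group_a == "b" & res$group_b == "c"], 0.01)

  # identical groups give t = 0
  same <- data.frame(condition = rep(c("x", "y"), each = 4),
                     peak_to_trough = rep(c(1, 2, 3, 4), 2))
  expect_equal(posthoc_pairwise(same, "condition")$statistic, 0)

  # Tukey HSD path matches stats::TukeyHSD
  hsd <- posthoc_pairwise(tab, group = "condition", method = "tukey")
  ref <- TukeyHSD(aov(peak_to_trough ~ factor(condition), data = tab))[[1]]
  expect_equal(sort(hsd$p_adj), sort(unname(ref[, "p adj"])))
  expect_error(posthoc_pairwise(data.frame(condition = c("a", "b"),
                                           peak_to_trough = c(1, 2)),
                                "condition"), "at least 2")
})

test_that("Watson-Williams separates and equates circular means correctly", {
  set.seed(53)
  g1 <- rnorm(20, 0, 0.2)
  g2 <- rnorm(20, pi, 0.2)
  ww <- watson_williams(list(g1, g2))
  expect_lt(ww$p_value, 1e-3)

  same <- watson_williams(list(g1, g1))
  expect_lt(same$statistic, 1e-9)
  expect_equal(same$p_value, 1)

  expect_error(watson_williams(list(g1, c(0.1, 0.2))), "at least 3")
  expect_warning(watson_williams(list(runif(30, -pi, pi),
                                      runif(30, -pi, pi))), "0.45")
})

test_that("Watson-Williams p agrees with a label-permutation oracle", {
  set.seed(54)
  g1 <- rnorm(20, 0, 0.4)
  g2 <- rnorm(20, 0.3, 0.4)
  obs <- watson_williams(list(g1, g2))$statistic
  pool <- c(g1, g2)
  perm <- replicate(1e4, {
    idx <- sample(40, 20)
    suppressWarnings(watson_williams(list(pool[idx], pool[-idx]))$statistic)
  })
  p_perm <- mean(perm >= obs)
  p_param <- watson_williams(list(g1, g2))$p_value
  expect_lt(abs(p_param - p_perm), 0.02)
})

test_that("2x2 chi-square matches hand computation", {
  r0 <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- chi_square_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r1$statistic, 10) # all expected counts 2.5
  expect_equal(r1$p_value, pchisq(10, 1, lower.tail = FALSE))

  expect_error(chi_square_2x2(matrix(c(1, 0, 2, 0), 2)), "margins")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(chi_square_2x2(matrix(1:9, 3)), "2x2")
})
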