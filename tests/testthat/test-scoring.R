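test_that("rounding is decimal half-up, not banker's", {
  expect_equal(round_half_up(0.625), 0.63) # round() would give 0.62
  expect_equal(round_half_up(0.875), 0.88)
  expect_equal(round_half_up(5 / 12), 0.42)
  expect_equal(round_half_up(1 / 3), 0.33)
  expect_equal(round_half_up(-0.625), -0.63)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("main-indicator score is the half-up rounded mean of its binaries", {
  expect_equal(score_main(c(rep(1, 7), 0)), 0.88)   # 7/8
  expect_equal(score_main(c(0, 0, 0)), 0.00)
  expect_equal(score_main(c(rep(1, 5), rep(0, 7))), 0.42) # 5/12
  expect_equal(score_main(c(1, 0, 0)), 0.33)
  expect_equal(score_main(c(1, 1, 0), round = FALSE), 2 / 3)
  expect_error(score_main(numeric(0)), "empty")
  expect_error(score_main(c(1, 0.5)), "non-binary")
})

test_that("main_score_table aggregates per schema block and checks columns", {
  s <- default_schema()
  m <- gen_table4_consistent_matrix()
  t4 <- load_fixture("table4")
  tab <- main_score_table(m, s)
  expect_equal(tab, t4, ignore_attr = TRUE)

  # every policy's X2 block with one coded sub scores 0.33
  expect_true(all(tab$X2 == 0.33))

  # all-ones matrix scores 1.00 everywhere
  ones <- m
  for (id in binary_ids(s)) ones[[id]] <- 1L
  expect_true(all(as.matrix(main_score_table(ones, s)[, -1]) == 1))

  bad <- m[, -which(names(m) == "X4:2")]
  expect_error(main_score_table(bad, s), "X4:2")
  extra <- m
  extra$bogus <- 1L
  expect_error(main_score_table(extra, s), "bogus")
})

test_that("pmc index sums all ten main indicators and matches printed values", {
  t4 <- load_fixture("table4")
  t5 <- load_fixture("table5")
  pmc <- pmc_index(t4)
  expect_equal(pmc, t5$pmc[1:12])
  expect_equal(pmc[t4$pid == "P2"], 7.63)
  expect_equal(pmc[t4$pid == "P8"], 4.21)
  expect_equal(pmc_index(tibble::tibble(pid = "Z", X1 = 0, X2 = 0)), 0)
  expect_error(pmc_index(tibble::tibble(pid = "Z", X1 = 0.5, X2 = NA)), "X2")
})

test_that("depression index is the shortfall from the maximum", {
  expect_equal(depression_index(7.63), 2.37)
  expect_equal(depression_index(4.33), 5.67)
  expect_equal(depression_index(10), 0)
  expect_equal(depression_index(4, max_score = 9), 5)
  expect_error(depression_index(10.5), "out of")
  t5 <- load_fixture("table5")
  expect_equal(depression_index(t5$pmc), t5$depression)
})

test_that("level thresholds partition the scale and match printed levels", {
  expect_equal(as.character(classify_level(6.91)), "Good")
  expect_equal(as.character(classify_level(5.79)), "Acceptable")
  expect_equal(as.character(classify_level(7.00)), "Excellent")
  expect_equal(as.character(classify_level(c(10, 6, 5, 4.999, 0))),
               c("Excellent", "Good", "Acceptable", "Poor", "Poor"))
  expect_error(classify_level(-0.1), "out of")
  expect_error(classify_level(10.01), "out of")
  # every value on [0,10] lands in exactly one level
  grid <- seq(0, 10, by = 0.01)
  expect_false(anyNA(classify_level(grid)))
  t5 <- load_fixture("table5")
  expect_equal(as.character(classify_level(t5$pmc)), as.character(t5$level))
})

test_that("ranking follows competition convention and the oracle", {
  expect_equal(rank_policies(c(5, 5)), c(1L, 1L))
  expect_equal(rank_policies(c(3, 5, 5, 1)), c(3L, 1L, 1L, 4L))
  expect_equal(rank_policies(c(3, 5, 5, 1), ties = "first"), c(3L, 1L, 2L, 4L))
  withr::with_seed(11, {
    x <- sample(round(runif(100) * 10, 2), 100)
    expect_equal(rank_policies(x), oracle_rank(x))
  })
  t5 <- load_fixture("table5")
  expect_equal(rank_policies(t5$pmc, ties = "first"), t5$rank)
})

test_that("sub-indicator averages reproduce the detailed-scoring table spots", {
  m13 <- tibble::tibble(pid = paste0("P", 1:13))
  m13[["X3:3"]] <- c(rep(1L, 12), 0L)
  m13[["X2:2"]] <- c(1L, rep(0L, 12))
  m13[["X10"]] <- 1L
  av <- sub_indicator_averages(m13)
  expect_equal(av$score[av$sub_id == "X3:3"], 0.92)
  expect_equal(av$score[av$sub_id == "X2:2"], 0.08)
  expect_equal(av$score[av$sub_id == "X10"], 1.00)
})

test_that("evaluate_policies reproduces the published result table", {
  s <- default_schema()
  m <- gen_table4_consistent_matrix()
  t5 <- load_fixture("table5")
  res <- evaluate_policies(m, s)
  expect_equal(res$pmc, t5$pmc[1:12])
  expect_equal(res$depression, t5$depression[1:12])
  expect_equal(as.character(res$level), as.character(t5$level[1:12]))

  one <- tibble::tibble(pid = "Q")
  for (id in binary_ids(s)) one[[id]] <- 1L
  r <- evaluate_policies(one, s)
  expect_equal(r$pmc, 10)
  expect_equal(as.character(r$level), "Excellent")
  expect_equal(r$rank, 1L)

  only10 <- one
  for (id in setdiff(binary_ids(s), "X10")) only10[[id]] <- 0L
  r <- evaluate_policies(only10, s)
  expect_equal(r$pmc, 1)
  expect_equal(as.character(r$level), "Poor")
})

test_that("pmc and depression are conserved and bounded", {
  s <- default_schema()
  withr::with_seed(42, {
    for (rep in 1:20) {
      m <- random_matrix(s, n = 25)
      res <- evaluate_policies(m, s)
      expect_true(all(abs(res$pmc + res$depression - 10) < 1e-9))
      expect_true(all(res$pmc >= 0 & res$pmc <= 10))
      tab <- main_score_table(m, s)
      expect_true(all(as.matrix(tab[, -1]) >= 0 & as.matrix(tab[, -1]) <= 1))
    }
  })
})

test_that("flipping any coding 0 to 1 never decreases the unrounded index", {
  s <- default_schema()
  ids <- binary_ids(s)
  withr::with_seed(7, {
    m <- random_matrix(s, n = 6)
    base <- pmc_index(main_score_table(m, s, round = FALSE), round = FALSE)
    for (i in seq_len(nrow(m))) {
      zeros <- ids[unlist(m[i, ids]) == 0]
      for (id in zeros) {
        m2 <- m
        m2[[id]][i] <- 1L
        flipped <- pmc_index(main_score_table(m2, s, round = FALSE),
                             round = FALSE)
        expect_gte(flipped[i], base[i])
      }
    }
  })
})

test_that("pipeline index equals a direct exact-decimal evaluation", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      s <- random_schema(max_mains = 4, max_subs = 5)
      m <- random_matrix(s, n = 4)
      res <- pmc_index(main_score_table(m, s))
      for (i in seq_len(nrow(m))) {
        expect_equal(res[i], oracle_pmc(split_row(m, s, i)))
      }
    }
  })
})

test_that("sub-indicator averages recover Bernoulli parameters", {
  s <- default_schema()
  p <- load_fixture("table6")$score # realistic per-variable rates
  cfg <- generator_config(n_policies = 2000, p = p, seed = 20031)
  m <- gen_score_matrix(cfg, s)
  est <- sub_indicator_averages(m, s)$score
  tol <- 3 * sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(est - p) <= tol + 0.005)) # +half-ulp of 2-dp rounding
})
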