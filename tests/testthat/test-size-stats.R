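test_that("paired size differences follow the textbook t statistic", {
  # toy set of 6 pairs, hand-computable
  a <- c(8.1, 7.4, 9.0, 8.8, 7.9, 8.5)
  p <- c(8.4, 8.1, 8.9, 9.5, 8.0, 9.1)
  pairs <- make_pairs(rep("saxatilis", 6), "saxatilis", "female",
                      active_h = a, passive_h = p)
  res <- paired_size_difference(pairs)
  d <- a - p
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  expect_equal(res$t, t_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 5))
  expect_equal(res$mean_difference_mm, mean(d))

  # identical partner heights: zero difference, p = 1
  same <- make_pairs(rep("saxatilis", 5), "saxatilis", "female",
                     active_h = 8, passive_h = 8)
  res0 <- paired_size_difference(same)
  expect_equal(res0$mean_difference_mm, 0)
  expect_equal(res0$p_value, 1)

  # fewer than 5 pairs: group skipped with a log message
  expect_message(
    few <- paired_size_difference(make_pairs(rep("obtusata", 4), "obtusata",
                                             "female", active_h = 9:12,
                                             passive_h = 10:13)),
    "skipped")
  expect_equal(nrow(few), 0)
  # male-male records never enter
  mm <- validate_pairs(expand_male_male("saxatilis", "saxatilis", "S1",
                                        "lower", "M1", 8, 9))
  expect_equal(nrow(suppressMessages(paired_size_difference(mm))), 0)
})

test_that("permutation correlation p agrees with exhaustive enumeration", {
  x <- c(6.1, 7.3, 8.2, 9.4)
  y <- c(6.5, 7.1, 8.9, 9.0)
  r_obs <- cor(x, y)
  all_perm <- as.matrix(expand.grid(rep(list(1:4), 4)))
  all_perm <- all_perm[apply(all_perm, 1, function(z)
    length(unique(z)) == 4), , drop = FALSE]
  r_all <- apply(all_perm, 1, function(idx) cor(x, y[idx]))
  p_exact <- mean(abs(r_all) >= abs(r_obs))
  res <- size_correlation_perm(x, y, n_perm = 10000, seed = 5)
  expect_equal(res$r, r_obs)
  expect_lt(abs(res$p_value - p_exact), 0.02)

  perfect <- size_correlation_perm(1:10, 2 * (1:10), n_perm = 999, seed = 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p_value, 0.05)

  expect_error(size_correlation_perm(c(1, 2), c(1, 2), seed = 1), "3 pairs")
  expect_error(size_correlation_perm(rep(1, 5), 1:5, seed = 1),
               "zero variance")
  expect_error(size_correlation_perm(1:5, 1:5), "seed")
})

test_that("random pairing within quadrats behaves structurally", {
  # all sizes identical within a quadrat, distinct between: any pairing gives
  # the same two points, r* is degenerate at 1
  cen <- rbind(
    make_census(c("saxatilis|male" = 2, "saxatilis|female" = 2),
                quadrat_id = "Q1", heights = 5),
    make_census(c("saxatilis|male" = 2, "saxatilis|female" = 2),
                quadrat_id = "Q2", heights = 10))
  res <- random_pairing_mc(cen, observed_r = 1, species = "saxatilis",
                           site_year = "S1", level = "lower",
                           n_iter = 50, seed = 2)
  expect_true(all(res$r_star == 1))
  expect_equal(res$p_value, 1)

  # single quadrat: within-quadrat pairing only, correlations still defined
  one <- make_census(c("saxatilis|male" = 5, "saxatilis|female" = 5),
                     quadrat_id = "Q1", heights = c(4:8, 5:9))
  r1 <- random_pairing_mc(one, observed_r = 0.9, species = "saxatilis",
                          site_year = "S1", level = "lower",
                          n_iter = 100, seed = 3)
  expect_equal(r1$n_used, 100)
  expect_true(all(abs(r1$r_star) <= 1))

  expect_error(random_pairing_mc(make_census(c("saxatilis|male" = 3)),
                                 0.5, "saxatilis", "S1", "lower",
                                 n_iter = 10, seed = 1), "quadrat")
})

test_that("random pairing matches an independently coded simulator", {
  set.seed(77)
  cen <- rbind(
    make_census(c("saxatilis|male" = 3, "saxatilis|female" = 4),
                quadrat_id = "Q1", heights = round(runif(7, 4, 12), 1)),
    make_census(c("saxatilis|male" = 2, "saxatilis|female" = 3),
                quadrat_id = "Q2", heights = round(runif(5, 4, 12), 1)))
  res <- random_pairing_mc(cen, observed_r = 0.5, species = "saxatilis",
                           site_year = "S1", level = "lower",
                           n_iter = 20, seed = 11)
  # oracle: literal reimplementation of the protocol
  sel <- cen[cen$species == "saxatilis", ]
  males <- split(sel$shell_height_mm[sel$status == "male"],
                 sel$quadrat_id[sel$status == "male"])
  females <- split(sel$shell_height_mm[sel$status == "female"],
                   sel$quadrat_id[sel$status == "female"])
  set.seed(11)
  oracle <- vapply(1:20, function(i) {
    hm <- c(); hf <- c()
    for (q in c("Q1", "Q2")) {
      k <- min(length(males[[q]]), length(females[[q]]))
      hm <- c(hm, sample(males[[q]])[1:k])
      hf <- c(hf, sample(females[[q]])[1:k])
    }
    sum((hm - mean(hm)) * (hf - mean(hf))) /
      sqrt(sum((hm - mean(hm))^2) * sum((hf - mean(hf))^2))
  }, 0)
  expect_equal(res$r_star, oracle)
})

test_that("segregation statistic and p-value behave as designed", {
  # perfectly segregated quadrats: mean rank variance 0
  seg <- rbind(
    make_census(c("saxatilis|male" = 4), quadrat_id = "Q1", heights = 4:7),
    make_census(c("saxatilis|male" = 4), quadrat_id = "Q2", heights = 10:13))
  res <- suppressWarnings(segregation_test(seg, "saxatilis", "S1", "lower",
                                           n_perm = 500, seed = 1))
  expect_equal(res$observed_mean_rank_variance, 0)
  expect_lt(res$p_value, 0.05)

  # every quadrat an even mix: statistic at its maximum, p near 1
  mix <- do.call(rbind, lapply(1:4, function(q)
    make_census(c("saxatilis|male" = 6), quadrat_id = paste0("Q", q),
                heights = c(4, 5, 6, 11, 12, 13) + 0.01 * q)))
  res2 <- segregation_test(mix, "saxatilis", "S1", "lower",
                           n_perm = 500, seed = 1)
  expect_equal(res2$observed_mean_rank_variance, 0.25)
  expect_gt(res2$p_value, 0.5)

  # rank variance of a 0/1 indicator is bounded by 0.25
  set.seed(4)
  for (rep in 1:5) {
    cen <- do.call(rbind, lapply(1:4, function(q)
      make_census(c("saxatilis|male" = sample(2:6, 1)),
                  quadrat_id = paste0("Q", q),
                  heights = runif(1, 4, 12) + runif(6)[1:6])))
    cen <- cen[!is.na(cen$shell_height_mm), ]
    r <- segregation_test(cen, "saxatilis", "S1", "lower",
                          n_perm = 50, seed = rep)
    expect_gte(r$observed_mean_rank_variance, 0)
    expect_lte(r$observed_mean_rank_variance, 0.25)
  }

  # degenerate census: everything on one side of the median
  degen <- rbind(
    make_census(c("saxatilis|male" = 3), quadrat_id = "Q1", heights = 8),
    make_census(c("saxatilis|male" = 3), quadrat_id = "Q2", heights = 8))
  expect_warning(dres <- segregation_test(degen, "saxatilis", "S1", "lower",
                                          n_perm = 50, seed = 1),
                 "one side")
  expect_true(dres$degenerate)
})

test_that("segregation p agrees with exhaustive enumeration on a toy census", {
  # 3 quadrats x 4 snails; enumeration over size-class allocations weighted
  # by multivariate hypergeometric probabilities
  heights <- c(4, 5, 6, 11, 4.5, 10, 12, 13, 5.5, 6.5, 10.5, 11.5)
  cen <- do.call(rbind, lapply(1:3, function(q)
    make_census(c("saxatilis|male" = 4), quadrat_id = paste0("Q", q),
                heights = heights[(q - 1) * 4 + 1:4])))
  res <- segregation_test(cen, "saxatilis", "S1", "lower",
                          n_perm = 10000, seed = 8)

  med <- median(heights)
  ranks <- as.integer(heights >= med)
  K <- sum(ranks)
  pv <- function(k, n) (k / n) * (1 - k / n)
  tot <- 0; less <- 0
  for (k1 in 0:4) for (k2 in 0:4) {
    k3 <- K - k1 - k2
    if (k3 < 0 || k3 > 4) next
    w <- choose(4, k1) * choose(4, k2) * choose(4, k3)
    s <- mean(c(pv(k1, 4), pv(k2, 4), pv(k3, 4)))
    tot <- tot + w
    if (s < res$observed_mean_rank_variance) less <- less + w
  }
  expect_lt(abs(res$p_value - less / tot), 0.02)
})
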