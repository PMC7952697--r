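# FI and I_PC point estimates against hand-evaluated cases, plus the
# bootstrap contract.

test_that("FI is zero exactly when observed equals expected", {
  # one active category, observed passive split 6/2/2 and census composition
  # 60/20/20 make O = S cell by cell
  pairs <- make_pairs("saxatilis",
                      rep(c("saxatilis", "arcana", "saxatilis_group"),
                          c(6, 2, 2)),
                      rep(c("female", "female", "immature_or_castrated"),
                          c(6, 2, 2)))
  cen <- make_census(c("saxatilis|female" = 60, "arcana|female" = 20,
                       "saxatilis_group|immature_or_castrated" = 20))
  fit <- mating_null(pairs, cen)
  expect_identical(unname(fit$strata[[1]]$observed),
                   unname(fit$strata[[1]]$expected))
  expect_equal(fidelity_index(fit, "saxatilis", "S1", "lower"), 0)
})

test_that("FI matches direct evaluation of its formula", {
  # a = 10 all with conspecific females, P_consp = 0.1, t = 10: S_consp = 1,
  # FI = (10 - 1)/10 = 0.9
  pairs <- make_pairs(rep("saxatilis", 10), "saxatilis", "female")
  cen <- make_census(c("saxatilis|female" = 1, "saxatilis|male" = 9))
  fit <- mating_null(pairs, cen)
  expect_equal(fidelity_index(fit, "saxatilis", "S1", "lower"), 0.9)

  # zero conspecific matings: FI = -P_consp
  pairs0 <- make_pairs(rep("saxatilis", 10), "saxatilis_group",
                       "immature_or_castrated")
  cen0 <- make_census(c("saxatilis|female" = 3,
                        "saxatilis_group|immature_or_castrated" = 7))
  fit0 <- mating_null(pairs0, cen0)
  expect_equal(fidelity_index(fit0, "saxatilis", "S1", "lower"), -0.3)

  # 1.5-row males count both saxatilis and arcana females as conspecific
  pairs15 <- make_pairs(rep("saxatilis_1p5", 10),
                        rep(c("saxatilis", "arcana"), c(6, 4)), "female")
  cen15 <- make_census(c("saxatilis|female" = 10, "arcana|female" = 10,
                         "saxatilis|male" = 80))
  fit15 <- mating_null(pairs15, cen15)
  expect_equal(fidelity_index(fit15, "saxatilis_1p5", "S1", "lower"),
               (10 - 0.2 * 10) / 10)
})

test_that("FI denominator identity holds on every fitted table", {
  cfg <- scenario("arcana_asymmetric", n_pairs = 300)
  pop <- simulate_population(cfg, seed = 21)
  pairs <- simulate_matings(pop, cfg, seed = 22)
  fit <- mating_null(pairs, pop)
  for (st in fit$strata)
    for (sp in colnames(st$expected))
      expect_equal(sum(st$expected[, sp]), sum(st$observed[, sp]))
})

test_that("female FI mirrors the male formula with roles swapped", {
  # hand case: t = 10; actives saxatilis 6, obtusata 4; composition
  # saxF 0.3, obtF 0.3, saxM 0.4; O[saxF, sax] = 3
  pairs <- make_pairs(rep(c("saxatilis", "saxatilis", "obtusata", "obtusata"),
                          c(3, 3, 3, 1)),
                      rep(c("saxatilis", "saxatilis", "obtusata", "saxatilis"),
                          c(3, 3, 3, 1)),
                      rep(c("female", "male", "female", "male"), c(3, 3, 3, 1)),
                      weight = 1, pair_id = sprintf("W%02d", 1:10))
  # (weight-1 male passives stand in for unresolved male-male observations)
  cen <- make_census(c("saxatilis|female" = 3, "obtusata|female" = 3,
                       "saxatilis|male" = 4))
  suppressWarnings(suppressMessages(fit <- mating_null(pairs, cen)))
  expect_equal(fidelity_index_female(fit, "saxatilis", "S1", "lower"),
               (3 - 0.3 * 6) / (0.3 * 10))
  # a female category engaged by no conspecific male: FI = -S_consp / sum S
  expect_equal(fidelity_index_female(fit, "obtusata", "S1", "lower"),
               (3 - 0.3 * 4) / (0.3 * 10))
})

test_that("I_PC reproduces hand-evaluated ratio cases and is symmetric", {
  # census: saxF = obtF = 0.1, saxM = 0.8; actives saxatilis 10, obtusata 10
  # observed female cells chosen so r = (2, 2, 1, 1) -> I_PC = 1/3
  pairs <- make_pairs(
    rep(c("saxatilis", "saxatilis", "saxatilis", "obtusata", "obtusata",
          "obtusata"), c(2, 1, 7, 1, 2, 7)),
    rep(c("saxatilis", "obtusata", "saxatilis", "saxatilis", "obtusata",
          "saxatilis"), c(2, 1, 7, 1, 2, 7)),
    rep(c("female", "female", "male", "female", "female", "male"),
        c(2, 1, 7, 1, 2, 7)),
    pair_id = sprintf("I%02d", 1:20))
  cen <- make_census(c("saxatilis|female" = 2, "obtusata|female" = 2,
                       "saxatilis|male" = 16))
  suppressWarnings(fit <- mating_null(pairs, cen))
  expect_equal(ipc(fit, c("saxatilis", "obtusata"), "S1", "lower"), 1 / 3)
  expect_equal(ipc(fit, c("obtusata", "saxatilis"), "S1", "lower"), 1 / 3)

  # all four ratios equal -> 0; no heterospecific cells -> 1
  eq <- make_pairs(rep(c("saxatilis", "obtusata"), each = 2),
                   rep(c("saxatilis", "obtusata"), 2),
                   "female", pair_id = sprintf("E%02d", 1:4))
  ceq <- make_census(c("saxatilis|female" = 5, "obtusata|female" = 5))
  expect_equal(ipc(mating_null(eq, ceq), c("saxatilis", "obtusata"),
                   "S1", "lower"), 0)
  hom <- make_pairs(rep(c("saxatilis", "obtusata"), each = 2),
                    rep(c("saxatilis", "obtusata"), each = 2),
                    "female", pair_id = sprintf("H%02d", 1:4))
  expect_equal(ipc(mating_null(hom, ceq), c("saxatilis", "obtusata"),
                   "S1", "lower"), 1)

  # a zero expected cell excludes the pair-stratum
  cmiss <- make_census(c("saxatilis|female" = 5, "obtusata|male" = 5))
  expect_message(
    v <- ipc(suppressMessages(mating_null(hom, cmiss)),
             c("saxatilis", "obtusata"), "S1", "lower"), "excluded")
  expect_true(is.na(v))
})

test_that("bootstrap replicates equal an independently coded resampler", {
  pairs <- rbind(
    make_pairs(rep(c("saxatilis", "saxatilis", "obtusata"), c(4, 2, 3)),
               rep(c("saxatilis", "saxatilis_group", "obtusata"), c(4, 2, 3)),
               rep(c("female", "immature_or_castrated", "female"), c(4, 2, 3))),
    validate_pairs(expand_male_male("saxatilis", "obtusata", "S1", "lower",
                                    "MM1")))
  cen <- make_census(c("saxatilis|female" = 30, "obtusata|female" = 30,
                       "saxatilis|male" = 20,
                       "saxatilis_group|immature_or_castrated" = 20))
  est <- bootstrap_index(pairs, cen, "fi_male", focal = "saxatilis",
                         site_year = "S1", level = "lower", B = 3, seed = 99)

  # naive oracle: same RNG protocol, statistic recomputed from raw records
  p_pas <- passive_composition(cen)
  units <- split(seq_len(nrow(pairs)), pairs$pair_id)
  set.seed(99)
  naive <- vapply(1:3, function(b) {
    take <- sample(length(units), length(units), replace = TRUE)
    res <- pairs[unlist(units[take]), , drop = FALSE]
    oracle_fi_male(res, p_pas, "saxatilis", "saxatilis_female")
  }, 0)
  expect_equal(est$replicates, naive)
  # the point estimate agrees with the closed-form index on the fitted model
  fit <- mating_null(pairs, cen)
  expect_equal(est$point, fidelity_index(fit, "saxatilis", "S1", "lower"))
})

test_that("bootstrap handles degenerate and undefined cases", {
  one_type <- make_pairs(rep("saxatilis", 5), "saxatilis", "female")
  cen <- make_census(c("saxatilis|female" = 5, "saxatilis|male" = 5))
  est <- bootstrap_index(one_type, cen, "fi_male", focal = "saxatilis",
                         site_year = "S1", level = "lower", B = 50, seed = 1)
  expect_equal(est$boot_sd, 0)
  expect_true(all(est$replicates == est$point))

  # focal category absent entirely: point undefined, estimate invalid
  est2 <- bootstrap_index(one_type, cen, "fi_male", focal = "obtusata",
                          site_year = "S1", level = "lower", B = 10, seed = 1)
  expect_true(is.na(est2$point))
  expect_false(est2$valid)
  expect_equal(est2$n_dropped, 10)

  expect_error(bootstrap_index(one_type, cen, "fi_male", focal = "saxatilis",
                               site_year = "S1", level = "lower", B = 10),
               "seed")
  expect_s3_class(as.data.frame(est), "data.frame")
})
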