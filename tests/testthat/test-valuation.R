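test_that("time value is 1 for perfect overlap and for static data", {
  cfg <- single_type_config(half_life = 1)
  recs <- data.frame(type = c("t1", "t1"), time = c(10, 10))
  expect_equal(time_value(recs, cfg, 12), 1)
  genome_cfg <- valuation_config(types = list(
    genome = record_type_spec("genome", 1, half_life = Inf)
  ))
  for (age in c(0, 1, 40, 90)) {
    expect_equal(time_value(data.frame(type = "genome", time = 0),
                            genome_cfg, age), 1)
  }
})

test_that("two unit-half-life records two years apart overlap at exactly 1/2", {
  cfg <- single_type_config(half_life = 1)
  recs <- data.frame(type = c("t1", "t1"), time = c(10, 12))
  expect_identical(time_value(recs, cfg, 15), 0.5)
})

test_that("records sampled after the valuation time are an error", {
  cfg <- single_type_config()
  expect_error(time_value(data.frame(type = "t1", time = 50), cfg, 40),
               "future")
})

test_that("max-min time value matches the fine-grid oracle", {
  set.seed(101)
  cfg <- valuation_config(types = list(
    a = record_type_spec("a", 1, half_life = 1),
    b = record_type_spec("b", 1, half_life = 3),
    c = record_type_spec("c", 1, half_life = 0.5, kernel = "rect"),
    d = record_type_spec("d", 1, half_life = 2, kernel = "exp2_onesided")
  ))
  for (trial in 1:100) {
    k <- sample(2:3, 1)
    recs <- data.frame(type = sample(c("a", "b", "c", "d"), k, replace = TRUE),
                       time = runif(k, 20, 25))
    vt <- max(recs$time) + runif(1, 0, 3)
    got <- time_value(recs, cfg, vt)
    want <- oracle_time_value(recs, cfg, vt)
    expect_lt(abs(got - want), 1e-6)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("adding a record to the overlap never increases the time value", {
  set.seed(7)
  cfg <- single_type_config(half_life = 2)
  for (trial in 1:25) {
    recs <- data.frame(type = "t1", time = runif(4, 10, 14))
    vt <- max(recs$time) + 1
    v3 <- time_value(recs[1:3, ], cfg, vt)
    v4 <- time_value(recs, cfg, vt)
    expect_lte(v4, v3 + 1e-9)
    expect_gte(v4, 0); expect_lte(v4, 1)
  }
})

test_that("quality aggregation follows the reciprocal-sum rule", {
  cfg <- fixture_config()
  expect_equal(quality_aggregate(c(1, 1), cfg), 0.5)
  expect_equal(quality_aggregate(c(2, 2, 2), cfg), 2 / 3)
  expect_equal(quality_aggregate(c(1, 0, 3), cfg), 0)
  expect_equal(quality_aggregate(5, cfg), 5)
  expect_error(quality_aggregate(numeric(0), cfg), "empty")
  # monotone nondecreasing in each argument
  set.seed(3)
  for (trial in 1:50) {
    q <- runif(4, 0.1, 2)
    i <- sample(4, 1)
    q2 <- q; q2[i] <- q2[i] + runif(1, 0, 1)
    expect_gte(quality_aggregate(q2, cfg), quality_aggregate(q, cfg))
  }
})

test_that("single-record cost multiplies base value, quality and time value", {
  cfg <- fixture_config()
  rec0 <- biomedical_record("r", "u", "blood_test", 30, 0)
  expect_equal(single_record_cost(rec0, NULL, cfg, 31), 0)
  cfg1 <- single_type_config(half_life = 7)
  rec <- biomedical_record("r", "u", "t1", 40, 1)
  expect_equal(single_record_cost(rec, NULL, cfg1, 40), 1)
  chol <- biomedical_record("r", "u", "cholesterol_panel", 40, 1)
  expect_equal(single_record_cost(chol, NULL, cfg, 45), 0.5)
  expect_error(single_record_cost(
    biomedical_record("r", "u", "nope", 1, 1), NULL, cfg, 2), "registry")
  # user base-value modifier scales the cost
  u2 <- lp_users("u", current_age = 50, base_value_modifier = 3)
  expect_equal(single_record_cost(chol, u2[1, ], cfg, 45), 1.5)
})

test_that("combination cost is sparse in the synergy table", {
  cfg <- fixture_config()
  pair <- lp_dataset(data.frame(
    record_id = c("r1", "r2"), owner_id = "u1",
    type = c("blood_test", "mri"), time = c(30, 30), quality = c(1, 1)
  ))
  expect_equal(combination_cost(pair, NULL, cfg, 30), 0) # no declared synergy
  synergetic <- lp_dataset(data.frame(
    record_id = c("r1", "r2"), owner_id = "u1",
    type = c("blood_test", "transcriptome"), time = c(30, 30),
    quality = c(1, 1)
  ))
  expect_equal(combination_cost(synergetic, NULL, cfg, 30), 2 * 0.5 * 1)
  zeroq <- synergetic; zeroq$quality[2] <- 0
  expect_equal(combination_cost(zeroq, NULL, cfg, 30), 0)
  dup <- synergetic; dup$record_id <- c("r1", "r1")
  expect_error(combination_cost(dup, NULL, cfg, 30), "duplicate")
})

test_that("per-user cost equals brute-force subset enumeration", {
  set.seed(11)
  for (trial in 1:10) {
    cfg <- random_config()
    ds <- random_dataset(cfg, n_users = 1, n_records = 10)
    user <- users_for(ds)[1, ]
    vt <- max(ds$time) + 1
    got <- user_cost(user, ds, cfg, vt)$total
    want <- oracle_user_cost(user, ds, cfg, vt)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a lone record reduces the per-user cost to the single-record cost", {
  cfg <- fixture_config()
  ds <- lp_dataset(data.frame(record_id = "r1", owner_id = "u1",
                              type = "mri", time = 42, quality = 1.2))
  user <- users_for(ds)[1, ]
  expect_equal(user_cost(user, ds, cfg, 43)$total,
               single_record_cost(ds[1, ], user, cfg, 43))
})

test_that("the relationship multiplier doubles cost for an enrolled MZ twin", {
  cfg <- fixture_config()
  ds <- random_dataset(cfg, n_users = 1, n_records = 4)
  user <- users_for(ds)[1, ]
  vt <- max(ds$time) + 1
  base <- user_cost(user, ds, cfg, vt, cohort_lambda = 0)$total
  doubled <- user_cost(user, ds, cfg, vt, cohort_lambda = 1)$total
  expect_equal(doubled, 2 * base)
})

test_that("the enumeration cap errors loudly instead of truncating", {
  cfg <- fixture_config()
  set.seed(1)
  ds <- random_dataset(cfg, n_users = 1, n_records = 25)
  expect_error(user_cost(users_for(ds)[1, ], ds, cfg, max(ds$time) + 1),
               "cap")
  expect_silent(user_cost(users_for(ds)[1, ], ds, cfg, max(ds$time) + 1,
                          record_cap = 30L))
})

test_that("group value grows superlinearly in the number of users", {
  cfg <- fixture_config()
  expect_equal(group_cost("genome", 1, cfg), 0) # K = 1, ln 1 = 0
  expect_equal(group_cost("genome", rep(1, 4), cfg), 4 * log(4))
  expect_error(group_cost("genome", numeric(0), cfg), "empty")
  cfg32 <- valuation_config(types = list(g = record_type_spec("g", 1)),
                            group_growth = list(form = "k_pow_3_2", C = 2))
  expect_equal(group_cost("g", rep(1, 4), cfg32), 2 * 4^1.5)
  for (form in c("k_log_k", "k_pow_3_2")) {
    cf <- valuation_config(types = list(g = record_type_spec("g", 1)),
                           group_growth = list(form = form, C = 1))
    for (K in 2:64) {
      expect_gt(group_cost("g", rep(1, 2 * K), cf),
                2 * group_cost("g", rep(1, K), cf))
    }
  }
})

test_that("dataset cost composes per-user and group terms", {
  cfg <- fixture_config()
  expect_equal(dataset_cost(lp_dataset(NULL), lp_users(character(0)),
                            NULL, cfg, 0)$total_cost, 0)
  ds <- lp_dataset(data.frame(
    record_id = c("r1", "r2"), owner_id = c("u1", "u2"),
    type = "mri", time = c(40, 40), quality = c(1, 0.5)
  ))
  users <- users_for(ds)
  res <- dataset_cost(ds, users, NULL, cfg, 40)
  singles <- sum(sapply(1:2, function(i) {
    single_record_cost(ds[i, ], users[users$user_id == ds$owner_id[i], ],
                       cfg, 40)
  }))
  grp <- group_cost("mri", c(1, 0.5), cfg)
  expect_equal(res$total_cost, singles + grp)
  expect_equal(sum(res$per_user_terms), res$total_cost, tolerance = 1e-9)
  # all-zero qualities zero the whole dataset
  ds0 <- ds; ds0$quality <- 0
  expect_equal(dataset_cost(lp_dataset(ds0), users, NULL, cfg, 40)$total_cost, 0)
})

test_that("adding a zero-quality record never changes the dataset cost", {
  set.seed(5)
  for (trial in 1:60) {
    cfg <- random_config()
    ds <- random_dataset(cfg, n_users = 3, n_records = 6)
    users <- users_for(ds)
    vt <- max(ds$time) + 1
    before <- dataset_cost(ds, users, NULL, cfg, vt)$total_cost
    extra <- data.frame(
      record_id = "zq", owner_id = sample(users$user_id, 1),
      type = sample(names(cfg$type_registry), 1),
      time = runif(1, 0, vt), quality = 0
    )
    after <- dataset_cost(lp_dataset(rbind(as.data.frame(ds), extra)),
                          users, NULL, cfg, vt)$total_cost
    expect_lt(abs(after - before), 1e-12)
  }
})

test_that("dataset cost is monotone in qualities and base values", {
  set.seed(9)
  for (trial in 1:20) {
    cfg <- random_config()
    ds <- random_dataset(cfg, n_users = 3, n_records = 6)
    users <- users_for(ds)
    vt <- max(ds$time) + 1
    base <- dataset_cost(ds, users, NULL, cfg, vt)$total_cost
    ds2 <- ds; i <- sample(nrow(ds2), 1)
    ds2$quality[i] <- ds2$quality[i] + runif(1, 0, 1)
    expect_gte(dataset_cost(lp_dataset(ds2), users, NULL, cfg, vt)$total_cost,
               base - 1e-12)
    # raise one base value
    cfg2 <- cfg
    tp <- sample(names(cfg2$type_registry), 1)
    cfg2$type_registry[[tp]]$base_value <-
      cfg2$type_registry[[tp]]$base_value * 2
    expect_gte(dataset_cost(ds, users, NULL, cfg2, vt)$total_cost,
               base - 1e-12)
  }
})

test_that("marginal cost prices only what is new", {
  cfg <- fixture_config()
  set.seed(21)
  ds <- random_dataset(cfg, n_users = 3, n_records = 8)
  users <- users_for(ds)
  vt <- max(ds$time) + 1
  full <- dataset_cost(ds, users, NULL, cfg, vt)$total_cost
  expect_equal(marginal_cost(ds, lp_dataset(NULL), users, NULL, cfg,
                             vt)$total_cost, full)
  expect_equal(marginal_cost(lp_dataset(ds[1:3, ]), ds, users, NULL, cfg,
                             vt)$total_cost, 0)
  conflicting <- as.data.frame(ds[1, ]); conflicting$quality <- 99
  expect_error(marginal_cost(lp_dataset(conflicting), ds, users, NULL, cfg, vt),
               "conflicting")
})

test_that("sequential purchases cost the same as one purchase", {
  set.seed(33)
  for (trial in 1:40) {
    cfg <- random_config()
    ds <- random_dataset(cfg, n_users = 3, n_records = 8)
    users <- users_for(ds)
    vt <- max(ds$time) + 1
    full <- dataset_cost(ds, users, NULL, cfg, vt)$total_cost
    idx <- sample(nrow(ds), sample(nrow(ds) - 1, 1))
    d1 <- lp_dataset(ds[idx, ]); d2 <- lp_dataset(ds[-idx, ])
    m1 <- marginal_cost(d1, lp_dataset(NULL), users, NULL, cfg, vt)$total_cost
    m2 <- marginal_cost(d2, d1, users, NULL, cfg, vt)$total_cost
    expect_lt(abs(m1 + m2 - full), 1e-9)
    expect_gte(m1, 0); expect_gte(m2, 0)
  }
})

test_that("payments split between validator share and submitters exactly", {
  cfg <- fixture_config()
  res <- structure(list(total_cost = 4,
                        per_user_terms = c(u1 = 3, u2 = 1)),
                   class = "lp_valuation")
  pay <- attribute_payments(res, 100, dv_share = 0.2)
  expect_equal(unname(pay[c("u1", "u2", "dv")]), c(60, 20, 20))
  expect_equal(sum(pay), 100)
  single <- structure(list(total_cost = 2, per_user_terms = c(u1 = 2)),
                      class = "lp_valuation")
  pay1 <- attribute_payments(single, 7, dv_share = 0)
  expect_equal(unname(pay1["u1"]), 7)
  zero <- structure(list(total_cost = 0, per_user_terms = numeric(0)),
                    class = "lp_valuation")
  expect_error(attribute_payments(zero, 5, 0), "zero-value")
  set.seed(55)
  for (trial in 1:1000) {
    k <- sample(1:6, 1)
    res <- structure(list(total_cost = 1,
                          per_user_terms = setNames(runif(k, 0.01, 5),
                                                    paste0("u", 1:k))),
                     class = "lp_valuation")
    amt <- runif(1, 0, 100)
    shr <- runif(1, 0, 0.9)
    pay <- attribute_payments(res, amt, shr)
    expect_identical(sum(pay), amt) # conservation to the last bit
    expect_true(all(pay >= 0))
  }
})
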