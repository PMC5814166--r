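# Shared fixtures and independent oracles used across the suite.

# -- configs ---------------------------------------------------------------

fixture_config <- function(...) default_valuation_config(...)

single_type_config <- function(half_life = 1, base_value = 1,
                               kernel = "exp2") {
  valuation_config(types = list(
    t1 = record_type_spec("t1", base_value, half_life = half_life,
                          kernel = kernel)
  ))
}

# a registry of generic types with random synergies, for randomized tests
random_config <- function(n_types = 4, n_synergy = 4, order = 3) {
  keys <- paste0("type", seq_len(n_types))
  types <- lapply(keys, function(k) {
    record_type_spec(k, base_value = runif(1, 0.5, 3),
                     half_life = sample(c(Inf, runif(1, 0.5, 10)), 1))
  })
  names(types) <- keys
  synergy <- list()
  for (i in seq_len(n_synergy)) {
    k <- sample(2:order, 1)
    synergy[[i]] <- list(types = sample(keys, k, replace = TRUE),
                         value = runif(1, 0.5, 3))
  }
  # drop duplicate multisets (the config keeps the last; make them unique)
  seen <- vapply(synergy, function(s) paste(sort(s$types), collapse = "+"),
                 character(1))
  valuation_config(types = types, synergy = synergy[!duplicated(seen)])
}

random_dataset <- function(config, n_users = 3, n_records = 6,
                           max_age = 50, zero_prob = 0) {
  keys <- names(config$type_registry)
  uid <- paste0("u", seq_len(n_users))
  q <- runif(n_records, 0.2, 2)
  if (zero_prob > 0) q[runif(n_records) < zero_prob] <- 0
  lp_dataset(data.frame(
    record_id = paste0("r", seq_len(n_records)),
    owner_id = sample(uid, n_records, replace = TRUE),
    type = sample(keys, n_records, replace = TRUE),
    time = runif(n_records, 0, max_age),
    quality = q,
    stringsAsFactors = FALSE
  ))
}

users_for <- function(dataset, modifier = 1) {
  lp_users(user_id = unique(dataset$owner_id),
           current_age = if (nrow(dataset)) max(dataset$time) + 1 else 50,
           base_value_modifier = modifier)
}

# -- pedigree fixtures -----------------------------------------------------

trio_ped <- function() {
  pedigree(id = c("father", "mother", "child"),
           father = c(NA, NA, "father"), mother = c(NA, NA, "mother"),
           sex = c(1, 2, 0))
}

three_gen_chain <- function() {
  pedigree(
    id = c("gf", "gm", "father", "mother", "child"),
    father = c(NA, NA, "gf", NA, "father"),
    mother = c(NA, NA, "gm", NA, "mother"),
    sex = c(1, 2, 1, 2, 0)
  )
}

sibs_ped <- function(mz = FALSE) {
  pedigree(id = c("f", "m", "a", "b"),
           father = c(NA, NA, "f", "f"), mother = c(NA, NA, "m", "m"),
           sex = c(1, 2, 1, 1),
           mz_pairs = if (mz) rbind(c("a", "b")))
}

cousins_ped <- function() {
  # two sibs marry unrelated spouses; their children are first cousins
  pedigree(
    id = c("gf", "gm", "p1", "p2", "s1", "s2", "c1", "c2"),
    father = c(NA, NA, "gf", "gf", NA, NA, "p1", "p2"),
    mother = c(NA, NA, "gm", "gm", NA, NA, "s1", "s2"),
    sex = c(1, 2, 1, 1, 2, 2, 0, 0)
  )
}

# -- independent oracles ---------------------------------------------------

# grid-search oracle for the max-min time value (step 1e-4)
oracle_time_value <- function(records, config, valuation_time, step = 1e-4) {
  records <- as.data.frame(records)
  specs <- lapply(records$type, function(tp) config$type_registry[[tp]])
  kern <- function(spec, t, time) {
    if (!is.finite(spec$half_life)) return(rep(1, length(t)))
    u <- (t - time - spec$kernel_offset) / spec$half_life
    switch(spec$kernel,
      exp2 = 2^(-abs(u)),
      exp2_onesided = ifelse(u < 0, 0, 2^(-u)),
      rect = as.numeric(abs(u) <= 1)
    )
  }
  if (nrow(records) == 1L) {
    return(kern(specs[[1]], valuation_time, records$time[1]))
  }
  lo <- min(records$time); hi <- valuation_time
  envelope <- function(ts) {
    vals <- rep(Inf, length(ts))
    for (m in seq_len(nrow(records))) {
      vals <- pmin(vals, kern(specs[[m]], ts, records$time[m]))
    }
    vals
  }
  ts <- seq(lo, hi, by = step)
  if (length(ts) == 0L || ts[length(ts)] < hi) ts <- c(ts, hi)
  vals <- envelope(ts)
  best <- ts[which.max(vals)]
  # two local re-gridding passes shrink the bracket far below the target
  # tolerance (the envelope has a first-order kink at crossings, so the
  # coarse grid alone is only step-accurate)
  win <- step
  for (pass in 1:2) {
    ts <- seq(max(lo, best - win), min(hi, best + win), length.out = 2001L)
    vals <- envelope(ts)
    best <- ts[which.max(vals)]
    win <- win / 500
  }
  max(vals)
}

# brute-force per-user cost: every subset of every size, f_k term by term.
# Uses the package's time_value (itself validated against the grid oracle)
# so this tests the subset-enumeration logic, not the optimizer.
oracle_user_cost <- function(user, records, config, valuation_time,
                             cohort_lambda = 0) {
  n <- nrow(records)
  mod <- if (is.null(user$base_value_modifier) ||
             is.na(user$base_value_modifier[1])) 1 else user$base_value_modifier[1]
  total <- 0
  for (size in seq_len(n)) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (idx in subsets) {
      sub <- records[idx, ]
      if (size == 1L) {
        spec <- config$type_registry[[sub$type]]
        if (sub$quality == 0) next
        tv <- time_value(sub, config, valuation_time)
        total <- total + spec$base_value * mod * sub$quality * tv
      } else {
        if (size > config$max_combination_order) next
        psi <- config$synergy_table[[paste(sort(sub$type), collapse = "+")]]
        if (is.null(psi)) next
        v <- if (any(sub$quality == 0)) 0 else 1 / sum(1 / sub$quality)
        if (v == 0) next
        tv <- time_value(sub, config, valuation_time)
        total <- total + psi * mod * v * tv
      }
    }
  }
  total * (1 + cohort_lambda)
}

# exhaustive path-enumeration relatedness on a plain parent list (no MZ)
oracle_relatedness <- function(parents, a, b) {
  paths_up <- function(x) {
    out <- list(list(top = x, nodes = x, len = 0L))
    i <- 1L
    while (i <= length(out)) {
      p <- out[[i]]
      for (par in parents[[p$top]]) {
        out[[length(out) + 1L]] <- list(top = par, nodes = c(p$nodes, par),
                                        len = p$len + 1L)
      }
      i <- i + 1L
    }
    out
  }
  if (a == b) return(1)
  r <- 0
  for (pa in paths_up(a)) for (pb in paths_up(b)) {
    if (pa$top == pb$top &&
        length(intersect(pa$nodes, pb$nodes)) == 1L) {
      r <- r + 2^-(pa$len + pb$len)
    }
  }
  r
}

# second, independent Merkle implementation (recursive, same dialect:
# odd node promoted)
oracle_merkle_root <- function(leaves) {
  if (length(leaves) == 0L) {
    return(as.character(openssl::sha256("lifepound:empty-tree")))
  }
  if (length(leaves) == 1L) return(leaves)
  half <- 2L * (length(leaves) %/% 2L)
  up <- character(0)
  for (i in seq(1L, half, by = 2L)) {
    up <- c(up, as.character(openssl::sha256(paste0(leaves[i], leaves[i + 1]))))
  }
  if (length(leaves) %% 2L == 1L) up <- c(up, leaves[length(leaves)])
  oracle_merkle_root(up)
}

# Lagrange interpolation oracle over the Shamir prime, straightforward form
oracle_lagrange_at0 <- function(xs, ys, p) {
  modinv <- function(a) {
    a <- a %% p
    t0 <- 0; t1 <- 1; r0 <- p; r1 <- a
    while (r1 != 0) {
      q <- r0 %/% r1
      tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
      tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    }
    ((t0 %% p) + p) %% p
  }
  acc <- 0
  for (i in seq_along(xs)) {
    term <- ys[i]
    for (j in seq_along(xs)) {
      if (i == j) next
      term <- (term * ((p - xs[j]) %% p)) %% p
      term <- (term * modinv(((xs[i] - xs[j]) %% p + p) %% p)) %% p
    }
    acc <- (acc + term) %% p
  }
  acc
}

market_fixture <- function(config = fixture_config(), n_users = 3,
                           dv_balance = 100, cust_balance = 100) {
  actors <- data.frame(
    actor_id = c(paste0("u", seq_len(n_users)), "dv1", "cust1"),
    role = c(rep("user", n_users), "data_validator", "customer"),
    balance = c(rep(0, n_users), dv_balance, cust_balance),
    stringsAsFactors = FALSE
  )
  market_init(config, actors)
}
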