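# ---- time-value kernels -------------------------------------------------

kernel_fun <- function(name) {
  switch(name,
    exp2 = function(u) 2^(-abs(u)),
    exp2_onesided = function(u) ifelse(u < 0, 0, 2^(-u)),
    rect = function(u) as.numeric(abs(u) <= 1),
    stop("unknown kernel: ", name)
  )
}

# per-record kernel value at analysis time t; vectorized over t
record_kernel_at <- function(t, spec, time) {
  if (!is.finite(spec$half_life)) return(rep(1, length(t)))
  u <- (t - time - spec$kernel_offset) / spec$half_life
  kernel_fun(spec$kernel)(u)
}

#' Time value of a set of records
#'
#' The time value measures the temporal overlap of the records' relevance
#' windows. For a single record it is the kernel value at the valuation time,
#' `w((valuation_time - time - t0) / T)`; for two or more records it is the
#' best jointly achievable value
#' `max_t min_m w_m((t - time_m - t0_m) / T_m)` over analysis times
#' `t` between the earliest sampling age and the valuation time. Records with
#' infinite half-life contribute a constant 1 and never bind the minimum.
#'
#' For all-default exponential kernels the optimum lies at a kernel peak or a
#' pairwise crossing and is computed in closed form; otherwise a dense grid
#' plus golden-section refinement (tolerance 1e-8) is used.
#'
#' @param records Data frame (or list of lists) with `type` and `time`.
#' @param config An `lp_config` supplying the per-type kernels.
#' @param valuation_time Age (years) at which the data is valued; must be at
#'   least the newest sampling age.
#' @return A value in `[0, 1]`.
#' @export
time_value <- function(records, config, valuation_time) {
  records <- as.data.frame(records)
  k <- nrow(records)
  if (k < 1L) stop("time_value needs at least one record")
  specs <- lapply(records$type, resolve_type, config = config)
  times <- records$time
  if (valuation_time < max(times)) {
    stop("valuation_time (", valuation_time, ") precedes a sampling age (",
         max(times), "): records from the future")
  }
  if (all(!vapply(specs, function(s) is.finite(s$half_life), logical(1)))) {
    return(1)
  }
  if (k == 1L) {
    return(record_kernel_at(valuation_time, specs[[1L]], times[1L]))
  }

  objective <- function(t) {
    vals <- vapply(seq_len(k), function(m) {
      record_kernel_at(t, specs[[m]], times[m])
    }, numeric(length(t)))
    if (length(t) == 1L) min(vals) else apply(matrix(vals, nrow = length(t)), 1L, min)
  }
  lo <- min(times)
  hi <- valuation_time
  if (hi <= lo) return(objective(lo))

  finite <- vapply(specs, function(s) is.finite(s$half_life), logical(1))
  all_exp2 <- all(vapply(specs[finite], function(s) s$kernel == "exp2", logical(1)))
  if (all_exp2) {
    # candidate optima: kernel peaks and pairwise crossings of the binding kernels
    idx <- which(finite)
    peaks <- vapply(idx, function(m) times[m] + specs[[m]]$kernel_offset, numeric(1))
    cand <- peaks
    if (length(idx) >= 2L) {
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i < j) {
          ai <- peaks[i]; aj <- peaks[j]
          Ti <- specs[[idx[i]]]$half_life; Tj <- specs[[idx[j]]]$half_life
          cand <- c(cand, (ai * Tj + aj * Ti) / (Ti + Tj))
        }
      }
    }
    cand <- unique(pmin(pmax(cand, lo), hi))
    cand <- c(cand, lo, hi)
    return(max(vapply(cand, objective, numeric(1))))
  }

  grid <- seq(lo, hi, length.out = 4096L)
  vals <- objective(grid)
  best <- which.max(vals)
  a <- grid[max(1L, best - 1L)]
  b <- grid[min(length(grid), best + 1L)]
  golden_section_max(objective, a, b, tol = 1e-8)
}

golden_section_max <- function(f, a, b, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  max(f1, f2)
}

resolve_type <- function(type, config) {
  spec <- config$type_registry[[type]]
  if (is.null(spec)) stop("record type not in registry: '", type, "'")
  spec
}

# ---- quality aggregation ------------------------------------------------

#' Aggregate qualities of a record combination
#'
#' Default aggregator is the reciprocal sum `(sum_m 1/quality_m)^-1`: monotone
#' nondecreasing in each argument and zero as soon as any member quality is
#' zero, so zero-quality records never contribute cost.
#'
#' @param qualities Nonnegative numeric vector, length >= 1.
#' @param config An `lp_config` (selects the aggregator).
#' @return A nonnegative scalar.
#' @export
quality_aggregate <- function(qualities, config) {
  if (length(qualities) == 0L) stop("quality_aggregate: empty quality list")
  if (any(qualities < 0)) stop("qualities must be nonnegative")
  if (any(qualities == 0)) return(0)
  1 / sum(1 / qualities)
}

# ---- per-user cost terms -----------------------------------------------

user_modifier <- function(user) {
  if (is.null(user)) return(1)
  if (is.data.frame(user)) {
    m <- user$base_value_modifier
    if (is.null(m) || is.na(m[1L])) 1 else m[1L]
  } else {
    user$base_value_modifier %||% 1
  }
}

#' Cost of a single record
#'
#' `base_value(type) * base_value_modifier(user) * quality * time_value`.
#'
#' @param record One-row data frame or list with `type`, `time`, `quality`.
#' @param user User row supplying `base_value_modifier` (or `NULL` for 1).
#' @param config An `lp_config`.
#' @param valuation_time Valuation age in years.
#' @return Nonnegative scalar cost in LifePounds.
#' @export
single_record_cost <- function(record, user, config, valuation_time) {
  record <- as.data.frame(record)
  spec <- resolve_type(record$type[1L], config)
  if (record$quality[1L] == 0) return(0)
  spec$base_value * user_modifier(user) * record$quality[1L] *
    time_value(record, config, valuation_time)
}

#' Cost of a combination of records from one user
#'
#' Combinations carry value only when their type multiset appears in the
#' config's synergy table; the cost is then
#' `synergy * quality_aggregate(qualities) * time_value(records)`.
#'
#' @param records Data frame of `k >= 2` distinct records of one user.
#' @inheritParams single_record_cost
#' @return Nonnegative scalar cost (0 for multisets without declared synergy).
#' @export
combination_cost <- function(records, user, config, valuation_time) {
  records <- as.data.frame(records)
  if (nrow(records) < 2L) stop("combination_cost needs k >= 2 records")
  if (anyDuplicated(records$record_id)) stop("duplicate record in combination")
  psi <- config$synergy_table[[synergy_key(records$type)]]
  if (is.null(psi)) return(0)
  for (tp in unique(records$type)) resolve_type(tp, config)
  v <- quality_aggregate(records$quality, config)
  if (v == 0) return(0)
  psi * user_modifier(user) * v * time_value(records, config, valuation_time)
}

#' Per-user cost: all record combinations of one user
#'
#' Sums the combination cost over every subset of the user's records of size
#' 1 to `max_combination_order`. Since undeclared type multisets have zero
#' synergy, only singles and subsets matching a synergy-table entry
#' contribute; the implementation enumerates exactly those, and equals the
#' brute-force enumeration over all subsets. When relationship
#' regularization is enabled the total is scaled by `1 + cohort_lambda`.
#'
#' @param user User row (supplies the base-value modifier).
#' @param records Data frame of the user's records.
#' @param config An `lp_config`.
#' @param valuation_time Valuation age in years.
#' @param cohort_lambda Summed coefficient of relationship between this user
#'   and enrolled relatives (see [cohort_lambda()]); default 0.
#' @param record_cap Enumeration guard on the per-user record count.
#' @return A list with `total` and a breakdown data frame (`kind`,
#'   `record_ids`, `value`).
#' @export
user_cost <- function(user, records, config, valuation_time,
                      cohort_lambda = 0, record_cap = 20L) {
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) {
    return(list(total = 0, terms = empty_terms()))
  }
  if (n > record_cap) {
    stop("user has ", n, " records, above the enumeration cap of ", record_cap,
         "; raise `record_cap` explicitly to value this user")
  }
  mult <- if (config$relationship_regularization) 1 + cohort_lambda else 1

  kinds <- character(); ids <- character(); vals <- numeric()
  for (i in seq_len(n)) {
    v <- single_record_cost(records[i, ], user, config, valuation_time) * mult
    kinds <- c(kinds, "single"); ids <- c(ids, records$record_id[i])
    vals <- c(vals, v)
  }

  # subsets matching a synergy entry, up to the combination order
  for (key in names(config$synergy_table)) {
    key_types <- strsplit(key, "+", fixed = TRUE)[[1L]]
    if (length(key_types) > config$max_combination_order) next
    for (subset_idx in match_type_multiset(records$type, key_types)) {
      sub <- records[subset_idx, ]
      v <- combination_cost(sub, user, config, valuation_time) * mult
      kinds <- c(kinds, "combination")
      ids <- c(ids, paste(sort(sub$record_id), collapse = ";"))
      vals <- c(vals, v)
    }
  }
  terms <- data.frame(kind = kinds, record_ids = ids, value = vals,
                      stringsAsFactors = FALSE)
  list(total = sum(vals), terms = terms)
}

empty_terms <- function() {
  data.frame(kind = character(), record_ids = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

# all index subsets of `types` whose multiset equals key_types
match_type_multiset <- function(types, key_types) {
  need <- table(key_types)
  per_type_choices <- vector("list", length(need))
  for (i in seq_along(need)) {
    tp <- names(need)[i]
    idx <- which(types == tp)
    if (length(idx) < need[[i]]) return(list())
    per_type_choices[[i]] <- if (length(idx) == 1L) {
      list(idx) # combn(n, m) would expand a scalar to seq_len(n)
    } else {
      utils::combn(idx, need[[i]], simplify = FALSE)
    }
  }
  out <- list(integer(0))
  for (choices in per_type_choices) {
    out <- unlist(lapply(out, function(base) {
      lapply(choices, function(ch) c(base, ch))
    }), recursive = FALSE)
  }
  out
}

# ---- group value --------------------------------------------------------

#' Group value of same-type records across users
#'
#' `gamma(K) * mean(best qualities)` where `K` is the number of distinct
#' users and `gamma(K) = C K ln K` (default) or `C K^(3/2)` — both
#' superlinear, so pooling data from more users is worth more than
#' proportionally. The default form yields zero for a lone user.
#'
#' @param type Record-type key (must be registered).
#' @param best_quality_per_user One quality per distinct user: that user's
#'   best quality for `type`.
#' @param config An `lp_config`.
#' @return Nonnegative scalar.
#' @export
group_cost <- function(type, best_quality_per_user, config) {
  resolve_type(type, config)
  K <- length(best_quality_per_user)
  if (K == 0L) stop("group_cost: empty quality list")
  g <- group_gamma(K, config)
  g * mean(best_quality_per_user)
}

group_gamma <- function(K, config) {
  C <- config$group_growth$C
  switch(config$group_growth$form,
    k_log_k = C * K * log(K),
    k_pow_3_2 = C * K^1.5
  )
}

# ---- dataset cost -------------------------------------------------------

#' Total cost of a dataset
#'
#' Sum of the per-user combination costs and, for every record type held by
#' two or more distinct users (with positive best quality), a superlinear
#' group term. Group terms are attributed to users proportionally to their
#' best quality for the type; zero-quality records are ignored throughout,
#' so adding one never changes the total.
#'
#' @param dataset An `lp_dataset`.
#' @param users An `lp_users` table resolving every `owner_id`.
#' @param lambda_per_user Named numeric of relationship-regularization
#'   lambdas per user (missing users default to 0); see [cohort_lambda()].
#' @param config An `lp_config`.
#' @param valuation_time Valuation age in years, or `NULL` to apply the
#'   config's `valuation_time_policy` (`"latest_sample"`).
#' @param record_cap Per-user enumeration guard, passed to [user_cost()].
#' @return An object of class `lp_valuation`: `total_cost`,
#'   `per_user_terms` (named numeric), `per_term_breakdown` (data frame with
#'   `user_id`, `kind`, `record_ids`, `value`), `valuation_time`.
#' @export
dataset_cost <- function(dataset, users, lambda_per_user = NULL, config,
                         valuation_time = NULL, record_cap = 20L) {
  dataset <- lp_dataset(dataset)
  if (is.null(valuation_time)) {
    if (config$valuation_time_policy == "latest_sample" && nrow(dataset) > 0L) {
      valuation_time <- max(dataset$time)
    } else if (nrow(dataset) > 0L) {
      stop("valuation_time must be given under the 'explicit' time policy")
    } else {
      valuation_time <- 0
    }
  }
  unresolved <- setdiff(unique(dataset$owner_id), users$user_id)
  if (length(unresolved)) {
    stop("owner_id not resolvable to a user profile: ",
         paste(unresolved, collapse = ", "))
  }

  breakdown <- data.frame(user_id = character(), kind = character(),
                          record_ids = character(), value = numeric(),
                          stringsAsFactors = FALSE)
  for (uid in unique(dataset$owner_id)) {
    urow <- users[users$user_id == uid, , drop = FALSE]
    lam <- if (!is.null(lambda_per_user) && uid %in% names(lambda_per_user)) {
      lambda_per_user[[uid]]
    } else 0
    uc <- user_cost(urow, dataset[dataset$owner_id == uid, ], config,
                    valuation_time, cohort_lambda = lam,
                    record_cap = record_cap)
    if (nrow(uc$terms)) {
      breakdown <- rbind(breakdown, cbind(user_id = uid, uc$terms))
    }
  }

  # group terms: one per type held (with positive best quality) by >= 2 users
  for (tp in unique(dataset$type)) {
    sub <- dataset[dataset$type == tp & dataset$quality > 0, ]
    if (nrow(sub) == 0L) next
    best <- tapply(sub$quality, sub$owner_id, max)
    if (length(best) < 2L) next
    total <- group_cost(tp, as.numeric(best), config)
    shares <- as.numeric(best) / sum(best)
    for (i in seq_along(best)) {
      uid <- names(best)[i]
      rid <- sub$record_id[sub$owner_id == uid][
        which.max(sub$quality[sub$owner_id == uid])]
      breakdown <- rbind(breakdown, data.frame(
        user_id = uid, kind = "group", record_ids = rid,
        value = total * shares[i], stringsAsFactors = FALSE
      ))
    }
  }

  per_user <- if (nrow(breakdown)) {
    tapply(breakdown$value, breakdown$user_id, sum)
  } else numeric(0)
  structure(
    list(
      total_cost = sum(breakdown$value),
      per_user_terms = stats::setNames(as.numeric(per_user), names(per_user)),
      per_term_breakdown = breakdown,
      valuation_time = valuation_time
    ),
    class = "lp_valuation"
  )
}

#' @export
print.lp_valuation <- function(x, ...) {
  cat("Dataset valuation at age", x$valuation_time, "\n")
  cat("  total cost:", format(x$total_cost), "LifePounds\n")
  cat("  users:", length(x$per_user_terms), " terms:",
      nrow(x$per_term_breakdown), "\n")
  invisible(x)
}

#' Marginal cost of buying records given a purchase history
#'
#' `Cost(dataset U already_bought) - Cost(already_bought)`: the customer pays
#' only for what is new. Nonnegative because the dataset cost is monotone
#' under adding records. The returned object's `per_user_terms` is the
#' per-user difference, i.e. exactly the newly paid amounts, suitable for
#' [attribute_payments()].
#'
#' @param dataset Records to buy (`lp_dataset`).
#' @param already_bought Records previously bought by this customer.
#' @inheritParams dataset_cost
#' @return An `lp_valuation` whose `total_cost` is the marginal price.
#' @export
marginal_cost <- function(dataset, already_bought, users,
                          lambda_per_user = NULL, config,
                          valuation_time = NULL, record_cap = 20L) {
  dataset <- lp_dataset(dataset)
  already_bought <- lp_dataset(already_bought)
  common <- intersect(dataset$record_id, already_bought$record_id)
  if (length(common)) {
    a <- dataset[match(common, dataset$record_id), ]
    b <- already_bought[match(common, already_bought$record_id), ]
    rownames(a) <- rownames(b) <- NULL
    if (!isTRUE(all.equal(as.data.frame(a), as.data.frame(b)))) {
      stop("overlapping record_ids with conflicting field values")
    }
  }
  union_ds <- lp_dataset(rbind(
    already_bought,
    dataset[!dataset$record_id %in% already_bought$record_id, ]
  ))
  full <- dataset_cost(union_ds, users, lambda_per_user, config,
                       valuation_time, record_cap)
  prev <- dataset_cost(already_bought, users, lambda_per_user, config,
                       full$valuation_time, record_cap)
  diff_total <- full$total_cost - prev$total_cost
  if (diff_total < -1e-9) {
    stop("internal error: dataset cost decreased when adding records")
  }
  diff_total <- max(diff_total, 0)
  uids <- union(names(full$per_user_terms), names(prev$per_user_terms))
  per_user <- vapply(uids, function(u) {
    (full$per_user_terms[u] %|na|% 0) - (prev$per_user_terms[u] %|na|% 0)
  }, numeric(1))
  per_user <- pmax(per_user, 0)
  structure(
    list(
      total_cost = diff_total,
      per_user_terms = stats::setNames(as.numeric(per_user), uids),
      per_term_breakdown = full$per_term_breakdown,
      valuation_time = full$valuation_time
    ),
    class = "lp_valuation"
  )
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Split a payment among data submitters and validators
#'
#' The data-validator share `dv_share` (a blockchain-wide parameter) is taken
#' off the top; the remainder is split among submitters proportionally to
#' their newly paid per-user terms. Payouts sum to `amount_paid` exactly: the
#' floating-point residual is assigned deterministically to the largest
#' share.
#'
#' @param result An `lp_valuation` (typically from [marginal_cost()]) whose
#'   `per_user_terms` are the newly paid amounts.
#' @param amount_paid Nonnegative payment in LifePounds.
#' @param dv_share Fraction in `[0, 1)` allocated to the data validator(s).
#' @param dv_weights Optional named nonnegative weights splitting the DV
#'   share among several validator accounts; default a single account
#'   `"dv"`.
#' @return Named numeric: payout per account, summing to `amount_paid`.
#' @export
attribute_payments <- function(result, amount_paid, dv_share = 0,
                               dv_weights = NULL) {
  stopifnot(amount_paid >= 0, dv_share >= 0, dv_share < 1)
  if (amount_paid == 0) return(stats::setNames(numeric(0), character(0)))
  w <- result$per_user_terms
  w <- w[w > 0]
  if (length(w) == 0L || sum(w) <= 0) {
    stop("cannot attribute a positive payment against a zero-value result")
  }
  dv_amount <- dv_share * amount_paid
  dv_pay <- numeric(0)
  if (dv_amount > 0) {
    if (is.null(dv_weights)) dv_weights <- c(dv = 1)
    dv_weights <- dv_weights[dv_weights > 0]
    dv_pay <- dv_amount * dv_weights / sum(dv_weights)
  }
  rem <- amount_paid - sum(dv_pay)
  user_pay <- rem * w / sum(w)
  # fold the float residual into the largest submitter share until the
  # payout vector re-sums to the payment bit-exactly (summation is not
  # associative, so a single correction can leave a one-ulp residual)
  imax <- which.max(user_pay)
  for (iter in 1:64) {
    resid <- amount_paid - sum(c(user_pay, dv_pay))
    if (resid == 0) break
    user_pay[imax] <- user_pay[imax] + resid
  }
  c(user_pay, dv_pay)
}
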