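# ---- payload "encryption" stand-in --------------------------------------
#
# A keyed reversible byte transform over the mock storage. The simulator's
# security claims concern protocol logic (threshold sharing, escrow, audit),
# not cipher strength; real symmetric encryption is a pluggable interface.

keystream <- function(key, n) {
  x <- key
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * (x %% 2^22) + 12345) %% 2^31
    out[i] <- x %% 256L
  }
  out
}

#' Keyed reversible transform standing in for symmetric encryption
#'
#' XORs the payload bytes with a keystream derived from the key; applying it
#' twice with the same key restores the input.
#'
#' @param payload Character scalar (UTF-8).
#' @param key Integer key (a Shamir field element).
#' @return Integer vector of transformed bytes.
#' @export
encrypt_payload <- function(payload, key) {
  bytes <- as.integer(charToRaw(enc2utf8(payload)))
  bitwXor(bytes, keystream(key, length(bytes)))
}

#' @rdname encrypt_payload
#' @param ciphertext Integer vector from [encrypt_payload()].
#' @return The original payload string.
#' @export
decrypt_payload <- function(ciphertext, key) {
  bytes <- bitwXor(as.integer(ciphertext), keystream(key, length(ciphertext)))
  rawToChar(as.raw(bytes))
}

# ---- marketplace state --------------------------------------------------

#' Initialize a marketplace simulation
#'
#' Sets up the actor registry, the initial LifePound allocation (committed
#' in the genesis block — the only point where supply is created apart from
#' optional upload minting), the key-keeper set, and an empty catalog.
#'
#' @param config An `lp_config`; its `marketplace` entry supplies dv_share,
#'   validation timeout, minting policy and the Shamir scheme dimensions.
#' @param actors Data frame with columns `actor_id`, `role`
#'   (`user`/`data_validator`/`customer`/`auditor`) and `balance` (initial
#'   LifePounds, >= 0).
#' @param users Optional `lp_users` table for valuation (defaults to
#'   modifier-1 profiles for every actor with role `user`).
#' @param ped Optional `lp_pedigree`; when given, each user's
#'   relationship-regularization lambda is computed against all other
#'   enrolled users.
#' @return A mutable environment of class `lp_market`.
#' @export
market_init <- function(config, actors, users = NULL, ped = NULL) {
  stopifnot(inherits(config, "lp_config"))
  stopifnot(all(c("actor_id", "role", "balance") %in% names(actors)))
  if (any(actors$balance < 0)) stop("initial balances must be >= 0")
  if (any(duplicated(actors$actor_id))) stop("duplicate actor_id")
  bad_role <- setdiff(actors$role, c("user", "data_validator", "customer",
                                     "auditor", "key_keeper"))
  if (length(bad_role)) stop("unknown role(s): ", paste(bad_role, collapse = ", "))

  st <- new.env(parent = emptyenv())
  st$config <- config
  st$scheme <- shamir_scheme(config$marketplace$n_keepers,
                             config$marketplace$threshold)
  keepers <- paste0("keeper", seq_len(st$scheme$n_keepers))
  st$actors <- rbind(
    actors[c("actor_id", "role", "balance")],
    data.frame(actor_id = keepers, role = "key_keeper", balance = 0,
               stringsAsFactors = FALSE)
  )
  st$keepers <- keepers
  st$keeper_outage <- character(0)
  st$balances <- stats::setNames(as.numeric(st$actors$balance),
                                 st$actors$actor_id)
  st$balances <- st$balances[st$balances != 0] # genesis commits nonzero accounts
  uid <- actors$actor_id[actors$role == "user"]
  st$users <- if (is.null(users)) {
    lp_users(user_id = uid, current_age = NA_real_, base_value_modifier = 1)
  } else users
  st$ped <- ped
  st$lambda <- if (!is.null(ped)) {
    stats::setNames(vapply(uid, function(u) {
      if (u %in% ped$ind$id) cohort_lambda(ped, u, uid) else 0
    }, numeric(1)), uid)
  } else stats::setNames(rep(0, length(uid)), uid)

  st$catalog <- data.frame(
    record_id = character(), owner_id = character(), type = character(),
    time = numeric(), quality = numeric(), status = character(),
    validator = character(), stringsAsFactors = FALSE
  )
  st$storage <- list()
  st$key_shares <- list()
  st$keys <- list() # plaintext keys retained for the decryption stand-in
  st$escrows <- list()
  st$purchases <- list()
  st$time <- 0L
  st$minted <- 0
  st$initial_supply <- sum(st$balances)
  st$chain <- chain_init(st$balances, timestamp = 0)
  st$events <- list()
  class(st) <- "lp_market"
  st
}

#' @export
print.lp_market <- function(x, ...) {
  cat("Marketplace at tick", x$time, "-", nrow(x$actors), "actors,",
      nrow(x$catalog), "records (",
      sum(x$catalog$status == "listed"), "listed ),",
      length(x$chain$blocks), "blocks\n")
  invisible(x)
}

log_event <- function(st, kind, ...) {
  st$events[[length(st$events) + 1L]] <- c(list(tick = st$time, event = kind),
                                           list(...))
  invisible(st)
}

commit_block <- function(st, txs) {
  st$time <- st$time + 1L
  st$balances <- apply_tx_deltas(st$balances, txs)
  if (any(st$balances < -1e-9)) stop("internal error: negative balance")
  st$chain <- append_block(st$chain, txs, st$balances, timestamp = st$time)
  invisible(st)
}

actor_role <- function(st, id) {
  r <- st$actors$role[st$actors$actor_id == id]
  if (length(r) == 0L) stop("unregistered actor: ", id)
  r
}

balance_of <- function(st, id) {
  if (id %in% names(st$balances)) st$balances[[id]] else 0
}

catalog_records <- function(st, ids) {
  idx <- match(ids, st$catalog$record_id)
  if (anyNA(idx)) stop("unknown record id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  st$catalog[idx, ]
}

market_valuation_time <- function(st, records) {
  if (nrow(records) == 0L) return(0)
  max(records$time)
}

# attribute a valuation's terms to individual records: each term's value is
# split equally among its member records (group terms already come one row
# per contributing record)
per_record_values <- function(valuation, record_ids) {
  vals <- stats::setNames(rep(0, length(record_ids)), record_ids)
  bd <- valuation$per_term_breakdown
  for (i in seq_len(nrow(bd))) {
    ids <- strsplit(bd$record_ids[i], ";", fixed = TRUE)[[1L]]
    ids <- ids[ids %in% record_ids]
    if (!length(ids)) next
    vals[ids] <- vals[ids] + bd$value[i] / length(strsplit(
      bd$record_ids[i], ";", fixed = TRUE)[[1L]])
  }
  vals
}

# ---- upload workflow ----------------------------------------------------

#' User uploads a record to the marketplace
#'
#' Encrypts the payload stand-in into the mock storage, splits the key among
#' all N key keepers, and appends an upload transaction carrying only
#' digests and ids (the record's sampling age and quality never reach the
#' chain). The record enters the catalog as unvalidated. With
#' `mint_on_upload` enabled the uploader is credited the mint amount.
#'
#' @param st An `lp_market`.
#' @param user Uploading user's actor id.
#' @param record One-row record (from [biomedical_record()] or a dataset row).
#' @param payload Character payload stand-in (the opaque data content).
#' @return The upload transaction, invisibly; a rejected upload errors.
#' @export
submit_upload <- function(st, user, record, payload = "") {
  record <- as.data.frame(record)
  if (actor_role(st, user) != "user") stop("actor ", user, " is not a user")
  if (record$record_id %in% st$catalog$record_id) {
    stop("duplicate record_id rejected: ", record$record_id)
  }
  resolve_type(record$type[1L], st$config) # unregistered type -> rejected
  key <- floor(stats::runif(1, 0, st$scheme$prime))
  shares <- split_secret(key, st$scheme)
  ct <- encrypt_payload(payload, key)
  payload_hash <- sha256_hex(payload)
  st$storage[[record$record_id]] <- ct
  st$keys[[record$record_id]] <- key
  st$key_shares[[record$record_id]] <- stats::setNames(shares, st$keepers)

  deltas <- NULL
  if (st$config$marketplace$mint_on_upload) {
    deltas <- stats::setNames(list(st$config$marketplace$mint_amount), user)
    st$minted <- st$minted + st$config$marketplace$mint_amount
  }
  tx <- make_transaction("upload", c(list(
    record_id = record$record_id,
    owner_pub = sha256_hex(paste0("pubkey:", user)),
    data_type = record$type[1L],
    storage_link = sha256_hex(paste(ct, collapse = ",")),
    payload_hash = payload_hash
  ), if (!is.null(deltas)) list(deltas = deltas)), originator = user)

  st$catalog <- rbind(st$catalog, data.frame(
    record_id = record$record_id, owner_id = record$owner_id,
    type = record$type, time = record$time, quality = record$quality,
    status = "unvalidated", validator = NA_character_,
    stringsAsFactors = FALSE
  ))
  commit_block(st, list(tx))
  log_event(st, "upload", user = user, record_id = record$record_id)
  invisible(tx)
}

# ---- validation workflow ------------------------------------------------

#' Data validator opens a validation escrow on a batch
#'
#' The DV buys the batch for validation: the batch's price under the
#' valuation model is locked from the DV's balance into an escrow account.
#' Key keepers then deliver their shares; with at least K of N delivered the
#' DV decrypts the payload stand-ins, otherwise decryption stays blocked and
#' the contract can only run to timeout. An underfunded DV gets no contract
#' (the workflow returns to batch selection).
#'
#' @param st An `lp_market`.
#' @param dv Data-validator actor id.
#' @param batch_ids Record ids, all currently unvalidated.
#' @return The escrow contract (list), or `NULL` when the DV cannot fund it.
#' @export
start_validation <- function(st, dv, batch_ids) {
  if (actor_role(st, dv) != "data_validator") {
    stop("actor ", dv, " is not a data validator")
  }
  recs <- catalog_records(st, batch_ids)
  if (any(recs$status != "unvalidated")) {
    stop("batch contains non-unvalidated record(s): ",
         paste(recs$record_id[recs$status != "unvalidated"], collapse = ", "))
  }
  vt <- market_valuation_time(st, recs)
  val <- dataset_cost(lp_dataset(recs[names(recs) %in%
                                        c("record_id", "owner_id", "type",
                                          "time", "quality")]),
                      st$users, st$lambda, st$config, valuation_time = vt,
                      record_cap = 100L)
  price <- val$total_cost
  if (balance_of(st, dv) < price) {
    log_event(st, "validation_rejected", dv = dv, reason = "insufficient balance",
              price = price)
    return(invisible(NULL))
  }
  contract_id <- sha256_hex(paste0("escrow:", dv, ":", st$time, ":",
                                   paste(sort(batch_ids), collapse = ",")))
  escrow_acct <- paste0("escrow:", substr(contract_id, 1, 16))

  deltas <- NULL
  if (price > 0) {
    deltas <- stats::setNames(list(-price, price), c(dv, escrow_acct))
  }
  tx <- make_transaction("validate", c(list(
    action = "open", contract_id = contract_id,
    batch = as.list(sort(batch_ids))
  ), if (!is.null(deltas)) list(deltas = deltas)), originator = dv)

  available <- setdiff(st$keepers, st$keeper_outage)
  delivered <- lapply(batch_ids, function(rid) {
    st$key_shares[[rid]][available]
  })
  can_decrypt <- length(available) >= st$scheme$threshold
  plaintexts <- NULL
  if (can_decrypt) {
    plaintexts <- lapply(seq_along(batch_ids), function(i) {
      key <- reconstruct_secret(delivered[[i]])
      decrypt_payload(st$storage[[batch_ids[i]]], key)
    })
    names(plaintexts) <- batch_ids
  }

  contract <- list(
    contract_id = contract_id, escrow_acct = escrow_acct, dv_id = dv,
    batch = batch_ids, locked_amount = price,
    per_record_value = per_record_values(val, batch_ids),
    deadline = st$time + st$config$marketplace$validation_timeout,
    status = "open", decrypted = can_decrypt, plaintexts = plaintexts
  )
  st$escrows[[contract_id]] <- contract
  commit_block(st, list(tx))
  log_event(st, "validation_opened", dv = dv, contract_id = contract_id,
            price = price, decrypted = can_decrypt)
  invisible(contract)
}

#' Settle a validation escrow
#'
#' With a verdict vector: each valid record's escrow portion is paid to its
#' submitter and the record is listed for sale with the DV recorded as
#' revenue-share beneficiary; each invalid record's portion is refunded to
#' the DV and the record is not listed. Without a verdict (`timeout = TRUE`)
#' the contract defaults to deeming the whole batch valid. The locked amount
#' is fully accounted: disbursed plus refunded equals locked, exactly.
#'
#' @param st An `lp_market`.
#' @param contract_id Open contract id.
#' @param verdicts Logical vector, one per batch record, or `NULL` with
#'   `timeout = TRUE`.
#' @param timeout Settle by timeout (all records deemed valid).
#' @return The settled contract, invisibly.
#' @export
finish_validation <- function(st, contract_id, verdicts = NULL,
                              timeout = FALSE) {
  contract <- st$escrows[[contract_id]]
  if (is.null(contract)) stop("unknown contract: ", contract_id)
  if (contract$status != "open") stop("contract is not open: ", contract_id)
  if (timeout || is.null(verdicts)) {
    verdicts <- rep(TRUE, length(contract$batch))
    terminal <- "timed_out"
  } else {
    if (length(verdicts) != length(contract$batch)) {
      stop("verdict vector length (", length(verdicts),
           ") does not match batch size (", length(contract$batch), ")")
    }
    terminal <- if (any(verdicts)) "settled_valid" else "settled_invalid"
  }

  portions <- contract$per_record_value
  disbursed <- stats::setNames(numeric(0), character(0))
  for (i in seq_along(contract$batch)) {
    rid <- contract$batch[i]
    row <- which(st$catalog$record_id == rid)
    if (verdicts[i]) {
      owner <- st$catalog$owner_id[row]
      disbursed[owner] <- (disbursed[owner] %|na|% 0) + portions[[rid]]
      st$catalog$status[row] <- "listed"
      st$catalog$validator[row] <- contract$dv_id
    } else {
      st$catalog$status[row] <- "invalid"
    }
  }
  refund <- contract$locked_amount - sum(disbursed)
  deltas <- numeric(0)
  if (contract$locked_amount > 0) {
    deltas[contract$escrow_acct] <- -contract$locked_amount
    for (acct in names(disbursed)) {
      if (disbursed[[acct]] != 0) {
        deltas[acct] <- (deltas[acct] %|na|% 0) + disbursed[[acct]]
      }
    }
    if (refund != 0) {
      deltas[contract$dv_id] <- (deltas[contract$dv_id] %|na|% 0) + refund
    }
  }
  tx <- make_transaction("validate", c(list(
    action = "settle", contract_id = contract_id,
    verdicts = as.list(verdicts), terminal = terminal
  ), if (length(deltas)) list(deltas = as.list(deltas))),
  originator = contract$dv_id)

  contract$status <- terminal
  contract$disbursed <- sum(disbursed)
  contract$refunded <- refund
  st$escrows[[contract_id]] <- contract
  commit_block(st, list(tx))
  log_event(st, "validation_settled", contract_id = contract_id,
            terminal = terminal, disbursed = sum(disbursed), refunded = refund)
  invisible(contract)
}

# ---- purchase workflow --------------------------------------------------

#' Customer buys a batch of validated records
#'
#' The price is the marginal cost given the customer's purchase history, so
#' re-buying already-owned records costs nothing. The DV share of the
#' payment goes to the validators of the batch (proportionally to the value
#' of the records each validated); the remainder is distributed to the
#' submitters via [attribute_payments()]. An underfunded customer causes no
#' state change. Key keepers release the batch's shares to the customer.
#'
#' @param st An `lp_market`.
#' @param customer Customer actor id.
#' @param batch_ids Record ids; all must be listed for sale.
#' @return A settlement list (`price`, `payouts`), or `NULL` when the
#'   customer cannot fund the purchase.
#' @export
purchase <- function(st, customer, batch_ids) {
  if (actor_role(st, customer) != "customer") {
    stop("actor ", customer, " is not a customer")
  }
  recs <- catalog_records(st, batch_ids)
  if (any(recs$status != "listed")) {
    stop("batch contains unlisted record(s): ",
         paste(recs$record_id[recs$status != "listed"], collapse = ", "))
  }
  history_ids <- st$purchases[[customer]] %||% character(0)
  hist <- if (length(history_ids)) catalog_records(st, history_ids) else NULL
  to_ds <- function(x) {
    if (is.null(x) || nrow(x) == 0L) return(lp_dataset(NULL))
    lp_dataset(x[c("record_id", "owner_id", "type", "time", "quality")])
  }
  vt <- market_valuation_time(st, rbind(recs, hist))
  mc <- marginal_cost(to_ds(recs), to_ds(hist), st$users, st$lambda,
                      st$config, valuation_time = vt, record_cap = 100L)
  price <- mc$total_cost
  if (balance_of(st, customer) < price) {
    log_event(st, "purchase_rejected", customer = customer,
              reason = "insufficient balance", price = price)
    return(invisible(NULL))
  }

  payouts <- numeric(0)
  if (price > 0) {
    dv_share <- st$config$marketplace$dv_share
    dv_weights <- NULL
    if (dv_share > 0) {
      vals <- per_record_values(mc, batch_ids)
      w <- tapply(vals[recs$record_id], recs$validator, sum)
      w <- w[w > 0]
      if (length(w) == 0L) {
        w <- table(recs$validator) # equal weights fallback
      }
      dv_weights <- stats::setNames(as.numeric(w), names(w))
    }
    payouts <- attribute_payments(mc, price, dv_share, dv_weights)
  }
  deltas <- numeric(0)
  if (price > 0) {
    deltas[customer] <- -price
    for (acct in names(payouts)) {
      deltas[acct] <- (deltas[acct] %|na|% 0) + payouts[[acct]]
    }
  }
  tx <- make_transaction("purchase", c(list(
    customer_pub = sha256_hex(paste0("pubkey:", customer)),
    batch = as.list(sort(batch_ids))
  ), if (length(deltas)) list(deltas = as.list(deltas))),
  originator = customer)

  st$purchases[[customer]] <- union(history_ids, batch_ids)
  commit_block(st, list(tx))
  log_event(st, "purchase", customer = customer, price = price,
            n_records = length(batch_ids))
  invisible(list(price = price, payouts = payouts))
}

# ---- scenario runner ----------------------------------------------------

#' Run a complete marketplace scenario
#'
#' Composes the three client workflows deterministically from a seed:
#' every record of the input dataset is uploaded by its owner, validators
#' process the catalog in batches (a configurable fraction of records draw
#' an invalid verdict and a fraction of contracts run to timeout), and
#' customers then buy random batches of the listed records. Every state
#' transition is a ledger transaction, so the report's chain fully replays.
#'
#' @param scenario List (or YAML path) with fields: `seed`, `config` (an
#'   `lp_config` or path), `records` (an `lp_dataset` or path), optional
#'   `ped`/`mz` paths or `lp_pedigree`, `n_validators`, `n_customers`,
#'   `validator_balance`, `customer_balance`, `batch_size`,
#'   `invalid_fraction`, `timeout_fraction`, `n_purchases`,
#'   `purchase_batch_size`.
#' @return A list of class `lp_scenario_report`: `events`, `final_balances`,
#'   `chain`, `supply` (initial, minted, final), `market`.
#' @export
run_scenario <- function(scenario) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  seed <- scenario$seed %||% 1L
  set.seed(seed)
  config <- scenario$config
  if (is.character(config)) config <- load_valuation_config(config)
  records <- scenario$records
  if (is.character(records)) records <- read_records(records)
  ped <- scenario$ped
  if (is.character(ped)) ped <- read_ped(ped, mz_path = scenario$mz)

  owners <- unique(records$owner_id)
  nv <- scenario$n_validators %||% 2L
  nc <- scenario$n_customers %||% 2L
  actors <- data.frame(
    actor_id = c(owners, paste0("dv", seq_len(nv)), paste0("cust", seq_len(nc))),
    role = c(rep("user", length(owners)), rep("data_validator", nv),
             rep("customer", nc)),
    balance = c(rep(0, length(owners)),
                rep(scenario$validator_balance %||% 500, nv),
                rep(scenario$customer_balance %||% 1000, nc)),
    stringsAsFactors = FALSE
  )
  users <- scenario$users
  if (!is.null(users) && !inherits(users, "lp_users")) users <- NULL
  st <- market_init(config, actors, users = users, ped = ped)

  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    submit_upload(st, rec$owner_id, rec,
                  payload = paste0("payload-of-", rec$record_id))
  }

  batch_size <- scenario$batch_size %||% 3L
  invalid_fraction <- scenario$invalid_fraction %||% 0.1
  timeout_fraction <- scenario$timeout_fraction %||% 0.1
  pending <- sample(st$catalog$record_id)
  dv_ids <- paste0("dv", seq_len(nv))
  b <- 0L
  while (length(pending)) {
    take <- utils::head(pending, batch_size)
    pending <- utils::tail(pending, -length(take))
    dv <- dv_ids[(b %% nv) + 1L]; b <- b + 1L
    contract <- start_validation(st, dv, take)
    if (is.null(contract)) next
    if (stats::runif(1) < timeout_fraction) {
      finish_validation(st, contract$contract_id, timeout = TRUE)
    } else {
      verdicts <- stats::runif(length(take)) >= invalid_fraction
      finish_validation(st, contract$contract_id, verdicts)
    }
  }

  listed <- st$catalog$record_id[st$catalog$status == "listed"]
  n_purchases <- scenario$n_purchases %||% 5L
  pb <- scenario$purchase_batch_size %||% 4L
  cust_ids <- paste0("cust", seq_len(nc))
  for (i in seq_len(if (length(listed)) n_purchases else 0L)) {
    cust <- sample(cust_ids, 1L)
    batch <- sample(listed, min(pb, length(listed)))
    purchase(st, cust, batch)
  }

  structure(
    list(
      events = st$events,
      final_balances = st$balances,
      chain = st$chain,
      supply = list(initial = st$initial_supply, minted = st$minted,
                    final = sum(st$balances)),
      market = st
    ),
    class = "lp_scenario_report"
  )
}

#' @export
print.lp_scenario_report <- function(x, ...) {
  cat("Scenario report:", length(x$events), "events,",
      length(x$chain$blocks), "blocks\n")
  cat("  supply: initial", x$supply$initial, "+ minted", x$supply$minted,
      "= final", format(x$supply$final), "\n")
  invisible(x)
}
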