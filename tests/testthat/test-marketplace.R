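test_that("the payload transform is reversible and key-sensitive", {
  set.seed(71)
  for (trial in 1:20) {
    msg <- paste(sample(c(letters, " "), sample(1:40, 1), replace = TRUE),
                 collapse = "")
    key <- floor(runif(1, 0, SHAMIR_PRIME))
    ct <- encrypt_payload(msg, key)
    expect_identical(decrypt_payload(ct, key), msg)
    wrong <- (key + 1) %% SHAMIR_PRIME
    garbled <- tryCatch(decrypt_payload(ct, wrong), error = function(e) NULL)
    expect_false(identical(garbled, msg)) # wrong key never restores the text
  }
})

test_that("uploads list the record off-chain and keep personal data off the ledger", {
  set.seed(73)
  st <- market_fixture()
  rec <- biomedical_record("r1", "u1", "blood_test", time = 30.5, quality = 0.9)
  tx <- submit_upload(st, "u1", rec, payload = "raw-bytes")
  expect_identical(st$catalog$status, "unvalidated")
  expect_identical(length(st$chain$blocks), 2L)
  expect_true(verify_chain(st$chain)$ok)
  # the transaction carries digests and ids only — never age or quality
  flat <- unlist(tx$payload)
  expect_false(any(grepl("30.5", flat, fixed = TRUE)))
  expect_false(any(grepl("0.9", flat, fixed = TRUE)))
  expect_identical(tx$payload$payload_hash, sha256_hex("raw-bytes"))
  # storage holds ciphertext, not the payload
  expect_false(identical(rawToChar(as.raw(st$storage[["r1"]])), "raw-bytes"))
  # K of N reconstructed key decrypts it
  k <- st$scheme$threshold
  key <- reconstruct_secret(st$key_shares[["r1"]][seq_len(k)])
  expect_identical(decrypt_payload(st$storage[["r1"]], key), "raw-bytes")

  expect_error(submit_upload(st, "u1", rec), "duplicate")
  expect_error(submit_upload(st, "dv1", rec), "not a user")
  expect_error(
    submit_upload(st, "u2", biomedical_record("r2", "u2", "nope", 1, 1)),
    "registry"
  )
})

test_that("validation escrow locks the model price and settles exactly", {
  set.seed(79)
  st <- market_fixture()
  submit_upload(st, "u1", biomedical_record("r1", "u1", "blood_test", 30, 1),
                payload = "payload-of-r1")
  submit_upload(st, "u2", biomedical_record("r2", "u2", "blood_test", 30, 1),
                payload = "payload-of-r2")
  price <- 2 + 2 * log(2) # two singles plus the K = 2 group term

  contract <- start_validation(st, "dv1", c("r1", "r2"))
  expect_equal(contract$locked_amount, price)
  expect_equal(balance_of(st, "dv1"), 100 - price)
  expect_equal(balance_of(st, contract$escrow_acct), price)
  expect_true(contract$decrypted)
  expect_identical(contract$plaintexts$r1, "payload-of-r1")
  expect_true(all(st$catalog$status == "unvalidated"))

  # r1 valid, r2 invalid: u1 paid its portion, the rest refunded to the DV
  settled <- finish_validation(st, contract$contract_id, c(TRUE, FALSE))
  expect_identical(settled$status, "settled_valid")
  expect_equal(settled$disbursed + settled$refunded, settled$locked_amount)
  expect_equal(balance_of(st, "u1"), 1 + log(2)) # single + half the group term
  expect_equal(balance_of(st, contract$escrow_acct), 0)
  expect_equal(balance_of(st, "dv1"), 100 - price + settled$refunded)
  expect_identical(st$catalog$status[st$catalog$record_id == "r1"], "listed")
  expect_identical(st$catalog$validator[st$catalog$record_id == "r1"], "dv1")
  expect_identical(st$catalog$status[st$catalog$record_id == "r2"], "invalid")
  expect_true(verify_chain(st$chain)$ok)
  expect_equal(sum(st$balances), 200) # escrow cycles conserve supply

  expect_error(finish_validation(st, contract$contract_id, c(TRUE, FALSE)),
               "not open")
  expect_error(start_validation(st, "u1", "r1"), "not a data validator")
  expect_error(start_validation(st, "dv1", "r1"), "non-unvalidated")
})

test_that("validation by timeout deems the whole batch valid", {
  set.seed(83)
  st <- market_fixture()
  submit_upload(st, "u1", biomedical_record("r1", "u1", "mri", 40, 1))
  contract <- start_validation(st, "dv1", "r1")
  settled <- finish_validation(st, contract$contract_id, timeout = TRUE)
  expect_identical(settled$status, "timed_out")
  expect_equal(settled$refunded, 0)
  expect_identical(st$catalog$status, "listed")
  expect_equal(balance_of(st, "u1"), settled$locked_amount)
})

test_that("an underfunded validator gets no contract and no state change", {
  set.seed(89)
  st <- market_fixture(dv_balance = 0.01)
  submit_upload(st, "u1", biomedical_record("r1", "u1", "mri", 40, 1))
  blocks_before <- length(st$chain$blocks)
  out <- start_validation(st, "dv1", "r1")
  expect_null(out)
  expect_identical(length(st$chain$blocks), blocks_before)
  expect_identical(st$catalog$status, "unvalidated")
  last <- st$events[[length(st$events)]]
  expect_identical(last$event, "validation_rejected")
  expect_identical(last$reason, "insufficient balance")
})

test_that("a keeper outage beyond N - K blocks decryption but not escrow", {
  set.seed(97)
  st <- market_fixture() # N = 4, K = 2
  submit_upload(st, "u1", biomedical_record("r1", "u1", "mri", 40, 1))
  st$keeper_outage <- st$keepers[1:3] # one keeper left < K
  contract <- start_validation(st, "dv1", "r1")
  expect_false(contract$decrypted)
  expect_null(contract$plaintexts)
  expect_gt(balance_of(st, contract$escrow_acct), 0)
  # the contract can still settle by timeout
  settled <- finish_validation(st, contract$contract_id, timeout = TRUE)
  expect_identical(settled$status, "timed_out")
  # with exactly K keepers up, decryption works
  st$keeper_outage <- st$keepers[1:2]
  submit_upload(st, "u2", biomedical_record("r2", "u2", "mri", 40, 1))
  c2 <- start_validation(st, "dv1", "r2")
  expect_true(c2$decrypted)
})

test_that("purchases pay marginal prices and route the validator share", {
  set.seed(101)
  st <- market_fixture()
  submit_upload(st, "u1", biomedical_record("r1", "u1", "blood_test", 30, 1))
  ct <- start_validation(st, "dv1", "r1")
  finish_validation(st, ct$contract_id, TRUE)
  u1_before <- balance_of(st, "u1")
  dv_before <- balance_of(st, "dv1")

  res <- purchase(st, "cust1", "r1")
  expect_equal(res$price, 1) # single blood test, quality 1, at its own age
  # dv_share = 0.1 goes to the validator, the rest to the submitter
  expect_equal(balance_of(st, "dv1"), dv_before + 0.1)
  expect_equal(balance_of(st, "u1"), u1_before + 0.9)
  expect_equal(balance_of(st, "cust1"), 99)

  # re-buying the same record is free and changes no balances
  bal <- st$balances
  res2 <- purchase(st, "cust1", "r1")
  expect_equal(res2$price, 0)
  expect_identical(st$balances, bal)

  expect_error(purchase(st, "u1", "r1"), "not a customer")
  expect_error(purchase(st, "cust1", "zzz"), "unknown record")
  expect_true(verify_chain(st$chain)$ok)
  expect_equal(sum(st$balances), 200)
})

test_that("unlisted and unaffordable purchases leave the market untouched", {
  set.seed(103)
  st <- market_fixture(cust_balance = 0.01)
  submit_upload(st, "u1", biomedical_record("r1", "u1", "mri", 40, 1))
  expect_error(purchase(st, "cust1", "r1"), "unlisted")
  ct <- start_validation(st, "dv1", "r1")
  finish_validation(st, ct$contract_id, TRUE)
  blocks_before <- length(st$chain$blocks)
  expect_null(purchase(st, "cust1", "r1"))
  expect_identical(length(st$chain$blocks), blocks_before)
  expect_identical(st$events[[length(st$events)]]$event, "purchase_rejected")
})

test_that("scenario runs are deterministic, conservative and fully replayable", {
  sc <- gen_scenario(n_users = 6, seed = 3)
  rep1 <- run_scenario(sc)
  rep2 <- run_scenario(sc)
  expect_identical(chain_tip(rep1$chain)$header$hash,
                   chain_tip(rep2$chain)$header$hash)
  expect_identical(rep1$final_balances, rep2$final_balances)

  expect_true(verify_chain(rep1$chain)$ok)
  # escrow cycles and payouts conserve supply up to float accumulation
  expect_equal(rep1$supply$final, rep1$supply$initial + rep1$supply$minted,
               tolerance = 1e-12)
  expect_identical(rep1$supply$minted, 0) # minting disabled by default

  # independent replay of the deltas reproduces the final balances exactly
  state <- rep1$chain$genesis_state
  for (blk in rep1$chain$blocks[-1]) {
    state <- apply_tx_deltas(state, blk$transactions)
  }
  expect_identical(state[order(names(state))],
                   rep1$final_balances[order(names(rep1$final_balances))])

  # the event log shows every workflow stage
  kinds <- vapply(rep1$events, `[[`, character(1), "event")
  expect_true(all(c("upload", "validation_opened", "validation_settled",
                    "purchase") %in% kinds))
  # one block per operation beyond genesis and rejected operations
  rejected <- sum(kinds %in% c("validation_rejected", "purchase_rejected"))
  expect_identical(length(rep1$chain$blocks) - 1L + rejected,
                   length(rep1$events))

  # the chain survives a disk round trip with digests intact
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_chain(rep1$chain, path)
  back <- read_chain(path)
  expect_true(verify_chain(back)$ok)
  expect_identical(chain_tip(back)$header$hash,
                   chain_tip(rep1$chain)$header$hash)
})

test_that("a scenario bundle on disk runs identically to the in-memory one", {
  dir <- withr::local_tempdir()
  sc <- gen_scenario(n_users = 5, seed = 9, out_dir = dir)
  rep_mem <- run_scenario(sc)
  rep_disk <- withr::with_dir(dir, run_scenario("scenario.yaml"))
  expect_identical(chain_tip(rep_disk$chain)$header$hash,
                   chain_tip(rep_mem$chain)$header$hash)
  expect_identical(rep_disk$final_balances, rep_mem$final_balances)
})

test_that("enrolled relatives inflate upload valuations via the pedigree", {
  set.seed(107)
  actors <- data.frame(
    actor_id = c("father", "mother", "child", "dv1"),
    role = c("user", "user", "user", "data_validator"),
    balance = c(0, 0, 0, 1000), stringsAsFactors = FALSE
  )
  cfg <- fixture_config()
  st_rel <- market_init(cfg, actors, ped = trio_ped())
  st_nor <- market_init(cfg, actors)
  expect_identical(unname(st_rel$lambda["child"]), 1) # r = 1/2 to each parent
  expect_identical(unname(st_nor$lambda["child"]), 0)
  for (st in list(st_rel, st_nor)) {
    submit_upload(st, "child", biomedical_record("r1", "child", "mri", 20, 1))
    ct <- start_validation(st, "dv1", "r1")
    finish_validation(st, ct$contract_id, TRUE)
  }
  expect_equal(balance_of(st_rel, "child"), 2 * balance_of(st_nor, "child"))
  expect_gt(balance_of(st_nor, "child"), 0)
})
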