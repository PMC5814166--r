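# ---- canonical serialization and hashing --------------------------------
#
# Deterministic byte encoding: key-sorted maps, length-prefixed strings,
# numbers printed with %.17g (round-trip exact for doubles). Identical R
# values always serialize to identical strings, so hashes are reproducible
# across sessions and platforms.

canonical_serialize <- function(x) {
  if (is.null(x)) return("N:")
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nm != "")) {
      ord <- order(nm, method = "radix")
      parts <- vapply(ord, function(i) {
        key <- nm[i]
        paste0(nchar(key, type = "bytes"), ":", key, "=",
               canonical_serialize(x[[i]]))
      }, character(1))
      return(paste0("M", length(x), "{", paste(parts, collapse = ""), "}"))
    }
    parts <- vapply(x, canonical_serialize, character(1))
    return(paste0("L", length(x), "[", paste(parts, collapse = ""), "]"))
  }
  if (is.character(x)) {
    parts <- vapply(x, function(s) paste0(nchar(s, type = "bytes"), ":", s),
                    character(1), USE.NAMES = FALSE)
    return(paste0("S", length(x), "(", paste(parts, collapse = ""), ")"))
  }
  if (is.logical(x)) {
    return(paste0("B", length(x), "(",
                  paste(ifelse(x, "T", "F"), collapse = ","), ")"))
  }
  if (is.numeric(x)) {
    return(paste0("D", length(x), "(",
                  paste(sprintf("%.17g", x), collapse = ","), ")"))
  }
  stop("cannot canonically serialize object of class ", class(x)[1L])
}

sha256_hex <- function(x) as.character(openssl::sha256(x))

ZERO_DIGEST <- strrep("0", 64L)
EMPTY_TREE_ROOT_SEED <- "lifepound:empty-tree"

empty_tree_root <- function() sha256_hex(EMPTY_TREE_ROOT_SEED)

# ---- Merkle trees -------------------------------------------------------

# bottom-up pairwise hashing; an odd node at any level is promoted unchanged
merkle_levels <- function(leaf_hashes) {
  levels <- list(leaf_hashes)
  cur <- leaf_hashes
  while (length(cur) > 1L) {
    n <- length(cur)
    pairs <- seq_len(n %/% 2L)
    nxt <- sha256_hex(paste0(cur[2L * pairs - 1L], cur[2L * pairs]))
    if (n %% 2L == 1L) nxt <- c(nxt, cur[n])
    levels[[length(levels) + 1L]] <- nxt
    cur <- nxt
  }
  levels
}

#' Merkle root of a vector of leaf hashes
#'
#' Pairwise SHA-256 over hex digests; an odd last node at any level is
#' promoted unchanged. The empty tree has a fixed constant root.
#'
#' @param leaf_hashes Character vector of hex digests.
#' @return Hex digest of the root.
#' @export
merkle_root <- function(leaf_hashes) {
  if (length(leaf_hashes) == 0L) return(empty_tree_root())
  levels <- merkle_levels(leaf_hashes)
  levels[[length(levels)]]
}

# audit path for leaf `index` (1-based): list of (sibling, side) where side
# is the side the sibling sits on
merkle_path <- function(leaf_hashes, index) {
  stopifnot(index >= 1L, index <= length(leaf_hashes))
  path <- list()
  cur <- leaf_hashes
  pos <- index
  while (length(cur) > 1L) {
    n <- length(cur)
    if (pos %% 2L == 1L) {
      if (pos < n) {
        path[[length(path) + 1L]] <- list(sibling = cur[pos + 1L], side = "R")
      } # else promoted: no sibling at this level
    } else {
      path[[length(path) + 1L]] <- list(sibling = cur[pos - 1L], side = "L")
    }
    # recompute next level
    pairs <- seq_len(n %/% 2L)
    nxt <- sha256_hex(paste0(cur[2L * pairs - 1L], cur[2L * pairs]))
    if (n %% 2L == 1L) nxt <- c(nxt, cur[n])
    pos <- if (pos %% 2L == 1L && pos == n) length(nxt) else (pos + 1L) %/% 2L
    cur <- nxt
  }
  path
}

merkle_path_verify <- function(leaf_hash, path, root) {
  h <- leaf_hash
  for (step in path) {
    h <- if (identical(step$side, "L")) {
      sha256_hex(paste0(step$sibling, h))
    } else {
      sha256_hex(paste0(h, step$sibling))
    }
  }
  identical(h, root)
}

# ---- transactions -------------------------------------------------------

#' Create a ledger transaction
#'
#' The transaction id is the SHA-256 of the canonical serialization of
#' (kind, originator, payload), so any payload mutation changes the id.
#' Payloads must carry only digests, ids and amounts — never raw personal
#' data. Balance-affecting transactions carry a named `deltas` vector inside
#' the payload so the chain state is replayable.
#'
#' @param kind One of `"upload"`, `"validate"`, `"purchase"`, `"transfer"`.
#' @param payload Named list of canonical values.
#' @param originator Actor id of the signer.
#' @return A list of class `lp_tx` with `tx_id`, `kind`, `payload`,
#'   `signature` (a placeholder `(signer, digest)` record).
#' @export
make_transaction <- function(kind, payload, originator) {
  kind <- match.arg(kind, c("upload", "validate", "purchase", "transfer"))
  payload <- normalize_payload(payload)
  body <- canonical_serialize(list(kind = kind, originator = originator,
                                   payload = payload))
  tx_id <- sha256_hex(body)
  structure(
    list(
      tx_id = tx_id, kind = kind, originator = originator, payload = payload,
      signature = list(signer = originator,
                       digest = sha256_hex(paste0(tx_id, "|", originator)))
    ),
    class = "lp_tx"
  )
}

tx_valid <- function(tx) {
  if (!all(c("tx_id", "kind", "originator", "payload") %in% names(tx))) {
    return(FALSE)
  }
  body <- canonical_serialize(list(kind = tx$kind, originator = tx$originator,
                                   payload = normalize_payload(tx$payload)))
  identical(tx$tx_id, sha256_hex(body))
}

# normalize payloads to scalars and (possibly named) lists of scalars, the
# common form shared by in-memory construction and the JSON Lines round trip
normalize_payload <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.list(x)) {
    out <- lapply(x, normalize_payload)
    names(out) <- names(x)
    return(out)
  }
  if (is.atomic(x)) {
    if (length(x) == 1L && is.null(names(x))) return(x[[1L]])
    out <- lapply(seq_along(x), function(i) x[[i]])
    names(out) <- names(x)
    return(out)
  }
  stop("payload fields must be atomic values or lists")
}

tx_leaf_hash <- function(tx_id) sha256_hex(paste0("txleaf:", tx_id))

# ---- state commitment (sorted-leaf Merkle tree) -------------------------

# each leaf commits to (index, n, key, value) so adjacency and boundaries
# are verifiable from the root alone
state_leaf_hashes <- function(state) {
  if (length(state) == 0L) return(character(0))
  keys <- sort(names(state), method = "radix")
  n <- length(keys)
  vapply(seq_len(n), function(i) {
    sha256_hex(canonical_serialize(list(
      index = i, n = n, key = keys[i], value = as.numeric(state[[keys[i]]])
    )))
  }, character(1))
}

#' Merkle commitment to a balance/state map
#'
#' @param state Named numeric vector (e.g. LifePound balances).
#' @return Hex root digest.
#' @export
state_root <- function(state) {
  if (length(state) == 0L) return(empty_tree_root())
  merkle_root(state_leaf_hashes(state))
}

# ---- blocks and chains --------------------------------------------------

block_header_hash <- function(header) {
  sha256_hex(canonical_serialize(header[c("height", "prev_hash", "tx_root",
                                          "state_root", "timestamp")]))
}

new_block <- function(height, prev_hash, transactions, state_after, timestamp) {
  tx_root <- merkle_root(vapply(transactions, function(tx) tx_leaf_hash(tx$tx_id),
                                character(1)))
  header <- list(height = height, prev_hash = prev_hash, tx_root = tx_root,
                 state_root = state_root(state_after), timestamp = timestamp)
  header$hash <- block_header_hash(header)
  list(header = header, transactions = transactions)
}

#' Initialize a hash-linked chain
#'
#' Creates the genesis block (height 0, zero previous digest) committing to
#' the initial balance allocation.
#'
#' @param initial_state Named numeric vector of initial balances.
#' @param timestamp Simulation time of genesis (default 0; digests never use
#'   the wall clock, so chains are reproducible).
#' @return A list of class `lp_chain` with `blocks` and `genesis_state`.
#' @export
chain_init <- function(initial_state = numeric(0), timestamp = 0) {
  genesis <- new_block(0L, ZERO_DIGEST, list(), initial_state, timestamp)
  structure(list(blocks = list(genesis), genesis_state = initial_state),
            class = "lp_chain")
}

chain_tip <- function(chain) chain$blocks[[length(chain$blocks)]]

#' Append a block of transactions to a chain
#'
#' All transactions must be individually valid (self-consistent ids); an
#' invalid transaction rejects the whole batch atomically.
#'
#' @param chain An `lp_chain`.
#' @param transactions List of `lp_tx`.
#' @param state_after Named numeric balances after applying the block.
#' @param timestamp Simulation time; defaults to the new height.
#' @return The extended `lp_chain`.
#' @export
append_block <- function(chain, transactions, state_after, timestamp = NULL) {
  stopifnot(inherits(chain, "lp_chain"))
  ok <- vapply(transactions, tx_valid, logical(1))
  if (length(ok) && !all(ok)) {
    stop("invalid transaction in batch (position ", which(!ok)[1L],
         "); block rejected atomically")
  }
  tip <- chain_tip(chain)
  height <- tip$header$height + 1L
  if (is.null(timestamp)) timestamp <- height
  blk <- new_block(height, tip$header$hash, transactions, state_after, timestamp)
  chain$blocks[[length(chain$blocks) + 1L]] <- blk
  chain
}

apply_tx_deltas <- function(state, transactions) {
  for (tx in transactions) {
    d <- tx$payload$deltas
    if (is.null(d)) next
    d <- unlist(d)
    for (acct in names(d)) {
      cur <- if (acct %in% names(state)) state[[acct]] else 0
      state[[acct]] <- cur + as.numeric(d[[acct]])
    }
  }
  state
}

#' Verify a chain end to end
#'
#' Checks, block by block: header hash integrity, previous-hash links,
#' strict height increments, transaction-root recomputability, transaction
#' id integrity, and state-root recomputability by replaying each block's
#' balance deltas from the genesis allocation. The verdict names the first
#' height at which any check fails.
#'
#' @param chain An `lp_chain`.
#' @return `list(ok = TRUE)` or `list(ok = FALSE, first_bad_height = h,
#'   reason = ...)`.
#' @export
verify_chain <- function(chain) {
  if (!inherits(chain, "lp_chain") || length(chain$blocks) == 0L) {
    return(list(ok = TRUE))
  }
  state <- chain$genesis_state
  prev_hash <- ZERO_DIGEST
  for (i in seq_along(chain$blocks)) {
    blk <- chain$blocks[[i]]
    h <- blk$header
    bad <- function(reason) list(ok = FALSE, first_bad_height = h$height,
                                 reason = reason)
    if (h$height != i - 1L) return(bad("height sequence broken"))
    if (!identical(h$prev_hash, prev_hash)) return(bad("previous-hash link broken"))
    if (!identical(h$hash, block_header_hash(h))) return(bad("header hash mismatch"))
    for (tx in blk$transactions) {
      if (!tx_valid(tx)) return(bad("transaction id does not match payload"))
    }
    tx_root <- merkle_root(vapply(blk$transactions,
                                  function(tx) tx_leaf_hash(tx$tx_id),
                                  character(1)))
    if (!identical(tx_root, h$tx_root)) return(bad("transaction root mismatch"))
    state <- apply_tx_deltas(state, blk$transactions)
    if (h$height == 0L) state <- chain$genesis_state
    if (!identical(state_root(state), h$state_root)) {
      return(bad("state root not reproducible from replayed transactions"))
    }
    prev_hash <- h$hash
  }
  list(ok = TRUE)
}

#' @export
print.lp_chain <- function(x, ...) {
  ntx <- sum(vapply(x$blocks, function(b) length(b$transactions), integer(1)))
  cat("Chain:", length(x$blocks), "blocks (incl. genesis),", ntx,
      "transactions, tip", substr(chain_tip(x)$header$hash, 1, 12), "...\n")
  invisible(x)
}

# ---- inclusion and absence proofs ---------------------------------------

#' Prove that a transaction is included in a block
#'
#' @param block A block from an `lp_chain` (`chain$blocks[[i]]`).
#' @param tx_id Transaction id to prove.
#' @return A list of class `lp_proof` (type `"inclusion"`) carrying the leaf
#'   hash, audit path and root. Proving an absent transaction is an error,
#'   never a bogus proof.
#' @export
prove_inclusion <- function(block, tx_id) {
  ids <- vapply(block$transactions, function(tx) tx$tx_id, character(1))
  idx <- match(tx_id, ids)
  if (is.na(idx)) stop("transaction not found in block: ", tx_id)
  leaves <- vapply(ids, tx_leaf_hash, character(1), USE.NAMES = FALSE)
  structure(
    list(type = "inclusion", leaf_hash = leaves[idx],
         path = merkle_path(leaves, idx), root = block$header$tx_root),
    class = "lp_proof"
  )
}

#' Prove that a key is absent from a committed state
#'
#' Uses the adjacent-leaves technique on the sorted-key state tree: the proof
#' exhibits the two neighboring leaves bracketing the key (or one boundary
#' leaf), each with its own audit path. Since every leaf commits to its index
#' and the leaf count, adjacency and boundaries are verifiable against the
#' root alone.
#'
#' @param state Named numeric state map.
#' @param key Key claimed absent. Proving absence of a present key errors.
#' @return An `lp_proof` of type `"absence"`.
#' @export
prove_absence <- function(state, key) {
  keys <- if (length(state)) sort(names(state), method = "radix") else character(0)
  if (key %in% keys) stop("key is present in state; cannot prove absence: ", key)
  leaves <- state_leaf_hashes(state)
  root <- state_root(state)
  n <- length(keys)
  if (n == 0L) {
    return(structure(list(type = "absence", key = key, n = 0L,
                          neighbors = list(), root = root),
                     class = "lp_proof"))
  }
  lower <- sum(keys < key) # 0 if key sorts before everything
  neighbor <- function(i) {
    list(index = i, n = n, key = keys[i],
         value = as.numeric(state[[keys[i]]]),
         leaf_hash = leaves[i], path = merkle_path(leaves, i))
  }
  neighbors <- list()
  if (lower >= 1L) neighbors$left <- neighbor(lower)
  if (lower < n) neighbors$right <- neighbor(lower + 1L)
  structure(list(type = "absence", key = key, n = n, neighbors = neighbors,
                 root = root),
            class = "lp_proof")
}

#' Verify a Merkle proof against a trusted root
#'
#' Pure verification: needs only the proof object and the root digest, never
#' the ledger. Any single-bit mutation of the proof makes it fail.
#'
#' @param proof An `lp_proof` from [prove_inclusion()] or [prove_absence()].
#' @param root Trusted root digest (hex).
#' @return `TRUE` or `FALSE`.
#' @export
verify_proof <- function(proof, root) {
  if (!identical(proof$root, root)) return(FALSE)
  if (identical(proof$type, "inclusion")) {
    return(merkle_path_verify(proof$leaf_hash, proof$path, root))
  }
  if (!identical(proof$type, "absence")) return(FALSE)
  if (proof$n == 0L) return(identical(root, empty_tree_root()))
  nb <- proof$neighbors
  check_leaf <- function(leaf) {
    expected <- sha256_hex(canonical_serialize(list(
      index = leaf$index, n = leaf$n, key = leaf$key, value = leaf$value
    )))
    identical(expected, leaf$leaf_hash) && leaf$n == proof$n &&
      merkle_path_verify(leaf$leaf_hash, leaf$path, root)
  }
  has_left <- !is.null(nb$left); has_right <- !is.null(nb$right)
  if (!has_left && !has_right) return(FALSE)
  if (has_left) {
    if (!check_leaf(nb$left)) return(FALSE)
    if (!(nb$left$key < proof$key)) return(FALSE)
  }
  if (has_right) {
    if (!check_leaf(nb$right)) return(FALSE)
    if (!(nb$right$key > proof$key)) return(FALSE)
  }
  if (has_left && has_right) {
    if (nb$right$index != nb$left$index + 1L) return(FALSE)
  } else if (!has_left) {
    if (nb$right$index != 1L) return(FALSE) # key sorts before all leaves
  } else {
    if (nb$left$index != proof$n) return(FALSE) # key sorts after all leaves
  }
  TRUE
}

# ---- anchoring ----------------------------------------------------------

#' Anchor the chain tip digest to an external append-only log
#'
#' Writes one JSON line `{height, block_hash, state_root}` for the tip to
#' the given log file (created if missing). A later rewrite or rollback of
#' the chain is detectable by replaying the log with [check_anchors()]. No
#' network activity is involved.
#'
#' @param chain A nonempty `lp_chain`.
#' @param anchor_path Path of the append-only anchor log (JSON Lines).
#' @return The anchor record, invisibly.
#' @export
anchor_digest <- function(chain, anchor_path) {
  stopifnot(inherits(chain, "lp_chain"))
  if (length(chain$blocks) == 0L) stop("cannot anchor an empty chain")
  tip <- chain_tip(chain)
  rec <- list(height = tip$header$height, block_hash = tip$header$hash,
              state_root = tip$header$state_root)
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17))
  cat(line, "\n", sep = "", file = anchor_path, append = TRUE)
  invisible(rec)
}

#' Check a chain against its anchor log
#'
#' Replays the anchor log: every anchored height must still exist on the
#' chain with the identical block hash and state root, and anchored heights
#' must be non-decreasing (a decreasing sequence, or a chain tip below the
#' last anchored height, indicates a rollback).
#'
#' @param chain An `lp_chain`.
#' @param anchor_path Anchor log path.
#' @return `list(ok = TRUE)` or `list(ok = FALSE, reason = ...)`.
#' @export
check_anchors <- function(chain, anchor_path) {
  if (!file.exists(anchor_path)) return(list(ok = TRUE))
  lines <- readLines(anchor_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  last_height <- -1L
  for (line in lines) {
    rec <- jsonlite::fromJSON(line)
    if (rec$height < last_height) {
      return(list(ok = FALSE, reason = "anchor log heights decrease"))
    }
    last_height <- rec$height
    if (rec$height > chain_tip(chain)$header$height) {
      return(list(ok = FALSE,
                  reason = paste0("chain tip rolled back below anchored height ",
                                  rec$height)))
    }
    blk <- chain$blocks[[rec$height + 1L]]
    if (!identical(blk$header$hash, rec$block_hash) ||
        !identical(blk$header$state_root, rec$state_root)) {
      return(list(ok = FALSE,
                  reason = paste0("anchored digest mismatch at height ",
                                  rec$height)))
    }
  }
  list(ok = TRUE)
}

# ---- chain import/export ------------------------------------------------

#' Export a chain as JSON Lines (one block per line)
#'
#' The first line holds the genesis allocation; each following line one
#' block with its transactions. [read_chain()] is the exact inverse.
#'
#' @param chain An `lp_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chain, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(genesis_state = as.list(chain$genesis_state)),
                              auto_unbox = TRUE, digits = I(17)), con)
  for (blk in chain$blocks) {
    blk$transactions <- lapply(blk$transactions, unclass)
    writeLines(jsonlite::toJSON(blk, auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' Import a chain from JSON Lines
#'
#' @param path Path written by [write_chain()].
#' @return An `lp_chain` (verify it with [verify_chain()]).
#' @export
read_chain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  meta <- jsonlite::fromJSON(lines[1L], simplifyVector = FALSE)
  gstate <- unlist(meta$genesis_state)
  if (is.null(gstate)) gstate <- numeric(0)
  blocks <- lapply(lines[-1L], function(line) {
    blk <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    blk$header$height <- as.integer(blk$header$height)
    blk$transactions <- lapply(blk$transactions, function(tx) {
      tx$payload <- normalize_payload(tx$payload)
      structure(tx, class = "lp_tx")
    })
    blk
  })
  structure(list(blocks = blocks, genesis_state = gstate), class = "lp_chain")
}
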