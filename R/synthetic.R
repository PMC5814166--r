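# ---- default study configuration ----------------------------------------

#' Default record-type registry
#'
#' Ships five types. The genome (infinite half-life: valid for the whole
#' life of the patient) and the cholesterol panel (5-year half-life, the
#' Mayo Clinic validity guidance) are literature-sourced; blood test (0.5
#' yr), transcriptome (1 yr) and MRI (2 yr) are documented fixture values
#' chosen to span fast- and slow-decaying dynamic data.
#'
#' @return Named list of [record_type_spec()] objects.
#' @export
default_type_registry <- function() {
  list(
    genome = record_type_spec("genome", base_value = 10, half_life = Inf,
                              static = TRUE, display_name = "Genome"),
    cholesterol_panel = record_type_spec("cholesterol_panel", base_value = 1,
                                         half_life = 5,
                                         display_name = "Cholesterol panel"),
    blood_test = record_type_spec("blood_test", base_value = 1,
                                  half_life = 0.5, display_name = "Blood test"),
    transcriptome = record_type_spec("transcriptome", base_value = 3,
                                     half_life = 1,
                                     display_name = "Transcriptome"),
    mri = record_type_spec("mri", base_value = 5, half_life = 2,
                           display_name = "MRI")
  )
}

#' Default valuation configuration for simulations
#'
#' The [default_type_registry()] plus a small synergy table (blood test with
#' transcriptome, and the genome with either) and default group growth
#' `C K ln K` with `C = 1`.
#'
#' @param ... Overrides passed to [valuation_config()].
#' @return An `lp_config`.
#' @export
default_valuation_config <- function(...) {
  args <- list(...)
  defaults <- list(
    types = default_type_registry(),
    synergy = list(
      list(types = c("blood_test", "transcriptome"), value = 2),
      list(types = c("genome", "blood_test"), value = 1.5),
      list(types = c("genome", "transcriptome"), value = 2.5)
    )
  )
  do.call(valuation_config, utils::modifyList(defaults, args))
}

# ---- pedigree generator -------------------------------------------------

#' Generate a synthetic pedigree
#'
#' Builds `families` independent families of `generations` generations: each
#' founding couple has `sibship` children per generation, children marry
#' unrelated founder spouses, and with probability `mz_prob` the first two
#' siblings of a sibship are monozygotic twins. Fully deterministic under
#' the seed.
#'
#' @param families Number of independent families (>= 1).
#' @param generations Generations per family (>= 1; 1 means founders only).
#' @param sibship Children per couple (>= 1).
#' @param mz_prob Probability that a sibship of >= 2 contains an MZ pair.
#' @param seed Integer seed.
#' @param path Optional path stem; when given, writes `<path>.ped` and (if
#'   any twins) `<path>.mz`.
#' @return An `lp_pedigree`.
#' @export
gen_pedigree <- function(families = 1L, generations = 3L, sibship = 2L,
                         mz_prob = 0, seed = 1L, path = NULL) {
  if (generations < 1L) stop("infeasible structure: generations must be >= 1")
  if (families < 1L) stop("infeasible structure: need at least one family")
  if (sibship < 1L) stop("infeasible structure: sibship must be >= 1")
  set.seed(seed)
  id <- character(); father <- character(); mother <- character()
  sex <- integer(); fid <- character()
  mz <- list()
  add <- function(i, fa, mo, sx, fam) {
    id <<- c(id, i); father <<- c(father, fa); mother <<- c(mother, mo)
    sex <<- c(sex, sx); fid <<- c(fid, fam)
  }
  for (f in seq_len(families)) {
    fam <- paste0("FAM", f)
    couples <- list()
    pa <- paste0(fam, "_g1_m"); ma <- paste0(fam, "_g1_f")
    add(pa, NA, NA, 1L, fam); add(ma, NA, NA, 2L, fam)
    if (generations >= 2L) couples <- list(c(pa, ma))
    for (g in seq_len(generations)[-1]) {
      next_couples <- list()
      for (ci in seq_along(couples)) {
        cp <- couples[[ci]]
        kid_sex <- 1L + stats::rbinom(sibship, 1L, 0.5)
        kids <- paste0(fam, "_g", g, "_c", ci, "_", seq_len(sibship))
        for (s in seq_len(sibship)) add(kids[s], cp[1L], cp[2L], kid_sex[s], fam)
        if (sibship >= 2L && stats::runif(1) < mz_prob) {
          kid_sex[2L] <- kid_sex[1L]
          sex[match(kids[2L], id)] <- kid_sex[1L]
          mz[[length(mz) + 1L]] <- c(kids[1L], kids[2L])
        }
        if (g < generations) {
          for (s in seq_len(sibship)) {
            sp <- paste0(kids[s], "_sp")
            add(sp, NA, NA, ifelse(kid_sex[s] == 1L, 2L, 1L), fam)
            next_couples[[length(next_couples) + 1L]] <- c(kids[s], sp)
          }
        }
      }
      couples <- next_couples
    }
  }
  mz_mat <- if (length(mz)) do.call(rbind, mz) else NULL
  ped <- pedigree(id = id, father = father, mother = mother, sex = sex,
                  fid = fid, mz_pairs = mz_mat)
  if (!is.null(path)) {
    write_ped(ped, paste0(path, ".ped"),
              mz_path = if (nrow(ped$mz)) paste0(path, ".mz"))
  }
  ped
}

# ---- record-stream generator --------------------------------------------

#' Generate a synthetic record stream for a set of users
#'
#' Static types (infinite half-life) are sampled exactly once per user at a
#' uniform random age; dynamic types arrive as a Poisson point process at
#' the configured per-type rate (records/year) over each user's age span.
#' Qualities are uniform on `[q_min, q_max]` with an optional spike at zero
#' (to exercise zero-quality invariance). Deterministic under the seed.
#'
#' @param users An `lp_users` table with `current_age` set.
#' @param config An `lp_config` whose registry defines the types.
#' @param rates Named per-type sampling rates in records/year for dynamic
#'   types (defaults: 1/yr for every dynamic type in the registry).
#' @param q_min,q_max Quality distribution bounds (default 0.5, 1.5).
#' @param zero_prob Probability of replacing a quality by 0 (default 0).
#' @param seed Integer seed.
#' @return An `lp_dataset`.
#' @export
gen_records <- function(users, config, rates = NULL, q_min = 0.5,
                        q_max = 1.5, zero_prob = 0, seed = 1L) {
  if (nrow(users) == 0L) stop("gen_records: users table is empty")
  set.seed(seed)
  registry <- config$type_registry
  dynamic <- names(registry)[!vapply(registry, function(t) t$static, logical(1))]
  static <- setdiff(names(registry), dynamic)
  if (is.null(rates)) rates <- stats::setNames(rep(1, length(dynamic)), dynamic)
  unknown <- setdiff(names(rates), names(registry))
  if (length(unknown)) stop("unknown type key in rates: ",
                            paste(unknown, collapse = ", "))
  if (any(rates < 0)) stop("sampling rates must be >= 0")

  rows <- list()
  n <- 0L
  draw_quality <- function(k) {
    q <- stats::runif(k, q_min, q_max)
    if (zero_prob > 0) q[stats::runif(k) < zero_prob] <- 0
    q
  }
  for (i in seq_len(nrow(users))) {
    uid <- users$user_id[i]
    age <- users$current_age[i]
    if (is.na(age)) stop("user ", uid, " has no current_age")
    for (tp in static) {
      n <- n + 1L
      rows[[n]] <- data.frame(
        record_id = sprintf("%s_%s_1", uid, tp), owner_id = uid, type = tp,
        time = stats::runif(1, 0, age), quality = draw_quality(1L),
        stringsAsFactors = FALSE
      )
    }
    for (tp in intersect(dynamic, names(rates))) {
      k <- stats::rpois(1L, rates[[tp]] * age)
      if (k == 0L) next
      n <- n + 1L
      rows[[n]] <- data.frame(
        record_id = sprintf("%s_%s_%d", uid, tp, seq_len(k)), owner_id = uid,
        type = tp, time = sort(stats::runif(k, 0, age)),
        quality = draw_quality(k), stringsAsFactors = FALSE
      )
    }
  }
  ds <- lp_dataset(do.call(rbind, rows))
  ds[order(ds$record_id), , drop = FALSE] -> ds
  rownames(ds) <- NULL
  lp_dataset(ds)
}

# ---- scenario bundles ---------------------------------------------------

#' Generate a ready-to-run marketplace scenario bundle
#'
#' Produces a pedigree, a user table, a record stream, a valuation config
#' and a scenario description that together exercise upload, validation
#' (with an injected invalid fraction), timeout, and purchase events; when
#' `out_dir` is given, everything is also written to disk in the package's
#' file formats (records CSV, PED + MZ sidecar, config YAML, scenario
#' YAML).
#'
#' @param n_users Target number of users (the pedigree is sized to reach at
#'   least this many individuals; extras are dropped).
#' @param seed Integer seed controlling every random choice.
#' @param invalid_fraction Fraction of records drawing an invalid verdict.
#' @param timeout_fraction Fraction of validation contracts left to time out.
#' @param mz_prob MZ-twin probability per sibship.
#' @param zero_prob Zero-quality spike probability.
#' @param out_dir Optional output directory (created if needed).
#' @return A scenario list runnable by [run_scenario()], with the generated
#'   objects attached (`config`, `records`, `ped`, `users`).
#' @export
gen_scenario <- function(n_users = 10L, seed = 1L, invalid_fraction = 0.1,
                         timeout_fraction = 0.1, mz_prob = 0.2,
                         zero_prob = 0.05, out_dir = NULL) {
  families <- max(1L, ceiling(n_users / 6L))
  ped <- gen_pedigree(families = families, generations = 3L, sibship = 2L,
                      mz_prob = mz_prob, seed = seed)
  set.seed(seed + 1L)
  uid <- utils::head(ped$ind$id, n_users)
  users <- lp_users(user_id = uid,
                    current_age = round(stats::runif(length(uid), 30, 70), 1))
  config <- default_valuation_config()
  records <- gen_records(users, config,
                         rates = c(blood_test = 0.05, transcriptome = 0.02,
                                   cholesterol_panel = 0.03, mri = 0.01),
                         zero_prob = zero_prob, seed = seed + 2L)
  scenario <- list(
    seed = seed, config = config, records = records, ped = ped,
    users = users,
    n_validators = 2L, n_customers = 2L,
    validator_balance = 5000, customer_balance = 10000,
    batch_size = 3L, invalid_fraction = invalid_fraction,
    timeout_fraction = timeout_fraction,
    n_purchases = 5L, purchase_batch_size = 4L
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_records(records, file.path(out_dir, "records.csv"))
    write_ped(ped, file.path(out_dir, "pedigree.ped"),
              mz_path = if (nrow(ped$mz)) file.path(out_dir, "pedigree.mz"))
    write_valuation_config(config, file.path(out_dir, "config.yaml"))
    on_disk <- scenario
    on_disk$config <- "config.yaml"
    on_disk$records <- "records.csv"
    on_disk$ped <- "pedigree.ped"
    on_disk$mz <- if (nrow(ped$mz)) "pedigree.mz" else NULL
    on_disk$users <- NULL
    yaml::write_yaml(on_disk, file.path(out_dir, "scenario.yaml"))
  }
  scenario
}
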