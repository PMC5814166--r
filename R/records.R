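# ---- domain constructors -----------------------------------------------

#' Create a biomedical record
#'
#' A record is the triplet (type, time, quality) with an owner reference:
#' `type` is a categorical record-type key, `time` is the patient's age at
#' sampling in years, and `quality` is a nonnegative dimensionless score.
#'
#' @param record_id Opaque record identifier (unique within a dataset).
#' @param owner_id Identifier of the owning user.
#' @param type Record-type key (must exist in the type registry at valuation
#'   time; not checked at construction so datasets can be inspected without a
#'   config).
#' @param time Patient age at sampling, years; must be `>= 0`.
#' @param quality Nonnegative quality score. Zero-quality records are valid
#'   and carry zero cost.
#' @return A one-row data frame of class `lp_record`.
#' @export
#' @examples
#' biomedical_record("r1", "u1", "blood_test", time = 30, quality = 1)
biomedical_record <- function(record_id, owner_id, type, time, quality) {
  stopifnot(length(record_id) == 1L, length(time) == 1L)
  if (!is.finite(time) || time < 0) {
    stop("record '", record_id, "': time must be a nonnegative, finite age in years")
  }
  if (!is.finite(quality) || quality < 0) {
    stop("record '", record_id, "': quality must be nonnegative and finite")
  }
  out <- data.frame(
    record_id = as.character(record_id),
    owner_id = as.character(owner_id),
    type = as.character(type),
    time = as.numeric(time),
    quality = as.numeric(quality),
    stringsAsFactors = FALSE
  )
  class(out) <- c("lp_record", class(out))
  out
}

#' Create a dataset of biomedical records
#'
#' A dataset is a set of (user, record) pairs, held as a data frame with
#' columns `record_id`, `owner_id`, `type`, `time`, `quality`.
#'
#' @param records A data frame with the five record columns, or `NULL` for an
#'   empty dataset.
#' @return A data frame of class `lp_dataset`.
#' @export
lp_dataset <- function(records = NULL) {
  cols <- c("record_id", "owner_id", "type", "time", "quality")
  if (is.null(records) || nrow(records) == 0L) {
    records <- data.frame(
      record_id = character(), owner_id = character(), type = character(),
      time = numeric(), quality = numeric(), stringsAsFactors = FALSE
    )
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[cols]
  records$record_id <- as.character(records$record_id)
  records$owner_id <- as.character(records$owner_id)
  records$type <- as.character(records$type)
  records$time <- as.numeric(records$time)
  records$quality <- as.numeric(records$quality)
  validate_dataset(records)
  rownames(records) <- NULL
  class(records) <- unique(c("lp_dataset", class(records)))
  records
}

validate_dataset <- function(records) {
  bad_time <- which(!is.finite(records$time) | records$time < 0)
  if (length(bad_time)) {
    stop("row ", bad_time[1L], ": time must be nonnegative and finite")
  }
  bad_q <- which(!is.finite(records$quality) | records$quality < 0)
  if (length(bad_q)) {
    stop("row ", bad_q[1L], ": quality must be nonnegative and finite")
  }
  dup <- duplicated(records$record_id)
  if (any(dup)) {
    stop("duplicate record_id: ", records$record_id[which(dup)[1L]])
  }
  invisible(records)
}

#' Create a user-profile table
#'
#' @param user_id Character vector of user identifiers.
#' @param current_age Current age in years; must be at least the maximum
#'   sampling age of the user's records (checked at valuation).
#' @param base_value_modifier Positive multiplier applied to every record base
#'   value for this user (default 1). This factors the per-user conditioning of
#'   the base value as base_value(type) * modifier(user).
#' @param ... Further per-user columns (sex, ethnicity, blood_type, ...).
#' @return A data frame of class `lp_users`.
#' @export
lp_users <- function(user_id, current_age = NA_real_, base_value_modifier = 1, ...) {
  user_id <- as.character(user_id)
  out <- data.frame(
    user_id = user_id,
    current_age = rep_len(as.numeric(current_age), length(user_id)),
    base_value_modifier = rep_len(as.numeric(base_value_modifier),
                                  length(user_id)),
    stringsAsFactors = FALSE, ...
  )
  if (any(duplicated(out$user_id))) stop("duplicate user_id in user table")
  if (any(!is.na(out$base_value_modifier) & out$base_value_modifier <= 0)) {
    stop("base_value_modifier must be > 0")
  }
  class(out) <- unique(c("lp_users", class(out)))
  out
}

# ---- record type specs and valuation config ----------------------------

#' Define a record type for the valuation registry
#'
#' @param type_key Categorical type key.
#' @param base_value Positive base value of the type (in LifePounds for a
#'   quality-1, freshly sampled record).
#' @param half_life Half-life of the record's relevance in years; `Inf` for
#'   static data such as the genome, whose time value is identically 1.
#' @param kernel Decay kernel name: `"exp2"` (default; `2^-|u|`, so the value
#'   at one half-life is exactly 1/2), `"exp2_onesided"` (zero before
#'   sampling, `2^-u` after) or `"rect"` (value 1 within one half-life of
#'   sampling, else 0).
#' @param kernel_offset Time offset t0 in years subtracted from the kernel
#'   argument (default 0).
#' @param static Logical; static types are sampled at most once per user by
#'   the synthetic generator.
#' @param display_name Human-readable name.
#' @return A list of class `lp_type_spec`.
#' @export
record_type_spec <- function(type_key, base_value, half_life = Inf,
                             kernel = "exp2", kernel_offset = 0,
                             static = !is.finite(half_life),
                             display_name = type_key) {
  if (!is.numeric(base_value) || length(base_value) != 1L ||
      is.na(base_value) || base_value <= 0) {
    stop("type '", type_key, "': base_value must be a positive number")
  }
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      is.na(half_life) || half_life <= 0) {
    stop("type '", type_key, "': half_life must be positive (possibly Inf)")
  }
  kernel <- match.arg(kernel, c("exp2", "exp2_onesided", "rect"))
  structure(
    list(
      type_key = as.character(type_key), base_value = base_value,
      half_life = half_life, kernel = kernel,
      kernel_offset = as.numeric(kernel_offset),
      static = isTRUE(static), display_name = as.character(display_name)
    ),
    class = "lp_type_spec"
  )
}

synergy_key <- function(types) paste(sort(as.character(types)), collapse = "+")

#' Build a valuation configuration
#'
#' @param types A named list of [record_type_spec()] objects (names are the
#'   type keys), or a list of plain lists with the same fields.
#' @param synergy A list of entries `list(types = c(...), value = x)` giving
#'   the interaction base value for a type multiset of size >= 2. Multisets
#'   absent from the table have synergy 0 (sparse default).
#' @param quality_aggregator Name of the combination quality aggregator;
#'   currently `"reciprocal_sum"`, the paper-style `(sum 1/q)^-1`.
#' @param group_growth List with `form` (`"k_log_k"` or `"k_pow_3_2"`) and
#'   positive constant `C`.
#' @param max_combination_order Largest combination size enumerated in the
#'   per-user cost (default 4).
#' @param relationship_regularization Logical; when `TRUE` each user's cost is
#'   scaled by `1 + lambda`, lambda being the summed coefficient of
#'   relationship to enrolled relatives.
#' @param valuation_time_policy `"explicit"` (caller supplies the valuation
#'   time) or `"latest_sample"` (use the newest sampling age in the dataset).
#' @param critical_representative_level Optional numeric threshold carried in
#'   the config for downstream consumers; no semantics are attached here.
#' @param marketplace Optional list of marketplace parameters (dv_share,
#'   validation_timeout, mint_on_upload, mint_amount, n_keepers, threshold).
#' @return A list of class `lp_config`.
#' @export
valuation_config <- function(types, synergy = list(),
                             quality_aggregator = "reciprocal_sum",
                             group_growth = list(form = "k_log_k", C = 1),
                             max_combination_order = 4L,
                             relationship_regularization = TRUE,
                             valuation_time_policy = "explicit",
                             critical_representative_level = NULL,
                             marketplace = list()) {
  if (length(types) == 0L) stop("configuration error: field 'types' must define at least one record type")
  if (is.null(names(types)) || any(names(types) == "")) {
    nm <- vapply(types, function(t) t$type_key, character(1))
    names(types) <- nm
  }
  registry <- lapply(names(types), function(key) {
    t <- types[[key]]
    if (inherits(t, "lp_type_spec")) return(t)
    record_type_spec(
      type_key = key,
      base_value = t$base_value,
      half_life = parse_half_life(t$half_life),
      kernel = t$kernel %||% "exp2",
      kernel_offset = t$kernel_offset %||% 0,
      static = t$static %||% !is.finite(parse_half_life(t$half_life)),
      display_name = t$display_name %||% key
    )
  })
  names(registry) <- names(types)

  table <- list()
  for (entry in synergy) {
    if (is.null(entry$types) || length(entry$types) < 2L) {
      stop("configuration error: field 'synergy': each entry needs >= 2 types")
    }
    unknown <- setdiff(entry$types, names(registry))
    if (length(unknown)) {
      stop("configuration error: field 'synergy': unknown type key(s): ",
           paste(unknown, collapse = ", "))
    }
    val <- entry$value
    if (!is.numeric(val) || length(val) != 1L || is.na(val) || val <= 0) {
      stop("validation error: field 'synergy': value must be > 0 for [",
           paste(entry$types, collapse = ", "), "]")
    }
    table[[synergy_key(entry$types)]] <- as.numeric(val)
  }

  quality_aggregator <- match.arg(quality_aggregator, "reciprocal_sum")
  form <- match.arg(group_growth$form %||% "k_log_k", c("k_log_k", "k_pow_3_2"))
  C <- as.numeric(group_growth$C %||% 1)
  if (!is.finite(C) || C <= 0) stop("configuration error: field 'group_growth$C': must be > 0")
  max_combination_order <- as.integer(max_combination_order)
  if (is.na(max_combination_order) || max_combination_order < 1L) {
    stop("configuration error: field 'max_combination_order': must be >= 1")
  }
  valuation_time_policy <- match.arg(valuation_time_policy, c("explicit", "latest_sample"))

  mkt <- list(
    dv_share = as.numeric(marketplace$dv_share %||% 0.1),
    validation_timeout = as.numeric(marketplace$validation_timeout %||% 10),
    mint_on_upload = isTRUE(marketplace$mint_on_upload),
    mint_amount = as.numeric(marketplace$mint_amount %||% 1),
    n_keepers = as.integer(marketplace$n_keepers %||% 4L),
    threshold = as.integer(marketplace$threshold %||% 2L)
  )
  if (mkt$dv_share < 0 || mkt$dv_share >= 1) {
    stop("configuration error: field 'marketplace$dv_share': must lie in [0, 1)")
  }

  structure(
    list(
      type_registry = registry,
      synergy_table = table,
      quality_aggregator = quality_aggregator,
      group_growth = list(form = form, C = C),
      max_combination_order = max_combination_order,
      relationship_regularization = isTRUE(relationship_regularization),
      valuation_time_policy = valuation_time_policy,
      critical_representative_level = critical_representative_level,
      marketplace = mkt
    ),
    class = "lp_config"
  )
}

parse_half_life <- function(x) {
  if (is.null(x)) return(Inf)
  if (is.character(x)) {
    if (tolower(x) %in% c("inf", ".inf", "infinity")) return(Inf)
    x <- suppressWarnings(as.numeric(x))
  }
  if (length(x) != 1L || is.na(x)) stop("half_life must be a positive number or Inf")
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a valuation configuration from YAML or JSON
#'
#' Expects the documented schema with top-level keys `types`, `synergy`,
#' `group_growth` and `marketplace` (plus the scalar options of
#' [valuation_config()]). YAML and JSON are both accepted; the format is
#' inferred from the file extension.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `lp_config`.
#' @export
load_valuation_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$types)) stop("configuration error: field 'types' is required")
  valuation_config(
    types = raw$types,
    synergy = raw$synergy %||% list(),
    quality_aggregator = raw$quality_aggregator %||% "reciprocal_sum",
    group_growth = raw$group_growth %||% list(form = "k_log_k", C = 1),
    max_combination_order = raw$max_combination_order %||% 4L,
    relationship_regularization = raw$relationship_regularization %||% TRUE,
    valuation_time_policy = raw$valuation_time_policy %||% "explicit",
    critical_representative_level = raw$critical_representative_level,
    marketplace = raw$marketplace %||% list()
  )
}

#' Write a valuation configuration to YAML
#'
#' Inverse of [load_valuation_config()] for configs built in code.
#'
#' @param config An `lp_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_valuation_config <- function(config, path) {
  stopifnot(inherits(config, "lp_config"))
  types <- lapply(config$type_registry, function(t) {
    list(
      base_value = t$base_value,
      half_life = if (is.finite(t$half_life)) t$half_life else ".inf",
      kernel = t$kernel, kernel_offset = t$kernel_offset,
      static = t$static, display_name = t$display_name
    )
  })
  synergy <- lapply(names(config$synergy_table), function(key) {
    list(types = strsplit(key, "+", fixed = TRUE)[[1L]],
         value = config$synergy_table[[key]])
  })
  out <- list(
    types = types, synergy = synergy,
    quality_aggregator = config$quality_aggregator,
    group_growth = config$group_growth,
    max_combination_order = config$max_combination_order,
    relationship_regularization = config$relationship_regularization,
    valuation_time_policy = config$valuation_time_policy,
    marketplace = config$marketplace
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- dataset I/O --------------------------------------------------------

#' Read a dataset of records from CSV or JSON
#'
#' CSV files must carry the header
#' `record_id,owner_id,type,time,quality`; JSON files are an array of objects
#' with those keys. Rows with `quality = 0` are retained (valid, zero-cost
#' records); negative times or qualities are rejected with the row number.
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return An `lp_dataset`.
#' @export
read_records <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- if (format == "json") {
    parsed <- jsonlite::fromJSON(path)
    if (length(parsed) == 0L) NULL else as.data.frame(parsed)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      record_id = "character", owner_id = "character", type = "character",
      time = "numeric", quality = "numeric"
    ))
  }
  lp_dataset(df)
}

#' Write a dataset of records to CSV or JSON
#'
#' Output is byte-stable for a given dataset: fixed column order, '.' decimal
#' separator, UTF-8, no row names. `read_records()` is the exact inverse.
#'
#' @param dataset An `lp_dataset`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_records <- function(dataset, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  dataset <- lp_dataset(dataset)
  if (format == "json") {
    jsonlite::write_json(dataset, path, dataframe = "rows", digits = I(17),
                         auto_unbox = FALSE)
  } else {
    out <- as.data.frame(dataset)
    # full-precision text so datasets round-trip bit-exactly
    out$time <- sprintf("%.17g", out$time)
    out$quality <- sprintf("%.17g", out$quality)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}
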