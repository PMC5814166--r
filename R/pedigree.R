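# ---- pedigree construction and I/O --------------------------------------

#' Build a pedigree
#'
#' A pedigree is a directed acyclic parent-to-child graph with optional
#' monozygotic (MZ) twin annotations. Unknown parents are `NA` (founders).
#'
#' @param id Character vector of individual ids.
#' @param father,mother Character vectors of parent ids (`NA` or `"0"` for
#'   unknown). Both parents of an individual may be unknown.
#' @param sex Optional integer/character sex codes (1 male, 2 female, 0
#'   unknown), PED convention.
#' @param fid Optional family ids (PED column 1); default `"F1"`.
#' @param mz_pairs Optional 2-column character matrix of unordered MZ twin
#'   pairs. Twins must share both parents when the parents are known.
#' @return An object of class `lp_pedigree`.
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = 0, fid = "F1",
                     mz_pairs = NULL) {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(p) {
    p <- as.character(rep_len(p, n))
    p[p %in% c("0", "", "NA") | is.na(p)] <- NA_character_
    p
  }
  ind <- data.frame(
    fid = as.character(rep_len(fid, n)), id = id,
    father = norm_parent(father), mother = norm_parent(mother),
    sex = rep_len(sex, n), stringsAsFactors = FALSE
  )
  if (any(duplicated(ind$id))) stop("duplicate individual id in pedigree")
  for (col in c("father", "mother")) {
    ref <- ind[[col]]
    missing_ref <- setdiff(ref[!is.na(ref)], ind$id)
    if (length(missing_ref)) {
      stop("child references missing parent id: ",
           paste(missing_ref, collapse = ", "))
    }
  }
  ped <- structure(list(ind = ind, mz = normalize_mz(mz_pairs)),
                   class = "lp_pedigree")
  check_acyclic(ped)
  check_mz_parents(ped)
  ped
}

normalize_mz <- function(mz_pairs) {
  if (is.null(mz_pairs) || NROW(mz_pairs) == 0L) {
    return(matrix(character(), ncol = 2L))
  }
  m <- matrix(as.character(unlist(mz_pairs)), ncol = 2L, byrow = is.list(mz_pairs))
  if (!is.list(mz_pairs)) m <- matrix(as.character(mz_pairs), ncol = 2L)
  t(apply(m, 1L, sort))
}

check_acyclic <- function(ped) {
  parents <- parent_map(ped)
  state <- stats::setNames(rep(0L, nrow(ped$ind)), ped$ind$id) # 0 new, 1 active, 2 done
  visit <- function(x, trail) {
    if (state[[x]] == 2L) return(invisible())
    if (state[[x]] == 1L) {
      cycle <- c(trail[which(trail == x)[1L]:length(trail)], x)
      stop("pedigree cycle detected: ", paste(cycle, collapse = " -> "))
    }
    state[[x]] <<- 1L
    for (p in parents[[x]]) visit(p, c(trail, x))
    state[[x]] <<- 2L
  }
  for (x in ped$ind$id) visit(x, character())
  invisible(ped)
}

check_mz_parents <- function(ped) {
  if (nrow(ped$mz) == 0L) return(invisible(ped))
  ind <- ped$ind
  for (i in seq_len(nrow(ped$mz))) {
    a <- ind[ind$id == ped$mz[i, 1L], ]; b <- ind[ind$id == ped$mz[i, 2L], ]
    if (nrow(a) == 0L || nrow(b) == 0L) {
      stop("MZ pair references unknown individual: ",
           paste(ped$mz[i, ], collapse = ", "))
    }
    for (col in c("father", "mother")) {
      pa <- a[[col]]; pb <- b[[col]]
      if (!is.na(pa) && !is.na(pb) && pa != pb) {
        stop("MZ twins ", a$id, " and ", b$id, " have different ", col, "s")
      }
    }
  }
  invisible(ped)
}

parent_map <- function(ped) {
  ind <- ped$ind
  stats::setNames(lapply(seq_len(nrow(ind)), function(i) {
    p <- c(ind$father[i], ind$mother[i])
    p[!is.na(p)]
  }), ind$id)
}

#' Read a pedigree from a PLINK PED/FAM file
#'
#' Whitespace-delimited rows `FID IID PAT MAT SEX PHENO` with `"0"` for
#' unknown parents. MZ twin pairs, which PED cannot express, come from an
#' optional sidecar file with two ids per line.
#'
#' @param path PED/FAM file path.
#' @param mz_path Optional MZ-twin sidecar path.
#' @return An `lp_pedigree`.
#' @export
read_ped <- function(path, mz_path = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 5L) stop("PED file needs at least 5 columns (FID IID PAT MAT SEX)")
  mz <- NULL
  if (!is.null(mz_path) && file.exists(mz_path)) {
    mz_df <- utils::read.table(mz_path, header = FALSE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
    if (nrow(mz_df)) mz <- as.matrix(mz_df[, 1:2])
  }
  pedigree(id = df[[2L]], father = df[[3L]], mother = df[[4L]],
           sex = df[[5L]], fid = df[[1L]], mz_pairs = mz)
}

#' Write a pedigree to a PLINK PED/FAM file
#'
#' @param ped An `lp_pedigree`.
#' @param path Output PED path.
#' @param mz_path Optional sidecar path for MZ twin pairs (written only when
#'   the pedigree has any).
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, mz_path = NULL) {
  stopifnot(inherits(ped, "lp_pedigree"))
  ind <- ped$ind
  out <- data.frame(
    ind$fid, ind$id,
    ifelse(is.na(ind$father), "0", ind$father),
    ifelse(is.na(ind$mother), "0", ind$mother),
    ind$sex, rep("-9", nrow(ind))
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  if (!is.null(mz_path) && nrow(ped$mz)) {
    utils::write.table(ped$mz, mz_path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE, sep = " ")
  }
  invisible(path)
}

#' @export
print.lp_pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x$ind), "individuals,",
      sum(!is.na(x$ind$father)) + sum(!is.na(x$ind$mother)), "parent links,",
      nrow(x$mz), "MZ twin pair(s)\n")
  invisible(x)
}

# ---- MZ merging ---------------------------------------------------------

# map each id to a representative, merging MZ twin pairs into one node
mz_representative <- function(ped) {
  rep_of <- stats::setNames(ped$ind$id, ped$ind$id)
  if (nrow(ped$mz)) {
    for (i in seq_len(nrow(ped$mz))) {
      a <- ped$mz[i, 1L]; b <- ped$mz[i, 2L]
      ra <- rep_of[[a]]; rb <- rep_of[[b]]
      rep_of[rep_of == rb] <- ra
    }
  }
  rep_of
}

# parent map on merged nodes (twins pooled; parents taken from whichever
# twin has them recorded)
merged_parent_map <- function(ped) {
  rep_of <- mz_representative(ped)
  raw <- parent_map(ped)
  merged <- list()
  for (x in names(raw)) {
    rx <- rep_of[[x]]
    ps <- unique(rep_of[raw[[x]]])
    merged[[rx]] <- unique(c(merged[[rx]], ps))
  }
  for (x in unique(rep_of)) if (is.null(merged[[x]])) merged[[x]] <- character()
  list(parents = merged, rep_of = rep_of)
}

# ---- coefficient of relationship ----------------------------------------

# all ancestor chains from x upward: list of (top, nodes, length)
ancestor_paths <- function(x, parents) {
  out <- list(list(top = x, nodes = x, length = 0L))
  frontier <- out
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (par in parents[[p$top]]) {
        np <- list(top = par, nodes = c(p$nodes, par), length = p$length + 1L)
        out[[length(out) + 1L]] <- np
        nxt[[length(nxt) + 1L]] <- np
      }
    }
    frontier <- nxt
  }
  out
}

#' Coefficient of relationship between two individuals
#'
#' Sums `2^-L` over all ancestor paths connecting the pair, where each path
#' climbs from one individual to a single common ancestor and descends to the
#' other without repeating any individual, and `L` is the path's total edge
#' count. So parent-offspring gives 1/2, grandparent-grandchild 1/4, full
#' siblings 1/2, first cousins 1/8. MZ twins are treated as one genetic
#' individual: their mutual coefficient is 1 and paths may pass through
#' either twin interchangeably.
#'
#' The default `"simplified"` method sets all inbreeding coefficients to
#' zero, appropriate for random-bred human populations. The `"wright"`
#' method applies the classical inbreeding-adjusted path coefficients,
#' `sum 2^-L (1 + f_A) / sqrt((1 + f_B)(1 + f_C))`, with each ancestor's
#' inbreeding coefficient `f` computed from the pedigree by the kinship
#' recursion.
#'
#' @param ped An `lp_pedigree`.
#' @param a,b Individual ids.
#' @param method `"simplified"` (default) or `"wright"`.
#' @return Nonnegative relatedness; 1 for self or an MZ twin pair.
#' @export
relationship_coefficient <- function(ped, a, b,
                                     method = c("simplified", "wright")) {
  method <- match.arg(method)
  stopifnot(inherits(ped, "lp_pedigree"))
  for (x in c(a, b)) {
    if (!x %in% ped$ind$id) stop("unknown individual id: ", x)
  }
  mg <- merged_parent_map(ped)
  ra <- mg$rep_of[[a]]; rb <- mg$rep_of[[b]]
  if (ra == rb) return(1)
  paths_a <- ancestor_paths(ra, mg$parents)
  paths_b <- ancestor_paths(rb, mg$parents)
  fco <- if (method == "wright") inbreeding_all(mg$parents) else NULL
  r <- 0
  for (pa in paths_a) {
    for (pb in paths_b) {
      if (pa$top != pb$top) next
      if (length(intersect(pa$nodes, pb$nodes)) != 1L) next
      contrib <- 2^-(pa$length + pb$length)
      if (method == "wright") contrib <- contrib * (1 + fco[[pa$top]])
      r <- r + contrib
    }
  }
  if (method == "wright") {
    r <- r / sqrt((1 + fco[[ra]]) * (1 + fco[[rb]]))
  }
  r
}

# inbreeding coefficients for all merged nodes via the kinship recursion:
# f(x) = phi(father(x), mother(x)); phi(x,x) = (1 + f(x))/2;
# phi(x,y) = (phi(fa(deeper), other) + phi(mo(deeper), other)) / 2,
# with unknown parents contributing 0.
inbreeding_all <- function(parents) {
  memo <- new.env(parent = emptyenv())
  depth_memo <- new.env(parent = emptyenv())
  depth <- function(x) {
    if (!is.null(depth_memo[[x]])) return(depth_memo[[x]])
    d <- if (length(parents[[x]]) == 0L) 0L else {
      1L + max(vapply(parents[[x]], depth, integer(1)))
    }
    depth_memo[[x]] <- d
    d
  }
  kinship <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      ps <- parents[[x]]
      f <- if (length(ps) == 2L) kinship(ps[1L], ps[2L]) else 0
      (1 + f) / 2
    } else {
      deeper <- if (depth(x) >= depth(y)) x else y
      other <- if (identical(deeper, x)) y else x
      ps <- parents[[deeper]]
      if (length(ps) == 0L) 0 else {
        sum(vapply(ps, kinship, numeric(1), y = other)) / 2
      }
    }
    memo[[key]] <- val
    val
  }
  out <- list()
  for (x in names(parents)) {
    ps <- parents[[x]]
    out[[x]] <- if (length(ps) == 2L) kinship(ps[1L], ps[2L]) else 0
  }
  out
}

#' Relatedness matrix over a set of individuals
#'
#' @param ped An `lp_pedigree`.
#' @param ids Individual ids (default: all in the pedigree).
#' @param method Passed to [relationship_coefficient()].
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
relatedness_matrix <- function(ped, ids = NULL,
                               method = c("simplified", "wright")) {
  method <- match.arg(method)
  if (is.null(ids)) ids <- ped$ind$id
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      r <- relationship_coefficient(ped, ids[i], ids[j], method)
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Relationship-regularization lambda for one user
#'
#' Sums the coefficient of relationship between `user` and every other
#' member of the enrolled cohort: the user's data cost is then scaled by
#' `1 + lambda`. A cohort of strangers gives 0; an enrolled MZ twin alone
#' gives 1, doubling the cost.
#'
#' @param ped An `lp_pedigree`.
#' @param user Individual id.
#' @param cohort Character vector of enrolled user ids; `user` itself is
#'   excluded automatically. Ids absent from the pedigree count as unrelated.
#' @param method Passed to [relationship_coefficient()].
#' @return Nonnegative lambda (unbounded: large enrolled families inflate it).
#' @export
cohort_lambda <- function(ped, user, cohort,
                          method = c("simplified", "wright")) {
  method <- match.arg(method)
  others <- setdiff(unique(as.character(cohort)), user)
  others <- others[others %in% ped$ind$id]
  if (!length(others)) return(0)
  sum(vapply(others, function(m) {
    relationship_coefficient(ped, user, m, method)
  }, numeric(1)))
}
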