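#' Read a pedigree file
#'
#' Reads a pedigree CSV with columns `animal,sire,dam,birth_year,sex,breed`
#' and validates it with [as_pedigree()]. Unknown parents may be coded as an
#' empty string, `"0"` or `NA`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A sorted pedigree tibble of class `ss_pedigree` (see
#'   [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, col_types = readr::cols(
    animal = readr::col_character(),
    sire = readr::col_character(),
    dam = readr::col_character(),
    birth_year = readr::col_integer(),
    sex = readr::col_character(),
    breed = readr::col_character()
  ))
  as_pedigree(ped)
}

#' Validate and topologically sort a pedigree
#'
#' Checks id uniqueness, parent sex consistency (an id used as a sire is never
#' used as a dam and vice versa) and absence of ancestral cycles, then reorders
#' records so that every parent precedes its offspring. Unknown parents
#' (`""`, `"0"` or `NA`) are treated as founders of a single base population.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam` and optionally
#'   `birth_year`, `sex`, `breed`.
#' @return A tibble of class `ss_pedigree`, topologically sorted, with `sire`
#'   and `dam` normalised to `NA` for unknown parents.
#' @export
as_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  req <- c("animal", "sire", "dam")
  miss <- setdiff(req, names(ped))
  if (length(miss) > 0) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  ped <- tibble::as_tibble(ped)
  ped$animal <- as.character(ped$animal)
  ped$sire <- normalise_parent(ped$sire)
  ped$dam <- normalise_parent(ped$dam)

  dup <- ped$animal[duplicated(ped$animal)]
  if (length(dup) > 0) {
    stop("duplicate animal id(s): ", paste(unique(dup), collapse = ", "))
  }
  self <- ped$animal == ped$sire | ped$animal == ped$dam
  self[is.na(self)] <- FALSE
  if (any(self)) {
    stop("animal is its own parent (cycle): ",
         paste(ped$animal[self], collapse = ", "))
  }
  both <- intersect(stats::na.omit(ped$sire), stats::na.omit(ped$dam))
  if (length(both) > 0) {
    stop("id(s) used both as sire and as dam: ",
         paste(both, collapse = ", "))
  }

  # parents that never appear as animals become implicit founders
  known <- ped$animal
  implied <- setdiff(unique(c(ped$sire, ped$dam)), c(known, NA))
  if (length(implied) > 0) {
    add <- tibble::tibble(animal = implied, sire = NA_character_,
                          dam = NA_character_)
    for (col in setdiff(names(ped), names(add))) add[[col]] <- NA
    ped <- dplyr::bind_rows(add[names(ped)], ped)
  }

  ord <- pedigree_topological_order(ped)
  out <- ped[ord, , drop = FALSE]
  class(out) <- c("ss_pedigree", class(tibble::tibble()))
  out
}

normalise_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# Kahn's algorithm; stable with respect to input order. Errors with the
# members of a cycle if one exists.
pedigree_topological_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  indeg <- (!is.na(si)) + (!is.na(di))

  children <- vector("list", n)
  for (i in idx) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  ready <- idx[indeg == 0]
  ord <- integer(0)
  while (length(ready) > 0) {
    i <- ready[1]
    ready <- ready[-1]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(ord) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ped$animal[setdiff(idx, ord)], collapse = ", "))
  }
  ord
}

is_sorted_pedigree <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  pos <- seq_len(nrow(ped))
  all(is.na(si) | si < pos) && all(is.na(di) | di < pos)
}

assert_sorted <- function(ped) {
  if (!inherits(ped, "ss_pedigree") || !is_sorted_pedigree(ped)) {
    stop("pedigree must be validated/sorted with as_pedigree() first")
  }
  invisible(ped)
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes the exact inbreeding coefficient F for every animal from the
#' sorted pedigree, using the L-vector recursion of Meuwissen and Luo. F is
#' half the additive relationship between the parents; founders have F = 0.
#'
#' @param ped A sorted `ss_pedigree`.
#' @return A tibble with columns `animal` and `f`.
#' @export
inbreeding_coef <- function(ped) {
  assert_sorted(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  f <- numeric(n)
  # Mendelian sampling variance d_i; unknown parent behaves as F = -1
  fpar <- function(p, i) if (is.na(p)) -1 else f[p]
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- 0.5 - 0.25 * (fpar(si[i], i) + fpar(di[i], i))
    if (is.na(si[i]) && is.na(di[i])) {
      f[i] <- 0
      next
    }
    # a_ii = sum over ancestors j of L_j^2 d_j, accumulated in descending
    # pedigree order so contributions flow from descendant to parent
    anc <- collect_ancestors(i, si, di)
    L <- numeric(n)
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * d[j]
      if (!is.na(si[j])) L[si[j]] <- L[si[j]] + 0.5 * lj
      if (!is.na(di[j])) L[di[j]] <- L[di[j]] + 0.5 * lj
    }
    f[i] <- aii - 1
  }
  tibble::tibble(animal = ped$animal, f = f)
}

# indices of i and all its ancestors, sorted descending
collect_ancestors <- function(i, si, di) {
  seen <- logical(length(si))
  stack <- i
  while (length(stack) > 0) {
    j <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[j]) next
    seen[j] <- TRUE
    for (p in c(si[j], di[j])) if (!is.na(p) && !seen[p]) stack <- c(stack, p)
  }
  sort(which(seen), decreasing = TRUE)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with the exact inbreeding
#' correction: each animal contributes 1/d_i to its own diagonal, -1/(2 d_i)
#' to animal-parent pairs and 1/(4 d_i) to parent-parent pairs, where d_i is
#' the Mendelian sampling variance from [inbreeding_coef()].
#'
#' @param ped A sorted `ss_pedigree`.
#' @param f Optional precomputed result of [inbreeding_coef()].
#' @return A sparse symmetric `dgCMatrix` with animal ids as dimnames.
#' @export
a_inverse <- function(ped, f = NULL) {
  assert_sorted(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding_coef(ped)
  stopifnot(identical(f$animal, ped$animal))
  fv <- f$f
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  fs <- ifelse(is.na(si), -1, fv[ifelse(is.na(si), 1L, si)])
  fd <- ifelse(is.na(di), -1, fv[ifelse(is.na(di), 1L, di)])
  alpha <- 1 / (0.5 - 0.25 * (fs + fd))

  ii <- seq_len(n)
  rows <- ii; cols <- ii; vals <- alpha
  add <- function(r, c, v) {
    rows <<- c(rows, r); cols <<- c(cols, c); vals <<- c(vals, v)
  }
  has_s <- !is.na(si); has_d <- !is.na(di)
  add(ii[has_s], si[has_s], -0.5 * alpha[has_s])
  add(si[has_s], ii[has_s], -0.5 * alpha[has_s])
  add(ii[has_d], di[has_d], -0.5 * alpha[has_d])
  add(di[has_d], ii[has_d], -0.5 * alpha[has_d])
  add(si[has_s], si[has_s], 0.25 * alpha[has_s])
  add(di[has_d], di[has_d], 0.25 * alpha[has_d])
  both <- has_s & has_d
  add(si[both], di[both], 0.25 * alpha[both])
  add(di[both], si[both], 0.25 * alpha[both])

  ainv <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  methods::as(ainv, "generalMatrix")
}

#' Dense relationship submatrix among a set of animals
#'
#' Computes the numerator relationships among `ids` (for example the
#' genotyped animals, giving A22) by running the tabular method on the
#' pedigree restricted to `ids` and their ancestors, then extracting the
#' requested block. Diagonals equal 1 + F.
#'
#' @param ped A sorted `ss_pedigree`.
#' @param ids Character vector of animal ids, all present in the pedigree.
#' @return A dense symmetric matrix ordered like `ids`.
#' @export
a_submatrix <- function(ped, ids) {
  assert_sorted(ped)
  ids <- as.character(ids)
  unknown <- setdiff(ids, ped$animal)
  if (length(unknown) > 0) {
    stop("id(s) not in pedigree: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  keep <- logical(nrow(ped))
  stack <- match(ids, ped$animal)
  while (length(stack) > 0) {
    j <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (keep[j]) next
    keep[j] <- TRUE
    for (p in c(si[j], di[j])) if (!is.na(p) && !keep[p]) stack <- c(stack, p)
  }
  sub <- which(keep)  # ascending, so still parents-first
  A <- tabular_a(ped$animal[sub],
                 match(ped$sire[sub], ped$animal[sub]),
                 match(ped$dam[sub], ped$animal[sub]))
  A[ids, ids, drop = FALSE]
}

# tabular (recursive) construction of A over a sorted index set
tabular_a <- function(ids, si, di) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}
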