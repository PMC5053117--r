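#' Pedigree validation and the numerator relationship matrix
#'
#' A pedigree is a data frame with character columns `animal`, `sire`, `dam`
#' and optionally `generation`. Unknown parents are the sentinel `NA`;
#' on file input both an empty field and `"0"` denote an unknown parent.
#' Ids are compared as exact strings and never coerced to numbers.
#'
#' @name pedigree
NULL

.PED_UNKNOWN <- NA_character_

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam` with an optional fourth column
#' `generation`. An empty field or `"0"` in the parent columns means the
#' parent is unknown.
#'
#' @param path path to a CSV file.
#' @return a validated pedigree (see [validate_pedigree()]).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  names(df) <- tolower(names(df))
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(df)))
    stop("pedigree file must have columns animal,sire,dam", call. = FALSE)
  validate_pedigree(df)
}

#' Validate a pedigree and order parents before offspring
#'
#' Checks that animal ids are unique, that every named parent is either
#' present as an animal or explicitly unknown, and that the parent-offspring
#' relation is acyclic. Records are returned topologically sorted so that
#' every parent precedes all of its offspring, which is the order the
#' tabular relationship-matrix recursion requires.
#'
#' @param records data frame with columns `animal`, `sire`, `dam`
#'   (character; `NA`, `""` or `"0"` for an unknown parent) and optionally
#'   `generation`.
#' @return a `data.frame` of class `pedigree` in topological order, with
#'   unknown parents normalised to `NA`.
#' @export
validate_pedigree <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("animal", "sire", "dam")
  if (!all(req %in% names(records)))
    stop("pedigree needs columns animal, sire, dam", call. = FALSE)
  for (col in req)
    records[[col]] <- as.character(records[[col]])
  for (col in c("sire", "dam")) {
    x <- records[[col]]
    x[!is.na(x) & (x == "" | x == "0")] <- .PED_UNKNOWN
    records[[col]] <- x
  }
  ids <- records$animal
  if (anyNA(ids) || any(ids == ""))
    stop("missing animal id in pedigree", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate animal id(s) in pedigree: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  parents <- c(records$sire, records$dam)
  orphan <- setdiff(parents[!is.na(parents)], ids)
  if (length(orphan))
    stop("parent id(s) not present as animals: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  ord <- .ped_toposort(records)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn's algorithm; reports a cycle by naming the animals left unplaced.
.ped_toposort <- function(records) {
  n <- nrow(records)
  idx <- seq_len(n)
  names(idx) <- records$animal
  sire_i <- idx[records$sire]
  dam_i <- idx[records$dam]
  indeg <- as.integer(!is.na(sire_i)) + as.integer(!is.na(dam_i))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i]))
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    stuck <- records$animal[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(stuck, collapse = ", "), call. = FALSE)
  }
  order
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the matrix A of expected additive-genetic relationships over all
#' pedigree members with the classical tabular recursion: processing animals
#' with parents before offspring, the diagonal is
#' `A[i,i] = 1 + 0.5 * A[f,m]` (1 plus the inbreeding coefficient) and the
#' off-diagonal with any previously processed animal j is
#' `A[i,j] = 0.5 * (A[j,f] + A[j,m])`, an unknown parent contributing zero.
#' Unknown parents are therefore treated as unrelated, non-inbred founders.
#'
#' @param ped a validated pedigree from [validate_pedigree()].
#' @param ids optional character vector: return the sub-matrix for these
#'   animals (in this order), e.g. the parents of the phenotyped generation.
#' @return symmetric numeric matrix with `dimnames` set to the animal ids.
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   animal = c("S", "D", "O"), sire = c(NA, NA, "S"), dam = c(NA, NA, "D")))
#' build_relationship_matrix(ped)["S", "O"] # 0.5
#' @export
build_relationship_matrix <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  fi <- idx[ped$sire]
  mi <- idx[ped$dam]
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (is.na(f)) 0 else A[j, f]) +
                   (if (is.na(m)) 0 else A[j, m]))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (is.na(f) || is.na(m)) 0 else 0.5 * A[f, m]
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$animal)
    if (length(miss))
      stop("ids not in pedigree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Parent incidence of phenotyped animals
#'
#' In the sire-dam model an animal's additive-genetic value is represented
#' as half the sum of its parents' additive effects, so each phenotyped
#' animal loads 0.5 on its sire's and 0.5 on its dam's effect. Returns the
#' corresponding incidence matrix Z (animals x parents); rows sum to one.
#'
#' @param ped validated pedigree.
#' @param phenotyped_ids ids of the phenotyped animals (must have both
#'   parents known).
#' @param parent_ids optional column order; defaults to all parents of the
#'   phenotyped animals, in pedigree order.
#' @return numeric matrix with `phenotyped_ids` rows and parent columns.
#' @export
parent_incidence <- function(ped, phenotyped_ids, parent_ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  i <- match(phenotyped_ids, ped$animal)
  if (anyNA(i))
    stop("phenotyped animals not in pedigree: ",
         paste(phenotyped_ids[is.na(i)], collapse = ", "), call. = FALSE)
  sire <- ped$sire[i]
  dam <- ped$dam[i]
  bad <- is.na(sire) | is.na(dam)
  if (any(bad))
    stop("phenotyped animal(s) with unknown parent: ",
         paste(phenotyped_ids[bad], collapse = ", "), call. = FALSE)
  if (is.null(parent_ids))
    parent_ids <- ped$animal[sort(unique(match(c(sire, dam), ped$animal)))]
  Z <- matrix(0, length(phenotyped_ids), length(parent_ids),
              dimnames = list(phenotyped_ids, parent_ids))
  Z[cbind(seq_along(i), match(sire, parent_ids))] <-
    Z[cbind(seq_along(i), match(sire, parent_ids))] + 0.5
  Z[cbind(seq_along(i), match(dam, parent_ids))] <-
    Z[cbind(seq_along(i), match(dam, parent_ids))] + 0.5
  Z
}

#' Write / read a relationship matrix as TSV
#'
#' Plain TSV with an `id` header column and one column per animal.
#' @param A relationship matrix with dimnames.
#' @param path output path.
#' @export
write_relationship_matrix <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_matrix
#' @export
read_relationship_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(id = "character"))
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$id
  storage.mode(A) <- "double"
  A
}
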