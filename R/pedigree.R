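#' Construct a pedigree
#'
#' A pedigree holds the members of one family: subject identifiers, parent
#' links, sex and age.  Founders have both parents missing; non-founders have
#' both parents present and resolvable within the family.  Pedigrees are the
#' source of relative-pair classes for the relationship-specific working
#' correlation and of Mendelian transmission during simulation.
#'
#' @param family_id Identifier of the family (scalar).
#' @param id Character or integer vector of subject identifiers, unique
#'   within the family.
#' @param father_id,mother_id Parent identifiers; `NA` or `"0"` denotes a
#'   missing parent (standard PED convention).  Either both parents are
#'   present or both are absent.
#' @param sex Integer vector, 1 = male, 2 = female.
#' @param age Numeric vector of ages in years.
#'
#' @return An object of class `"pedigree"`: a data frame with columns
#'   `id`, `father_id`, `mother_id`, `sex`, `age` and attribute `family_id`.
#' @export
#' @examples
#' ped <- pedigree("fam1",
#'   id        = c("p1", "p2", "c1"),
#'   father_id = c(NA, NA, "p1"),
#'   mother_id = c(NA, NA, "p2"),
#'   sex       = c(1, 2, 1),
#'   age       = c(52, 50, 24))
#' classify_relationship(ped, "p1", "c1")
pedigree <- function(family_id, id, father_id, mother_id, sex, age) {
  id <- as.character(id)
  father_id <- .norm_parent(father_id)
  mother_id <- .norm_parent(mother_id)
  n <- length(id)
  stopifnot(length(father_id) == n, length(mother_id) == n,
            length(sex) == n, length(age) == n)
  if (anyDuplicated(id))
    jx_stop(sprintf("duplicate subject ids in family %s", family_id),
            "jx_identifier_error")
  half <- xor(is.na(father_id), is.na(mother_id))
  if (any(half))
    jx_stop(sprintf("family %s: subjects %s have exactly one known parent; both or none required",
                    family_id, paste(id[half], collapse = ", ")),
            "jx_pedigree_error")
  dangling <- c(setdiff(stats::na.omit(father_id), id),
                setdiff(stats::na.omit(mother_id), id))
  if (length(dangling))
    jx_stop(sprintf("family %s: parent id(s) %s not present among members",
                    family_id, paste(unique(dangling), collapse = ", ")),
            "jx_identifier_error")
  ped <- data.frame(id = id, father_id = father_id, mother_id = mother_id,
                    sex = as.integer(sex), age = as.numeric(age),
                    stringsAsFactors = FALSE)
  attr(ped, "family_id") <- family_id
  class(ped) <- c("pedigree", "data.frame")
  if (any(is.na(.generation_depth(ped))))
    jx_stop(sprintf("family %s: pedigree contains an ancestry cycle", family_id),
            "jx_pedigree_error")
  ped
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == "0"] <- NA_character_
  x
}

## depth of each subject above its founder line; NA signals a cycle
.generation_depth <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  depth <- ifelse(is.na(fa) & is.na(mo), 0L, NA_integer_)
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      df <- depth[fa[i]]; dm <- depth[mo[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree of family %s: %d members, %d founders\n",
              attr(x, "family_id"), nrow(x),
              sum(is.na(x$father_id))))
  print(as.data.frame(x), ...)
  invisible(x)
}

.ped_index <- function(ped, id) {
  i <- match(as.character(id), ped$id)
  if (anyNA(i))
    jx_stop(sprintf("unknown subject id(s): %s",
                    paste(id[is.na(i)], collapse = ", ")),
            "jx_identifier_error")
  i
}

#' Classify the relationship of a pair of family members
#'
#' The six relative-pair classes used by the relationship-specific working
#' correlation are: spouse, parent-offspring, sibling (full siblings),
#' avuncular (aunt/uncle with niece/nephew), grandparent-grandchild and
#' first-cousin.  Every other pair (including half-siblings) is classified
#' `"other"`.  When a pair satisfies several definitions the closest genetic
#' relationship wins: parent-offspring > sibling > grandparent-grandchild >
#' avuncular > first-cousin > spouse.  A spouse pair is a pair with at least
#' one common offspring in the pedigree.
#'
#' @param ped A [pedigree()].
#' @param i,j Subject identifiers, `i != j`.
#' @return A character scalar, one of `"parent-offspring"`, `"sibling"`,
#'   `"grandparent-grandchild"`, `"avuncular"`, `"first-cousin"`,
#'   `"spouse"`, `"other"`.  Symmetric in `(i, j)`.
#' @export
classify_relationship <- function(ped, i, j) {
  a <- .ped_index(ped, i); b <- .ped_index(ped, j)
  if (a == b)
    jx_stop("relationship classification requires two distinct subjects",
            "jx_argument_error")
  .classify_idx(ped, a, b)
}

.classify_idx <- function(ped, a, b) {
  fa <- ped$father_id; mo <- ped$mother_id; id <- ped$id
  parents <- function(k) stats::na.omit(c(fa[k], mo[k]))
  pa <- parents(a); pb <- parents(b)
  # parent-offspring
  if (id[a] %in% pb || id[b] %in% pa) return("parent-offspring")
  # full siblings: same father and same mother, both known
  if (length(pa) == 2 && length(pb) == 2 && setequal(pa, pb)) return("sibling")
  gp <- function(k) unique(unlist(lapply(match(parents(k), id), parents)))
  ga <- gp(a); gb <- gp(b)
  if (id[a] %in% gb || id[b] %in% ga) return("grandparent-grandchild")
  # avuncular: one is a full sibling of a parent of the other
  full_sib <- function(u, v) {
    pu <- parents(u); pv <- parents(v)
    length(pu) == 2 && length(pv) == 2 && setequal(pu, pv)
  }
  sib_of_parent <- function(u, v) {
    any(vapply(match(parents(v), id), function(p) full_sib(u, p), logical(1)))
  }
  if (sib_of_parent(a, b) || sib_of_parent(b, a)) return("avuncular")
  # first cousins: a parent of each are full siblings
  pia <- match(pa, id); pib <- match(pb, id)
  for (u in pia) for (v in pib)
    if (u != v && full_sib(u, v)) return("first-cousin")
  # spouses: at least one common offspring
  for (k in seq_len(nrow(ped)))
    if (!is.na(fa[k]) && ((fa[k] == id[a] && identical(mo[k], id[b])) ||
                          (fa[k] == id[b] && identical(mo[k], id[a]))))
      return("spouse")
  "other"
}

#' All within-family pairs with their relationship classes
#'
#' @param ped A [pedigree()].
#' @return A data frame with columns `id1`, `id2`, `class`, one row per
#'   unordered pair of distinct members.
#' @export
relationship_pairs <- function(ped) {
  n <- nrow(ped)
  if (n < 2)
    return(data.frame(id1 = character(), id2 = character(),
                      class = character(), stringsAsFactors = FALSE))
  pr <- utils::combn(n, 2)
  cls <- vapply(seq_len(ncol(pr)),
                function(k) .classify_idx(ped, pr[1, k], pr[2, k]),
                character(1))
  data.frame(id1 = ped$id[pr[1, ]], id2 = ped$id[pr[2, ]], class = cls,
             stringsAsFactors = FALSE)
}

#' Kinship coefficient of a pair
#'
#' Recursive kinship coefficient for pedigrees with non-inbred, unrelated
#' founders: the probability that one allele sampled at random from each of
#' the two subjects is identical by descent.  `kinship(ped, i, i)` is 1/2
#' for a non-inbred subject; parent-offspring pairs give 1/4, full siblings
#' 1/4, avuncular and grandparent-grandchild 1/8, first cousins 1/16,
#' spouses and unrelated pairs 0.
#'
#' @param ped A [pedigree()].
#' @param i,j Subject identifiers.
#' @return Kinship coefficient in `[0, 0.5]` (up to 0.5 + inbreeding/2 in
#'   looped pedigrees).
#' @export
kinship <- function(ped, i, j) {
  a <- .ped_index(ped, i); b <- .ped_index(ped, j)
  kinship_matrix(ped)[a, b]
}

#' Kinship matrix of a whole pedigree
#'
#' @param ped A [pedigree()].
#' @return Symmetric matrix with subject ids as dimnames.
#' @export
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  depth <- .generation_depth(ped)
  ord <- order(depth)                     # parents before children
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (ii in seq_len(n)) {
    i <- ord[ii]
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 + 0.5 * K[fa[i], mo[i]]
    }
    if (ii > 1) for (jj in seq_len(ii - 1L)) {
      j <- ord[jj]
      K[i, j] <- K[j, i] <-
        if (is.na(fa[i])) 0 else 0.5 * (K[fa[i], j] + K[mo[i], j])
    }
  }
  K
}

## classed error helper used across the package
jx_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "jx_error")))
}
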