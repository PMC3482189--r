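# ---- Fitch scoring (bitmask implementation) ---------------------------------

# states as bitmasks over k <= 30 states; missing = full set
.state_masks <- function(X, k) {
  full <- bitwShiftL(1L, k) - 1L
  M <- matrix(full, nrow(X), ncol(X), dimnames = dimnames(X))
  obs <- !is.na(X)
  M[obs] <- bitwShiftL(1L, X[obs] - 1L)
  M
}

# vectorised Fitch down-pass over all columns at once; polytomies by
# sequential pairwise set combination
.fitch_pass <- function(tree, M) {
  nnode <- max(tree$edge)
  npat <- ncol(M)
  sets <- vector("list", nnode)
  sets[seq_len(nrow(M))] <- lapply(seq_len(nrow(M)), function(i) M[i, ])
  score <- rep(0L, npat)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    cs <- sets[[child]]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- cs
    } else {
      inter <- bitwAnd(sets[[parent]], cs)
      empty <- inter == 0L
      inter[empty] <- bitwOr(sets[[parent]], cs)[empty]
      score <- score + empty
      sets[[parent]] <- inter
    }
  }
  list(sets = sets, score = score)
}

#' Fitch parsimony score of one character column
#'
#' Minimum number of state changes on the tree under unordered parsimony
#' (Fitch down-pass on an arbitrary rooting; missing tips contribute the
#' full state set; polytomies are handled by sequential pairwise set
#' combination).
#'
#' @param tree `ape::phylo`; its tips must cover the column's taxa.
#' @param column named vector of 1-based state indices (NA = missing),
#'   names = taxa, or an unnamed vector in `tree$tip.label` order.
#' @param k state count; defaults to the largest observed state.
#' @return integer score.  An all-missing column scores 0 with a warning.
#' @export
fitch_score <- function(tree, column, k = NULL) {
  X <- .column_to_matrix(tree, column)
  if (all(is.na(X))) {
    warning("all-missing character column")
    return(0L)
  }
  if (is.null(k)) k <- max(X, na.rm = TRUE)
  as.integer(.fitch_pass(tree, .state_masks(X, k))$score)
}

.column_to_matrix <- function(tree, column) {
  if (!is.null(names(column))) {
    miss <- setdiff(tree$tip.label, names(column))
    full <- stats::setNames(rep(NA_integer_, length(tree$tip.label)),
                            tree$tip.label)
    full[names(column)[names(column) %in% tree$tip.label]] <-
      column[names(column) %in% tree$tip.label]
    column <- full
  } else if (length(column) != length(tree$tip.label)) {
    stop("unnamed column must have one state per tip")
  } else names(column) <- tree$tip.label
  matrix(as.integer(column), ncol = 1L, dimnames = list(names(column), NULL))
}

#' Total Fitch length of a character matrix
#'
#' @param tree `ape::phylo`.
#' @param X integer matrix of 1-based states (taxa x characters, NA =
#'   missing) or a [structure_alignment()].
#' @param k state count (defaults to max observed).
#' @param weights optional per-column multiplicities.
#' @return total weighted parsimony length (integer-valued numeric).
#' @export
fitch_length <- function(tree, X, k = NULL, weights = NULL) {
  X <- .as_state_matrix(X, k)
  X <- .match_tips(tree, X)
  if (is.null(k)) k <- max(X, 1L, na.rm = TRUE)
  cp <- .compress_patterns(X)
  sc <- .fitch_pass(tree, .state_masks(cp$X, k))$score
  w <- if (is.null(weights)) cp$weights else {
    # recompress with external weights
    key <- apply(X, 2L, paste, collapse = "\r")
    as.vector(tapply(weights, factor(key, levels = unique(key)), sum))
  }
  sum(sc * w)
}

# ---- Sankoff dynamic programming (exact MPR state sets) ---------------------

# Down-pass cost vectors under unit change cost; handles polytomies and
# missing tips exactly.
.sankoff_down <- function(tree, X, k) {
  nnode <- max(tree$edge)
  C <- matrix(0, nnode, k)
  for (i in seq_len(nrow(X))) {
    if (is.na(X[i, 1L])) C[i, ] <- 0
    else {
      C[i, ] <- Inf
      C[i, X[i, 1L]] <- 0
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    C[parent, ] <- C[parent, ] + pmin(C[child, ], 1 + min(C[child, ]))
  }
  C
}

#' Most-parsimonious ancestral state sets of one character
#'
#' For every internal node, the set of states that occur in at least one
#' most-parsimonious reconstruction (computed exactly by Sankoff
#' dynamic programming with an up-pass, so polytomies and missing tips
#' are handled without approximation).
#'
#' @inheritParams fitch_score
#' @return list with `sets` (list over internal nodes, each an integer
#'   vector of 1-based states; names are ape node numbers), `score`
#'   (the minimum total changes), and `node_cost` (internal-node x state
#'   matrix of minimal total tree length with the node fixed to each
#'   state).
#' @export
mpr_sets <- function(tree, column, k = NULL) {
  X <- .column_to_matrix(tree, column)
  if (is.null(k)) k <- max(X, 1L, na.rm = TRUE)
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  C <- .sankoff_down(tree, X, k)
  # children lists
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  U <- matrix(NA_real_, nnode, k)
  root <- ntip + 1L
  U[root, ] <- 0
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]   # preorder
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1L]; child <- pre[e, 2L]
    sibs <- setdiff(kids[[as.character(parent)]], child)
    A <- U[parent, ]
    for (w in sibs) A <- A + pmin(C[w, ], 1 + min(C[w, ]))
    U[child, ] <- pmin(A, 1 + min(A))
  }
  total <- C + U
  internal <- (ntip + 1L):nnode
  score <- min(total[root, ])
  sets <- lapply(internal, function(v) which(total[v, ] <= min(total[v, ]) + 1e-9))
  names(sets) <- internal
  list(sets = sets, score = score,
       node_cost = total[internal, , drop = FALSE])
}
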