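# ---- data normalisation -----------------------------------------------------

# Coerce supported data representations to an integer matrix of 1-based
# state indices (taxa x sites, NA = missing data).
.as_state_matrix <- function(data, k = NULL) {
  if (inherits(data, "structure_alignment")) {
    X <- data$codes + 1L
    rownames(X) <- data$taxa
    return(X)
  }
  if (is.matrix(data) && is.numeric(data)) {
    X <- data
    storage.mode(X) <- "integer"
    return(X)
  }
  if (is.matrix(data) && is.character(data)) {
    up <- toupper(data)
    X <- matrix(.base_index(up) + 1L, nrow(data), dimnames = dimnames(data))
    bad <- unique(up[is.na(X) & !.is_missing_char(up)])
    if (length(bad))
      stop("unknown residue characters: ", paste(bad, collapse = " "))
    return(X)
  }
  if (is.character(data)) return(.as_state_matrix(.as_char_matrix(data)))
  stop("unsupported data representation")
}

# site pattern compression: unique columns and their multiplicities
.compress_patterns <- function(X) {
  key <- apply(X, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  list(X = X[, first, drop = FALSE],
       weights = as.vector(table(key)[key[first]]))
}

# tip partial likelihoods: k x npat matrix per tip; missing = ones
.tip_partials <- function(X, k) {
  lapply(seq_len(nrow(X)), function(i) {
    P <- matrix(0, k, ncol(X))
    obs <- !is.na(X[i, ])
    P[cbind(X[i, obs], which(obs))] <- 1
    P[, !obs] <- 1
    P
  })
}

# align data rows to tree tip labels, erroring informatively
.match_tips <- function(tree, X) {
  missing_in_data <- setdiff(tree$tip.label, rownames(X))
  if (length(missing_in_data))
    stop("taxa in tree but not in data: ", paste(missing_in_data, collapse = ", "))
  X[tree$tip.label, , drop = FALSE]
}

# ---- pruning ----------------------------------------------------------------

# Per-pattern log-likelihood under one rate class.  partials: list of
# k x npat tip matrices in tip order.  Returns list(loglik = npat vector).
.prune_class <- function(tree, partials, model, rate) {
  k <- model$k
  npat <- ncol(partials[[1L]])
  nnode <- max(tree$edge)
  edge <- tree$edge
  L <- vector("list", nnode)
  L[seq_along(partials)] <- partials
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    P <- transition_matrix(model, po$edge.length[e], rate)
    contrib <- P %*% L[[child]]
    if (is.null(L[[parent]])) L[[parent]] <- contrib
    else L[[parent]] <- L[[parent]] * contrib
  }
  root <- ape::Ntip(tree) + 1L
  lik <- colSums(model$freqs * L[[root]])
  # partials are rescaled lazily: for the tree sizes used here a single
  # final log suffices unless a pattern underflowed to zero
  if (any(lik <= 0) || any(lik < 1e-280)) {
    # redo with per-node scaling
    L <- vector("list", nnode)
    L[seq_along(partials)] <- partials
    scal <- rep(0, npat)
    for (e in seq_len(nrow(po$edge))) {
      parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
      P <- transition_matrix(model, po$edge.length[e], rate)
      contrib <- P %*% L[[child]]
      if (is.null(L[[parent]])) L[[parent]] <- contrib
      else L[[parent]] <- L[[parent]] * contrib
      mx <- apply(L[[parent]], 2L, max)
      mx[mx == 0] <- 1
      L[[parent]] <- sweep(L[[parent]], 2L, mx, "/")
      scal <- scal + log(mx)
    }
    # scal accumulates extra factors each time a parent is rescaled
    lik <- colSums(model$freqs * L[[root]])
    return(log(lik) + scal)
  }
  log(lik)
}

# per-pattern probability of being an invariant site (for +I)
.invariant_pattern_prob <- function(X, model) {
  npat <- ncol(X)
  out <- numeric(npat)
  for (p in seq_len(npat)) {
    states <- X[, p]
    obs <- unique(states[!is.na(states)])
    if (length(obs) == 0L) out[p] <- 1
    else if (length(obs) == 1L) out[p] <- model$freqs[obs]
    else out[p] <- 0
  }
  out
}

#' Felsenstein-pruning log-likelihood
#'
#' Computes the log-likelihood of aligned discrete data on a phylogeny
#' under a reversible k-state model, summing over discrete-gamma rate
#' categories and the invariant-site class when the model carries them.
#' Missing symbols contribute partial-likelihood vectors of ones; site
#' patterns are compressed internally (which does not change the value).
#'
#' @param tree an `ape::phylo` tree with branch lengths; may be rooted or
#'   unrooted and may contain polytomies.
#' @param data a [structure_alignment()], an integer matrix of 1-based
#'   states (NA missing), a character nucleotide matrix, or named
#'   nucleotide strings.  Rows are matched to tip labels.
#' @param model a `submodel` from [build_model()]; `model$k` must match
#'   the data alphabet.
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, data, model) {
  X <- .as_state_matrix(data, model$k)
  if (ncol(X) == 0L) stop("zero-length alignment")
  kmax <- suppressWarnings(max(X, na.rm = TRUE))
  if (is.finite(kmax) && kmax > model$k)
    stop("data contain state ", kmax, " but model has k = ", model$k)
  X <- .match_tips(tree, X)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  cp <- .compress_patterns(X)
  partials <- .tip_partials(cp$X, model$k)
  rc <- .rate_classes(model)
  # gamma rates are mean-1; under +I the variable-class rates are used
  # as-is (branch lengths absorb the overall scale)
  ll_class <- vapply(rc$rates, function(r)
    .prune_class(tree, partials, model, r),
    numeric(ncol(cp$X)))
  ll_class <- matrix(ll_class, ncol = length(rc$rates))
  mx <- apply(ll_class, 1L, max)
  lik_var <- rowSums(exp(ll_class - mx) * rep(rc$weights, each = nrow(ll_class)))
  if (model$p_inv > 0) {
    inv <- .invariant_pattern_prob(cp$X, model)
    site_l <- (1 - model$p_inv) * lik_var * exp(mx) + model$p_inv * inv
    return(sum(cp$weights * log(site_l)))
  }
  sum(cp$weights * (log(lik_var) + mx))
}
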