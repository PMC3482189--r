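# Independent brute-force oracles: exhaustive enumeration over ancestral
# state assignments.  Deliberately written against the raw edge matrix,
# sharing no code path with the package's pruning/Sankoff machinery.

# log-likelihood by explicit summation over all internal-node states,
# mixing over rate classes with the given weights
brute_loglik <- function(tree, X, model, rates = 1, weights = 1) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  k <- model$k
  internal <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  lik_site <- function(site, rate) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(model, tree$edge.length[e], rate))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[internal] <- grid[g, ]
      st[1:ntip] <- X[tree$tip.label, site]
      p <- model$freqs[st[ntip + 1L]]
      for (e in seq_len(nrow(tree$edge))) {
        ch <- st[tree$edge[e, 2L]]
        if (is.na(ch)) next           # missing tip: row sums to 1
        p <- p * Ps[[e]][st[tree$edge[e, 1L]], ch]
      }
      tot <- tot + p
    }
    tot
  }
  sum(vapply(seq_len(ncol(X)), function(s)
    log(sum(weights * vapply(rates, function(r) lik_site(s, r), numeric(1L)))),
    numeric(1L)))
}

# minimum change count and per-internal-node MPR state sets by exhaustive
# enumeration
brute_mpr <- function(tree, col, k) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  internal <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  tipst <- col[tree$tip.label]
  costs <- apply(grid, 1L, function(g) {
    st <- c(tipst, g)
    sum(apply(tree$edge, 1L, function(e) {
      b <- st[e[2L]]
      if (is.na(b)) 0 else as.integer(st[e[1L]] != b)
    }))
  })
  best <- min(costs)
  sets <- lapply(seq_along(internal), function(i)
    sort(unique(grid[costs == best, i])))
  names(sets) <- internal
  list(sets = sets, score = best)
}

# marginal node probabilities by exhaustive enumeration
brute_marginals <- function(tree, col, k, model, rate) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  internal <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, tree$edge.length[e], rate))
  w <- apply(grid, 1L, function(g) {
    st <- c(col[tree$tip.label], g)
    p <- model$freqs[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      ch <- st[tree$edge[e, 2L]]
      if (is.na(ch)) next
      p <- p * Ps[[e]][st[tree$edge[e, 1L]], ch]
    }
    p
  })
  M <- t(vapply(seq_along(internal), function(i)
    vapply(1:k, function(s) sum(w[grid[, i] == s]), numeric(1L)),
    numeric(k)))
  M / rowSums(M)
}

# split frequency of a taxon subset across trees, by rooting each tree at
# an anchor tip and asking whether the subset is a clade (phangorn's
# Descendants, a code path disjoint from the package's split hashing)
brute_split_freq <- function(trees, subset) {
  anchor <- sort(trees[[1L]]$tip.label)[1L]
  stopifnot(!(anchor %in% subset))
  mean(vapply(trees, function(tr) {
    r <- ape::root(tr, anchor, resolve.root = TRUE)
    desc <- phangorn::Descendants(r, (ape::Ntip(r) + 1L):max(r$edge), "tips")
    any(vapply(desc, function(d)
      setequal(r$tip.label[d], subset), logical(1L)))
  }, logical(1L)))
}

# all unrooted binary topologies on n taxa with seeded random branch lengths
all_topologies <- function(n, labels = paste0("t", seq_len(n)), seed = 1) {
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  withr::with_seed(seed, lapply(trees, function(tr) {
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
    tr
  }))
}
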