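#' Search configuration
#'
#' @param criterion `"ml"` or `"mp"`.
#' @param n_starts number of random-addition starting trees (default 10,
#'   mirroring common parsimony practice).
#' @param seed integer seed; every stochastic step derives from it.
#' @param bootstrap_replicates replicate count for [bootstrap_trees()]
#'   (defaults: 100 for ML, 1000 for MP are the full-analysis settings;
#'   tests and examples use far fewer).
#' @param quick_cycles branch-length optimization cycles used when
#'   screening NNI neighbours under ML (the accepted tree is always
#'   re-optimized fully).
#' @return list of class `search_config`.
#' @export
search_config <- function(criterion = c("ml", "mp"),
                          n_starts = 10L,
                          seed = 1L,
                          bootstrap_replicates = NULL,
                          quick_cycles = 2L) {
  criterion <- match.arg(criterion)
  if (n_starts < 1L) stop("n_starts must be >= 1")
  if (is.null(bootstrap_replicates))
    bootstrap_replicates <- if (criterion == "ml") 100L else 1000L
  if (bootstrap_replicates < 0L) stop("bootstrap_replicates must be >= 0")
  structure(list(criterion = criterion, n_starts = as.integer(n_starts),
                 seed = as.integer(seed),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 quick_cycles = as.integer(quick_cycles)),
            class = "search_config")
}

# data -> phangorn phyDat over an explicit k-state alphabet
.as_phydat <- function(X, k) {
  lv <- as.character(seq_len(k))
  M <- matrix(lv[X], nrow(X), dimnames = dimnames(X))
  M[is.na(M)] <- "?"
  phangorn::phyDat(M, type = "USER", levels = lv, ambiguity = "?")
}

# one seeded random-addition parsimony starting tree
.random_addition_start <- function(X, k, seed) {
  pd <- .as_phydat(X, k)
  tr <- withr::with_seed(seed, phangorn::random.addition(pd))
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr
}

# NNI hill-climb under parsimony; returns list(tree, score)
.climb_mp <- function(tree, X, k, max_rounds = 50L) {
  score <- fitch_length(tree, X, k)
  for (r in seq_len(max_rounds)) {
    nb <- phangorn::nni(tree)
    sc <- vapply(nb, function(tr) fitch_length(tr, X, k), numeric(1L))
    if (min(sc) < score) {
      tree <- nb[[which.min(sc)]]
      tree$edge.length <- rep(0.1, nrow(tree$edge))
      score <- min(sc)
    } else break
  }
  list(tree = tree, score = score)
}

# NNI hill-climb under likelihood; returns list(tree, score = lnL).
# Moves are evaluated with capped branch-length passes; only the final
# tree gets the full-tolerance optimization that produces the reported
# score.
.climb_ml <- function(tree, X, model, quick_cycles = 2L, max_rounds = 25L) {
  fit <- optimize_fit(tree, X, model, "branch_lengths",
                      tol = 1e-4, max_cycles = 8L)
  tree <- fit$tree; lnl <- fit$logLik
  for (r in seq_len(max_rounds)) {
    nb <- phangorn::nni(tree)
    improved <- FALSE
    quick <- vapply(nb, function(tr) {
      tr$edge.length <- rep(mean(tree$edge.length), nrow(tr$edge))
      optimize_fit(tr, X, model, "branch_lengths",
                   tol = 1e-3, max_cycles = quick_cycles)$logLik
    }, numeric(1L))
    for (i in order(quick, decreasing = TRUE)[1L]) {
      if (quick[i] > lnl + 1e-6) {
        cand <- nb[[i]]
        cand$edge.length <- rep(mean(tree$edge.length), nrow(cand$edge))
        fit <- optimize_fit(cand, X, model, "branch_lengths",
                            tol = 1e-4, max_cycles = 8L)
        if (fit$logLik > lnl + 1e-6) {
          tree <- fit$tree; lnl <- fit$logLik; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  fit <- optimize_fit(tree, X, model, "branch_lengths")
  list(tree = fit$tree, score = fit$logLik)
}

#' Heuristic tree search by maximum likelihood or parsimony
#'
#' For each seeded random-addition starting tree, hill-climbs through
#' NNI rearrangements until no neighbour improves the criterion, then
#' returns the best tree(s) over all starts (ties by topology are all
#' retained).
#'
#' @param data a [structure_alignment()], integer state matrix, or
#'   nucleotide character matrix/strings.
#' @param model a `submodel` (required for `criterion = "ml"`; ignored
#'   for `"mp"`).
#' @param config a [search_config()].
#' @param k state count override (defaults to `model$k` or max observed).
#' @return list with `trees` (list of `phylo`, best first), `tree` (the
#'   single best), `score` (lnL for ML, total changes for MP),
#'   `criterion`, and `start_scores`.
#' @export
search_trees <- function(data, model = NULL, config = search_config("mp"),
                         k = NULL) {
  X <- .as_state_matrix(data, k)
  if (nrow(X) < 4L) stop("tree search needs at least 4 taxa")
  if (is.null(k)) k <- if (!is.null(model)) model$k else max(X, na.rm = TRUE)
  if (config$criterion == "ml" && is.null(model))
    stop("ML search needs a model")
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max %/% 2L,
                                       config$n_starts))
  results <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    start <- .random_addition_start(X, k, seeds[s])
    results[[s]] <- if (config$criterion == "mp")
      .climb_mp(start, X, k)
    else
      .climb_ml(start, X, model, config$quick_cycles)
  }
  scores <- vapply(results, `[[`, numeric(1L), "score")
  best <- if (config$criterion == "mp") min(scores) else max(scores)
  tol <- if (config$criterion == "mp") 0.5 else 1e-4
  hit <- which(abs(scores - best) <= tol)
  trees <- lapply(results[hit], `[[`, "tree")
  # deduplicate topologies among ties
  if (length(trees) > 1L) {
    keep <- rep(TRUE, length(trees))
    for (i in seq_along(trees)[-1L])
      for (j in seq_len(i - 1L))
        if (keep[j] && robinson_foulds(trees[[i]], trees[[j]]) == 0) {
          keep[i] <- FALSE; break
        }
    trees <- trees[keep]
  }
  list(trees = trees, tree = trees[[1L]], score = best,
       criterion = config$criterion, start_scores = scores)
}

#' Nonparametric bootstrap over sites
#'
#' Resamples character sites (columns; one stem pair is a single
#' resampling unit in recoded data) with replacement, reruns the search
#' on each pseudo-replicate, and returns one best tree per replicate.
#' Fully reproducible from `config$seed`.
#'
#' @inheritParams search_trees
#' @param n_starts_per_replicate random-addition starts per replicate
#'   (default 2; replicate searches are conventionally shallower than
#'   the main search).
#' @return list of `phylo` trees, one per replicate.
#' @export
bootstrap_trees <- function(data, model = NULL,
                            config = search_config("mp"),
                            k = NULL, n_starts_per_replicate = 2L) {
  X <- .as_state_matrix(data, k)
  if (is.null(k)) k <- if (!is.null(model)) model$k else max(X, na.rm = TRUE)
  B <- config$bootstrap_replicates
  if (B < 1L) stop("bootstrap needs at least 1 replicate")
  plan <- withr::with_seed(config$seed, {
    lapply(seq_len(B), function(b)
      list(cols = sample.int(ncol(X), ncol(X), replace = TRUE),
           seed = sample.int(.Machine$integer.max %/% 2L, 1L)))
  })
  lapply(plan, function(p) {
    cfg <- search_config(config$criterion, n_starts = n_starts_per_replicate,
                         seed = p$seed, bootstrap_replicates = 0L,
                         quick_cycles = config$quick_cycles)
    search_trees(X[, p$cols, drop = FALSE], model = model, config = cfg,
                 k = k)$tree
  })
}

# ---- splits and consensus ---------------------------------------------------

# canonical bipartition keys of a tree's internal edges; anchor taxon is
# excluded from every key so keys are rooting-independent
.split_keys <- function(tree, anchor) {
  ntip <- ape::Ntip(tree)
  tips_below <- .tips_below(tree)
  internal_children <- tree$edge[tree$edge[, 2L] > ntip, 2L]
  keys <- vapply(internal_children, function(v) {
    side <- tips_below[[v]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "|")
  }, character(1L))
  stats::setNames(keys, internal_children)
}

.tips_below <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- max(tree$edge)
  below <- vector("list", nnode)
  below[seq_len(ntip)] <- as.list(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    below[[po$edge[e, 1L]]] <- c(below[[po$edge[e, 1L]]],
                                 below[[po$edge[e, 2L]]])
  below
}

# frequency table of non-trivial splits across a list of trees
.split_frequencies <- function(trees) {
  taxa <- sort(trees[[1L]]$tip.label)
  anchor <- taxa[1L]
  all_keys <- unlist(lapply(trees, function(tr) {
    k <- .split_keys(tr, anchor)
    unique(k[nzchar(k)])   # a rooted tree repeats the root split
  }))
  ntaxa <- length(taxa)
  # drop trivial splits (all remaining taxa = full set minus anchor)
  sizes <- lengths(strsplit(all_keys, "|", fixed = TRUE))
  all_keys <- all_keys[sizes >= 2L & sizes <= ntaxa - 2L]
  table(all_keys) / length(trees)
}

#' Majority-rule consensus or support annotation
#'
#' Without `annotate_onto`, returns the >= 50% majority-rule consensus of
#' the input trees with each retained split's frequency (as a percentage)
#' in the node labels.  With `annotate_onto`, returns that tree with each
#' of its internal edges labelled by the percentage of input trees
#' containing the corresponding split.
#'
#' @param trees list of `phylo` on identical taxon sets.
#' @param annotate_onto optional `phylo` to annotate instead of building
#'   a consensus.
#' @return a `phylo` whose `node.label` carries support percentages in
#'   [0, 100] (empty at the root).
#' @export
majority_consensus <- function(trees, annotate_onto = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), taxa))
      stop("trees carry different taxon sets")
  freq <- .split_frequencies(trees)
  target <- annotate_onto
  if (is.null(target)) {
    target <- ape::consensus(trees, p = 0.5, rooted = FALSE)
    if (is.null(target$edge.length))
      target$edge.length <- rep(1, nrow(target$edge))
  } else if (!identical(sort(target$tip.label), taxa))
    stop("annotate_onto tree carries a different taxon set")
  keys <- .split_keys(target, taxa[1L])
  ntip <- ape::Ntip(target)
  ntaxa <- length(taxa)
  labels <- rep("", target$Nnode)
  for (i in seq_along(keys)) {
    v <- as.integer(names(keys)[i])
    size <- length(strsplit(keys[i], "|", fixed = TRUE)[[1L]])
    if (size < 2L || size > ntaxa - 2L) next   # trivial split, no support
    f <- freq[keys[i]]
    labels[v - ntip] <- as.character(round(100 * ifelse(is.na(f), 0, f), 1))
  }
  target$node.label <- labels
  target
}

#' Robinson--Foulds distance between two unrooted topologies
#'
#' @param t1,t2 `phylo` trees on the same taxa.
#' @return the RF distance (0 = identical unrooted topologies).
#' @export
robinson_foulds <- function(t1, t2) {
  phangorn::RF.dist(t1, t2)
}
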