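#' Discrete morphological character
#'
#' @param name character name.
#' @param states ordered character vector of state labels (state index
#'   0 is the first label).
#' @param assignments named vector: taxon -> state.  Either 0-based
#'   integer indices or state labels; NA = missing/unknown.
#' @return object of class `morph_character` with `name`, `states`, and
#'   `assignments` (named 0-based integer vector).
#' @export
morph_character <- function(name, states, assignments) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels")
  if (is.null(names(assignments))) stop("assignments must be named by taxon")
  if (is.character(assignments)) {
    idx <- match(assignments, states) - 1L
    bad <- !is.na(assignments) & is.na(idx)
    if (any(bad))
      stop("unknown state label(s): ",
           paste(unique(assignments[bad]), collapse = ", "))
  } else {
    idx <- as.integer(assignments)
    if (any(idx < 0L | idx >= length(states), na.rm = TRUE))
      stop("state indices must lie in 0..", length(states) - 1L)
  }
  names(idx) <- names(assignments)
  structure(list(name = name, states = states, assignments = idx),
            class = "morph_character")
}

#' @export
print.morph_character <- function(x, ...) {
  cat("morph_character '", x$name, "': ", length(x$states), " states, ",
      sum(!is.na(x$assignments)), "/", length(x$assignments),
      " taxa scored\n", sep = "")
  invisible(x)
}

#' Collapse weakly supported internal edges into polytomies
#'
#' Every internal edge whose support is strictly below the threshold is
#' contracted: its children reattach to its parent keeping their own
#' branch lengths (the contracted edge's length is discarded, not
#' redistributed).  Support exactly at the threshold is retained.
#'
#' @param tree `phylo` whose `node.label` holds support percentages on
#'   internal nodes (the root label may be empty).
#' @param threshold_percent collapse strictly-below threshold (default 50).
#' @param unsupported what to do with internal nodes lacking a numeric
#'   label: `"error"` (default) or `"full"` (treat as 100).
#' @return the collapsed `phylo` (possibly multifurcating).
#' @export
collapse_weak_nodes <- function(tree, threshold_percent = 50,
                                unsupported = c("error", "full")) {
  unsupported <- match.arg(unsupported)
  if (is.null(tree$node.label))
    stop("tree carries no support values (node.label is NULL)")
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- seq_len(tree$Nnode) + ntip
  no_label <- is.na(sup) & internal != root
  if (any(no_label)) {
    if (unsupported == "error")
      stop("internal node(s) without numeric support: ",
           paste(which(no_label) + ntip, collapse = ", "),
           " (use unsupported = 'full' to keep them)")
    sup[no_label] <- 100
  }
  drop <- internal[!is.na(sup) & sup < threshold_percent & internal != root]
  if (!length(drop)) return(tree)
  # contract by zeroing the parent edge and collapsing zero-length edges
  work <- tree
  if (is.null(work$edge.length))
    work$edge.length <- rep(1, nrow(work$edge))
  edge_idx <- match(drop, work$edge[, 2L])
  work$edge.length[edge_idx] <- 0
  ape::di2multi(work, tol = 1e-12)
}

# ---- ML marginal reconstruction (Mk model) ----------------------------------

# joint P(data, node = s) for every node via down (D) and above (A)
# partial vectors; single-column data, handles polytomies
.node_joint <- function(tree, X, model, rate = 1) {
  k <- model$k
  nnode <- max(tree$edge)
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  D <- matrix(1, nnode, k)
  for (i in seq_len(ntip)) {
    if (!is.na(X[i, 1L])) {
      D[i, ] <- 0
      D[i, X[i, 1L]] <- 1
    }
  }
  Pmat <- vector("list", nrow(po$edge))
  PD <- matrix(NA_real_, nnode, k)   # (P(t_v) D_v)(parent state), per child v
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    Pmat[[e]] <- transition_matrix(model, po$edge.length[e], rate)
    PD[child, ] <- as.vector(Pmat[[e]] %*% D[child, ])
    D[parent, ] <- D[parent, ] * PD[child, ]
  }
  A <- matrix(NA_real_, nnode, k)
  A[ntip + 1L, ] <- model$freqs
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    # above(child) = t(P) %*% (A(parent) * prod of sibling PD)
    hold <- A[parent, ] * D[parent, ] / PD[child, ]
    # guard 0/0 from zero sibling contributions
    bad <- PD[child, ] == 0
    if (any(bad)) {
      prod_sib <- rep(1, k)
      for (w in po$edge[po$edge[, 1L] == parent, 2L])
        if (w != child) prod_sib <- prod_sib * PD[w, ]
      hold[bad] <- (A[parent, ] * prod_sib)[bad]
    }
    A[child, ] <- as.vector(t(Pmat[[e]]) %*% hold)
  }
  A * D
}

#' Fit the single rate of the Mk model on a fixed tree
#'
#' Maximises the likelihood of one or more independent Mk characters
#' over the shared symmetric rate (a multiplier on the tree's branch
#' lengths; the model is normalised so rate 1 means one expected change
#' per unit branch length).
#'
#' @param tree `phylo` with branch lengths.
#' @param X integer matrix of 1-based states (taxa x characters, NA =
#'   missing).
#' @param k state count.
#' @return list with `rate` and `logLik`.
#' @export
fit_mk_rate <- function(tree, X, k) {
  model <- build_model("poisson", k)
  f <- function(lr) {
    tr <- tree
    tr$edge.length <- tr$edge.length * exp(lr)
    log_likelihood(tr, X, model)
  }
  opt <- stats::optimize(f, log(c(1e-6, 1e3)), maximum = TRUE, tol = 1e-8)
  list(rate = exp(opt$maximum), logLik = opt$objective)
}

#' Marginal ML ancestral states under the Mk model
#'
#' Fits the single symmetric rate of the Markov k-state one-parameter
#' (Mk) model on the given tree (branch lengths fixed, the rate scales
#' them), then computes each internal node's marginal posterior state
#' probabilities.  Missing tips contribute uniform partials; polytomies
#' are handled natively.
#'
#' @param tree `phylo` with branch lengths (typically the
#'   support-collapsed best tree).
#' @param char a [morph_character()]; tips of `tree` not scored in it are
#'   treated as missing.
#' @return object of class `asr_ml`: `node_probs` (internal-node x state
#'   matrix of marginal probabilities, rows named by ape node number,
#'   columns by state label), `rate`, `logLik`, `character`, `tree`.
#' @export
mk_asr_ml <- function(tree, char) {
  stopifnot(inherits(char, "morph_character"))
  k <- length(char$states)
  X <- .char_matrix(tree, char)
  model <- build_model("poisson", k = k)
  obs <- X[!is.na(X)]
  if (length(unique(obs)) <= 1L)
    warning("character is constant across scored tips; reconstruction is degenerate")
  if (is.null(tree$edge.length) || all(tree$edge.length == 0))
    tree$edge.length <- rep(1e-8, nrow(tree$edge))
  f <- function(lr) {
    tr <- tree
    tr$edge.length <- tr$edge.length * exp(lr)
    log_likelihood(tr, X, model)
  }
  opt <- stats::optimize(f, log(c(1e-6, 1e3)), maximum = TRUE, tol = 1e-8)
  rate <- exp(opt$maximum)
  joint <- .node_joint(tree, X, model, rate)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):max(tree$edge)
  probs <- joint[internal, , drop = FALSE]
  probs <- probs / rowSums(probs)
  dimnames(probs) <- list(internal, char$states)
  structure(list(node_probs = probs, rate = rate, logLik = opt$objective,
                 character = char, tree = tree),
            class = "asr_ml")
}

#' Most-parsimonious ancestral state sets (Fitch/MP reconstruction)
#'
#' For every internal node, the set of states present in at least one
#' most-parsimonious reconstruction (exact, via Sankoff dynamic
#' programming; polytomies allowed).  Pie fractions are reported as
#' 1/|set| per member state, matching the usual equivocal-node display.
#'
#' @inheritParams mk_asr_ml
#' @return object of class `asr_mp`: `sets` (list, internal-node ->
#'   0-based state indices), `pie` (internal-node x state matrix of
#'   1/|set| fractions), `score` (minimum changes), `character`, `tree`.
#' @export
fitch_asr_mp <- function(tree, char) {
  stopifnot(inherits(char, "morph_character"))
  k <- length(char$states)
  X <- .char_matrix(tree, char)
  col <- stats::setNames(X[, 1L], rownames(X))
  mp <- mpr_sets(tree, col, k)
  pie <- matrix(0, length(mp$sets), k,
                dimnames = list(names(mp$sets), char$states))
  for (i in seq_along(mp$sets))
    pie[i, mp$sets[[i]]] <- 1 / length(mp$sets[[i]])
  sets0 <- lapply(mp$sets, function(s) s - 1L)
  structure(list(sets = sets0, pie = pie, score = mp$score,
                 character = char, tree = tree),
            class = "asr_mp")
}

.char_matrix <- function(tree, char) {
  x <- rep(NA_integer_, length(tree$tip.label))
  names(x) <- tree$tip.label
  hit <- intersect(tree$tip.label, names(char$assignments))
  x[hit] <- char$assignments[hit] + 1L
  matrix(x, ncol = 1L, dimnames = list(names(x), char$name))
}

#' Joint ML + MP ancestral reconstruction with a TSV report
#'
#' Runs [mk_asr_ml()] and [fitch_asr_mp()] on the same tree and
#' character and optionally writes a per-node report: node id, the tips
#' defining the node, ML state probabilities, and the MP state set.
#'
#' @inheritParams mk_asr_ml
#' @param report_path optional TSV output path.
#' @param tree_path optional path for an annotated Newick whose node
#'   labels carry the ML modal state and its probability.
#' @return list with `ml` (`asr_ml`), `mp` (`asr_mp`) and `report`
#'   (data frame).
#' @export
reconstruct_ancestral_states <- function(tree, char, report_path = NULL,
                                         tree_path = NULL) {
  ml <- mk_asr_ml(tree, char)
  mp <- fitch_asr_mp(tree, char)
  below <- .tips_below(tree)
  ntip <- ape::Ntip(tree)
  nodes <- as.integer(rownames(ml$node_probs))
  report <- data.frame(
    node = nodes,
    clade = vapply(nodes, function(v) paste(sort(below[[v]]), collapse = ","),
                   character(1L)),
    stringsAsFactors = FALSE
  )
  for (j in seq_along(char$states))
    report[[paste0("ml_p_", char$states[j])]] <- round(ml$node_probs[, j], 6)
  report$mp_set <- vapply(mp$sets, function(s)
    paste(char$states[s + 1L], collapse = "|"), character(1L))
  if (!is.null(report_path))
    utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(tree_path)) {
    annotated <- tree
    modal <- apply(ml$node_probs, 1L, which.max)
    annotated$node.label <- sprintf("%s=%.3f", char$states[modal],
                                    ml$node_probs[cbind(seq_along(modal), modal)])
    ape::write.tree(annotated, tree_path)
  }
  list(ml = ml, mp = mp, report = report)
}
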