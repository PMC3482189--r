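# ---- cached machinery for repeated likelihood evaluation --------------------

# down (D), above (A) and through-edge (PD) partials for one rate class,
# over a postorder-sorted tree.  A[[v]] * D[[v]] column-sums give the
# per-pattern likelihood; H = A[[u]] * D[[u]] / PD[[v]] is the whole-tree
# context of edge (u, v) and does not depend on that edge's length.
.updown <- function(po, ntip, partials, model, rate) {
  nE <- nrow(po$edge)
  nnode <- max(po$edge)
  npat <- ncol(partials[[1L]])
  D <- vector("list", nnode)
  D[seq_len(ntip)] <- partials
  PD <- vector("list", nnode)
  P <- vector("list", nE)
  for (e in seq_len(nE)) {
    pa <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    P[[e]] <- transition_matrix(model, po$edge.length[e], rate)
    PD[[ch]] <- P[[e]] %*% D[[ch]]
    D[[pa]] <- if (is.null(D[[pa]])) PD[[ch]] else D[[pa]] * PD[[ch]]
  }
  A <- vector("list", nnode)
  A[[ntip + 1L]] <- matrix(model$freqs, model$k, npat)
  for (e in rev(seq_len(nE))) {
    pa <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    H <- A[[pa]] * D[[pa]] / pmax(PD[[ch]], 1e-300)
    A[[ch]] <- crossprod(P[[e]], H)
  }
  list(D = D, A = A, PD = PD)
}

# combine per-class per-pattern likelihoods into the total lnL
.combine_site_lik <- function(lik_classes, weights, p_inv, inv, pat_w) {
  lik <- as.vector(lik_classes %*% weights)
  if (p_inv > 0) lik <- (1 - p_inv) * lik + p_inv * inv
  sum(pat_w * log(lik))
}

# total lnL from a list of per-class up/down caches
.lnl_from_ud <- function(ud_list, root, model, rc, inv, pat_w) {
  lik_classes <- vapply(ud_list, function(ud)
    colSums(model$freqs * ud$D[[root]]), numeric(length(pat_w)))
  .combine_site_lik(matrix(lik_classes, ncol = length(rc$rates)),
                    rc$weights, model$p_inv, inv, pat_w)
}

#' Optimize branch lengths and model parameters by maximum likelihood
#'
#' Coordinate-wise optimization: each branch length in turn (each a
#' bounded univariate problem solved against cached edge partials), then
#' the gamma shape, invariant proportion and/or frequencies if freed;
#' cycles repeat until the log-likelihood improves by less than `tol` or
#' `max_cycles` cycles have run.  The returned log-likelihood is never
#' below the starting one.
#'
#' Branch lengths are bounded to [1e-8, 20] expected substitutions per
#' site.  Frequencies are optimized on a softmax parameterisation with
#' Nelder--Mead (practical only for small k).
#'
#' @param tree `ape::phylo` starting tree (branch lengths required; they
#'   are the starting values).
#' @param data data as accepted by [log_likelihood()].
#' @param model a `submodel`.
#' @param free character vector, subset of `c("branch_lengths", "alpha",
#'   "p_inv", "frequencies")`.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param max_cycles maximum optimization cycles (default 100).
#' @return list with `tree`, `model`, `logLik`, `cycles`, and `trace`
#'   (the log-likelihood after each cycle, non-decreasing).
#' @export
optimize_fit <- function(tree, data, model,
                         free = "branch_lengths",
                         tol = 1e-6, max_cycles = 100L) {
  free <- match.arg(free, c("branch_lengths", "alpha", "p_inv", "frequencies"),
                    several.ok = TRUE)
  X <- .as_state_matrix(data, model$k)
  X <- .match_tips(tree, X)
  if (ncol(X) == 0L) stop("zero-length alignment")
  cp <- .compress_patterns(X)
  partials <- .tip_partials(cp$X, model$k)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L

  refresh <- function(model) {
    rc <- .rate_classes(model)
    inv <- if (model$p_inv > 0) .invariant_pattern_prob(cp$X, model) else NULL
    ud <- lapply(rc$rates, function(r) .updown(po, ntip, partials, model, r))
    list(rc = rc, inv = inv, ud = ud)
  }
  st <- refresh(model)
  ll <- .lnl_from_ud(st$ud, root, model, st$rc, st$inv, cp$weights)
  if (!is.finite(ll)) stop("non-finite log-likelihood at starting values")
  trace <- ll

  for (cycle in seq_len(max_cycles)) {
    if ("branch_lengths" %in% free) {
      for (e in seq_len(nrow(po$edge))) {
        ch <- po$edge[e, 2L]
        pa <- po$edge[e, 1L]
        H <- lapply(st$ud, function(ud)
          ud$A[[pa]] * ud$D[[pa]] / pmax(ud$PD[[ch]], 1e-300))
        Dv <- lapply(st$ud, function(ud) ud$D[[ch]])
        obj <- function(t) {
          lik <- vapply(seq_along(st$rc$rates), function(r)
            colSums(H[[r]] * (transition_matrix(model, t, st$rc$rates[r]) %*%
                                Dv[[r]])),
            numeric(length(cp$weights)))
          .combine_site_lik(matrix(lik, ncol = length(st$rc$rates)),
                            st$rc$weights, model$p_inv, st$inv, cp$weights)
        }
        opt <- stats::optimize(obj, c(1e-8, 20), maximum = TRUE, tol = 1e-7)
        if (opt$objective > ll) {
          po$edge.length[e] <- opt$maximum
          ll <- opt$objective
          st$ud <- lapply(st$rc$rates, function(r)
            .updown(po, ntip, partials, model, r))
        }
      }
    }
    if ("alpha" %in% free) {
      f <- function(la) {
        m <- .finish_model(model$kind, model$k, model$S, model$freqs,
                           exp(la), model$n_categories, model$p_inv)
        s <- refresh(m)
        .lnl_from_ud(s$ud, root, m, s$rc, s$inv, cp$weights)
      }
      opt <- stats::optimize(f, log(c(0.02, 100)), maximum = TRUE, tol = 1e-6)
      if (opt$objective > ll) {
        model <- .finish_model(model$kind, model$k, model$S, model$freqs,
                               exp(opt$maximum), model$n_categories, model$p_inv)
        st <- refresh(model)
        ll <- opt$objective
      }
    }
    if ("p_inv" %in% free) {
      f <- function(p) {
        m <- .finish_model(model$kind, model$k, model$S, model$freqs,
                           model$gamma_alpha, model$n_categories, p)
        s <- refresh(m)
        .lnl_from_ud(s$ud, root, m, s$rc, s$inv, cp$weights)
      }
      opt <- stats::optimize(f, c(0, 0.99), maximum = TRUE, tol = 1e-6)
      if (opt$objective > ll) {
        model <- .finish_model(model$kind, model$k, model$S, model$freqs,
                               model$gamma_alpha, model$n_categories,
                               opt$maximum)
        st <- refresh(model)
        ll <- opt$objective
      }
    }
    if ("frequencies" %in% free) {
      f <- function(w) {
        fr <- exp(w - max(w)); fr <- fr / sum(fr)
        m <- .finish_model(model$kind, model$k, model$S, fr,
                           model$gamma_alpha, model$n_categories, model$p_inv)
        s <- refresh(m)
        -.lnl_from_ud(s$ud, root, m, s$rc, s$inv, cp$weights)
      }
      opt <- stats::optim(log(model$freqs), f, method = "Nelder-Mead",
                          control = list(maxit = 200L))
      if (-opt$value > ll) {
        fr <- exp(opt$par - max(opt$par)); fr <- fr / sum(fr)
        model <- .finish_model(model$kind, model$k, model$S, fr,
                               model$gamma_alpha, model$n_categories,
                               model$p_inv)
        st <- refresh(model)
        ll <- -opt$value
      }
    }
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol) break
  }
  # map optimized lengths back onto the input tree's edge order
  key_po <- paste(po$edge[, 1L], po$edge[, 2L])
  key_in <- paste(tree$edge[, 1L], tree$edge[, 2L])
  tree$edge.length <- po$edge.length[match(key_in, key_po)]
  list(tree = tree, model = model, logLik = ll, cycles = cycle, trace = trace)
}
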