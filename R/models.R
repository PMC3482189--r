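#' Build a k-state reversible substitution model
#'
#' Constructs a continuous-time Markov model on k states from an
#' exchangeability structure and equilibrium frequencies, normalised so
#' that one unit of branch length equals one expected substitution per
#' site at equilibrium.  Optional among-site rate variation: a
#' discrete-gamma distribution (`gamma_alpha`, `n_categories`) and/or a
#' proportion of invariant sites (`p_inv`).
#'
#' @param kind `"poisson"` (all exchangeabilities equal; with equal
#'   frequencies this is the Jukes--Cantor/Mk family), `"gtr"` (free
#'   symmetric exchangeabilities), or `"fixed_exchangeability"` (a
#'   published table, e.g. LG, supplied via `exchangeabilities`).
#' @param k state count (4 for nucleotides, 20 for the structure code).
#' @param frequencies `"equal"`, `"empirical"` (counted from `data`,
#'   missing cells excluded, pooled over the whole matrix), or a
#'   length-k numeric simplex.
#' @param data optional data (a [structure_alignment()] or integer/
#'   character matrix) used when `frequencies = "empirical"`.
#' @param exchangeabilities symmetric k x k matrix of nonnegative
#'   exchangeabilities, or a path to a PAML-style table
#'   (see [read_paml_exchangeability()]); required for
#'   `kind = "fixed_exchangeability"`, optional starting values for
#'   `"gtr"`.
#' @param gamma_alpha optional positive gamma shape for rate variation.
#' @param n_categories number of discrete gamma categories (default 4).
#' @param p_inv optional invariant-site proportion in [0, 1).
#' @return object of class `submodel`: `k`, `kind`, `Q` (normalised rate
#'   matrix), `freqs`, `S` (exchangeabilities), eigen system for fast
#'   matrix exponentials, and the rate-variation settings.
#' @export
build_model <- function(kind = c("poisson", "gtr", "fixed_exchangeability"),
                        k,
                        frequencies = "equal",
                        data = NULL,
                        exchangeabilities = NULL,
                        gamma_alpha = NULL,
                        n_categories = 4L,
                        p_inv = NULL) {
  kind <- match.arg(kind)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")

  if (is.character(exchangeabilities) && length(exchangeabilities) == 1L) {
    tab <- read_paml_exchangeability(exchangeabilities, k)
    exchangeabilities <- tab$exchangeabilities
    if (identical(frequencies, "file")) {
      if (is.null(tab$frequencies)) stop("exchangeability file carries no frequencies")
      frequencies <- tab$frequencies
    }
  }
  S <- switch(kind,
    poisson = matrix(1, k, k),
    gtr = if (is.null(exchangeabilities)) matrix(1, k, k) else exchangeabilities,
    fixed_exchangeability = {
      if (is.null(exchangeabilities))
        stop("kind = 'fixed_exchangeability' needs an exchangeability table")
      exchangeabilities
    })
  if (!isTRUE(all.equal(S, t(S))) || any(S < 0))
    stop("exchangeabilities must be symmetric and nonnegative")
  diag(S) <- 0

  freqs <- .resolve_frequencies(frequencies, k, data)
  if (!is.null(gamma_alpha) && gamma_alpha <= 0) stop("gamma_alpha must be > 0")
  if (!is.null(p_inv) && (p_inv < 0 || p_inv >= 1))
    stop("p_inv must lie in [0, 1)")

  .finish_model(kind, k, S, freqs, gamma_alpha, as.integer(n_categories), p_inv)
}

.resolve_frequencies <- function(frequencies, k, data) {
  if (identical(frequencies, "equal")) return(rep(1 / k, k))
  if (identical(frequencies, "empirical")) {
    if (is.null(data)) stop("frequencies = 'empirical' needs data")
    return(empirical_frequencies(data, k))
  }
  f <- as.numeric(frequencies)
  if (length(f) != k || any(f < 0) || abs(sum(f) - 1) > 1e-6)
    stop("frequencies must be a length-", k, " simplex")
  f / sum(f)
}

#' Pooled empirical state frequencies of a data matrix
#'
#' @param data a [structure_alignment()], or an integer matrix of 1-based
#'   state indices (NA = missing), or a character nucleotide matrix.
#' @param k state count.
#' @return length-k frequency vector (missing cells excluded; a pseudo
#'   count of one is spread over states never observed so that no
#'   frequency is exactly zero).
#' @export
empirical_frequencies <- function(data, k) {
  X <- .as_state_matrix(data, k)
  counts <- tabulate(X[!is.na(X)], nbins = k)
  if (any(counts == 0L)) counts <- counts + 1 / k
  counts / sum(counts)
}

.finish_model <- function(kind, k, S, freqs, gamma_alpha, n_categories, p_inv) {
  Q <- S * rep(freqs, each = k)     # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))       # expected rate at equilibrium
  if (mu <= 0) stop("degenerate model: zero total rate")
  Q <- Q / mu
  # symmetrise for a stable eigen decomposition: B = D^{1/2} Q D^{-1/2}
  sq <- sqrt(freqs)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  model <- structure(list(
    k = k, kind = kind, S = S, freqs = freqs, Q = Q,
    eigen_values = es$values,
    U = es$vectors / sq,            # row-scaled: P(t) = U diag(e^{lambda t}) Uinv
    Uinv = t(es$vectors) * rep(sq, each = k),
    gamma_alpha = gamma_alpha,
    n_categories = n_categories,
    p_inv = if (is.null(p_inv)) 0 else p_inv
  ), class = "submodel")
  model
}

#' @export
print.submodel <- function(x, ...) {
  cat("submodel:", x$kind, "k =", x$k,
      if (!is.null(x$gamma_alpha)) paste0("+G(", signif(x$gamma_alpha, 4),
                                          ", ", x$n_categories, " cat)") else "",
      if (x$p_inv > 0) paste0("+I(", signif(x$p_inv, 4), ")") else "", "\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model a `submodel`.
#' @param t branch length (expected substitutions per site at rate 1).
#' @param rate rate multiplier (e.g. a gamma category rate).
#' @return k x k stochastic matrix `expm(Q * t * rate)`.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("negative branch length")
  P <- model$U %*% (exp(model$eigen_values * t * rate) * model$Uinv)
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P
}

#' Discrete-gamma rate multipliers
#'
#' Equal-probability discretisation of the Gamma(alpha, alpha)
#' distribution: category rate = mean of its quantile slice, renormalised
#' to mean exactly 1.
#'
#' @param alpha positive shape.
#' @param n_categories number of categories (>= 1).
#' @return numeric vector of `n_categories` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, n_categories = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  n <- as.integer(n_categories)
  if (n < 1L) stop("n_categories must be >= 1")
  if (n == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = n + 1L), shape = alpha, rate = alpha)
  # mean of Gamma(a, a) over (b_i, b_{i+1}] = pgamma(b, a+1, a) difference / prob
  means <- n * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  means / mean(means)
}

# rate classes of a model: list(rates, weights) incl. invariant class
.rate_classes <- function(model) {
  if (!is.null(model$gamma_alpha))
    rates <- discrete_gamma_rates(model$gamma_alpha, model$n_categories)
  else
    rates <- 1
  list(rates = rates, weights = rep(1 / length(rates), length(rates)))
}
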