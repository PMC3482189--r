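test_that("two-state symmetric chain matches its closed form", {
  m <- build_model("poisson", 2)
  for (t in c(0, 0.1, 0.5, 2)) {
    P <- transition_matrix(m, t)
    expect_equal(P[1, 1], 0.5 + 0.5 * exp(-2 * t), tolerance = 1e-12)
  }
  expect_equal(transition_matrix(m, 0), diag(2), tolerance = 1e-12)
})

test_that("equal-everything GTR reproduces the Jukes-Cantor closed form", {
  m <- build_model("gtr", 4)
  for (t in c(0.01, 0.3, 1.5)) {
    P <- transition_matrix(m, t)
    expect_equal(P[1, 1], 0.25 + 0.75 * exp(-4 * t / 3), tolerance = 1e-12)
    expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 * t / 3), tolerance = 1e-12)
  }
})

test_that("models are stochastic, reversible, and unit mean rate", {
  withr::with_seed(11, {
    mods <- list(
      build_model("poisson", 20),
      build_model("gtr", 4, frequencies = c(.1, .2, .3, .4),
                  exchangeabilities = local({
                    S <- matrix(stats::runif(16, .2, 3), 4)
                    (S + t(S)) / 2
                  })),
      build_model("fixed_exchangeability", 3,
                  frequencies = c(.5, .3, .2),
                  exchangeabilities = local({
                    S <- matrix(stats::runif(9, .2, 3), 3)
                    (S + t(S)) / 2
                  }))
    )
  })
  for (m in mods) {
    expect_equal(-sum(m$freqs * diag(m$Q)), 1, tolerance = 1e-12)
    for (t in c(0, 0.05, 1, 10)) {
      P <- transition_matrix(m, t)
      expect_equal(rowSums(P), rep(1, m$k), tolerance = 1e-10)
      # detailed balance
      expect_equal(m$freqs * P, t(m$freqs * P), tolerance = 1e-10)
    }
  }
})

test_that("model construction rejects invalid inputs", {
  expect_error(build_model("poisson", 1), "at least 2")
  expect_error(build_model("poisson", 4, frequencies = c(.5, .5, .5, .5)),
               "simplex")
  expect_error(build_model("gtr", 2, exchangeabilities = matrix(c(0, -1, -1, 0), 2)),
               "nonnegative")
  expect_error(build_model("fixed_exchangeability", 4), "needs an exchangeability")
  expect_error(build_model("poisson", 4, gamma_alpha = -1), "gamma_alpha")
  expect_error(build_model("poisson", 4, p_inv = 1), "p_inv")
})

test_that("discrete-gamma rates have mean one and match numerical integration", {
  expect_equal(discrete_gamma_rates(0.5, 1), 1)
  for (alpha in c(0.2, 1, 5)) {
    r <- discrete_gamma_rates(alpha, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_false(is.unsorted(r))
  }
  # independent quantile-integration oracle
  for (alpha in c(0.5, 1, 2)) {
    n <- 4
    b <- stats::qgamma(seq(0, 1, length.out = n + 1), alpha, alpha)
    oracle <- vapply(seq_len(n), function(i) {
      n * stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                           b[i], b[i + 1], rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(discrete_gamma_rates(alpha, n), oracle, tolerance = 1e-6)
  }
  expect_error(discrete_gamma_rates(0, 4), "alpha")
})

test_that("PAML exchangeability tables are read back symmetric", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("2", "3 4", "", "0.4 0.3 0.3"), f)
  tab <- read_paml_exchangeability(f, 3)
  expect_equal(tab$exchangeabilities,
               rbind(c(0, 2, 3), c(2, 0, 4), c(3, 4, 0)))
  expect_equal(tab$frequencies, c(0.4, 0.3, 0.3))
  m <- build_model("fixed_exchangeability", 3,
                   frequencies = tab$frequencies,
                   exchangeabilities = tab$exchangeabilities)
  expect_s3_class(m, "submodel")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  withr::with_seed(3, {
    for (k in c(2, 4, 20)) {
      for (rep in 1:3) {
        n <- sample(4:5, 1)
        tr <- ape::rtree(n)
        tr$tip.label <- paste0("t", 1:n)
        X <- matrix(sample(c(seq_len(k), NA), n * 3, replace = TRUE), n,
                    dimnames = list(tr$tip.label, NULL))
        m <- if (k == 4)
          build_model("gtr", 4, frequencies = c(.1, .2, .3, .4))
        else build_model("poisson", k)
        expect_equal(log_likelihood(tr, X, m), brute_loglik(tr, X, m),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("gamma and invariant classes are mixed correctly", {
  withr::with_seed(4, {
    tr <- ape::rtree(4); tr$tip.label <- paste0("t", 1:4)
    X <- matrix(sample(1:4, 4 * 6, replace = TRUE), 4,
                dimnames = list(tr$tip.label, NULL))
    X[, 6] <- 2L   # ensure a constant pattern for the invariant class
    m <- build_model("poisson", 4, gamma_alpha = 0.7)
    r <- discrete_gamma_rates(0.7, 4)
    expect_equal(log_likelihood(tr, X, m),
                 brute_loglik(tr, X, m, rates = r, weights = rep(1 / 4, 4)),
                 tolerance = 1e-8)
    # +I: mix a zero-rate class explicitly in the oracle
    mi <- build_model("poisson", 4, p_inv = 0.3)
    expect_equal(log_likelihood(tr, X, mi),
                 brute_loglik(tr, X, mi, rates = c(1, 1e-12),
                              weights = c(0.7, 0.3)),
                 tolerance = 1e-6)
  })
})

test_that("likelihood is invariant to re-rooting under reversible models", {
  withr::with_seed(5, {
    tr <- ape::unroot(ape::rtree(6)); tr$tip.label <- paste0("t", 1:6)
    X <- matrix(sample(c(1:4, NA), 6 * 10, replace = TRUE), 6,
                dimnames = list(tr$tip.label, NULL))
    m <- build_model("gtr", 4, frequencies = c(.4, .3, .2, .1))
    base <- log_likelihood(tr, X, m)
    for (tip in c("t2", "t5"))
      expect_equal(log_likelihood(ape::root(tr, tip, resolve.root = TRUE), X, m),
                   base, tolerance = 1e-9)
  })
})

test_that("degenerate and erroneous likelihood inputs are handled", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  m <- build_model("poisson", 4, frequencies = c(.1, .2, .3, .4))
  X <- rbind(a = 3L, b = 3L)
  # zero branch lengths: likelihood collapses to the state frequency
  expect_equal(log_likelihood(tr, X, m), log(0.3), tolerance = 1e-12)
  # a fully missing column contributes nothing
  X2 <- cbind(X, c(NA, NA))
  expect_equal(log_likelihood(tr, X2, m), log(0.3), tolerance = 1e-12)
  expect_error(log_likelihood(tr, rbind(a = 1L, c = 2L), m), "t(axa)? in tree")
  expect_error(log_likelihood(tr, matrix(integer(0), 2, 0,
                                         dimnames = list(c("a", "b"), NULL)), m),
               "zero-length")
})

test_that("pattern compression does not change the likelihood", {
  withr::with_seed(6, {
    tr <- ape::rtree(5); tr$tip.label <- paste0("t", 1:5)
    X <- matrix(sample(c(1:4, NA), 5 * 40, replace = TRUE), 5,
                dimnames = list(tr$tip.label, NULL))
    X <- cbind(X, X[, 1:10])   # force duplicate patterns
    m <- build_model("poisson", 4)
    perm <- sample(ncol(X))
    expect_equal(log_likelihood(tr, X, m), log_likelihood(tr, X[, perm], m),
                 tolerance = 1e-10)
  })
})
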