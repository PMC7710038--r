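test_that("raw rate matrix matches the fixation-rate formula", {
  a2 <- alphabet(c("0", "1"))
  M2 <- uniform_mutation_matrix(a2)

  # equal fitness: q_ij collapses to M_ij, diagonal is -(|A|-1) for uniform M
  Q <- build_raw_rate_matrix(fitness_vector(rep(3.7, 4), NUC),
                             uniform_mutation_matrix(NUC))
  expect_equal(unname(unclass(Q)[row(Q) != col(Q)]), rep(1, 12))
  expect_equal(unname(diag(unclass(Q))), rep(-3, 4))

  # F = (0, 1): direct high-precision evaluation of the formula
  Q <- build_raw_rate_matrix(fitness_vector(c(0, 1), a2), M2)
  expect_equal(unclass(Q)["0", "1"], 1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(unclass(Q)["1", "0"], 1 / (exp(1) - 1), tolerance = 1e-12)

  # equal fitness with non-uniform M: rates are just M_ij
  M <- mutation_matrix(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE), a2)
  Q <- build_raw_rate_matrix(fitness_vector(c(0, 0), a2), M)
  expect_equal(unclass(Q)["0", "1"], 2)
  expect_equal(unclass(Q)["1", "0"], 1)

  # contract errors
  expect_error(build_raw_rate_matrix(fitness_vector(c(0, 1), a2),
                                     uniform_mutation_matrix(NUC)),
               "different alphabets")
  expect_error(fitness_vector(c(0, Inf), a2), "finite")
  expect_error(mutation_matrix(matrix(c(0, -1, 1, 0), 2, 2), a2), ">= 0")
})

test_that("stationary distribution agrees between softmax and linear solve", {
  a2 <- alphabet(c("0", "1"))
  M2 <- uniform_mutation_matrix(a2)

  # flat landscape: uniform by symmetry
  p <- stationary_distribution(fitness_vector(rep(0, 4), NUC),
                               uniform_mutation_matrix(NUC))
  expect_equal(unname(as.numeric(p)), rep(0.25, 4))

  # F = (0, 1): closed-form softmax
  p <- stationary_distribution(fitness_vector(c(0, 1), a2), M2)
  expect_equal(as.numeric(p), c(1 / (1 + exp(1)), exp(1) / (1 + exp(1))),
               tolerance = 1e-12)

  # asymmetric M, equal fitness: solve pi Q = 0 by hand -> (1/3, 2/3)
  M <- mutation_matrix(matrix(c(0, 2, 1, 0), 2, 2, byrow = TRUE), a2)
  F0 <- fitness_vector(c(0, 0), a2)
  p <- stationary_distribution(F0, M, build_raw_rate_matrix(F0, M))
  expect_equal(unname(as.numeric(p)), c(1 / 3, 2 / 3), tolerance = 1e-10)

  # softmax path vs forced linear solve agree for uniform M
  set.seed(11)
  for (rep in 1:20) {
    F <- stats::rlnorm(4, 0, 0.5)
    Qb <- fitscape:::.raw_Q(F, matrix(1, 4, 4))
    expect_equal(fitscape:::.pi_solve(Qb), fitscape:::.pi_softmax(F),
                 tolerance = 1e-10)
  }

  # a disconnected symbol is reported by name
  Mdis <- matrix(1, 3, 3); Mdis[, 3] <- 0; Mdis[3, ] <- 0
  a3 <- alphabet(c("x", "y", "z"))
  expect_error(stationary_distribution(fitness_vector(c(0, 0, 0), a3),
                                       mutation_matrix(Mdis, a3)),
               "z")
})

test_that("rescaling yields unit expected rate; flat scaling divides by |A|-1", {
  Ff <- fitness_vector(rep(0, 4), NUC)
  Mf <- uniform_mutation_matrix(NUC)
  Qraw <- build_raw_rate_matrix(Ff, Mf)
  pif <- stationary_distribution(Ff, Mf, Qraw)

  Qn <- rescale_rate_matrix(Qraw, pif, "normalized")
  expect_equal(unname(unclass(Qn)[1, 2]), 1 / 3)
  expect_equal(unname(diag(unclass(Qn))), rep(-1, 4))

  # for a flat landscape the flat divisor |A|-1 equals the expected rate
  Qs <- rescale_rate_matrix(Qraw, pif, "flat_scaled")
  expect_equal(unclass(Qs), unclass(Qn), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(attr(rescale_rate_matrix(Qraw, pif, "raw"), "scaling_mode"),
                   "raw")

  # F = (0, 1): the normalization divisor is the expected raw rate
  a2 <- alphabet(c("0", "1"))
  F <- fitness_vector(c(0, 1), a2); M <- uniform_mutation_matrix(a2)
  Q <- build_raw_rate_matrix(F, M)
  p <- stationary_distribution(F, M, Q)
  div <- -sum(diag(unclass(Q)) * as.numeric(p))
  expect_equal(div, 0.850918, tolerance = 1e-6)
  Qn2 <- rescale_rate_matrix(Q, p, "normalized")
  expect_equal(unclass(Qn2), unclass(Q) / div, tolerance = 1e-12,
               ignore_attr = TRUE)

  # an all-absorbing matrix cannot be normalized
  Mzero <- mutation_matrix(matrix(0, 2, 2), a2)
  Qz <- build_raw_rate_matrix(fitness_vector(c(0, 0), a2), Mzero)
  expect_error(rescale_rate_matrix(Qz, fixed_pi(c(0.5, 0.5), a2), "normalized"),
               "degenerate|normalize")
})

test_that("algebraic invariants hold across random landscapes", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    ab <- alphabet(letters[seq_len(n)])
    F <- fitness_vector(stats::rnorm(n, 0, 1.5), ab)
    Msym <- matrix(stats::runif(n * n, 0.2, 2), n, n)
    Msym <- mutation_matrix((Msym + t(Msym)) / 2, ab)
    Mu <- uniform_mutation_matrix(ab)

    Qu <- build_raw_rate_matrix(F, Mu)
    Qs <- build_raw_rate_matrix(F, Msym)

    # row sums zero
    expect_lt(max(abs(rowSums(unclass(Qu)))), 1e-10)
    expect_lt(max(abs(rowSums(unclass(Qs)))), 1e-10)

    # skew identity for uniform M: q_ij - q_ji = F_j - F_i
    D <- outer(as.numeric(F), as.numeric(F), function(fi, fj) fj - fi)
    off <- row(D) != col(D)
    expect_equal((unclass(Qu) - t(unclass(Qu)))[off], D[off], tolerance = 1e-10)

    # detailed balance for symmetric M
    p <- stationary_distribution(F, Msym, Qs)
    flux <- as.numeric(p) * unclass(Qs)
    expect_lt(max(abs(flux - t(flux))), 1e-10)

    # pi Q = 0 and normalization invariant
    expect_lt(max(abs(as.numeric(p) %*% unclass(Qs))), 1e-8)
    Qn <- rescale_rate_matrix(Qs, p, "normalized")
    expect_equal(-sum(diag(unclass(Qn)) * as.numeric(p)), 1, tolerance = 1e-10)
  }

  # continuity across the equal-fitness limit
  a2 <- alphabet(c("0", "1"))
  M2 <- uniform_mutation_matrix(a2)
  Qeps <- build_raw_rate_matrix(fitness_vector(c(0, 1e-8), a2), M2)
  expect_equal(unclass(Qeps)["0", "1"], 1, tolerance = 1e-6)
  expect_equal(unclass(Qeps)["1", "0"], 1, tolerance = 1e-6)
})
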