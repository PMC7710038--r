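test_that("root sequences are drawn from the stationary distribution", {
  ctx <- flat_ctx()
  set.seed(8)
  idx <- sample_root_sequence(ctx$pi, 1e5)
  freq <- tabulate(idx, 4) / 1e5
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 1e5)))

  # degenerate distribution
  idx <- sample_root_sequence(fixed_pi(c(1, 0, 0, 0)), 50)
  expect_true(all(idx == 1L))

  # user-supplied root is used verbatim, after validation
  expect_equal(sample_root_sequence(ctx$pi, 4, root_sequence = "ACGT"), 1:4)
  expect_error(sample_root_sequence(ctx$pi, 3, root_sequence = "ACGT"), "length")
  expect_error(sample_root_sequence(ctx$pi, 4, root_sequence = "ACGX"),
               "outside the alphabet")
})

test_that("waiting times and event selection follow the Gillespie rates", {
  # a zero-length branch does nothing
  ctx <- flat_ctx()
  r <- simulate_branch(c(1L, 3L), ctx, 0)
  expect_equal(r$alleles, c(1L, 3L))
  expect_equal(nrow(r$events), 0L)

  # flat normalized 4-letter landscape, branch length 1: the probability the
  # end allele differs from the start is (3/4) * (1 - exp(-4/3))
  set.seed(14)
  n <- 20000
  cnt <- 0L
  for (i in seq_len(n)) {
    a0 <- sample.int(4, 1)
    cnt <- cnt + (simulate_branch(a0, ctx, 1)$alleles != a0)
  }
  p <- (3 / 4) * (1 - exp(-4 / 3))
  expect_lt(abs(cnt / n - p), 4 * sqrt(p * (1 - p) / n))

  # position selection proportional to exit rates (rates 1 vs 3):
  # over a short interval, the substituted position is #2 w.p. 3/4
  a2 <- alphabet(c("0", "1"))
  M3 <- mutation_matrix(matrix(c(0, 1, 3, 0), 2, 2, byrow = TRUE), a2)
  ctx3 <- landscape_context(fitness_vector(c(0, 0), a2), M3, "raw")
  # exit(allele 0) = 1, exit(allele 1) = 3; start state (0, 1)
  set.seed(15)
  hits2 <- 0L; tot <- 0L
  for (i in 1:6000) {
    r <- simulate_branch(c(1L, 2L), ctx3, 0.04)
    ch <- which(r$alleles != c(1L, 2L))
    if (length(ch) == 1L) { tot <- tot + 1L; hits2 <- hits2 + (ch == 2L) }
  }
  expect_lt(abs(hits2 / tot - 3 / 4), 4 * sqrt(0.75 * 0.25 / tot))
})

test_that("single-position transition frequencies match the matrix exponential", {
  ab <- NUC
  F <- fitness_vector(c(0.2, 0.9, 0.4, 1.3), ab)
  ctx <- landscape_context(F, uniform_mutation_matrix(ab), "normalized")
  P <- transition_probability_oracle(ctx$Q, 0.7)
  set.seed(16)
  n <- 10000
  ends <- integer(n)
  for (i in seq_len(n)) ends[i] <- simulate_branch(2L, ctx, 0.7)$alleles
  freq <- tabulate(ends, 4) / n
  se <- sqrt(P[2, ] * (1 - P[2, ]) / n)
  expect_true(all(abs(freq - P[2, ]) < 4 * se))
})

test_that("event times are ordered, in range, and change the context", {
  ctx <- flat_ctx()
  rule <- landscape_rule(init = list(dist = "lognormal", mu = 0, sigma = 0.5),
                         change_rule = "resample")
  set.seed(17)
  for (i in 1:20) {
    r <- simulate_branch(1L, ctx, 2, lambda = 4, rule = rule)
    if (nrow(r$events) > 1L) expect_true(all(diff(r$events$offset) > 0))
    if (nrow(r$events) > 0L) {
      expect_true(all(r$events$offset >= 0 & r$events$offset < 2))
      # the returned context reflects the landscape after the last change
      expect_equal(as.numeric(r$ctx$F),
                   unname(unlist(r$events[nrow(r$events),
                                          paste0("F_", unclass(NUC))])))
    }
  }

  # change-record invariant: global_time = parent's global time + offset
  cfg <- poisson_change_config(simple_tree(), lambda = 3)
  set.seed(18)
  r <- run_simulation(cfg)
  tr <- simple_tree()
  pt <- tr$time[tr$parent[match(r$change_log$branch, tr$names)]]
  expect_equal(r$change_log$global_time, pt + r$change_log$offset)
})

test_that("runs are reproducible and thread-count independent", {
  cfg <- simulation_config(simple_tree(), list(landscape_spec(1:20,
    rule = landscape_rule(init = list(dist = "gamma", shape = 2, scale = 1),
                          change_rule = "resample"),
    regime = change_regime("stochastic", lambda = 0.5))))
  r1 <- run_parallel(cfg, seed = 99, replicates = 6, threads = 1)
  r2 <- run_parallel(cfg, seed = 99, replicates = 6, threads = 3)
  expect_identical(lapply(r1, `[[`, "node_sequences"),
                   lapply(r2, `[[`, "node_sequences"))
  expect_identical(lapply(r1, `[[`, "change_log"),
                   lapply(r2, `[[`, "change_log"))
  # different replicates have different histories
  expect_false(identical(r1[[1]]$node_sequences, r1[[2]]$node_sequences))
})

test_that("deterministic changes recompute the landscape mid-branch", {
  # force a change to a strongly peaked landscape half-way down one branch;
  # the leaf allele should then favour the peak allele
  tr <- parse_newick("A:6;")
  ev <- data.frame(branch = "A", offset = 1)
  ev$fitness <- list(c(4, 0, 0, 0))
  cfg <- simulation_config(tr, list(landscape_spec(1L,
    rule = landscape_rule(init = list(values = rep(0, 4)),
                          change_rule = "explicit",
                          explicit_vectors = list(c(4, 0, 0, 0))),
    regime = change_regime("explicit", events = ev))))
  set.seed(19)
  res <- run_parallel(cfg, seed = 19, replicates = 400)
  leafA <- vapply(res, function(r) r$node_sequences[["A"]], "")
  pA <- exp(4) / (exp(4) + 3)
  expect_lt(abs(mean(leafA == "A") - pA), 4 * sqrt(pA * (1 - pA) / 400))
})
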