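# Shared fixtures: built in code, no files.

NUC <- alphabet(c("A", "C", "G", "T"))

# four-leaf tree with total branch length 8 (the "simple" validation tree)
simple_tree <- function() parse_newick("((A:1.5,B:1.5)E:1,(C:1.5,D:1.5)F:1)G;")

flat_ctx <- function(ab = NUC, scaling = "normalized")
  landscape_context(fitness_vector(rep(0, length(ab)), ab),
                    uniform_mutation_matrix(ab), scaling)

# stochastic-change-only config (sequence length 1) on an arbitrary tree;
# the validation setup: lognormal(0, 0.5) initial landscape, permute rule
poisson_change_config <- function(tree, lambda)
  simulation_config(tree, list(landscape_spec(
    1L,
    rule = landscape_rule(init = list(dist = "lognormal", mu = 0, sigma = 0.5),
                          change_rule = "permute"),
    regime = change_regime("stochastic", lambda = lambda))))

change_counts <- function(results)
  vapply(results, function(r) nrow(r$change_log), 0L)

# manually assembled stationary distribution (for degenerate test cases)
fixed_pi <- function(p, ab = NUC)
  structure(stats::setNames(p, unclass(ab)), alphabet = ab,
            class = "stationary_distribution")
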