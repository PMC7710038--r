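# Synthetic trees and independent oracles used by the validation
# experiments; everything is generated in code, nothing is downloaded.

#' Build a comb (caterpillar) tree
#'
#' A linear spine of internal nodes, each with exactly two children, one of
#' which is a leaf; the terminal internal node carries two leaves. `depth`
#' is the number of generations (the height of the tree in edges); all
#' branches share one length. Internal nodes are named `I1..I<depth>` along
#' the spine, leaves `T1..T<depth+1>`.
#'
#' @param depth number of generations, >= 1 (`depth = 1` is a two-leaf
#'   cherry).
#' @param branch_length common branch length, > 0.
#' @return An `"fs_tree"` with `depth + 1` leaves and total branch length
#'   `2 * depth * branch_length`.
#' @export
make_comb_tree <- function(depth, branch_length = 1) {
  depth <- as.integer(depth)
  stopifnot(depth >= 1L, branch_length > 0)
  b <- format(branch_length, digits = 15)
  s <- sprintf("(T%d:%s,T%d:%s)I%d", depth, b, depth + 1L, b, depth)
  if (depth > 1L)
    for (k in (depth - 1L):1L)
      s <- sprintf("(T%d:%s,%s:%s)I%d", k, b, s, b, k)
  parse_newick(paste0(s, ";"))
}

#' Simulate a pure-birth (Yule) tree
#'
#' A realistic-shape fixture: a birth-death tree with death rate 0,
#' conditioned on the requested number of extant leaves. Uses R's global
#' random number stream.
#'
#' @param n_leaves number of leaves, >= 2.
#' @param rate birth rate, > 0.
#' @return An `"fs_tree"` with `n_leaves` leaves.
#' @export
make_birth_death_tree <- function(n_leaves, rate = 1) {
  stopifnot(n_leaves >= 2, rate > 0)
  phy <- ape::rphylo(n_leaves, birth = rate, death = 0)
  parse_newick(ape::write.tree(phy))
}

#' Transition-probability oracle
#'
#' `exp(Q t)` computed by scaling-and-squaring ([Matrix::expm()]),
#' independent of the Gillespie event loop; used to cross-check simulated
#' transition frequencies.
#'
#' @param Q a `"rate_matrix"` (or plain rate matrix with zero row sums).
#' @param t elapsed branch length, >= 0.
#' @return `|A| x |A|` probability matrix (rows sum to 1).
#' @export
transition_probability_oracle <- function(Q, t) {
  stopifnot(t >= 0)
  P <- as.matrix(Matrix::expm(unclass(Q) * t))
  dimnames(P) <- dimnames(unclass(Q))
  P
}

#' Summarize replicate simulations
#'
#' Computes, over a list of replicate results on one tree: the mean and sd
#' of the per-replicate landscape-change count; the fraction of positions
#' whose symbol differs between each node and its parent, averaged over
#' nodes at each depth (depth = number of edges from the root) and over
#' replicates; and the pooled leaf allele frequencies.
#'
#' @param results list of `"simulation_result"`s (or a single one).
#' @param tree the `"fs_tree"` the results were simulated on.
#' @return An object of class `"validation_summary"`: list with
#'   `change_count_mean`, `change_count_sd`, `per_depth_substituted_fraction`
#'   (named numeric, names = depth), `leaf_allele_frequencies`.
#' @export
summarize_results <- function(results, tree) {
  if (inherits(results, "simulation_result")) results <- list(results)
  stopifnot(inherits(tree, "fs_tree"), length(results) > 0L)
  nn <- vapply(results, function(r) length(r$node_sequences), 0L)
  if (any(nn != tree$n))
    stop("results do not all match the tree's node count", call. = FALSE)

  counts <- vapply(results, function(r) nrow(r$change_log), 0L)

  depth <- integer(tree$n)
  for (id in seq_len(tree$n)[-tree$root])
    depth[id] <- depth[tree$parent[id]] + 1L

  L <- nchar(results[[1]]$node_sequences[[1]])
  per_depth <- NULL
  if (L > 0L) {
    non_root <- seq_len(tree$n)[-tree$root]
    frac <- matrix(0, length(results), length(non_root))
    for (ri in seq_along(results)) {
      sq <- results[[ri]]$node_sequences
      for (k in seq_along(non_root)) {
        id <- non_root[k]
        a <- strsplit(sq[[id]], "", fixed = TRUE)[[1]]
        b <- strsplit(sq[[tree$parent[id]]], "", fixed = TRUE)[[1]]
        frac[ri, k] <- mean(a != b)
      }
    }
    mfrac <- colMeans(frac)
    per_depth <- tapply(mfrac, depth[non_root], mean)
    per_depth <- stats::setNames(as.numeric(per_depth), names(per_depth))
  }

  leaf_freq <- NULL
  if (L > 0L) {
    pool <- unlist(lapply(results, function(r)
      strsplit(paste(r$node_sequences[tree$is_leaf], collapse = ""), "",
               fixed = TRUE)[[1]]))
    tab <- table(pool)
    leaf_freq <- as.numeric(tab) / sum(tab)
    names(leaf_freq) <- names(tab)
  }

  structure(list(change_count_mean = mean(counts),
                 change_count_sd = stats::sd(counts),
                 per_depth_substituted_fraction = per_depth,
                 leaf_allele_frequencies = leaf_freq),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation summary>\n",
      "change count: mean", format(x$change_count_mean),
      "sd", format(x$change_count_sd), "\n")
  if (!is.null(x$leaf_allele_frequencies)) {
    cat(" leaf allele frequencies:\n")
    print(round(x$leaf_allele_frequencies, 4))
  }
  invisible(x)
}
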