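# The Gillespie event loop. All simulation state in the hot path is bare
# numerics: allele indices (1..|A|), a landscape "context" (fitness vector,
# scaled Q, pi, per-allele exit rates), and per-branch deterministic event
# lists. Draw order is fixed — waiting time, then event type, then position,
# then target allele, one uniform per decision — so a seed reproduces the
# run exactly.

#' Build a landscape context
#'
#' Bundles everything the engine needs for a fixed landscape: the fitness
#' vector, the (rescaled) rate matrix, its stationary distribution, and the
#' per-allele exit rates. Recomputed from scratch after every landscape
#' change (each landscape is independently normalized).
#'
#' @param F a [fitness_vector()].
#' @param M a [mutation_matrix()]; `NULL` means the all-ones default.
#' @param scaling `"normalized"` (default), `"flat_scaled"`, or `"raw"`.
#' @return An object of class `"landscape_context"`: list with elements `F`,
#'   `Q` (a `"rate_matrix"`), `pi` (a `"stationary_distribution"`) and
#'   `alphabet`.
#' @export
landscape_context <- function(F, M = NULL,
                              scaling = c("normalized", "flat_scaled", "raw")) {
  scaling <- match.arg(scaling)
  ab <- attr(F, "alphabet")
  if (is.null(M)) M <- uniform_mutation_matrix(ab)
  uniform_M <- .is_uniform_M(M)
  if (!uniform_M) .check_irreducible(M, unclass(ab))
  ctx <- .landscape_ctx(as.numeric(F), unclass(M), uniform_M, scaling)
  structure(list(
    F = F,
    Q = structure(`dimnames<-`(ctx$Q, list(unclass(ab), unclass(ab))),
                  alphabet = ab, scaling_mode = scaling, class = "rate_matrix"),
    pi = structure(stats::setNames(ctx$pi, unclass(ab)), alphabet = ab,
                   class = "stationary_distribution"),
    alphabet = ab,
    .bare = ctx, .M = unclass(M), .uniform_M = uniform_M, .scaling = scaling),
    class = "landscape_context")
}

#' @export
print.landscape_context <- function(x, ...) {
  cat("<landscape context> scaling:", x$.scaling, "\n")
  print(x$F); print(x$pi)
  invisible(x)
}

#' Sample a root sequence from the stationary distribution
#'
#' Positions are drawn independently from `pi`; a user-supplied root sequence
#' is used verbatim instead (validated against the alphabet and length only —
#' its plausibility under `pi` is the user's responsibility).
#'
#' @param pi a [stationary_distribution()].
#' @param length number of positions (>= 1).
#' @param root_sequence optional character string of alphabet symbols.
#' @return Integer vector of allele indices (1-based into the alphabet).
#' @export
sample_root_sequence <- function(pi, length, root_sequence = NULL) {
  ab <- attr(pi, "alphabet")
  if (!is.null(root_sequence)) {
    sym <- strsplit(root_sequence, "", fixed = TRUE)[[1]]
    if (base::length(sym) != length)
      stop("root sequence has length ", base::length(sym), ", expected ",
           length, call. = FALSE)
    idx <- match(sym, unclass(ab))
    if (anyNA(idx))
      stop("root sequence contains symbol(s) outside the alphabet: ",
           paste(unique(sym[is.na(idx)]), collapse = ", "), call. = FALSE)
    return(idx)
  }
  if (length < 0) stop("negative sequence length", call. = FALSE)
  if (length == 0L) return(integer(0))
  sample.int(base::length(pi), length, replace = TRUE, prob = as.numeric(pi))
}

# Core branch simulation on bare state. `det` is a list(offset, fitness,
# index) of deterministic changes on this branch, offsets strictly increasing
# in [0, blen). Returns end state, end context, and the change events.
.sim_branch_core <- function(alleles, ctx, blen, det, lam, rule,
                             M_raw, uniform_M, scaling, scale_lam) {
  rexp_ <- stats::rexp; runif_ <- stats::runif
  n_pos <- length(alleles)
  n_sym <- length(ctx$F)
  exit <- if (n_pos > 0L) ctx$exit[alleles] else numeric(0)
  S <- sum(exit)
  lam_eff <- if (scale_lam) lam * ctx$Qraw_rate else lam
  t <- 0
  di <- 1L
  nd <- if (is.null(det)) 0L else length(det$offset)
  n_ch <- 0L
  ch_t <- numeric(16L); ch_F <- vector("list", 16L)   # grow by doubling

  repeat {
    tdet <- if (di <= nd) det$offset[di] else Inf
    Rtot <- S + lam_eff
    w <- if (Rtot > 0) rexp_(1L, Rtot) else Inf
    if (t + w >= (if (tdet < blen) tdet else blen)) {
      if (is.finite(tdet)) {               # deterministic landscape change
        t <- tdet
        Fnew <- det$fitness[[di]]
        if (is.null(Fnew))
          Fnew <- .derive_F(rule, ctx$F,
                            if (n_pos == 1L) alleles[1L] else NA_integer_,
                            det$index[di], n_sym)
        di <- di + 1L
      } else break                          # branch elapses
    } else {
      t <- t + w
      u <- runif_(1L)
      if (lam_eff > 0 && u * Rtot < lam_eff) {  # stochastic landscape change
        Fnew <- .derive_F(rule, ctx$F,
                          if (n_pos == 1L) alleles[1L] else NA_integer_,
                          NA_integer_, n_sym)
      } else {                                  # substitution
        pos <- if (n_pos == 1L) 1L else {
          cs <- cumsum(exit)
          min(findInterval(runif_(1L) * S, cs) + 1L, n_pos)
        }
        i <- alleles[pos]
        rates <- ctx$Q[i, ]
        rates[i] <- 0
        cs <- cumsum(rates)
        j <- min(findInterval(runif_(1L) * cs[n_sym], cs) + 1L, n_sym)
        alleles[pos] <- j
        S <- S - exit[pos]
        exit[pos] <- ctx$exit[j]
        S <- S + exit[pos]
        next
      }
    }
    # a landscape change (deterministic or stochastic) happened at time t:
    # recompute Q and pi under the new landscape and redraw the waiting time
    ctx <- .landscape_ctx(Fnew, M_raw, uniform_M, scaling)
    if (n_pos > 0L) { exit <- ctx$exit[alleles]; S <- sum(exit) }
    if (scale_lam) lam_eff <- lam * ctx$Qraw_rate
    n_ch <- n_ch + 1L
    if (n_ch > length(ch_t)) {
      length(ch_t) <- 2L * length(ch_t)
      length(ch_F) <- 2L * length(ch_F)
    }
    ch_t[n_ch] <- t
    ch_F[[n_ch]] <- Fnew
  }
  list(alleles = alleles, ctx = ctx,
       change_t = ch_t[seq_len(n_ch)], change_F = ch_F[seq_len(n_ch)])
}

#' Simulate substitutions along a single branch
#'
#' Runs the Gillespie loop over one branch: exponential waiting times from
#' the summed exit rates (plus the stochastic landscape-change rate, treated
#' as an extra "site"), interleaved with any deterministic landscape changes,
#' which trigger recomputation of `Q` and `pi` and a fresh waiting-time draw.
#'
#' @param alleles integer vector of allele indices entering the branch.
#' @param ctx the entering [landscape_context()].
#' @param branch_length branch length (>= 0), in expected substitutions per
#'   site when `ctx` is normalized.
#' @param lambda stochastic landscape-change rate (0 for none).
#' @param rule the [landscape_rule()] used to derive new landscapes at change
#'   events (may be `NULL` when no changes can occur).
#' @param det_events optional deterministic events on this branch: list with
#'   `offset` (increasing, in `[0, branch_length)`), `fitness` (list of
#'   numeric vectors or `NULL`s) and `index` (integers passed to the rule).
#' @param scale_lambda_with_q co-scale `lambda` by the raw expected
#'   substitution rate (raw-scaling option).
#' @return List with `alleles` (end state), `ctx` (landscape context at the
#'   branch end, handed to both daughter branches) and `events`, a data.frame
#'   of landscape changes (`offset`, plus the new fitness values).
#' @export
simulate_branch <- function(alleles, ctx, branch_length, lambda = 0,
                            rule = NULL, det_events = NULL,
                            scale_lambda_with_q = FALSE) {
  stopifnot(inherits(ctx, "landscape_context"))
  if (branch_length < 0) stop("negative branch length", call. = FALSE)
  res <- .sim_branch_core(as.integer(alleles), ctx$.bare, branch_length,
                          det_events, lambda, rule, ctx$.M, ctx$.uniform_M,
                          ctx$.scaling, scale_lambda_with_q)
  out_ctx <- ctx
  if (length(res$change_t) > 0L) {
    out_ctx <- landscape_context(
      fitness_vector(res$ctx$F, ctx$alphabet),
      mutation_matrix(ctx$.M, ctx$alphabet), ctx$.scaling)
  }
  ev <- data.frame(offset = res$change_t)
  if (length(res$change_F) > 0L) {
    fm <- do.call(rbind, res$change_F)
    colnames(fm) <- paste0("F_", unclass(ctx$alphabet))
    ev <- cbind(ev, as.data.frame(fm))
  }
  list(alleles = res$alleles, ctx = out_ctx, events = ev)
}

# Expand a change_schedule's event table into a per-node list of
# list(offset, fitness, index), NULL where a branch has no events.
.events_by_node <- function(tree, schedule) {
  det <- vector("list", tree$n)
  ev <- schedule$events
  if (nrow(ev) == 0L) return(det)
  ids <- .node_id(tree, ev$branch)
  for (id in unique(ids)) {
    sel <- which(ids == id)
    sel <- sel[order(ev$offset[sel])]
    det[[id]] <- list(offset = ev$offset[sel], fitness = ev$fitness[sel],
                      index = ev$index[sel])
  }
  det
}

#' Run one full simulation over the tree
#'
#' Traverses the tree breadth-first (parents before children), simulating
#' every configured landscape's positions along every branch and recording
#' the sequence at each node plus the full landscape-change log.
#'
#' @param config a [simulation_config()].
#' @return An object of class `"simulation_result"`: list with
#'   `node_sequences` (named character vector over all nodes, internal nodes
#'   included), `change_log` (data.frame: `landscape_id`, `branch`,
#'   `global_time`, `offset`, new fitness values) and `seed` (`NA` unless run
#'   through [run_parallel()]).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- config$tree
  ab <- config$alphabet
  n_sym <- length(ab)
  M_raw <- unclass(config$mutation)
  uniform_M <- .is_uniform_M(config$mutation)
  scaling <- config$scaling
  L <- config$sequence_length
  seq_mat <- matrix(NA_character_, tree$n, L)
  logs <- list()

  for (li in seq_along(config$landscapes)) {
    spec <- config$landscapes[[li]]
    rule <- spec$rule
    npos <- length(spec$positions)

    F0 <- if (!is.null(spec$init_fitness)) as.numeric(spec$init_fitness)
          else as.numeric(sample_fitness_vector(rule, ab))
    ctx0 <- .landscape_ctx(F0, M_raw, uniform_M, scaling)

    root_alleles <- if (!is.null(config$root_sequence)) {
      idx <- match(strsplit(config$root_sequence, "", fixed = TRUE)[[1]],
                   unclass(ab))
      idx[spec$positions]
    } else if (npos > 0L) {
      sample.int(n_sym, npos, replace = TRUE, prob = ctx0$pi)
    } else integer(0)

    regime <- spec$regime
    lam <- if (regime$type == "stochastic") regime$lambda else 0
    det <- spec$.det_by_node %||% vector("list", tree$n)
    # shared periodic epochs: generate the epoch landscape sequence once,
    # from the shared epoch state, before any lineage proceeds
    if (regime$type == "periodic" && regime$sharing == "shared" &&
        (spec$.det_max_index %||% 0L) > 0L) {
      K <- spec$.det_max_index
      shared <- vector("list", K)
      prev <- F0
      for (k in seq_len(K)) {
        prev <- .derive_F(rule, prev, NA_integer_, k, n_sym)
        shared[[k]] <- prev
      }
      for (id in which(!vapply(det, is.null, TRUE)))
        det[[id]]$fitness <- shared[det[[id]]$index]
    }

    alleles_at <- vector("list", tree$n)
    ctx_at <- vector("list", tree$n)
    alleles_at[[tree$root]] <- root_alleles
    ctx_at[[tree$root]] <- ctx0

    ch_branch <- character(0); ch_gt <- numeric(0); ch_off <- numeric(0)
    ch_F <- list()

    for (id in seq_len(tree$n)[-tree$root]) {     # node ids are in BFS order
      p <- tree$parent[id]
      res <- .sim_branch_core(alleles_at[[p]], ctx_at[[p]], tree$blen[id],
                              det[[id]], lam, rule, M_raw, uniform_M, scaling,
                              regime$scale_lambda_with_q && scaling == "raw")
      alleles_at[[id]] <- res$alleles
      ctx_at[[id]] <- res$ctx
      if (length(res$change_t) > 0L) {
        ch_branch <- c(ch_branch, rep(tree$names[id], length(res$change_t)))
        ch_gt <- c(ch_gt, tree$time[p] + res$change_t)
        ch_off <- c(ch_off, res$change_t)
        ch_F <- c(ch_F, res$change_F)
      }
    }

    if (npos > 0L) {
      sym <- as.character(unclass(ab))
      for (id in seq_len(tree$n))
        seq_mat[id, spec$positions] <- sym[alleles_at[[id]]]
    }
    log <- data.frame(landscape_id = rep(li, length(ch_gt)),
                      branch = ch_branch, global_time = ch_gt,
                      offset = ch_off)
    if (length(ch_F) > 0L) {
      fm <- do.call(rbind, ch_F)
      colnames(fm) <- paste0("F_", unclass(ab))
      log <- cbind(log, as.data.frame(fm))
    } else {
      for (s in unclass(ab)) log[[paste0("F_", s)]] <- numeric(0)
    }
    logs[[li]] <- log
  }

  change_log <- do.call(rbind, logs)
  change_log <- change_log[order(change_log$landscape_id,
                                 change_log$global_time), , drop = FALSE]
  rownames(change_log) <- NULL
  node_sequences <- stats::setNames(
    if (L > 0L) apply(seq_mat, 1L, paste, collapse = "")
    else rep("", tree$n),
    tree$names)
  structure(list(node_sequences = node_sequences, change_log = change_log,
                 seed = NA_integer_),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation result>", length(x$node_sequences), "node sequences of length",
      nchar(x$node_sequences[[1]]), "-", nrow(x$change_log),
      "landscape change(s)\n")
  invisible(x)
}
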