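# Landscape-change timing. Three regimes:
#   stochastic  Poisson process at rate lambda per unit branch length,
#               realized inside the Gillespie loop as an extra "site";
#   periodic    deterministic epochs at global times interval, 2*interval, ...
#               measured as distance from the root, hitting every lineage
#               alive at that depth, with the new landscape either shared by
#               all parallel lineages or drawn independently per lineage;
#   explicit    user-specified branch coordinates (branch, offset), with
#               optional explicit fitness vectors.
# Coordinates are half-open on each branch: offset in [0, branch_length); an
# event within 1e-9 of the daughter node is snapped to the node and applied
# to the daughter branches (offset 0 on each).

.SNAP_EPS <- 1e-9

#' Specify a landscape-change timing regime
#'
#' @param type one of `"none"`, `"stochastic"`, `"periodic"`, `"explicit"`.
#' @param lambda Poisson rate per unit branch length (`stochastic`), >= 0.
#' @param interval epoch spacing in branch-length units (`periodic`), > 0.
#' @param sharing `"independent"` or `"shared"`: whether parallel lineages
#'   crossing the same periodic epoch receive separate draws or one common
#'   new landscape (`periodic` only).
#' @param events for `explicit`: a data.frame with columns `branch`
#'   (child-node name of the branch), `offset` (distance from the branch's
#'   parent end), and optionally a list-column `fitness` of numeric vectors
#'   (`NULL` entries are generated from the landscape rule).
#' @param scale_lambda_with_q if `TRUE` and the rate matrix is left raw, the
#'   stochastic change rate is co-scaled by the landscape's expected raw
#'   substitution rate; ignored under normalized scaling.
#' @return An object of class `"change_regime"`.
#' @export
change_regime <- function(type = c("none", "stochastic", "periodic", "explicit"),
                          lambda = NULL, interval = NULL,
                          sharing = c("independent", "shared"),
                          events = NULL, scale_lambda_with_q = FALSE) {
  type <- match.arg(type)
  sharing <- match.arg(sharing)
  if (type == "stochastic") {
    if (is.null(lambda) || !is.finite(lambda) || lambda < 0)
      stop("stochastic regime requires lambda >= 0", call. = FALSE)
  } else if (!is.null(lambda)) {
    stop("lambda is only meaningful for the stochastic regime", call. = FALSE)
  }
  if (type == "periodic") {
    if (is.null(interval) || !is.finite(interval) || interval <= 0)
      stop("periodic regime requires interval > 0", call. = FALSE)
  } else if (!is.null(interval)) {
    stop("interval is only meaningful for the periodic regime", call. = FALSE)
  }
  if (type == "explicit") {
    if (is.null(events) || nrow(as.data.frame(events[c("branch", "offset")])) == 0L)
      stop("explicit regime requires an events table", call. = FALSE)
    if (!all(c("branch", "offset") %in% names(events)))
      stop("explicit events need columns 'branch' and 'offset'", call. = FALSE)
  } else if (!is.null(events)) {
    stop("events are only meaningful for the explicit regime", call. = FALSE)
  }
  structure(list(type = type, lambda = lambda, interval = interval,
                 sharing = sharing, events = events,
                 scale_lambda_with_q = isTRUE(scale_lambda_with_q)),
            class = "change_regime")
}

#' @export
print.change_regime <- function(x, ...) {
  cat("<change regime>", x$type,
      switch(x$type,
             stochastic = paste0("(lambda = ", x$lambda, ")"),
             periodic = paste0("(interval = ", x$interval, ", ", x$sharing, ")"),
             explicit = paste0("(", nrow(as.data.frame(x$events[c("branch", "offset")])),
                               " events)"),
             ""), "\n")
  invisible(x)
}

# Deterministic events on one branch under a periodic regime: global ticks
# k*interval with parent_time <= tick < node_time (half-open; snapping moves
# near-node ticks to the daughters).
.periodic_ticks_on_branch <- function(parent_time, node_time, interval) {
  if (node_time - parent_time < .SNAP_EPS) return(integer(0))
  kmin <- max(1L, as.integer(ceiling((parent_time - .SNAP_EPS) / interval)))
  kmax <- as.integer(floor((node_time - .SNAP_EPS) / interval))
  if (kmax * interval >= node_time - .SNAP_EPS) kmax <- kmax - 1L
  while (kmin <= kmax && kmin * interval < parent_time - .SNAP_EPS) kmin <- kmin + 1L
  if (kmin > kmax) integer(0) else kmin:kmax
}

#' Build the deterministic change schedule for a tree
#'
#' Expands a [change_regime()] against a tree into the concrete list of
#' deterministic change events, one row per (event, branch): periodic epochs
#' are intersected with every branch spanning them; explicit events are
#' validated (and snapped to the daughter branches when within `1e-9` of a
#' node). The stochastic regime has no precomputed events (they are drawn
#' inside the Gillespie loop).
#'
#' @param tree an `"fs_tree"`.
#' @param regime a [change_regime()].
#' @return An object of class `"change_schedule"`: list with the `regime` and
#'   an `events` data.frame with columns `branch`, `offset`, `global_time`,
#'   `index` (tick number, or event rank for explicit schedules) and a
#'   list-column `fitness`.
#' @export
build_change_schedule <- function(tree, regime) {
  stopifnot(inherits(tree, "fs_tree"), inherits(regime, "change_regime"))
  empty <- data.frame(branch = character(0), offset = numeric(0),
                      global_time = numeric(0), index = integer(0))
  empty$fitness <- list()
  ev <- empty
  if (regime$type == "periodic") {
    b <- character(0); o <- numeric(0); g <- numeric(0); k_ <- integer(0)
    for (id in seq_len(tree$n)[-tree$root]) {
      pt <- tree$time[tree$parent[id]]; nt <- tree$time[id]
      ks <- .periodic_ticks_on_branch(pt, nt, regime$interval)
      if (length(ks) == 0L) next
      off <- ks * regime$interval - pt
      off[off < .SNAP_EPS] <- 0
      b <- c(b, rep(tree$names[id], length(ks)))
      o <- c(o, off); g <- c(g, ks * regime$interval); k_ <- c(k_, as.integer(ks))
    }
    if (length(b) > 0L) {
      ev <- data.frame(branch = b, offset = o, global_time = g, index = k_)
      ev$fitness <- rep(list(NULL), nrow(ev))
    }
  } else if (regime$type == "explicit") {
    raw <- regime$events
    fit <- if (!is.null(raw$fitness)) raw$fitness else rep(list(NULL), length(raw$branch))
    branch <- as.character(raw$branch); offset <- as.numeric(raw$offset)
    out_b <- character(0); out_o <- numeric(0); out_f <- list()
    for (r in seq_along(branch)) {
      id <- .node_id(tree, branch[r])
      if (id == tree$root)
        stop("explicit change events cannot be placed on the root", call. = FALSE)
      bl <- tree$blen[id]
      if (offset[r] < 0 || offset[r] > bl + .SNAP_EPS)
        stop("explicit event offset ", offset[r], " outside branch '",
             branch[r], "' (length ", bl, ")", call. = FALSE)
      if (offset[r] >= bl - .SNAP_EPS) {
        kids <- tree$children[[id]]
        if (length(kids) == 0L) {
          warning("explicit event at the very end of leaf branch '", branch[r],
                  "' has no daughter branches and is dropped")
          next
        }
        for (k in kids) {              # snap to the node: daughters, offset 0
          out_b <- c(out_b, tree$names[k]); out_o <- c(out_o, 0)
          out_f[[length(out_f) + 1L]] <- fit[[r]]
        }
      } else {
        out_b <- c(out_b, branch[r]); out_o <- c(out_o, offset[r])
        out_f[[length(out_f) + 1L]] <- fit[[r]]
      }
    }
    if (length(out_b) > 0L) {
      gt <- tree$time[tree$parent[.node_id(tree, out_b)]] + out_o
      if (any(gt < .SNAP_EPS))
        stop("a change event at the root (global time 0) is not allowed; ",
             "the initial landscape governs from time 0", call. = FALSE)
      ord <- order(gt, match(out_b, tree$names))
      ev <- data.frame(branch = out_b[ord], offset = out_o[ord],
                       global_time = gt[ord], index = seq_along(ord))
      ev$fitness <- out_f[ord]
    }
  }
  structure(list(regime = regime, events = ev, tree_names = tree$names),
            class = "change_schedule")
}

#' @export
print.change_schedule <- function(x, ...) {
  cat("<change schedule>", x$regime$type, "-", nrow(x$events),
      "precomputed event(s)\n")
  invisible(x)
}

#' Assign new landscapes to lineages crossing a periodic epoch
#'
#' Under `sharing = "shared"` one new fitness vector is generated per epoch
#' and assigned to every lineage alive at it; under `"independent"` a fresh
#' vector is drawn per lineage.
#'
#' @param rule a [landscape_rule()].
#' @param sharing `"shared"` or `"independent"`.
#' @param lineages character vector of lineage (branch) names at the epoch.
#' @param previous for `"shared"`, the single epoch [fitness_vector()]; for
#'   `"independent"`, a named list of per-lineage fitness vectors.
#' @param current_alleles optional named vector of resident alleles per
#'   lineage (for the increase/decrease rules, independent mode only).
#' @param change_index event index forwarded to [derive_new_landscape()].
#' @return Named list (one entry per lineage) of fitness vectors.
#' @export
resolve_sharing <- function(rule, sharing, lineages, previous,
                            current_alleles = NULL, change_index = 1L) {
  sharing <- match.arg(sharing, c("shared", "independent"))
  if (sharing == "shared") {
    if (rule$change_rule %in% c("increase_current", "decrease_current"))
      stop("increase/decrease rules are undefined in shared mode: parallel ",
           "lineages generally hold different resident alleles", call. = FALSE)
    v <- derive_new_landscape(rule, previous, change_index = change_index)
    stats::setNames(rep(list(v), length(lineages)), lineages)
  } else {
    stats::setNames(lapply(lineages, function(ln)
      derive_new_landscape(rule, previous[[ln]],
                           current_allele = current_alleles[[ln]],
                           change_index = change_index)), lineages)
  }
}

#' Read an explicit change-schedule file
#'
#' Plain text, one event per line: branch name, offset, and optionally `|A|`
#' whitespace-separated fitness values.
#'
#' @param path file path.
#' @param alphabet optional [alphabet()] used to validate fitness values.
#' @return A data.frame with columns `branch`, `offset` and list-column
#'   `fitness`, suitable for [change_regime()].
#' @export
read_schedule <- function(path, alphabet = NULL) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln); ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L) stop("empty schedule file: ", path, call. = FALSE)
  branch <- character(0); offset <- numeric(0); fitness <- list()
  for (l in ln) {
    f <- strsplit(l, "\\s+")[[1]]
    if (length(f) < 2L) stop("schedule line needs at least branch and offset: '",
                             l, "'", call. = FALSE)
    branch <- c(branch, f[1]); offset <- c(offset, as.numeric(f[2]))
    v <- if (length(f) > 2L) {
      vv <- as.numeric(f[-(1:2)])
      if (!is.null(alphabet) && length(vv) != length(.as_alphabet(alphabet)))
        stop("schedule line fitness vector has wrong length: '", l, "'",
             call. = FALSE)
      vv
    } else NULL
    fitness[[length(fitness) + 1L]] <- v
  }
  if (anyNA(offset)) stop("non-numeric offset in schedule file", call. = FALSE)
  out <- data.frame(branch = branch, offset = offset)
  out$fitness <- fitness
  out
}
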