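#' Specify one landscape and the positions it governs
#'
#' @param positions integer vector of 1-based sequence positions governed by
#'   this landscape (may be empty for a landscape-change-only instance).
#' @param rule a [landscape_rule()].
#' @param regime a [change_regime()].
#' @param init_fitness optional numeric vector fixing the initial fitness
#'   values (otherwise drawn from the rule's init source at run time).
#' @return An object of class `"landscape_spec"`.
#' @export
landscape_spec <- function(positions, rule = landscape_rule(),
                           regime = change_regime("none"),
                           init_fitness = NULL) {
  positions <- as.integer(positions)
  if (length(positions) > 0L && (any(positions < 1L) || anyDuplicated(positions)))
    stop("positions must be distinct positive integers", call. = FALSE)
  stopifnot(inherits(rule, "landscape_rule"), inherits(regime, "change_regime"))
  if (rule$change_rule == "explicit" && regime$type != "explicit")
    stop("explicit fitness vectors require explicitly specified change times ",
         "(regime type 'explicit')", call. = FALSE)
  if (regime$type != "none" && rule$change_rule == "resample" &&
      is.null(rule$init$dist))
    stop("change rule 'resample' requires a distributional init ",
         "(gamma or lognormal) to resample from", call. = FALSE)
  if (rule$change_rule %in% c("increase_current", "decrease_current")) {
    if (length(positions) != 1L)
      stop("change rule '", rule$change_rule, "' is only defined for a ",
           "landscape governing exactly one position (got ", length(positions),
           ")", call. = FALSE)
    if (regime$type == "periodic" && regime$sharing == "shared")
      stop("change rule '", rule$change_rule, "' cannot be combined with ",
           "shared periodic changes: parallel lineages hold different ",
           "resident alleles", call. = FALSE)
  }
  structure(list(positions = positions, rule = rule, regime = regime,
                 init_fitness = init_fitness),
            class = "landscape_spec")
}

#' Assemble and validate a full simulation configuration
#'
#' All cross-option conflicts are surfaced here, before any simulation
#' starts. Defaults follow the package conventions: an all-ones mutation
#' matrix, normalized rate-matrix scaling, and a root sequence sampled from
#' the initial stationary distribution.
#'
#' @param tree an `"fs_tree"` or a path to a Newick file.
#' @param landscapes list of [landscape_spec()]s. Their position ranges must
#'   be disjoint and jointly cover `1..sequence_length`.
#' @param alphabet an [alphabet()] (or character vector).
#' @param mutation a [mutation_matrix()], plain matrix, or `NULL` (all ones).
#' @param scaling `"normalized"`, `"flat_scaled"`, or `"raw"`.
#' @param root_sequence optional explicit root sequence (string).
#' @param write_change_log include the change log in written outputs.
#' @param write_internal_nodes also write internal-node sequences to FASTA.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(tree, landscapes,
                              alphabet = c("A", "C", "G", "T"),
                              mutation = NULL,
                              scaling = c("normalized", "flat_scaled", "raw"),
                              root_sequence = NULL,
                              write_change_log = TRUE,
                              write_internal_nodes = FALSE) {
  scaling <- match.arg(scaling)
  if (is.character(tree) && length(tree) == 1L && !grepl(";", tree))
    tree <- read_newick(tree)
  else if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "fs_tree"))
  alphabet <- .as_alphabet(alphabet)
  if (inherits(landscapes, "landscape_spec")) landscapes <- list(landscapes)
  if (length(landscapes) < 1L)
    stop("at least one landscape_spec is required", call. = FALSE)
  if (!all(vapply(landscapes, inherits, TRUE, "landscape_spec")))
    stop("landscapes must be a list of landscape_spec objects", call. = FALSE)

  all_pos <- unlist(lapply(landscapes, `[[`, "positions"))
  L <- if (length(all_pos) == 0L) 0L else max(all_pos)
  if (anyDuplicated(all_pos))
    stop("landscape position ranges overlap at position(s) ",
         paste(unique(all_pos[duplicated(all_pos)]), collapse = ", "),
         call. = FALSE)
  if (L > 0L && length(all_pos) != L)
    stop("landscape position ranges leave gap(s): positions ",
         paste(setdiff(seq_len(L), all_pos), collapse = ", "),
         " are governed by no landscape", call. = FALSE)

  mutation <- if (is.null(mutation)) uniform_mutation_matrix(alphabet)
              else if (inherits(mutation, "mutation_matrix")) mutation
              else mutation_matrix(mutation, alphabet)
  if (!identical(unclass(attr(mutation, "alphabet")), unclass(alphabet)))
    stop("mutation matrix alphabet does not match the configured alphabet",
         call. = FALSE)
  .check_irreducible(mutation, unclass(alphabet))

  for (i in seq_along(landscapes)) {
    spec <- landscapes[[i]]
    if (!is.null(spec$init_fitness) &&
        length(spec$init_fitness) != length(alphabet))
      stop("init_fitness length does not match the alphabet", call. = FALSE)
    if (spec$regime$type %in% c("periodic", "explicit")) {
      # validate against the tree and cache the expanded per-branch event
      # lists; only shared-epoch fitness draws remain per-run work
      sch <- build_change_schedule(tree, spec$regime)
      spec$.det_by_node <- .events_by_node(tree, sch)
      spec$.det_max_index <- if (nrow(sch$events) > 0L) max(sch$events$index)
                             else 0L
      landscapes[[i]] <- spec
    }
  }

  if (!is.null(root_sequence)) {
    sym <- strsplit(root_sequence, "", fixed = TRUE)[[1]]
    if (length(sym) != L)
      stop("root_sequence length ", length(sym), " does not match the ",
           "configured sequence length ", L, call. = FALSE)
    if (!all(sym %in% unclass(alphabet)))
      stop("root_sequence contains symbols outside the alphabet", call. = FALSE)
  }

  structure(list(tree = tree, alphabet = alphabet, landscapes = landscapes,
                 mutation = mutation, scaling = scaling,
                 root_sequence = root_sequence,
                 sequence_length = L,
                 write_change_log = isTRUE(write_change_log),
                 write_internal_nodes = isTRUE(write_internal_nodes)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation config>\n")
  print(x$tree)
  cat(" alphabet:", paste(unclass(x$alphabet), collapse = ""),
      "| sequence length:", x$sequence_length,
      "| scaling:", x$scaling, "\n")
  cat(" landscapes:", length(x$landscapes), "\n")
  invisible(x)
}

#' Run replicate simulations with deterministic per-replicate seeding
#'
#' Replicate `i` runs under a child seed derived deterministically from
#' `(seed, i)`, so results are bitwise identical for any `threads` value,
#' including 1.
#'
#' @param config a [simulation_config()].
#' @param seed integer master seed.
#' @param replicates number of independent replicate simulations.
#' @param threads number of worker processes (forked; serial when 1).
#' @return List of `"simulation_result"`s, one per replicate, each carrying
#'   its child seed.
#' @export
run_parallel <- function(config, seed, replicates = 1L, threads = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  seeds <- .child_seeds(seed, replicates)
  one <- function(i) {
    set.seed(seeds[i])
    res <- run_simulation(config)
    res$seed <- seeds[i]
    res
  }
  if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(replicates), one, mc.cores = threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(replicates), one)
  }
}

# Deterministic child seeds, kept within 32-bit integer range.
.child_seeds <- function(seed, n) {
  base <- as.numeric(seed) %% 2147483647
  as.integer((base + 48271 * seq_len(n)) %% 2147483647)
}
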