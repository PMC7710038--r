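#' Rules for creating and updating fitness landscapes
#'
#' A landscape rule bundles (i) the source of the initial fitness vector and
#' (ii) the rule applied at every landscape-change event.
#'
#' Initial sources: `gamma(shape, scale)` or `lognormal(mu, sigma)` (i.i.d.
#' draws per symbol; the lognormal is parameterized by the mean and sd of the
#' underlying normal), a plain-text `file`, or a fixed numeric `values`
#' vector.
#'
#' Change rules:
#' \describe{
#'   \item{resample}{fresh i.i.d. draw from the initial distribution.}
#'   \item{permute}{uniform random permutation of the previous values
#'     (the identity permutation is possible).}
#'   \item{explicit}{the next user-supplied vector, verbatim; only valid with
#'     user-specified change times.}
#'   \item{increase_current / decrease_current}{previous vector with the
#'     fitness of the allele currently occupying the site shifted by
#'     `+delta` / `-delta`; only valid for single-position landscapes.}
#' }
#'
#' @param init one of: `list(dist = "gamma", shape =, scale =)`,
#'   `list(dist = "lognormal", mu =, sigma =)`, `list(file = "<path>")`, or
#'   `list(values = <numeric>)`.
#' @param change_rule one of `"resample"`, `"permute"`, `"explicit"`,
#'   `"increase_current"`, `"decrease_current"`; `"resample"` by default.
#' @param delta positive real, the shift magnitude in scaled-fitness units;
#'   required iff `change_rule` is `increase_current`/`decrease_current`.
#' @param explicit_vectors ordered list of numeric vectors, required iff
#'   `change_rule = "explicit"`.
#' @return An object of class `"landscape_rule"`.
#' @examples
#' landscape_rule(init = list(dist = "lognormal", mu = 0, sigma = 0.5),
#'                change_rule = "permute")
#' @export
landscape_rule <- function(init = list(dist = "lognormal", mu = 0, sigma = 0.5),
                           change_rule = "resample",
                           delta = NULL,
                           explicit_vectors = NULL) {
  change_rule <- match.arg(change_rule,
    c("resample", "permute", "explicit", "increase_current", "decrease_current"))
  if (!is.list(init)) stop("init must be a list", call. = FALSE)
  if (!is.null(init$dist)) {
    init$dist <- match.arg(init$dist, c("gamma", "lognormal"))
    if (init$dist == "gamma") {
      if (is.null(init$shape) || is.null(init$scale) ||
          init$shape <= 0 || init$scale <= 0)
        stop("gamma init requires shape > 0 and scale > 0", call. = FALSE)
    } else {
      if (is.null(init$mu) || is.null(init$sigma) || init$sigma <= 0)
        stop("lognormal init requires mu and sigma > 0", call. = FALSE)
    }
  } else if (is.null(init$file) && is.null(init$values)) {
    stop("init must name a distribution, a file, or fixed values", call. = FALSE)
  }
  if (change_rule %in% c("increase_current", "decrease_current")) {
    if (is.null(delta) || !is.finite(delta) || delta <= 0)
      stop("change_rule '", change_rule, "' requires a positive delta",
           call. = FALSE)
  } else if (!is.null(delta)) {
    stop("delta is only meaningful for increase_current/decrease_current",
         call. = FALSE)
  }
  if (change_rule == "explicit") {
    if (is.null(explicit_vectors) || length(explicit_vectors) == 0L)
      stop("change_rule 'explicit' requires explicit_vectors", call. = FALSE)
    explicit_vectors <- lapply(explicit_vectors, as.numeric)
  } else if (!is.null(explicit_vectors)) {
    stop("explicit_vectors are only meaningful for change_rule 'explicit'",
         call. = FALSE)
  }
  structure(list(init = init, change_rule = change_rule, delta = delta,
                 explicit_vectors = explicit_vectors),
            class = "landscape_rule")
}

#' @export
print.landscape_rule <- function(x, ...) {
  src <- if (!is.null(x$init$dist)) {
    if (x$init$dist == "gamma")
      sprintf("gamma(shape = %g, scale = %g)", x$init$shape, x$init$scale)
    else sprintf("lognormal(mu = %g, sigma = %g)", x$init$mu, x$init$sigma)
  } else if (!is.null(x$init$file)) paste0("file: ", x$init$file)
  else "fixed values"
  cat("<landscape rule> init:", src, "| change:", x$change_rule,
      if (!is.null(x$delta)) paste0("(delta = ", x$delta, ")") else "", "\n")
  invisible(x)
}

#' Sample an initial fitness vector
#'
#' Draws one independent value per alphabet symbol from the rule's initial
#' distribution (or loads the fixed/file-based values). Uses R's global
#' random number stream; set a seed for reproducibility.
#'
#' @param rule a [landscape_rule()].
#' @param alphabet an [alphabet()].
#' @return A [fitness_vector()].
#' @export
sample_fitness_vector <- function(rule, alphabet) {
  stopifnot(inherits(rule, "landscape_rule"))
  alphabet <- .as_alphabet(alphabet)
  n <- length(alphabet)
  init <- rule$init
  v <- if (!is.null(init$dist)) {
    if (init$dist == "gamma") stats::rgamma(n, shape = init$shape, scale = init$scale)
    else stats::rlnorm(n, meanlog = init$mu, sdlog = init$sigma)
  } else if (!is.null(init$values)) {
    as.numeric(init$values)
  } else {
    as.numeric(read_fitness_vector(init$file, alphabet))
  }
  fitness_vector(v, alphabet)
}

#' Derive the next fitness landscape at a change event
#'
#' @param rule a [landscape_rule()].
#' @param previous the [fitness_vector()] in force before the change.
#' @param current_allele integer index (or symbol) of the allele occupying
#'   the site; required for `increase_current`/`decrease_current`.
#' @param change_index 1-based index of this change event within its
#'   landscape's history; addresses the vector used by the `explicit` rule.
#' @return A [fitness_vector()] over the same alphabet.
#' @export
derive_new_landscape <- function(rule, previous, current_allele = NULL,
                                 change_index = 1L) {
  stopifnot(inherits(rule, "landscape_rule"),
            inherits(previous, "fitness_vector"))
  ab <- attr(previous, "alphabet")
  switch(rule$change_rule,
    resample = sample_fitness_vector(rule, ab),
    permute = fitness_vector(sample(as.numeric(previous)), ab),
    explicit = {
      if (change_index > length(rule$explicit_vectors))
        stop("explicit landscape list exhausted: change ", change_index,
             " requested but only ", length(rule$explicit_vectors),
             " vectors supplied", call. = FALSE)
      fitness_vector(rule$explicit_vectors[[change_index]], ab)
    },
    increase_current = ,
    decrease_current = {
      if (is.null(current_allele))
        stop(rule$change_rule, " requires the current allele", call. = FALSE)
      i <- if (is.character(current_allele))
        match(current_allele, unclass(ab)) else as.integer(current_allele)
      if (is.na(i) || i < 1L || i > length(previous))
        stop("current allele out of range", call. = FALSE)
      v <- as.numeric(previous)
      v[i] <- v[i] + if (rule$change_rule == "increase_current") rule$delta
                     else -rule$delta
      fitness_vector(v, ab)
    })
}

# bare-numeric fast path used inside the simulation loop
.derive_F <- function(rule, prev, cur_allele, change_index, n) {
  switch(rule$change_rule,
    resample = if (rule$init$dist == "gamma")
        stats::rgamma(n, shape = rule$init$shape, scale = rule$init$scale)
      else stats::rlnorm(n, meanlog = rule$init$mu, sdlog = rule$init$sigma),
    permute = prev[sample.int(n)],
    explicit = {
      if (change_index > length(rule$explicit_vectors))
        stop("explicit landscape list exhausted at change ", change_index,
             call. = FALSE)
      rule$explicit_vectors[[change_index]]
    },
    increase_current = { prev[cur_allele] <- prev[cur_allele] + rule$delta; prev },
    decrease_current = { prev[cur_allele] <- prev[cur_allele] - rule$delta; prev })
}

#' Read a fitness vector file
#'
#' Plain text: one line of whitespace-separated reals ordered as the
#' alphabet, optionally preceded by a header line listing the alphabet
#' symbols.
#'
#' @param path file path.
#' @param alphabet the [alphabet()] the vector is defined over.
#' @return A [fitness_vector()].
#' @export
read_fitness_vector <- function(path, alphabet) {
  alphabet <- .as_alphabet(alphabet)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln); ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0L) stop("empty fitness vector file: ", path, call. = FALSE)
  fields <- strsplit(ln[1], "\\s+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(fields))))) {
    # header line: must match the alphabet
    if (!identical(fields, as.character(unclass(alphabet))))
      stop("fitness file header (", paste(fields, collapse = " "),
           ") does not match the alphabet", call. = FALSE)
    if (length(ln) < 2L) stop("fitness file has a header but no values",
                              call. = FALSE)
    fields <- strsplit(ln[2], "\\s+")[[1]]
  }
  fitness_vector(as.numeric(fields), alphabet)
}

#' Read a mutation-rate matrix file
#'
#' Plain text: first line lists the alphabet symbols (whitespace-separated),
#' followed by `|A|` rows of `|A|` nonnegative reals. Diagonal entries are
#' ignored.
#'
#' @param path file path.
#' @return A [mutation_matrix()] (its alphabet is taken from the header).
#' @export
read_mutation_matrix <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln); ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) < 2L) stop("mutation matrix file too short: ", path, call. = FALSE)
  ab <- alphabet(strsplit(ln[1], "\\s+")[[1]])
  n <- length(ab)
  if (length(ln) < 1L + n)
    stop("mutation matrix file: expected ", n, " rate rows", call. = FALSE)
  rows <- lapply(ln[2:(1 + n)], function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
  if (any(lengths(rows) != n))
    stop("mutation matrix rows must each have ", n, " entries", call. = FALSE)
  mutation_matrix(do.call(rbind, rows), ab)
}
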