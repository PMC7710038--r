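#' Define a sequence alphabet
#'
#' An alphabet is an ordered set of distinct single-character symbols over
#' which fitness vectors, mutation matrices and rate matrices are defined.
#' Any character states may be used (nucleotides, amino acids, or arbitrary
#' labels), as long as each symbol is a single character.
#'
#' @param symbols character vector of distinct single characters, length >= 2.
#' @return An object of class `"fs_alphabet"` (a character vector).
#' @examples
#' alphabet(c("A", "C", "G", "T"))
#' @export
alphabet <- function(symbols) {
  symbols <- as.character(symbols)
  if (length(symbols) < 2L)
    stop("alphabet must contain at least 2 symbols", call. = FALSE)
  if (any(nchar(symbols) != 1L))
    stop("alphabet symbols must be single characters", call. = FALSE)
  if (anyDuplicated(symbols))
    stop("alphabet contains duplicate symbols: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "),
         call. = FALSE)
  structure(symbols, class = "fs_alphabet")
}

#' @export
print.fs_alphabet <- function(x, ...) {
  cat("<alphabet> |A| =", length(x), ":", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

.as_alphabet <- function(x) {
  if (inherits(x, "fs_alphabet")) x else alphabet(x)
}

#' Construct a scaled fitness vector
#'
#' Holds one population-size-scaled additive fitness value `F = 2*N*f` per
#' alphabet symbol. Scaled fitnesses are dimensionless reals; negative and
#' zero values are allowed.
#'
#' @param values numeric vector of finite fitness values, one per symbol.
#' @param alphabet an [alphabet()] (or character vector coerced to one).
#' @return An object of class `"fitness_vector"`: a named numeric vector with
#'   an `alphabet` attribute.
#' @examples
#' fitness_vector(c(0, 1, 0.5, 0), c("A", "C", "G", "T"))
#' @export
fitness_vector <- function(values, alphabet) {
  alphabet <- .as_alphabet(alphabet)
  values <- as.numeric(values)
  if (length(values) != length(alphabet))
    stop("fitness vector length (", length(values),
         ") does not match alphabet size (", length(alphabet), ")",
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("fitness values must all be finite", call. = FALSE)
  structure(stats::setNames(values, unclass(alphabet)),
            alphabet = alphabet, class = "fitness_vector")
}

#' @export
print.fitness_vector <- function(x, ...) {
  cat("<fitness vector>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Construct a mutation-rate matrix
#'
#' Relative rates of mutational input between alleles, fixed for the whole
#' simulation. Off-diagonal entries must be nonnegative; the diagonal is
#' ignored. When no matrix is supplied anywhere in the package the default is
#' a matrix with every entry equal to 1.
#'
#' @param rates square numeric matrix, `|A| x |A|`, nonnegative off-diagonals.
#' @param alphabet an [alphabet()].
#' @return An object of class `"mutation_matrix"`.
#' @examples
#' mutation_matrix(matrix(1, 4, 4), c("A", "C", "G", "T"))
#' @export
mutation_matrix <- function(rates, alphabet) {
  alphabet <- .as_alphabet(alphabet)
  rates <- as.matrix(rates)
  n <- length(alphabet)
  if (!is.numeric(rates) || nrow(rates) != n || ncol(rates) != n)
    stop("mutation matrix must be numeric ", n, "x", n,
         " to match the alphabet", call. = FALSE)
  off <- rates[row(rates) != col(rates)]
  if (any(!is.finite(off)) || any(off < 0))
    stop("off-diagonal mutation rates must be finite and >= 0", call. = FALSE)
  dimnames(rates) <- list(unclass(alphabet), unclass(alphabet))
  structure(rates, alphabet = alphabet, class = "mutation_matrix")
}

#' Default all-ones mutation matrix
#' @param alphabet an [alphabet()].
#' @return A [mutation_matrix()] with every entry 1.
#' @export
uniform_mutation_matrix <- function(alphabet) {
  alphabet <- .as_alphabet(alphabet)
  mutation_matrix(matrix(1, length(alphabet), length(alphabet)), alphabet)
}

.is_uniform_M <- function(M) {
  m <- unclass(M); diag(m) <- 1
  all(m == 1)
}

# Fast internal kernel: raw rate matrix from bare numeric inputs.
# q_ij = M_ij * (F_j - F_i) / (1 - exp(F_i - F_j)), with the equal-fitness
# limit q_ij = M_ij taken whenever |F_i - F_j| < 1e-9 to avoid catastrophic
# cancellation near the removable singularity.
.raw_Q <- function(F, M) {
  n <- length(F)
  D <- matrix(F, n, n, byrow = TRUE) - F       # D[i, j] = F_j - F_i
  q <- M * D / (1 - exp(-D))
  lim <- abs(D) < 1e-9
  q[lim] <- M[lim]
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  q
}

#' Build the raw (unnormalized) substitution rate matrix
#'
#' Converts a scaled fitness vector and a mutation matrix into the
#' instantaneous substitution rate matrix of the mutation-selection process:
#' `q_ij = M_ij * (F_j - F_i) / (1 - exp(F_i - F_j))` for `i != j`, with
#' `q_ij = M_ij` in the equal-fitness limit, and `q_ii = -sum_{j != i} q_ij`.
#'
#' @param F a [fitness_vector()].
#' @param M a [mutation_matrix()] over the same alphabet.
#' @return A `"rate_matrix"`: numeric matrix with attributes `alphabet` and
#'   `scaling_mode = "raw"`. Rows sum to zero.
#' @examples
#' a <- alphabet(c("0", "1"))
#' build_raw_rate_matrix(fitness_vector(c(0, 1), a), uniform_mutation_matrix(a))
#' @export
build_raw_rate_matrix <- function(F, M) {
  if (!inherits(F, "fitness_vector")) stop("F must be a fitness_vector", call. = FALSE)
  if (!inherits(M, "mutation_matrix")) stop("M must be a mutation_matrix", call. = FALSE)
  af <- attr(F, "alphabet"); am <- attr(M, "alphabet")
  if (!identical(unclass(af), unclass(am)))
    stop("fitness vector and mutation matrix are defined over different alphabets",
         call. = FALSE)
  q <- .raw_Q(as.numeric(F), unclass(M))
  dimnames(q) <- list(unclass(af), unclass(af))
  structure(q, alphabet = af, scaling_mode = "raw", class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate matrix> scaling:", attr(x, "scaling_mode"), "\n")
  m <- unclass(x); attr(m, "alphabet") <- NULL; attr(m, "scaling_mode") <- NULL
  print(m)
  invisible(x)
}

# Connectivity check on the directed graph with an edge i -> j wherever
# M_ij > 0; alleles not reachable from every other allele make pi ill-defined.
.check_irreducible <- function(M, symbols) {
  n <- nrow(M)
  adj <- (unclass(M) > 0); diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)  # transitive closure
  bad <- !apply(reach & t(reach), 1, all)
  if (any(bad))
    stop("mutation matrix leaves symbol(s) disconnected from the rest of the ",
         "alphabet: ", paste(symbols[bad], collapse = ", "),
         "; the stationary distribution is undefined", call. = FALSE)
  invisible(TRUE)
}

# Internal stationary-distribution kernels. Softmax applies only when M is
# uniformly 1; the general path solves pi Q = 0, sum(pi) = 1 by least squares
# on the augmented system (robust null-space extraction for irreducible Q).
.pi_softmax <- function(F) {
  e <- exp(F - max(F))
  e / sum(e)
}

.pi_solve <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- as.numeric(qr.solve(A, b))
  p[p < 0 & p > -1e-12] <- 0
  p / sum(p)
}

#' Stationary distribution of the substitution process
#'
#' Long-run allele frequencies `pi` of the fixed-landscape substitution
#' process, satisfying `pi Q = 0`, `sum(pi) = 1`. When the mutation matrix is
#' uniformly 1 the closed-form softmax `pi_i = exp(F_i) / sum_j exp(F_j)` is
#' used; otherwise the linear system is solved directly. Both paths agree
#' whenever both apply.
#'
#' @param F a [fitness_vector()].
#' @param M a [mutation_matrix()] over the same alphabet.
#' @param Q optional `"rate_matrix"` already built from `(F, M)`; built on the
#'   fly if missing.
#' @return An object of class `"stationary_distribution"`: named numeric
#'   probability vector.
#' @examples
#' a <- alphabet(c("0", "1"))
#' stationary_distribution(fitness_vector(c(0, 1), a), uniform_mutation_matrix(a))
#' @export
stationary_distribution <- function(F, M, Q = NULL) {
  if (is.null(Q)) Q <- build_raw_rate_matrix(F, M)
  af <- attr(F, "alphabet")
  .check_irreducible(M, unclass(af))
  p <- if (.is_uniform_M(M)) .pi_softmax(as.numeric(F)) else .pi_solve(unclass(Q))
  if (any(p < 0))
    stop("stationary solve produced negative probabilities; ",
         "the rate matrix appears ill-conditioned", call. = FALSE)
  structure(stats::setNames(p, unclass(af)), alphabet = af,
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat("<stationary distribution>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Rescale a raw rate matrix
#'
#' `normalized` (the default throughout the package) divides `Q_raw` by the
#' expected substitution rate `-sum_i pi_i q_ii`, so that one substitution is
#' expected per site per unit of branch length under the current landscape.
#' `flat_scaled` divides by `|A| - 1`, which yields unit expected rate only
#' for a flat (neutral) landscape. `raw` returns the matrix unchanged.
#'
#' @param Qraw a `"rate_matrix"` with `scaling_mode = "raw"`.
#' @param pi the [stationary_distribution()] of `Qraw`.
#' @param mode one of `"normalized"`, `"flat_scaled"`, `"raw"`.
#' @return A `"rate_matrix"` with the requested `scaling_mode`.
#' @export
rescale_rate_matrix <- function(Qraw, pi,
                                mode = c("normalized", "flat_scaled", "raw")) {
  mode <- match.arg(mode)
  q <- unclass(Qraw)
  if (mode == "normalized") {
    rate <- -sum(diag(q) * as.numeric(pi))
    if (rate <= 0 || !is.finite(rate))
      stop("expected substitution rate is ", signif(rate, 4),
           "; cannot normalize a degenerate rate matrix", call. = FALSE)
    q <- q / rate
  } else if (mode == "flat_scaled") {
    q <- q / (nrow(q) - 1)
  }
  structure(q, alphabet = attr(Qraw, "alphabet"), scaling_mode = mode,
            class = "rate_matrix")
}

# One-call landscape context used by the engine: fitness -> (Q, pi), with the
# scaling mode applied. Returns bare numerics for the hot loop; `uniform_M`
# short-circuits pi to the softmax closed form. Recomputed after every
# landscape change, so kept allocation-lean.
.landscape_ctx <- function(F, M_raw, uniform_M, scaling) {
  n <- length(F)
  D <- matrix(F, n, n, byrow = TRUE) - F     # D[i, j] = F_j - F_i
  q <- D / (1 - exp(-D))
  lim <- abs(D) < 1e-9
  if (uniform_M) q[lim] <- 1
  else { q <- M_raw * q; q[lim] <- M_raw[lim] }
  dg <- seq.int(1L, n * n, by = n + 1L)
  q[dg] <- 0
  rs <- .rowSums(q, n, n)                    # total exit rate per allele (raw)
  q[dg] <- -rs
  p <- if (uniform_M) { e <- exp(F - max(F)); e / sum(e) } else .pi_solve(q)
  raw_rate <- sum(rs * p)
  if (scaling == "normalized") {
    if (raw_rate <= 0 || !is.finite(raw_rate))
      stop("degenerate landscape: expected substitution rate <= 0", call. = FALSE)
    div <- raw_rate
  } else if (scaling == "flat_scaled") div <- n - 1
  else div <- 1
  if (div != 1) { q <- q / div; rs <- rs / div }
  list(F = F, Q = q, pi = p, exit = rs, Qraw_rate = raw_rate)
}
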