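# Rooted trees are stored flat, indexed in breadth-first order:
#   names    character, unique node names (internal nodes auto-named)
#   parent   integer, 0 for the root
#   blen     numeric branch length of the edge above each node (NA for root)
#   children list of integer child indices, in input (Newick) order
#   time     numeric distance from the root ("global time" of the node)
# Unifurcations and single-leaf trees are legal; multifurcations are kept
# as-is. All scheduling coordinates build on `time`.

.nwk_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  toks <- list(); i <- 1L; n <- length(chars)
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(t = type, v = value)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "[") {                      # bracketed comment: skip to ]
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated [comment] in Newick string", call. = FALSE)
      i <- j + 1L; next
    }
    if (ch %in% c("(", ")", ",", ":", ";")) { push(ch, ch); i <- i + 1L; next }
    if (ch == "'") {                      # quoted label, '' escapes a quote
      j <- i + 1L; buf <- character(0)
      repeat {
        if (j > n) stop("unterminated quoted label in Newick string", call. = FALSE)
        if (chars[j] == "'") {
          if (j < n && chars[j + 1L] == "'") { buf <- c(buf, "'"); j <- j + 2L }
          else break
        } else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      push("label", paste(buf, collapse = ""))
      attr(toks[[length(toks)]], "quoted") <- TRUE
      i <- j + 1L; next
    }
    j <- i                                 # bare label / number
    while (j <= n && !(chars[j] %in% c("(", ")", ",", ":", ";", "[", "'",
                                       " ", "\t", "\n", "\r"))) j <- j + 1L
    push("label", paste(chars[i:(j - 1L)], collapse = ""))
    i <- j
  }
  toks
}

#' Parse a rooted Newick tree
#'
#' Parses a single rooted Newick statement into the package's tree
#' representation. Branch lengths are required on every non-root edge (a
#' branch length on the root is parsed and ignored); bracketed comments are
#' stripped; quoted labels are supported. Internal labels that look like bare
#' numbers are rejected rather than silently treated as support values.
#' Unnamed internal nodes are auto-named `"N1"`, `"N2"`, ... in breadth-first
#' order. A bare leaf with a branch length (`"A:1;"`) parses as a one-branch
#' tree below an implicit root.
#'
#' @param text a Newick string terminated by `";"`.
#' @return An object of class `"fs_tree"`; see [tree_stats()], [bfs_order()].
#' @examples
#' parse_newick("((A:1.5,B:1.5)E:1,(C:1.5,D:1.5)F:1)G;")
#' @export
parse_newick <- function(text) {
  text <- paste(text, collapse = "")
  toks <- .nwk_tokens(text)
  if (length(toks) == 0L) stop("empty Newick string", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { tk <- peek(); pos <<- pos + 1L; tk }

  parse_clade <- function() {
    tk <- peek()
    if (is.null(tk)) stop("unexpected end of Newick string (unbalanced parentheses?)",
                          call. = FALSE)
    children <- list(); name <- NA_character_; quoted <- FALSE
    if (tk$t == "(") {
      take()
      repeat {
        children[[length(children) + 1L]] <- parse_clade()
        tk <- take()
        if (is.null(tk)) stop("unbalanced parentheses in Newick string", call. = FALSE)
        if (tk$t == ")") break
        if (tk$t != ",")
          stop("unbalanced parentheses or malformed Newick near token '",
               tk$v, "'", call. = FALSE)
      }
      tk <- peek()
      if (!is.null(tk) && tk$t == "label") { name <- tk$v; quoted <- isTRUE(attr(tk, "quoted")); take() }
    } else if (tk$t == "label") {
      name <- tk$v; quoted <- isTRUE(attr(tk, "quoted")); take()
    } else {
      stop("malformed Newick string near token '", tk$v, "'", call. = FALSE)
    }
    blen <- NA_real_
    tk <- peek()
    if (!is.null(tk) && tk$t == ":") {
      take(); tk <- take()
      if (is.null(tk) || tk$t != "label")
        stop("expected a branch length after ':'", call. = FALSE)
      blen <- suppressWarnings(as.numeric(tk$v))
      if (is.na(blen)) stop("invalid branch length '", tk$v, "'", call. = FALSE)
      if (blen < 0) stop("negative branch length ", blen, call. = FALSE)
    }
    if (length(children) > 0L && !is.na(name) && !quoted &&
        !is.na(suppressWarnings(as.numeric(name))))
      stop("internal node label '", name, "' is a bare number; support values ",
           "are not accepted (quote the label if it really is a name)",
           call. = FALSE)
    list(name = name, blen = blen, children = children)
  }

  root <- parse_clade()
  tk <- take()
  if (is.null(tk) || tk$t != ";")
    stop("Newick string must end with ';'", call. = FALSE)
  if (!is.null(peek()))
    stop("trailing content after ';' in Newick string", call. = FALSE)

  # a lone leaf with a branch length hangs below an implicit root
  if (length(root$children) == 0L) {
    if (is.na(root$blen))
      stop("single-node tree has no branch length", call. = FALSE)
    root <- list(name = NA_character_, blen = NA_real_, children = list(root))
  }

  # flatten with a FIFO queue, so node ids come out in breadth-first order
  names_ <- character(0); parent <- integer(0); blen <- numeric(0)
  children <- list()
  queue_nodes <- list(root); queue_parent <- c(0L)
  while (length(queue_nodes) > 0L) {
    nd <- queue_nodes[[1L]]; pa <- queue_parent[1L]
    queue_nodes <- queue_nodes[-1L]; queue_parent <- queue_parent[-1L]
    id <- length(names_) + 1L
    names_[id] <- nd$name; parent[id] <- pa; blen[id] <- nd$blen
    children[[id]] <- integer(0)
    if (pa > 0L) children[[pa]] <- c(children[[pa]], id)
    for (ch in nd$children) {
      queue_nodes[[length(queue_nodes) + 1L]] <- ch
      queue_parent <- c(queue_parent, id)
    }
  }

  n <- length(names_)
  is_leaf <- lengths(children) == 0L
  if (any(is_leaf & is.na(names_)))
    stop("leaf without a name in Newick string", call. = FALSE)
  miss <- which(parent > 0L & is.na(blen))
  if (length(miss) > 0L)
    stop("missing branch length on ", length(miss), " edge(s); branch lengths ",
         "are required on all non-root edges", call. = FALSE)
  # auto-name unnamed internal nodes N1, N2, ... in BFS order
  k <- 0L
  for (id in seq_len(n)) {
    if (is.na(names_[id])) {
      repeat { k <- k + 1L; cand <- paste0("N", k); if (!cand %in% names_) break }
      names_[id] <- cand
    }
  }
  if (anyDuplicated(names_))
    stop("duplicate node names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "), call. = FALSE)
  time <- numeric(n); time[1L] <- 0
  for (id in seq_len(n)[-1L]) time[id] <- time[parent[id]] + blen[id]
  structure(list(names = names_, parent = parent, blen = blen,
                 children = children, time = time, root = 1L, n = n,
                 is_leaf = is_leaf),
            class = "fs_tree")
}

#' Read a Newick tree from a file
#' @param path path to a file containing one Newick statement.
#' @return An `"fs_tree"`.
#' @export
read_newick <- function(path) parse_newick(readLines(path, warn = FALSE))

.nwk_quote <- function(x) {
  needs <- grepl("[(),:;\\[\\]' \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree to Newick
#' @param tree an `"fs_tree"`.
#' @param path optional file to write to; if `NULL` the string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "fs_tree"))
  rec <- function(id) {
    lab <- .nwk_quote(tree$names[id])
    core <- if (length(tree$children[[id]]) == 0L) lab
            else paste0("(", paste(vapply(tree$children[[id]], rec, ""),
                                   collapse = ","), ")", lab)
    if (tree$parent[id] > 0L) paste0(core, ":", format(tree$blen[id], digits = 15))
    else core
  }
  out <- paste0(rec(tree$root), ";")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' @export
print.fs_tree <- function(x, ...) {
  st <- tree_stats(x)
  cat("<rooted tree>", st$leaf_count, "leaves,", x$n, "nodes, total branch length",
      format(st$total_branch_length), ", height", format(st$height), "\n")
  invisible(x)
}

#' Basic tree statistics
#'
#' @param tree an `"fs_tree"`.
#' @return A list with `leaf_count`, `total_branch_length` (sum over all
#'   non-root edges) and `height` (longest root-to-leaf path).
#' @export
tree_stats <- function(tree) {
  stopifnot(inherits(tree, "fs_tree"))
  list(leaf_count = sum(tree$is_leaf),
       total_branch_length = sum(tree$blen[tree$parent > 0L]),
       height = max(tree$time[tree$is_leaf]))
}

#' Breadth-first node order
#'
#' Root first, every parent before its children, siblings in Newick (input)
#' order. All simulation traversals use this order.
#'
#' @param tree an `"fs_tree"`.
#' @return Character vector of node names in BFS order.
#' @export
bfs_order <- function(tree) {
  stopifnot(inherits(tree, "fs_tree"))
  tree$names        # nodes are stored in BFS order
}

.node_id <- function(tree, name) {
  id <- match(name, tree$names)
  if (anyNA(id))
    stop("unknown node name(s): ", paste(name[is.na(id)], collapse = ", "),
         call. = FALSE)
  id
}
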