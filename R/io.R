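# Flat INI-style configuration files. Global keys first, then one
# `[landscape]` section per landscape. The schema is documented in
# ?load_inputs and in the package vignette.

.parse_bool <- function(x, key) {
  v <- tolower(trimws(x))
  if (v %in% c("true", "yes", "1")) return(TRUE)
  if (v %in% c("false", "no", "0")) return(FALSE)
  stop("config key '", key, "': expected a boolean, got '", x, "'",
       call. = FALSE)
}

.parse_kv_args <- function(fields, key) {
  # "lognormal mu=0 sigma=0.5" -> list(head = "lognormal", mu = 0, sigma = 0.5)
  out <- list(head = fields[1])
  for (f in fields[-1]) {
    kv <- strsplit(f, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("config key '", key, "': malformed argument '", f, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(kv[2]))
    out[[kv[1]]] <- if (is.na(num)) kv[2] else num
  }
  out
}

#' Read an INI-style configuration file
#'
#' Returns the raw key-value structure: a list with `global` (named list)
#' and `landscapes` (list of named lists, one per `[landscape]` section).
#' Use [load_inputs()] to turn it into a validated [simulation_config()].
#'
#' @param path config file path.
#' @return A list with elements `global` and `landscapes`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln); ln <- ln[nzchar(ln)]
  global <- list(); landscapes <- list(); cur <- NULL
  for (l in ln) {
    if (grepl("^\\[", l)) {
      sec <- tolower(gsub("\\[|\\]", "", l))
      if (sec != "landscape")
        stop("config file ", path, ": unknown section [", sec, "]",
             call. = FALSE)
      if (!is.null(cur)) landscapes[[length(landscapes) + 1L]] <- cur
      cur <- list()
      next
    }
    kv <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("config file ", path, ": cannot parse line '", l, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (is.null(cur)) global[[key]] <- val else cur[[key]] <- val
  }
  if (!is.null(cur)) landscapes[[length(landscapes) + 1L]] <- cur
  list(global = global, landscapes = landscapes)
}

.positions_from_string <- function(x, key) {
  if (is.null(x)) stop("each [landscape] section needs 'positions'", call. = FALSE)
  parts <- strsplit(trimws(x), "[,\\s]+")[[1]]
  out <- integer(0)
  for (p in parts) {
    if (p == "none") next
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      if (length(ab) != 2L || anyNA(ab))
        stop("config key '", key, "': bad range '", p, "'", call. = FALSE)
      out <- c(out, ab[1]:ab[2])
    } else out <- c(out, as.integer(p))
  }
  out
}

.landscape_from_section <- function(sec, alphabet, base_dir) {
  rel <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  key <- function(k) sec[[k]]

  init_f <- key("init")
  if (is.null(init_f)) init_f <- "lognormal mu=0 sigma=0.5"
  init_fields <- strsplit(trimws(init_f), "\\s+")[[1]]
  init <- if (init_fields[1] == "file") {
    if (length(init_fields) < 2L)
      stop("config key 'init': 'file' needs a path", call. = FALSE)
    list(file = rel(init_fields[2]))
  } else if (init_fields[1] == "values") {
    list(values = as.numeric(init_fields[-1]))
  } else {
    fi <- .parse_kv_args(init_fields, "init")
    switch(fi$head,
      gamma = list(dist = "gamma", shape = fi$shape, scale = fi$scale),
      lognormal = list(dist = "lognormal", mu = fi$mu, sigma = fi$sigma),
      stop("config key 'init': unknown source '", fi$head, "'", call. = FALSE))
  }

  reg_f <- key("regime")
  if (is.null(reg_f)) reg_f <- "none"
  ri <- .parse_kv_args(strsplit(trimws(reg_f), "\\s+")[[1]], "regime")
  events <- NULL
  if (identical(ri$head, "explicit")) {
    if (is.null(ri$file))
      stop("config key 'regime': explicit regime needs file=<schedule path>",
           call. = FALSE)
    events <- read_schedule(rel(ri$file), alphabet)
  }
  regime <- switch(ri$head,
    none = change_regime("none"),
    stochastic = change_regime("stochastic", lambda = ri$lambda,
      scale_lambda_with_q = isTRUE(.parse_bool(
        key("scale_lambda_with_q") %||% "false", "scale_lambda_with_q"))),
    periodic = change_regime("periodic", interval = ri$interval,
                             sharing = ri$sharing %||% "independent"),
    explicit = change_regime("explicit", events = events),
    stop("config key 'regime': unknown regime '", ri$head, "'", call. = FALSE))

  delta <- if (!is.null(key("delta"))) as.numeric(key("delta")) else NULL
  explicit_vectors <- NULL
  cr <- key("change_rule") %||% "resample"
  if (cr == "explicit" && !is.null(events))
    explicit_vectors <- Filter(Negate(is.null), events$fitness)
  rule <- landscape_rule(init = init, change_rule = cr, delta = delta,
                         explicit_vectors = explicit_vectors)

  init_fit <- NULL
  if (!is.null(key("init_fitness")))
    init_fit <- as.numeric(strsplit(trimws(key("init_fitness")), "\\s+")[[1]])

  landscape_spec(positions = .positions_from_string(key("positions"), "positions"),
                 rule = rule, regime = regime, init_fitness = init_fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate all simulation inputs
#'
#' Reads the configuration file, the tree, and any referenced fitness-vector,
#' mutation-matrix and schedule files, applies defaults (all-ones mutation
#' matrix, normalized scaling, stationary-sampled root), and returns a fully
#' validated configuration. Every invalid option combination raises an error
#' naming the offending key before any simulation starts.
#'
#' Global keys: `tree` (Newick path; required unless `tree_path` is given),
#' `alphabet` (e.g. `ACGT`), `scaling`, `seed`, `replicates`, `threads`,
#' `mutation_matrix` (path), `root_sequence`, `write_change_log`,
#' `write_internal_nodes`, `output_dir`. Per-`[landscape]` keys: `positions`
#' (e.g. `1-10`, or `none`), `init` (`lognormal mu=0 sigma=0.5`,
#' `gamma shape=2 scale=1`, `file <path>`, or `values v1 v2 ...`),
#' `change_rule`, `delta`, `regime` (`none`, `stochastic lambda=1`,
#' `periodic interval=0.5 sharing=shared`, `explicit file=<schedule>`),
#' `init_fitness`, `scale_lambda_with_q`.
#'
#' @param config_path path to the INI-style config file.
#' @param tree_path optional tree path overriding the config's `tree` key.
#' @return A list with `config` (a [simulation_config()]), `seed`,
#'   `replicates`, `threads`, `output_dir`, and the raw key-values in `raw`.
#' @export
load_inputs <- function(config_path, tree_path = NULL) {
  raw <- read_config(config_path)
  g <- raw$global
  base_dir <- dirname(normalizePath(config_path))
  rel <- function(p) if (file.exists(p)) p else file.path(base_dir, p)

  tp <- tree_path %||% g$tree
  if (is.null(tp))
    stop("config ", config_path, ": no 'tree' key and no tree_path given",
         call. = FALSE)
  tree <- read_newick(rel(tp))

  ab <- .as_alphabet(strsplit(g$alphabet %||% "ACGT", "")[[1]])
  mutation <- if (!is.null(g$mutation_matrix)) {
    m <- read_mutation_matrix(rel(g$mutation_matrix))
    if (!identical(unclass(attr(m, "alphabet")), unclass(ab)))
      stop("config key 'mutation_matrix': file alphabet does not match ",
           "'alphabet'", call. = FALSE)
    m
  } else NULL

  if (length(raw$landscapes) == 0L)
    stop("config ", config_path, ": at least one [landscape] section required",
         call. = FALSE)
  landscapes <- lapply(raw$landscapes, .landscape_from_section,
                       alphabet = ab, base_dir = base_dir)

  cfg <- simulation_config(
    tree = tree, landscapes = landscapes, alphabet = ab, mutation = mutation,
    scaling = g$scaling %||% "normalized",
    root_sequence = g$root_sequence,
    write_change_log = .parse_bool(g$write_change_log %||% "true",
                                   "write_change_log"),
    write_internal_nodes = .parse_bool(g$write_internal_nodes %||% "false",
                                       "write_internal_nodes"))
  list(config = cfg,
       seed = if (!is.null(g$seed)) as.integer(g$seed) else NULL,
       replicates = as.integer(g$replicates %||% "1"),
       threads = as.integer(g$threads %||% "1"),
       output_dir = g$output_dir %||% ".",
       raw = raw)
}

.write_fasta <- function(named_seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(named_seqs)) {
    writeLines(paste0(">", nm), con)
    s <- named_seqs[[nm]]
    if (nchar(s) == 0L) { writeLines("", con); next }
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

.config_fingerprint <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(list(tree = write_newick(config$tree),
            alphabet = unclass(config$alphabet),
            scaling = config$scaling,
            sequence_length = config$sequence_length,
            landscapes = lapply(config$landscapes, unclass),
            mutation = unclass(config$mutation),
            root_sequence = config$root_sequence), file = tf)
  unname(tools::md5sum(tf))
}

#' Write simulation outputs to a directory
#'
#' Writes `leaf_sequences.fasta` (all replicates; headers are node names,
#' suffixed `|rep<i>` when more than one replicate is present), optionally
#' `node_sequences.fasta` including internal nodes, `change_log.tsv` (one row
#' per landscape-change event, tab-separated), and `manifest.txt` recording
#' the seed, a config fingerprint, and per-replicate change counts.
#'
#' @param results a single `"simulation_result"` or a list of them.
#' @param config the [simulation_config()] that produced them.
#' @param output_dir directory (created if needed).
#' @param seed the master seed used (recorded in the manifest).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, config, output_dir, seed = NA) {
  if (inherits(results, "simulation_result")) results <- list(results)
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  tree <- config$tree
  multi <- length(results) > 1L
  tag <- function(nm, i) if (multi) paste0(nm, "|rep", i) else nm

  paths <- character(0)
  leaf_names <- tree$names[tree$is_leaf]
  leaf <- list(); full <- list()
  for (i in seq_along(results)) {
    sq <- results[[i]]$node_sequences
    for (nm in leaf_names) leaf[[tag(nm, i)]] <- sq[[nm]]
    if (config$write_internal_nodes)
      for (nm in tree$names) full[[tag(nm, i)]] <- sq[[nm]]
  }
  paths <- c(paths, .write_fasta(leaf, file.path(output_dir, "leaf_sequences.fasta")))
  if (config$write_internal_nodes)
    paths <- c(paths, .write_fasta(full, file.path(output_dir, "node_sequences.fasta")))

  if (config$write_change_log) {
    logs <- lapply(seq_along(results), function(i) {
      cl <- results[[i]]$change_log
      cbind(replicate = rep(i, nrow(cl)), cl)
    })
    log <- do.call(rbind, logs)
    p <- file.path(output_dir, "change_log.tsv")
    utils::write.table(log, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  counts <- vapply(results, function(r) nrow(r$change_log), 0L)
  man <- c(
    paste0("seed\t", seed),
    paste0("replicates\t", length(results)),
    paste0("config_md5\t", .config_fingerprint(config)),
    paste0("sequence_length\t", config$sequence_length),
    paste0("tree_leaves\t", sum(tree$is_leaf)),
    paste0("total_branch_length\t", format(tree_stats(tree)$total_branch_length)),
    "replicate\tchild_seed\tn_landscape_changes",
    vapply(seq_along(results), function(i)
      paste(i, results[[i]]$seed, counts[i], sep = "\t"), ""))
  mp <- file.path(output_dir, "manifest.txt")
  writeLines(man, mp)
  invisible(c(paths, mp))
}

#' Serialize a validated configuration back to INI text
#'
#' The written file reloads through [load_inputs()] into an equivalent run
#' (same seed, same outputs). File-based inputs (tree, schedules, mutation
#' matrix) are re-written alongside the config.
#'
#' @param config a [simulation_config()].
#' @param path config file path to write; auxiliary files are placed next to
#'   it.
#' @param seed,replicates,threads run parameters to record.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path, seed = NULL, replicates = 1L,
                         threads = 1L) {
  dir <- dirname(path)
  tree_file <- file.path(dir, "tree.nwk")
  write_newick(config$tree, tree_file)
  out <- c(
    paste0("tree = ", basename(tree_file)),
    paste0("alphabet = ", paste(unclass(config$alphabet), collapse = "")),
    paste0("scaling = ", config$scaling),
    if (!is.null(seed)) paste0("seed = ", seed),
    paste0("replicates = ", replicates),
    paste0("threads = ", threads),
    paste0("write_change_log = ", tolower(config$write_change_log)),
    paste0("write_internal_nodes = ", tolower(config$write_internal_nodes)),
    if (!is.null(config$root_sequence))
      paste0("root_sequence = ", config$root_sequence))
  if (!.is_uniform_M(config$mutation)) {
    mf <- file.path(dir, "mutation_matrix.txt")
    writeLines(c(paste(unclass(config$alphabet), collapse = " "),
                 apply(unclass(config$mutation), 1, paste, collapse = " ")), mf)
    out <- c(out, paste0("mutation_matrix = ", basename(mf)))
  }
  for (i in seq_along(config$landscapes)) {
    spec <- config$landscapes[[i]]
    out <- c(out, "", "[landscape]")
    pos <- spec$positions
    pos_str <- if (length(pos) == 0L) "none"
      else if (identical(pos, min(pos):max(pos))) paste0(min(pos), "-", max(pos))
      else paste(pos, collapse = " ")
    out <- c(out, paste0("positions = ", pos_str))
    init <- spec$rule$init
    out <- c(out, paste0("init = ",
      if (!is.null(init$dist)) {
        if (init$dist == "gamma")
          sprintf("gamma shape=%g scale=%g", init$shape, init$scale)
        else sprintf("lognormal mu=%g sigma=%g", init$mu, init$sigma)
      } else if (!is.null(init$values))
        paste("values", paste(init$values, collapse = " "))
      else paste("file", init$file)))
    out <- c(out, paste0("change_rule = ", spec$rule$change_rule))
    if (!is.null(spec$rule$delta))
      out <- c(out, paste0("delta = ", spec$rule$delta))
    if (!is.null(spec$init_fitness))
      out <- c(out, paste0("init_fitness = ",
                           paste(spec$init_fitness, collapse = " ")))
    reg <- spec$regime
    out <- c(out, paste0("regime = ", switch(reg$type,
      none = "none",
      stochastic = sprintf("stochastic lambda=%g", reg$lambda),
      periodic = sprintf("periodic interval=%g sharing=%s",
                         reg$interval, reg$sharing),
      explicit = {
        sf <- file.path(dir, sprintf("schedule_%d.txt", i))
        ev <- reg$events
        lines <- vapply(seq_along(ev$branch), function(r) {
          v <- ev$fitness[[r]]
          paste(c(ev$branch[r], ev$offset[r], v), collapse = " ")
        }, "")
        writeLines(lines, sf)
        sprintf("explicit file=%s", basename(sf))
      })))
    if (reg$type == "stochastic" && reg$scale_lambda_with_q)
      out <- c(out, "scale_lambda_with_q = true")
  }
  writeLines(out, path)
  invisible(path)
}
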