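#' Read DNA sequences from a FASTA file
#'
#' Standard FASTA parsing (multi-line records joined, IDs taken up to the
#' first whitespace, sequences upper-cased) with strict validation: empty
#' files and any character outside ACGT (including U and ambiguity codes)
#' raise a structured parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `seq`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_lasso(sprintf("file not found: %s", path), "io_error")
  if (file.size(path) == 0) stop_lasso(sprintf("FASTA file is empty: %s", path), "parse_error")
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_lasso(sprintf("cannot parse FASTA file %s: %s",
                                           path, conditionMessage(e)), "parse_error")
  )
  if (length(set) == 0) stop_lasso(sprintf("no FASTA records in %s", path), "parse_error")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    lines <- readLines(path, warn = FALSE)
    body <- !startsWith(lines, ">")
    offending <- which(body & grepl("[^ACGTacgt[:space:]]", lines))[1]
    stop_lasso(sprintf(
      "non-ACGT character in record '%s'%s",
      ids[which(bad)[1]],
      if (is.na(offending)) "" else sprintf(" (line %d of %s)", offending, path)),
      "parse_error", line = offending)
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with columns `id` and `seq` (as from [read_fasta()]), a
#'   named character vector, or a list of [nt_seq()] objects.
#' @param path Output path.
#' @param header Optional named character vector written as leading
#'   `; key: value` comment lines (e.g. the generating seed).
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path, header = NULL) {
  if (is.data.frame(x)) {
    ids <- x$id; seqs <- x$seq
  } else if (is.list(x)) {
    ids <- vapply(x, function(s) s$id, character(1))
    seqs <- vapply(x, function(s) s$seq, character(1))
  } else {
    ids <- names(x) %||% as.character(seq_along(x)); seqs <- as.character(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("; %s: %s", names(header), as.character(header)), con)
  }
  for (i in seq_along(ids)) {
    writeLines(sprintf(">%s", ids[i]), con)
    writeLines(gsub("(.{70})", "\\1\n", seqs[i]), con)
  }
  invisible(path)
}

# oxDNA length unit in nm (1 simulation unit = 0.8518 nm)
OXDNA_LENGTH_NM <- 0.8518

#' Export a configuration in the oxDNA two-file dialect
#'
#' Writes a topology file (particle and strand counts; per-nucleotide
#' strand, base, 3' and 5' neighbours) and a configuration file (time, box
#' and energy headers; per-nucleotide position plus identity orientation and
#' zero velocity vectors) that standard oxDNA viewers can render. Positions
#' are converted from nm to oxDNA length units (0.8518 nm each). The export
#' is visualization-grade: this package tracks bead positions only, so
#' orientations are placeholders.
#'
#' @param system A [capture_system()].
#' @param topology_path,configuration_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_oxdna_files <- function(system, topology_path, configuration_path) {
  stopifnot(inherits(system, "capture_system"))
  n <- nrow(system$positions)
  n_chain <- length(system$n_per_chain)
  bases <- system$sequence %||% rep("A", n)
  tryCatch({
    top <- file(topology_path, "w")
  }, error = function(e) stop_lasso(sprintf("cannot write topology to %s: %s",
                                            topology_path, conditionMessage(e)), "io_error"))
  on.exit(close(top), add = TRUE)
  writeLines(sprintf("%d %d", n, n_chain), top)
  idx <- seq_len(n) - 1L
  chain <- system$chain_id
  prev <- ifelse(idx > 0 & chain == c(-1L, chain[-n]), idx - 1L, -1L)
  nxt <- ifelse(idx < n - 1L & chain == c(chain[-1], -1L), idx + 1L, -1L)
  writeLines(sprintf("%d %s %d %d", chain + 1L, bases, prev, nxt), top)

  tryCatch({
    conf <- file(configuration_path, "w")
  }, error = function(e) stop_lasso(sprintf("cannot write configuration to %s: %s",
                                            configuration_path, conditionMessage(e)), "io_error"))
  on.exit(close(conf), add = TRUE)
  b <- system$box_side / OXDNA_LENGTH_NM
  writeLines(c("t = 0",
               sprintf("b = %.8f %.8f %.8f", b, b, b),
               "E = 0 0 0"), conf)
  p <- system$positions / OXDNA_LENGTH_NM
  writeLines(sprintf("%.8f %.8f %.8f 1 0 0 0 1 0 0 0 0 0 0 0",
                     p[, 1], p[, 2], p[, 3]), conf)
  invisible(list(topology = topology_path, configuration = configuration_path))
}

#' Read back an oxDNA configuration written by [write_oxdna_files()]
#'
#' @param configuration_path Path to the configuration file.
#' @return List with `positions` (n x 3 matrix, nm) and `box_side` (nm).
#' @export
read_oxdna_configuration <- function(configuration_path) {
  lines <- readLines(configuration_path)
  if (length(lines) < 4) stop_lasso("not an oxDNA configuration file", "parse_error")
  b <- as.numeric(strsplit(sub("^b = ", "", lines[2]), " ")[[1]])
  rows <- do.call(rbind, lapply(strsplit(lines[-(1:3)], " +"), as.numeric))
  list(positions = rows[, 1:3, drop = FALSE] * OXDNA_LENGTH_NM,
       box_side = b[1] * OXDNA_LENGTH_NM)
}

# --- grid (histogram / weight / distribution) CSV I/O -----------------------

write_grid_csv <- function(mat, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(sprintf("# %s: %s", names(header), as.character(header)), con)
  }
  utils::write.table(as.matrix(mat), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_grid_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  header <- list()
  for (h in hdr_lines) {
    kv <- sub("^# *", "", lines[h])
    key <- sub(":.*$", "", kv)
    header[[key]] <- sub("^[^:]*: *", "", kv)
  }
  mat <- as.matrix(utils::read.table(text = lines[setdiff(seq_along(lines), hdr_lines)],
                                     sep = ",", header = FALSE))
  dimnames(mat) <- NULL
  list(matrix = mat, header = header)
}

#' Write / read umbrella grids as CSV
#'
#' 2D grids (histograms, weight tables, unbiased distributions) are stored
#' as plain CSV matrices, one row per `Q_ex` value, preceded by `# key:
#' value` comment lines carrying the seed, the weight-table hash, and the
#' bin edges, so every artifact is traceable to the run that made it.
#'
#' @param x A `capture_histogram` or [weight_table()].
#' @param path Output path.
#' @return The path (writers) or a reconstructed object (readers).
#' @export
write_histogram_csv <- function(x, path) {
  stopifnot(inherits(x, "capture_histogram"))
  write_grid_csv(x$counts, path,
                 c(type = "histogram", seed = x$seed,
                   weight_hash = x$weight_hash, n_samples = x$n_samples,
                   edges = paste(x$edges, collapse = " ")))
}

#' @rdname write_histogram_csv
#' @export
write_weights_csv <- function(x, path) {
  stopifnot(inherits(x, "weight_table"))
  write_grid_csv(x$weights, path,
                 c(type = "weights", weight_hash = x$hash,
                   edges = paste(x$edges, collapse = " ")))
}

#' @rdname write_histogram_csv
#' @export
read_weights_csv <- function(path) {
  g <- read_grid_csv(path)
  edges <- as.numeric(strsplit(g$header$edges, " ")[[1]])
  weight_table(g$matrix, bin_table(edges))
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  g <- read_grid_csv(path)
  edges <- as.numeric(strsplit(g$header$edges, " ")[[1]])
  nq <- length(edges)
  counts <- g$matrix
  dimnames(counts) <- list(q_ex = 0:(nq - 1L), q_lig = 0:(nq - 1L))
  structure(
    list(counts = counts, n_samples = sum(counts), weight_table = NULL,
         weight_hash = g$header$weight_hash,
         trajectory = tibble(step = integer(0), q_ex = integer(0), q_lig = integer(0)),
         edges = edges, acceptance = NA_real_, capped_rejections = NA_real_,
         system = NULL, seed = as.integer(g$header$seed), engine = NA_character_),
    class = "capture_histogram"
  )
}

#' Read a run configuration from a YAML file
#'
#' The file may set `seed`, `box_side`, `engine`, `bin_edges`, the stage
#' step counts (`adapt_blocks`, `block_steps`, `flatness_target`,
#' `equil_steps`, `production_steps`, `stride`), `out_dir`, and nested
#' `energy:` / `move:` blocks with [energy_params()] / [move_params()]
#' arguments. Unknown keys anywhere are rejected.
#'
#' @param path Path to a YAML config file.
#' @return A [capture_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_lasso(sprintf("config file not found: %s", path), "io_error")
  raw <- yaml::read_yaml(path)
  known_top <- c("seed", "box_side", "engine", "bin_edges", "adapt_blocks",
                 "block_steps", "flatness_target", "equil_steps",
                 "production_steps", "stride", "out_dir", "energy", "move")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop_lasso(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
               "invalid_config")
  }
  chk_args <- function(given, fn, label) {
    bad <- setdiff(names(given), names(formals(fn)))
    if (length(bad)) {
      stop_lasso(paste0("unknown ", label, " key(s): ", paste(bad, collapse = ", ")),
                 "invalid_config")
    }
    given
  }
  params <- do.call(energy_params, chk_args(raw$energy %||% list(), energy_params, "energy"))
  move <- do.call(move_params, chk_args(raw$move %||% list(), move_params, "move"))
  bins <- if (is.null(raw$bin_edges)) default_bin_table() else bin_table(unlist(raw$bin_edges))
  args <- raw[setdiff(names(raw), c("energy", "move", "bin_edges"))]
  do.call(capture_config, c(list(params = params, move = move, bins = bins), args))
}
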