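# Reading and writing the formats the pipeline touches: newick tree lists,
# NEXUS trees blocks (MrBayes ".t" files with translate tables), NEXUS
# character matrices, and TSV ranking files.

#' Read a sample of trees with burn-in handling
#'
#' Reads an ordered list of trees from a newick file (one tree per line) or
#' a NEXUS trees block (translate tables, as written by MrBayes, are
#' resolved so returned trees carry full taxon names), discards an initial
#' burn-in, and returns the remainder in file order.  All trees are treated
#' as unrooted: a degree-2 root is suppressed on read.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (sniff for a `#NEXUS` header), `"newick"` or
#'   `"nexus"`.
#' @param burnin fraction of trees in the file to discard from the front,
#'   in `[0, 1)`.  The first `floor(burnin * N)` of the `N` trees are
#'   dropped.
#' @param burnin_count alternatively, an absolute number of leading trees to
#'   discard (overrides `burnin` when given).
#' @return a list of `phylo` trees, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines(c("((A,B),(C,D));", "((A,C),(B,D));"), tf)
#' length(read_trees(tf, burnin = 0.5))
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       burnin = 0, burnin_count = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  if (!is.numeric(burnin) || length(burnin) != 1L || burnin < 0 ||
      burnin >= 1) {
    stop("burnin must be a fraction in [0, 1)", call. = FALSE)
  }
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (length(first) && startsWith(first, "#NEXUS")) "nexus"
              else "newick"
  }
  trees <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
    ),
    error = function(e) {
      stop("failed to parse ", format, " tree file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(trees)) {
    stop("failed to parse ", format, " tree file '", path, "'",
         call. = FALSE)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unname(lapply(trees, as_topology))
  n <- length(trees)
  drop <- if (!is.null(burnin_count)) as.integer(burnin_count)
          else as.integer(floor(burnin * n))
  if (drop < 0 || drop >= n) {
    stop("burn-in discards all ", n, " trees in '", path, "'", call. = FALSE)
  }
  trees[seq.int(drop + 1L, n)]
}

#' Character matrix class
#'
#' A taxa-by-characters table of single-character state symbols, as read
#' from a NEXUS data/characters block.  Missing data is coded `"?"` and
#' inapplicable/gap states `"-"`; both are preserved verbatim.
#'
#' @param x a character matrix (rows = taxa, one symbol per cell) with
#'   unique, nonempty row names.
#' @return an object of class `character_matrix` (a character matrix with
#'   taxon row names).
#' @export
character_matrix <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("x must be a character matrix", call. = FALSE)
  }
  rn <- rownames(x)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn))) {
    stop("taxon row names must be unique and nonempty", call. = FALSE)
  }
  rownames(x) <- normalize_label(rn)
  structure(x, class = c("character_matrix", "matrix"))
}

#' Read a NEXUS character matrix
#'
#' Parses the data/characters block of a NEXUS file (sequential or
#' interleaved) into a [character_matrix()], preserving state symbols
#' verbatim including missing (`?`) and gap (`-`) codes.
#'
#' @param path path to the NEXUS file.
#' @return a `character_matrix`.
#' @export
read_character_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  rows <- tryCatch(
    ape::read.nexus.data(path),
    error = function(e) {
      stop("failed to parse NEXUS matrix '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged NEXUS matrix: row lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  character_matrix(m)
}

# Emit a character_matrix as a standard-datatype NEXUS file.
write_nexus_matrix <- function(mat, path) {
  rows <- lapply(seq_len(nrow(mat)), function(i) unname(mat[i, ]))
  names(rows) <- rownames(mat)
  ape::write.nexus.data(rows, path, format = "standard")
  invisible(path)
}

#' Write drop-one jackknife matrices
#'
#' Prepares the inputs for taxon jackknifing: one NEXUS file per taxon, each
#' containing the full character matrix minus that taxon's row, characters
#' unchanged.  File names encode the dropped taxon.
#'
#' @param matrix a [character_matrix()] with at least 4 taxa.
#' @param outdir output directory (created if absent).
#' @param stem file-name stem; files are named `<stem>_drop_<taxon>.nex`.
#' @return invisibly, a named character vector of file paths (names are the
#'   dropped taxa).
#' @export
write_jackknife_matrices <- function(matrix, outdir, stem = "jackknife") {
  stopifnot(inherits(matrix, "character_matrix"))
  if (nrow(matrix) < 4L) {
    stop("jackknife matrices need at least 4 taxa (pruned trees must keep ",
         ">= 3 leaves)", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  taxa <- rownames(matrix)
  paths <- character(length(taxa))
  for (i in seq_along(taxa)) {
    paths[i] <- file.path(outdir, paste0(stem, "_drop_", taxa[i], ".nex"))
    write_nexus_matrix(matrix[-i, , drop = FALSE], paths[i])
  }
  names(paths) <- taxa
  invisible(paths)
}

#' Write and read taxon rankings
#'
#' Rankings are exchanged as TSV with columns `taxon`, `score`, `rank`
#' (rank is the 1-based position).  Scores are written with 15 significant
#' digits so a round trip preserves the ordering.
#'
#' @param ranking a [ranking()] object.
#' @param path file path.
#' @return `write_ranking` returns `path` invisibly; `read_ranking` returns
#'   a [ranking()].
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "taxon_ranking"))
  df <- data.frame(taxon = ranking$taxon,
                   score = format(ranking$score, digits = 15,
                                  scientific = TRUE, trim = TRUE),
                   rank = ranking$rank)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("ranking file not found: ", path,
                               call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed ranking TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("taxon", "score", "rank")
  if (!all(need %in% names(df))) {
    stop("ranking TSV must have columns taxon, score, rank", call. = FALSE)
  }
  df <- df[order(df$rank), , drop = FALSE]
  if (!identical(as.integer(df$rank), seq_len(nrow(df)))) {
    stop("rank column must be 1..n with no gaps", call. = FALSE)
  }
  ranking(df$taxon, as.numeric(df$score))
}
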