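# Plain-text interchange: FASTA plus Vienna dot-bracket sidecar files for
# structured sequences, square TSV distance matrices, and Newick trees.

#' Write structured sequences to FASTA plus a structure sidecar
#'
#' The FASTA file holds the nucleotides (written as DNA, `U` -> `T`); the
#' sidecar holds one line per record in the form `>id` / dot-bracket, in
#' the same order.
#'
#' @param seqs list of [structured_seq()] objects.
#' @param fasta,sidecar output paths.
#' @return invisibly, the two paths.
#' @export
write_structured_fasta <- function(seqs, fasta, sidecar) {
  fa <- unlist(lapply(seqs, function(s) {
    c(paste0(">", s$id), chartr("U", "T", s$seq))
  }))
  db <- unlist(lapply(seqs, function(s) c(paste0(">", s$id), s$structure)))
  writeLines(fa, fasta)
  writeLines(db, sidecar)
  invisible(c(fasta = fasta, sidecar = sidecar))
}

#' Read structured sequences from FASTA plus a structure sidecar
#'
#' @param fasta,sidecar paths written by [write_structured_fasta()] (or any
#'   FASTA and matching dot-bracket sidecar with identical ids).
#' @return named list of [structured_seq()] objects.
#' @export
read_structured_fasta <- function(fasta, sidecar) {
  if (!file.exists(fasta)) stop("missing FASTA file: ", fasta, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("missing structure sidecar file: ", sidecar, call. = FALSE)
  }
  parse_fa <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no records in ", path, call. = FALSE)
    ids <- sub("^>\\s*", "", lines[hdr])
    ends <- c(hdr[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1):ends[i]], collapse = "")
    }, character(1))
    setNames(seqs, ids)
  }
  nt <- parse_fa(fasta)
  db <- parse_fa(sidecar)
  if (!identical(names(nt), names(db))) {
    stop("FASTA and sidecar ids differ", call. = FALSE)
  }
  out <- lapply(names(nt), function(id) structured_seq(id, nt[id], db[id]))
  setNames(out, names(nt))
}

#' Write a square distance matrix as TSV
#'
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  write.table(as.matrix(d), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' Read a square TSV distance matrix
#'
#' @param path a file written by [write_distance_tsv()] (PHYLIP-style
#'   square matrices with a leading id column are accepted).
#' @return symmetric numeric matrix.
#' @export
read_distance_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                            row.names = 1, check.names = FALSE))
  .check_distance_matrix(m)
}

#' Write a planted-truth object as JSON
#'
#' Serializes the `truth` element of any `simulate_*` result (planted CBC
#' matrix, strain-to-ribotype map, copy numbers, niche optima, ...) so a
#' generated data set can be re-checked against its ground truth later.
#'
#' @param truth a truth list from one of the simulators.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  truth <- rapply(truth, unclass, how = "replace")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}

#' Write a tree with support labels as Newick
#'
#' @param tree a `phylo` tree (e.g. from [bootstrap_support()]).
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
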