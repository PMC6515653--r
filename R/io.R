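#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a plain named
#' character vector, which is the sequence container used throughout the
#' package. Headers are kept verbatim (free text allowed).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a TSV table with required-column validation
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of column names that must be present.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path, required = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("TSV file '", path, "' is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Write a data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Wrappers over [ape::read.tree()] / [ape::write.tree()]; bootstrap supports
#' travel as internal node labels (the common Newick dialect).
#'
#' @param path Path to a Newick file.
#' @return `read_newick`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file '", path, "' does not exist")
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file '", path, "'")
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @return `write_newick`: `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
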