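#' Construct a sequence set
#'
#' A `seq_set` holds DNA sequences together with the two orderings the
#' clustering algorithm relies on: a lexicographic order of the residues
#' (the backbone of the implicit trie used by the search) and a
#' non-increasing length order (the greedy center-picking order).
#'
#' Residues are uppercased on construction; only the characters
#' `A`, `C`, `G`, `T`, `N` are accepted. Length ties in `len_order` are
#' broken lexicographically by residues and then by id, so both orderings
#' are total and the whole pipeline is deterministic.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of residue strings, same length as `id`.
#' @return An object of class `seq_set`: a list with elements `id`, `seq`,
#'   `length`, `lex_order` and `len_order` (both orders are permutations of
#'   `seq_along(id)`).
#' @examples
#' ss <- seq_set(c("X", "Y"), c("acgt", "ACG"))
#' ss$seq[ss$len_order]   # longest first
#' ss$seq[ss$lex_order]   # lexicographic
#' @export
seq_set <- function(id, seq) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("id and seq must have the same length")
  if (anyNA(id) || any(!nzchar(id)))
    stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate sequence id: '", dup, "'")
  }
  if (any(!nzchar(seq))) {
    empty <- id[!nzchar(seq)][1L]
    stop("empty sequence for id '", empty, "'")
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid residue '", substr(seq[i], bad[i], bad[i]), "' at position ",
         bad[i], " in sequence '", id[i], "' (alphabet is A/C/G/T/N)")
  }
  len <- nchar(seq)
  structure(
    list(
      id = id,
      seq = seq,
      length = len,
      lex_order = order(seq, id, method = "radix"),
      len_order = order(-len, seq, id, method = "radix")
    ),
    class = "seq_set"
  )
}

#' Number of sequences in a set
#' @param x a [seq_set()].
#' @return Integer count.
#' @export
n_seq <- function(x) {
  stopifnot(inherits(x, "seq_set"))
  length(x$id)
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", length(x$id), " sequences",
      if (length(x$id)) paste0(", lengths ", min(x$length), "-",
                               max(x$length), " bp"),
      "\n", sep = "")
  invisible(x)
}

#' Read a multi-FASTA file into a sequence set
#'
#' Wraps [Biostrings::readDNAStringSet()]; the id of each record is the
#' first whitespace-delimited token of its header. Line wrapping is
#' ignored, residues are uppercased, and both canonical orderings are
#' computed. An empty file yields an empty (valid) set; duplicate ids,
#' empty records and residues outside `A/C/G/T/N` are hard errors.
#'
#' @param path path to a FASTA file.
#' @return A [seq_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(seq_set(character(), character()))
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  seq_set(ids, as.character(x))
}

#' Write a sequence set to a FASTA file
#'
#' @param x a [seq_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  dss <- Biostrings::DNAStringSet(x$seq)
  names(dss) <- x$id
  Biostrings::writeXStringSet(dss, filepath = path, width = 20000L)
  invisible(path)
}

#' Write a clustering to a flat cluster file
#'
#' One line per cluster, tab-separated member ids with the representative
#' first; clusters appear in order of creation and members in order of
#' recruitment. The lines partition the input id set.
#'
#' @param clustering a `dna_clustering` as returned by [dna_cluster()].
#' @param file a file path or connection (default: standard output).
#' @return Invisibly, the character vector of lines written.
#' @export
write_clusters <- function(clustering, file = stdout()) {
  stopifnot(inherits(clustering, "dna_clustering"))
  ids <- clustering$seqs$id
  lines <- vapply(
    clustering$clusters,
    function(cl) paste(ids[cl$members], collapse = "\t"),
    character(1)
  )
  writeLines(lines, con = file)
  invisible(lines)
}

#' Parse a cluster file back into id groups
#'
#' @param file path or connection to a file written by [write_clusters()].
#' @return A list of character vectors of member ids, representative first.
#' @export
read_clusters <- function(file) {
  lines <- readLines(file)
  strsplit(lines, "\t", fixed = TRUE)
}
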