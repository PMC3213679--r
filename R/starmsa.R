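#' Star multiple sequence alignment of one cluster
#'
#' Reconciles the member-versus-representative pairwise alignments
#' produced during clustering into one rectangular alignment. For every
#' representative position, a block of columns is allocated *before* it
#' whose width is the longest insertion run any member places there;
#' members write their insertions left-justified into the block and pad
#' with gaps ("once a gap, always a gap" relative to the pairwise
#' alignments). Columns in which the representative has a residue
#' reproduce each pairwise alignment's column pairing exactly, so the
#' column-wise distance between any two rows is at most twice the cluster
#' radius (see [msa_column_dist()]).
#'
#' @param clustering a `dna_clustering` built with `alignments = TRUE`.
#' @param cluster index of the cluster within `clustering$clusters`.
#' @return A `star_msa`: list with `ids` (representative first), `rows`
#'   (equal-length gapped strings) and `policy`.
#' @export
build_star_msa <- function(clustering, cluster) {
  stopifnot(inherits(clustering, "dna_clustering"))
  cl <- clustering$clusters[[cluster]]
  if (is.null(cl$alignments))
    stop("cluster carries no pairwise alignments; ",
         "rerun dna_cluster() with alignments = TRUE")
  seqs <- clustering$seqs
  rep_seq <- seqs$seq[cl$center]
  L <- nchar(rep_seq)
  m <- length(cl$members)

  # ins[[i]]: insertion run lengths of member i before rep positions 1..L+1
  ins <- vector("list", m)
  parsed <- vector("list", m)
  for (i in seq_len(m)) {
    al <- cl$alignments[[i]]
    q <- strsplit(al$query_row, "", fixed = TRUE)[[1]]
    s <- strsplit(al$subject_row, "", fixed = TRUE)[[1]]
    runs <- integer(L + 1L)
    pos <- 1L # next representative position
    run <- 0L
    member_at <- vector("list", L + 1L) # member chars: insertions per slot
    aligned <- character(L)             # member char aligned to rep position
    buf <- character(0)
    for (c in seq_along(q)) {
      if (q[c] == "-") {
        run <- run + 1L
        buf <- c(buf, s[c])
      } else {
        runs[pos] <- run
        member_at[[pos]] <- buf
        aligned[pos] <- s[c]
        run <- 0L
        buf <- character(0)
        pos <- pos + 1L
      }
    }
    runs[L + 1L] <- run
    member_at[[L + 1L]] <- buf
    if (pos != L + 1L)
      stop("pairwise alignment does not cover the full representative")
    ins[[i]] <- runs
    parsed[[i]] <- list(inserts = member_at, aligned = aligned)
  }
  widths <- do.call(pmax, c(ins, list(integer(L + 1L))))

  pad <- function(chars, w) {
    c(chars, rep("-", w - length(chars)))
  }
  rows <- character(m)
  for (i in seq_len(m)) {
    p <- parsed[[i]]
    pieces <- character(0)
    for (pos in seq_len(L)) {
      pieces <- c(pieces, pad(p$inserts[[pos]], widths[pos]), p$aligned[pos])
    }
    pieces <- c(pieces, pad(p$inserts[[L + 1L]], widths[L + 1L]))
    rows[i] <- paste(pieces, collapse = "")
  }
  structure(
    list(ids = seqs$id[cl$members], rows = rows,
         policy = clustering$params$policy),
    class = "star_msa"
  )
}

#' @export
print.star_msa <- function(x, ...) {
  cat("<star_msa> ", length(x$ids), " rows x ", nchar(x$rows[1]),
      " columns\n", sep = "")
  invisible(x)
}

#' Column-wise pairwise distances within a star MSA
#'
#' Scores each pair of rows column by column: a mismatch between two
#' residues or a residue against a charged gap costs 1; a double gap costs
#' 0. Terminal gap runs of a row are free exactly when the alignment
#' policy leaves that end of the shorter sequence unpenalised (the default
#' policy charges leading, frees trailing), mirroring how the pairwise
#' costs themselves are charged. Under this scoring the column-wise
#' triangle inequality holds, so the matrix is bounded by twice the
#' cluster radius.
#'
#' @param msa a [build_star_msa()] result.
#' @return A symmetric integer matrix of column-charged distances.
#' @export
msa_column_dist <- function(msa) {
  stopifnot(inherits(msa, "star_msa"))
  m <- length(msa$rows)
  chars <- lapply(msa$rows, function(r) strsplit(r, "", fixed = TRUE)[[1]])
  w <- length(chars[[1]])
  charged <- lapply(chars, function(cc) {
    ch <- rep(TRUE, w)
    gap <- cc == "-"
    if (!msa$policy$anchor_start && gap[1]) {
      r <- rle(gap)
      ch[seq_len(r$lengths[1])] <- FALSE
    }
    if (!msa$policy$anchor_end && gap[w]) {
      r <- rle(gap)
      ch[(w - r$lengths[length(r$lengths)] + 1L):w] <- FALSE
    }
    ch
  })
  out <- matrix(0L, m, m, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j <= i) next
      a <- chars[[i]]; b <- chars[[j]]
      ga <- a == "-"; gb <- b == "-"
      diff <- (!ga & !gb & a != b) |
        (ga & !gb & charged[[i]]) |
        (!ga & gb & charged[[j]])
      out[i, j] <- out[j, i] <- sum(diff)
    }
  }
  out
}

#' Degap the rows of a star MSA
#' @param msa a `star_msa`.
#' @return Character vector of the original (ungapped) member sequences.
#' @export
degap <- function(msa) {
  stopifnot(inherits(msa, "star_msa"))
  gsub("-", "", msa$rows, fixed = TRUE)
}

#' Write a star MSA as aligned multi-FASTA
#'
#' One record per member, representative first, `-` as the gap character.
#'
#' @param msa a [build_star_msa()] result.
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_msa <- function(msa, file) {
  stopifnot(inherits(msa, "star_msa"))
  dss <- Biostrings::DNAStringSet(msa$rows)
  names(dss) <- msa$ids
  Biostrings::writeXStringSet(dss, filepath = file, width = 20000L)
  invisible(file)
}

#' Write one aligned FASTA file per cluster
#'
#' @param clustering a `dna_clustering` built with `alignments = TRUE`.
#' @param dir output directory (created if missing); files are named after
#'   the representative id.
#' @return Invisibly, the vector of files written.
#' @export
write_all_msas <- function(clustering, dir) {
  stopifnot(inherits(clustering, "dna_clustering"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(clustering$clusters))
  for (i in seq_along(clustering$clusters)) {
    msa <- build_star_msa(clustering, i)
    rep_id <- clustering$seqs$id[clustering$clusters[[i]]$center]
    safe <- gsub("[^A-Za-z0-9._-]", "_", rep_id)
    files[i] <- file.path(dir, paste0(safe, ".fasta"))
    write_msa(msa, files[i])
  }
  invisible(files)
}
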