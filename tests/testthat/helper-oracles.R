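# Independent reference implementations used as oracles. These deliberately
# share no code with the package: the edit-distance oracle fills whole
# unbanded rows with vectorised column closures, the spectrum oracle counts
# substrings via table(), and the lcp oracle compares characters directly.

# Unbanded (semi-)global unit-cost edit distance. Returns the final cost, or
# with keep_rows = TRUE the whole (|subject|+1) x (|query|+1) matrix.
ref_edit_cost <- function(query, subject, anchor_start = TRUE,
                          anchor_end = FALSE, keep_rows = FALSE) {
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  s <- strsplit(subject, "", fixed = TRUE)[[1]]
  n <- length(q)
  prev <- if (anchor_start) 0:n else rep(0L, n + 1)
  rows <- if (keep_rows) matrix(0L, length(s) + 1, n + 1) else NULL
  if (keep_rows) rows[1, ] <- prev
  idx <- 0:n
  for (i in seq_along(s)) {
    sub <- prev[seq_len(n)] + ifelse(q == s[i] & q != "N", 0L, 1L)
    up <- prev[2:(n + 1)] + 1L
    base <- c(i, pmin(sub, up))
    # close over horizontal moves: cur[j] = min_h base[h] + (j - h)
    cur <- cummin(base - idx) + idx
    prev <- cur
    if (keep_rows) rows[i + 1, ] <- cur
  }
  if (keep_rows) return(rows)
  if (anchor_end) prev[n + 1] else min(prev)
}

ref_cost_policy <- function(query, subject, policy) {
  ref_edit_cost(query, subject, policy$anchor_start, policy$anchor_end)
}

# Brute-force hit list: every eligible candidate not longer than the query
# whose reference cost is within its own acceptance radius.
ref_search <- function(seqs, eligible, query, policy, accept_fun) {
  hits <- data.frame(index = integer(0), cost = integer(0))
  for (i in seq_along(seqs)) {
    if (!eligible[i] || nchar(seqs[i]) > nchar(query)) next
    cost <- ref_cost_policy(query, seqs[i], policy)
    if (cost <= accept_fun(nchar(seqs[i])))
      hits <- rbind(hits, data.frame(index = i, cost = cost))
  }
  hits
}

ref_spectrum <- function(s, k) {
  n <- nchar(s)
  counts <- integer(4^k)
  if (n >= k) {
    words <- substring(s, 1:(n - k + 1), k:n)
    words <- words[!grepl("N", words, fixed = TRUE)]
    if (length(words)) {
      codes <- vapply(strsplit(words, "", fixed = TRUE), function(w) {
        sum((match(w, c("A", "C", "G", "T")) - 1L) * 4^((k - 1):0))
      }, numeric(1))
      tab <- table(codes)
      counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
  }
  counts
}

ref_lcp <- function(sorted_seqs) {
  n <- length(sorted_seqs)
  out <- integer(n)
  for (i in seq_len(n)[-1]) {
    a <- strsplit(sorted_seqs[i - 1], "", fixed = TRUE)[[1]]
    b <- strsplit(sorted_seqs[i], "", fixed = TRUE)[[1]]
    m <- 0L
    while (m < min(length(a), length(b)) && a[m + 1] == b[m + 1]) m <- m + 1L
    out[i] <- m
  }
  out
}

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Charge an alignment column by column under the policy: mismatch or charged
# gap = 1; terminal gap runs of the subject row are free when that end is
# unanchored. Used to confirm traceback cost bookkeeping.
charged_cost <- function(aln, policy) {
  q <- strsplit(aln$query_row, "", fixed = TRUE)[[1]]
  s <- strsplit(aln$subject_row, "", fixed = TRUE)[[1]]
  stopifnot(length(q) == length(s))
  w <- length(q)
  free <- rep(FALSE, w)
  gaps <- s == "-"
  if (!policy$anchor_start && gaps[1]) {
    r <- rle(gaps)
    free[seq_len(r$lengths[1])] <- TRUE
  }
  if (!policy$anchor_end && gaps[w]) {
    r <- rle(gaps)
    free[(w - r$lengths[length(r$lengths)] + 1L):w] <- TRUE
  }
  sum((q != "-" & s != "-" & (q != s | q == "N")) |
        (s == "-" & !free) |
        (q == "-"))
}

# Mutate a sequence with exactly n_edits random substitutions/indels.
apply_edits <- function(s, n_edits) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (t in seq_len(n_edits)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    if (op == "del" && length(chars) <= 1L) op <- "sub"
    p <- sample(length(chars), 1L)
    if (op == "sub") chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    else if (op == "del") chars <- chars[-p]
    else chars <- append(chars, sample(bases, 1L), after = p - 1L)
  }
  paste(chars, collapse = "")
}

both_policies <- list(
  semi = alignment_policy(TRUE, FALSE),
  global = alignment_policy(TRUE, TRUE)
)
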