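#' Enumerate candidate clonal structures
#'
#' A clonal structure is a set partition of a participant's variant labels
#' into clones; variants sharing a block share one fitness value. For `k`
#' variants there are Bell-number `B(k)` partitions; all are returned in
#' canonical restricted-growth-string order when `k <= max_exhaustive`.
#' Above that the exhaustive set is intractable and a reduced candidate
#' set is produced by greedy agglomeration during fitting (see
#' [ch_fit()]); here the singleton and a flag are returned.
#'
#' @param variants Character vector of distinct variant labels.
#' @param max_exhaustive Largest `k` for which all `B(k)` partitions are
#'   enumerated (default 8; `B(8) = 4140`).
#' @return A list of partitions; each partition is a list of character
#'   vectors (blocks). Attribute `exhaustive` records whether the set is
#'   complete.
#' @examples
#' length(enumerate_structures(c("a", "b", "c")))  # B(3) = 5
#' @export
enumerate_structures <- function(variants, max_exhaustive = 8) {
  if (anyDuplicated(variants))
    condition_error("variant labels must be distinct", "clonedyn_parameter_error")
  k <- length(variants)
  if (k == 0L) return(structure(list(), exhaustive = TRUE))
  if (k > max_exhaustive) {
    out <- list(lapply(variants, identity))  # singletons; search refines later
    out[[1]] <- lapply(variants, function(v) v)
    attr(out, "exhaustive") <- FALSE
    return(out)
  }
  codes <- rgs_enumerate(k)
  out <- lapply(codes, function(code) {
    lapply(seq_len(max(code)), function(b) variants[code == b])
  })
  attr(out, "exhaustive") <- TRUE
  out
}

# All restricted growth strings of length k in lexicographic order:
# code[1] = 1, code[i] <= max(code[1..i-1]) + 1.
rgs_enumerate <- function(k) {
  acc <- list()
  recurse <- function(code, mx) {
    if (length(code) == k) { acc[[length(acc) + 1L]] <<- code; return(invisible()) }
    for (b in seq_len(mx + 1L)) recurse(c(code, b), max(mx, b))
  }
  recurse(1L, 1L)
  acc
}

# Canonical comparable key for a partition (used for deterministic ties).
partition_key <- function(partition, variants) {
  code <- integer(length(variants))
  for (b in seq_along(partition)) code[match(partition[[b]], variants)] <- b
  # renumber to restricted-growth form
  seen <- integer(0)
  rg <- integer(length(code))
  for (i in seq_along(code)) {
    j <- match(code[i], seen)
    if (is.na(j)) { seen <- c(seen, code[i]); j <- length(seen) }
    rg[i] <- j
  }
  paste(rg, collapse = ".")
}
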