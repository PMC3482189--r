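#' Base-pair table of a reference secondary structure
#'
#' A `pair_table` records, for an ungapped reference sequence of known
#' length, which positions are base-paired with which.  Positions are
#' 0-based and every position belongs to at most one pair.
#'
#' @param length positive integer, the ungapped reference length.
#' @param pairs two-column integer matrix (or empty) of 0-based position
#'   pairs; rows are reordered so the 5' (smaller) position comes first.
#' @return an object of class `pair_table` with elements `length` and
#'   `pairs` (a two-column integer matrix, ordered by 5' position).
#' @export
pair_table <- function(length, pairs) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    stop("reference length must be a positive integer")
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    swap <- pairs[, 1L] > pairs[, 2L]
    pairs[swap, ] <- pairs[swap, 2:1]
  }
  if (any(pairs < 0L) || any(pairs >= length))
    stop("pair positions out of range [0, length)")
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a position cannot pair with itself")
  occ <- c(pairs)
  if (anyDuplicated(occ))
    stop("position ", occ[duplicated(occ)][1L], " occurs in more than one pair")
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  colnames(pairs) <- c("pos5", "pos3")
  structure(list(length = length, pairs = pairs), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table: length", x$length, "with", nrow(x$pairs), "base pairs\n")
  invisible(x)
}

#' Parse a secondary-structure annotation into a pair table
#'
#' Accepts dot-bracket strings (round brackets plus the optional extra
#' tiers `[]`, `{}`, `<>` for crossing interactions) and the 1-based
#' tabular CT and bpseq formats.
#'
#' @param text the annotation: a single string (dot-bracket) or the lines
#'   of a CT/bpseq file (character vector or single string with newlines).
#' @param format one of `"auto"`, `"dotbracket"`, `"ct"`, `"bpseq"`.
#' @return a [pair_table()].
#' @examples
#' parse_structure("((..))")
#' @export
parse_structure <- function(text, format = c("auto", "dotbracket", "ct", "bpseq")) {
  format <- match.arg(format)
  if (length(text) == 0L || !nzchar(paste(text, collapse = "")))
    stop("empty structure annotation")
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    body <- lines[!startsWith(trimws(lines), "#")]
    first <- trimws(body[if (length(body) > 1L) 2L else 1L])
    nfield <- length(strsplit(first, "[ \t]+")[[1L]])
    format <- if (grepl("^[]().{}<>[]+$", gsub("[ \t]", "", paste(body, collapse = ""))))
      "dotbracket"
    else if (nfield >= 6L) "ct" else "bpseq"
  }
  switch(format,
    dotbracket = .parse_dotbracket(paste(gsub("[ \t]", "", lines), collapse = "")),
    ct = .parse_ct(lines),
    bpseq = .parse_bpseq(lines)
  )
}

.parse_dotbracket <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  open <- c("(", "[", "{", "<")
  close <- c(")", "]", "}", ">")
  bad <- setdiff(unique(chars), c(open, close, "."))
  if (length(bad))
    stop("invalid dot-bracket characters: ", paste(bad, collapse = " "))
  stacks <- vector("list", length(open))
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(chars)) {
    ci <- chars[i]
    tier <- match(ci, open)
    if (!is.na(tier)) {
      stacks[[tier]] <- c(stacks[[tier]], i)
      next
    }
    tier <- match(ci, close)
    if (!is.na(tier)) {
      if (length(stacks[[tier]]) == 0L)
        stop("unbalanced bracket: unmatched '", ci, "' at position ", i)
      j <- stacks[[tier]][length(stacks[[tier]])]
      stacks[[tier]] <- stacks[[tier]][-length(stacks[[tier]])]
      pairs <- rbind(pairs, c(j - 1L, i - 1L))
    }
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left)) {
    pos <- stacks[[left[1L]]][1L]
    stop("unbalanced bracket: unclosed '", open[left[1L]], "' at position ", pos)
  }
  pair_table(length(chars), pairs)
}

.read_num_table <- function(lines, min_fields) {
  lines <- lines[!startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  keep <- vapply(fields, function(f)
    length(f) >= min_fields && !is.na(suppressWarnings(as.integer(f[[1L]]))), logical(1L))
  fields[keep]
}

.pairs_from_partner <- function(idx, partner, what) {
  # idx, partner 1-based; partner 0 = unpaired
  n <- max(idx)
  p <- integer(n)
  p[idx] <- partner
  paired <- which(p > 0L)
  bad <- paired[p[p[paired]] != paired]
  if (length(bad))
    stop(what, " pairing not reciprocated at position ", bad[1L])
  sel <- paired[paired < p[paired]]
  pair_table(n, cbind(sel - 1L, p[sel] - 1L))
}

.parse_ct <- function(lines) {
  rows <- .read_num_table(lines, 6L)
  # drop a header row whose first field is the sequence length
  if (length(rows) > 1L && length(rows[[1L]]) >= 1L &&
      suppressWarnings(as.integer(rows[[1L]][1L])) == length(rows) - 1L)
    rows <- rows[-1L]
  if (!length(rows)) stop("no CT data rows found")
  idx <- vapply(rows, function(f) as.integer(f[1L]), integer(1L))
  partner <- vapply(rows, function(f) as.integer(f[5L]), integer(1L))
  .pairs_from_partner(idx, partner, "CT")
}

.parse_bpseq <- function(lines) {
  rows <- .read_num_table(lines, 3L)
  if (!length(rows)) stop("no bpseq data rows found")
  idx <- vapply(rows, function(f) as.integer(f[1L]), integer(1L))
  partner <- vapply(rows, function(f) as.integer(f[3L]), integer(1L))
  .pairs_from_partner(idx, partner, "bpseq")
}

#' Write a pair table as a dot-bracket string
#'
#' Nested pairs use round brackets; pairs that cross the already-placed
#' ones fall back to higher bracket tiers.
#'
#' @param pt a [pair_table()].
#' @return a single dot-bracket string of length `pt$length`.
#' @export
to_dotbracket <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  open <- c("(", "[", "{", "<")
  close <- c(")", "]", "}", ">")
  out <- rep(".", pt$length)
  placed <- list()
  for (r in seq_len(nrow(pt$pairs))) {
    i <- pt$pairs[r, 1L]; j <- pt$pairs[r, 2L]
    tier <- 1L
    repeat {
      crossing <- FALSE
      if (length(placed) >= tier)
        for (q in placed[[tier]])
          if ((q[1L] < i && i < q[2L]) != (q[1L] < j && j < q[2L])) {
            crossing <- TRUE; break
          }
      if (!crossing) break
      tier <- tier + 1L
      if (tier > 4L) stop("structure needs more than 4 bracket tiers")
    }
    if (length(placed) < tier) placed[[tier]] <- list()
    placed[[tier]] <- c(placed[[tier]], list(c(i, j)))
    out[i + 1L] <- open[tier]
    out[j + 1L] <- close[tier]
  }
  paste(out, collapse = "")
}
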