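#' Project a reference pair table onto alignment columns
#'
#' The secondary structure is known for one ungapped reference sequence;
#' this maps it through that taxon's gapped alignment row, labelling each
#' alignment column by its structural role.
#'
#' Columns holding a paired reference residue become `stem5` / `stem3`
#' (with mutual `partner` columns); columns holding an unpaired reference
#' residue become `loop`; columns where the reference row has a gap are
#' `uncovered` (the structure says nothing about them).
#'
#' @param pt a [pair_table()] for the ungapped reference.
#' @param aligned_ref_row the reference taxon's aligned row: a single
#'   string or character vector of residues/gaps.
#' @return an object of class `column_annotation`: `n_columns`, `role`
#'   (character vector over `loop`, `stem5`, `stem3`, `uncovered`) and
#'   `partner` (1-based column index, NA off stems).
#' @export
project_to_alignment <- function(pt, aligned_ref_row) {
  stopifnot(inherits(pt, "pair_table"))
  row <- .split_chars(aligned_ref_row)
  if (length(row) == 0L) stop("empty reference row")
  is_gap <- row %in% c("-", ".")
  ungapped <- which(!is_gap)
  if (length(ungapped) != pt$length)
    stop("ungapped reference row has ", length(ungapped),
         " residues but pair table expects ", pt$length)
  n <- length(row)
  role <- ifelse(is_gap, "uncovered", "loop")
  partner <- rep(NA_integer_, n)
  if (nrow(pt$pairs)) {
    c5 <- ungapped[pt$pairs[, 1L] + 1L]
    c3 <- ungapped[pt$pairs[, 2L] + 1L]
    role[c5] <- "stem5"
    role[c3] <- "stem3"
    partner[c5] <- c3
    partner[c3] <- c5
  }
  structure(list(n_columns = n, role = role, partner = partner),
            class = "column_annotation")
}

#' @export
print.column_annotation <- function(x, ...) {
  tab <- table(factor(x$role, levels = c("loop", "stem5", "stem3", "uncovered")))
  cat("column_annotation:", x$n_columns, "columns (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Recover the reference pair table from a column annotation
#'
#' Inverse of [project_to_alignment()]: drops `uncovered` columns and
#' renumbers the remaining ones back into ungapped reference coordinates.
#'
#' @param ann a `column_annotation`.
#' @return a [pair_table()].
#' @export
annotation_to_pair_table <- function(ann) {
  stopifnot(inherits(ann, "column_annotation"))
  covered <- which(ann$role != "uncovered")
  pos <- rep(NA_integer_, ann$n_columns)
  pos[covered] <- seq_along(covered) - 1L
  c5 <- which(ann$role == "stem5")
  pair_table(length(covered), cbind(pos[c5], pos[ann$partner[c5]]))
}

# split a string (or pass through a character vector of single chars)
.split_chars <- function(x) {
  if (length(x) == 1L && nchar(x) != 1L) strsplit(x, "")[[1L]] else as.character(x)
}
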