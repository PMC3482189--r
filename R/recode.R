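#' Construct a structure alignment object
#'
#' @param codes integer matrix, taxa x sites, entries in 0--19 or NA
#'   (missing); rownames are taxon labels.
#' @param site_map optional data frame mapping each structure site to its
#'   source alignment column(s): columns `site`, `role`, `col5`, `col3`
#'   (1-based; `col3` NA off stems).
#' @return object of class `structure_alignment`.
#' @export
structure_alignment <- function(codes, site_map = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes))) stop("codes must carry taxon rownames")
  rng <- range(codes, na.rm = TRUE)
  if (length(codes) && !all(is.na(codes)) && (rng[1L] < 0L || rng[2L] > 19L))
    stop("symbol codes must lie in 0..19")
  if (!is.null(site_map) && nrow(site_map) != ncol(codes))
    stop("site_map rows must match number of sites")
  structure(list(taxa = rownames(codes), codes = codes, site_map = site_map),
            class = "structure_alignment")
}

#' @export
print.structure_alignment <- function(x, ...) {
  cat("structure_alignment:", length(x$taxa), "taxa x", ncol(x$codes),
      "sites (", sum(is.na(x$codes)), "missing cells )\n")
  invisible(x)
}

#' @export
dim.structure_alignment <- function(x) dim(x$codes)

#' Recode a nucleotide alignment over the 20-symbol structure alphabet
#'
#' Every loop or uncovered column becomes one unpaired-base site; every
#' stem pair of columns becomes one 16-state doublet site (5' base first).
#' Gaps and IUPAC ambiguity codes become missing data; at a stem site a
#' gap/ambiguity in either partner makes the whole doublet missing.
#' Non-canonical doublets (e.g. A.G) are ordinary symbols: all 16 ordered
#' combinations exist.  Sites are emitted in ascending order of their 5'
#' source column.
#'
#' @param aln nucleotide alignment: a character matrix (taxa x columns,
#'   taxon rownames) or a named character vector of equal-length strings.
#'   T is treated as U.
#' @param ann a `column_annotation` from [project_to_alignment()].
#' @param drop_uncovered if TRUE, columns not covered by the reference
#'   structure are dropped instead of being coded as unpaired bases.
#' @return a [structure_alignment()] with a populated `site_map`.
#' @export
recode_alignment <- function(aln, ann, drop_uncovered = FALSE) {
  m <- .as_char_matrix(aln)
  stopifnot(inherits(ann, "column_annotation"))
  if (ncol(m) != ann$n_columns)
    stop("alignment has ", ncol(m), " columns but annotation expects ",
         ann$n_columns)
  up <- toupper(m)
  unknown <- unique(up[!(.is_canonical(up) | .is_missing_char(up))])
  if (length(unknown))
    stop("unknown residue characters: ", paste(unknown, collapse = " "))

  single_roles <- if (drop_uncovered) "loop" else c("loop", "uncovered")
  single_cols <- which(ann$role %in% single_roles)
  stem5_cols <- which(ann$role == "stem5")
  site_col5 <- c(single_cols, stem5_cols)
  ord <- order(site_col5)

  site_map <- data.frame(
    site = seq_along(site_col5),
    role = c(ann$role[single_cols], rep("stem", length(stem5_cols)))[ord],
    col5 = site_col5[ord],
    col3 = c(rep(NA_integer_, length(single_cols)), ann$partner[stem5_cols])[ord],
    stringsAsFactors = FALSE
  )

  codes <- matrix(NA_integer_, nrow(m), nrow(site_map),
                  dimnames = list(rownames(m), NULL))
  for (s in seq_len(nrow(site_map))) {
    c5 <- site_map$col5[s]
    if (site_map$role[s] == "stem") {
      codes[, s] <- doublet_symbol(up[, c5], up[, site_map$col3[s]])
    } else {
      codes[, s] <- unpaired_symbol(up[, c5])
    }
  }
  structure_alignment(codes, site_map)
}

#' Emit a structure alignment as amino-acid one-letter strings
#'
#' Each of the 20 structure symbols has a fixed amino-acid alias (see
#' [structure_alphabet()]), so the recoded matrix can be analysed by any
#' 20-state protein phylogenetics program.  The inverse is
#' [from_protein_letters()]; the round trip is lossless.
#'
#' @param sa a [structure_alignment()].
#' @param missing_char character used for missing cells, `"?"` (default)
#'   or `"-"`.
#' @return named character vector of sequences, one per taxon.
#' @export
to_protein_letters <- function(sa, missing_char = c("?", "-")) {
  stopifnot(inherits(sa, "structure_alignment"))
  missing_char <- match.arg(missing_char)
  lut <- c(.STRUCT_AA, missing_char)
  idx <- sa$codes + 1L
  idx[is.na(idx)] <- 21L
  seqs <- apply(idx, 1L, function(i) paste(lut[i], collapse = ""))
  stats::setNames(as.character(seqs), sa$taxa)
}

#' Read amino-acid letter strings back into a structure alignment
#'
#' @param seqs named character vector of equal-length amino-acid strings
#'   (as produced by [to_protein_letters()]); `?` and `-` mean missing.
#' @return a [structure_alignment()] (without a site map).
#' @export
from_protein_letters <- function(seqs) {
  m <- .as_char_matrix(seqs)
  codes <- matrix(match(toupper(m), .STRUCT_AA) - 1L, nrow(m),
                  dimnames = list(rownames(m), NULL))
  bad <- unique(m[is.na(codes) & !(m %in% c("?", "-"))])
  if (length(bad))
    stop("characters outside the 20-letter alias alphabet: ",
         paste(bad, collapse = " "))
  structure_alignment(codes)
}

# alignment input normalisation: named strings or character matrix
.as_char_matrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop("alignment matrix needs taxon rownames")
    return(aln)
  }
  if (is.character(aln)) {
    if (is.null(names(aln))) stop("alignment sequences must be named")
    n <- nchar(aln)
    if (length(unique(n)) != 1L)
      stop("ragged alignment: sequence lengths ", paste(unique(n), collapse = ", "))
    return(do.call(rbind, lapply(stats::setNames(aln, names(aln)), .split_chars)))
  }
  stop("unsupported alignment representation")
}
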