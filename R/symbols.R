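#' The 20-symbol secondary-structure alphabet
#'
#' Recoded rRNA data live on a fixed 20-state alphabet: four symbols for
#' unpaired bases (A, C, G, U) and sixteen for ordered base-pair doublets
#' (AA, AC, ..., UU; 5' base first, bases ordered A < C < G < U).  So the
#' alphabet can be fed to any 20-state (protein-style) likelihood machinery,
#' each symbol carries a fixed one-letter amino-acid alias.
#'
#' @return A data frame with one row per symbol: `index` (0--19), `symbol`
#'   (e.g. `"A"` or `"GC"`), `paired` (logical), and `aa` (the one-letter
#'   amino-acid alias used when the matrix is written out for 20-state
#'   programs).
#' @examples
#' structure_alphabet()
#' @export
structure_alphabet <- function() {
  bases <- c("A", "C", "G", "U")
  doublets <- as.vector(t(outer(bases, bases, paste0)))
  data.frame(
    index = 0:19,
    symbol = c(bases, doublets),
    paired = rep(c(FALSE, TRUE), c(4L, 16L)),
    aa = .STRUCT_AA,
    stringsAsFactors = FALSE
  )
}

# fixed bijection onto the 20 amino-acid letters; order matches index 0:19
.STRUCT_AA <- c(
  "A", "C", "G", "T",                                # unpaired A C G U
  "D", "E", "F", "H",                                # AA AC AG AU
  "I", "K", "L", "M",                                # CA CC CG CU
  "N", "P", "Q", "R",                                # GA GC GG GU
  "S", "V", "W", "Y"                                 # UA UC UG UU
)

.BASES <- c("A", "C", "G", "U")

# base character -> 0:3, with T folded into U; NA for anything else
.base_index <- function(x) {
  x <- toupper(x)
  x[x == "T"] <- "U"
  match(x, .BASES) - 1L
}

#' Symbol index of an unpaired base
#'
#' @param base character vector of single bases (T is treated as U).
#' @return integer vector of symbol indices in 0--3 (NA where the base is
#'   not one of A, C, G, U/T).
#' @export
unpaired_symbol <- function(base) {
  .base_index(base)
}

#' Symbol index of an ordered base-pair doublet
#'
#' @param base5,base3 character vectors: the 5' and 3' bases of each pair.
#' @return integer vector of symbol indices in 4--19 (NA where either base
#'   is not canonical).
#' @examples
#' doublet_symbol("G", "C")  # 13
#' @export
doublet_symbol <- function(base5, base3) {
  i5 <- .base_index(base5)
  i3 <- .base_index(base3)
  4L + 4L * i5 + i3
}

# characters that map to missing data rather than a symbol
.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.GAP_CHARS <- c("-", ".", "?")

.is_missing_char <- function(x) {
  toupper(x) %in% c(.IUPAC_AMBIG, .GAP_CHARS)
}

.is_canonical <- function(x) {
  toupper(x) %in% c(.BASES, "T")
}
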