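#' Metadata table of the 66-sequence study dataset
#'
#' The packaged replica of the study's taxon table: one row per taxon
#' with its class (or outgroup phylum), the species and GenBank
#' accessions of its SSU and LSU rRNA sequences, and the
#' ingroup/outgroup flag.  The sequences themselves are not shipped;
#' the table documents provenance and anchors the character fixtures.
#'
#' @return data frame with columns `taxon`, `class`, `ssu_species`,
#'   `ssu_accession`, `lsu_species`, `lsu_accession`, `group`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "study_taxa.tsv", package = "strucphylo",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' The two built-in morphological characters
#'
#' Ascus dehiscence mechanism (six states) and ascoma shape (three
#' states) for the 66 study taxa, encoded at class level from the
#' published character definitions; the three outgroup taxa form no
#' asci, so their ascus state is missing while their ascoma is scored
#' absent.  See the comments in `extdata/morph_characters.tsv` for the
#' coding notes and flagged ambiguities.
#'
#' @return named list of two [morph_character()] objects, `ascus` and
#'   `ascoma`.
#' @export
builtin_characters <- function() {
  path <- system.file("extdata", "morph_characters.tsv",
                      package = "strucphylo", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, na.strings = "-")
  ascus_states <- c("schizo_saccharomyces", "taphrina_neolecta", "orbilia",
                    "operculate", "bitunicate", "inoperculate")
  ascoma_states <- c("absent", "exposed_hymenium", "ostiolar_sealed")
  list(
    ascus = morph_character("ascus_dehiscence", ascus_states,
                            stats::setNames(tab$ascus, tab$taxon)),
    ascoma = morph_character("ascoma_shape", ascoma_states,
                             stats::setNames(tab$ascoma, tab$taxon))
  )
}

#' Read a tip character table from TSV or a NEXUS characters block
#'
#' TSV input needs columns `taxon` and `state` (state labels or 0-based
#' indices).  NEXUS input reads the first character of a CHARACTERS /
#' DATA block MATRIX (states `0..9`, `?`/`-` missing).
#'
#' @param path file path.
#' @param name character name (defaults to the file stem).
#' @param states optional explicit state labels; inferred from the data
#'   when omitted.
#' @return a [morph_character()].
#' @export
read_character <- function(path, name = NULL, states = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  first <- toupper(trimws(readLines(path, n = 1L)))
  if (startsWith(first, "#NEXUS")) {
    lines <- readLines(path)
    i0 <- grep("^\\s*MATRIX\\s*$", toupper(lines))[1L]
    i1 <- grep(";", lines)
    i1 <- i1[i1 > i0][1L]
    rows <- trimws(lines[(i0 + 1L):(i1 - 1L)])
    rows <- rows[nzchar(rows) & rows != ";"]
    rows <- sub(";$", "", rows)
    parts <- strsplit(rows, "[ \t]+")
    taxa <- vapply(parts, `[[`, character(1L), 1L)
    st <- vapply(parts, function(p) substr(paste(p[-1L], collapse = ""), 1L, 1L),
                 character(1L))
    idx <- suppressWarnings(as.integer(st))
    if (is.null(states)) states <- as.character(0:max(idx, na.rm = TRUE))
    return(morph_character(name, states, stats::setNames(idx, taxa)))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = c("-", "?", "NA"))
  if (!all(c("taxon", "state") %in% names(tab)))
    stop("character TSV needs 'taxon' and 'state' columns")
  vals <- tab$state
  if (is.numeric(vals)) {
    if (is.null(states)) states <- as.character(0:max(vals, na.rm = TRUE))
    return(morph_character(name, states,
                           stats::setNames(as.integer(vals), tab$taxon)))
  }
  if (is.null(states)) states <- sort(unique(vals[!is.na(vals)]))
  morph_character(name, states, stats::setNames(vals, tab$taxon))
}
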