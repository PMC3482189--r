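#' Read a multiple alignment from FASTA or relaxed PHYLIP
#'
#' @param path file path.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"`, or
#'   `"phylip"` (relaxed: whitespace-separated name then sequence,
#'   sequential, possibly wrapped).
#' @return character matrix, taxa x columns, with taxon rownames.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  seqs <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    },
    phylip = .read_relaxed_phylip(path)
  )
  .as_char_matrix(seqs)
}

#' Write a multiple alignment as FASTA or relaxed PHYLIP
#'
#' @param aln character matrix or named character vector of sequences.
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (is.matrix(aln))
    aln <- stats::setNames(apply(aln, 1L, paste, collapse = ""), rownames(aln))
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path, width = 80L)
  } else {
    lines <- c(paste(length(aln), nchar(aln[[1L]])),
               paste(format(names(aln), width = max(nchar(names(aln)))), aln))
    writeLines(lines, path)
  }
  invisible(path)
}

# relaxed sequential PHYLIP: header "ntax nchar", then name + sequence
# tokens (sequence may continue on following lines until nchar is reached)
.read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  if (length(hdr) < 2L || anyNA(hdr)) stop("malformed PHYLIP header")
  ntax <- hdr[1L]; nchar_exp <- hdr[2L]
  toks <- strsplit(trimws(lines[-1L]), "[ \t]+")
  seqs <- character(0); cur_name <- NULL; cur_seq <- ""
  for (tk in toks) {
    if (is.null(cur_name)) {
      cur_name <- tk[1L]
      cur_seq <- paste(tk[-1L], collapse = "")
    } else {
      cur_seq <- paste0(cur_seq, paste(tk, collapse = ""))
    }
    if (nchar(cur_seq) >= nchar_exp) {
      seqs[cur_name] <- substr(cur_seq, 1L, nchar_exp)
      cur_name <- NULL; cur_seq <- ""
    }
  }
  if (length(seqs) != ntax)
    stop("PHYLIP file promises ", ntax, " taxa but ", length(seqs), " were read")
  seqs
}

#' Write the site map of a structure alignment as TSV
#'
#' Columns: `site` (1-based structure site), `role` (`loop`, `uncovered`,
#' `stem`), `col5`, `col3` (1-based source alignment columns; `col3`
#' empty off stems).
#'
#' @param sa a [structure_alignment()] with a site map.
#' @param path output path.
#' @export
write_site_map <- function(sa, path) {
  stopifnot(inherits(sa, "structure_alignment"))
  if (is.null(sa$site_map)) stop("structure alignment carries no site map")
  utils::write.table(sa$site_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a fitted model report as TSV
#'
#' One row per parameter: kind, k, log-likelihood (when supplied), the
#' rate-variation settings and the equilibrium frequencies.
#'
#' @param model a `submodel`.
#' @param path output path.
#' @param logLik optional log-likelihood to include.
#' @export
write_model_report <- function(model, path, logLik = NULL) {
  stopifnot(inherits(model, "submodel"))
  rows <- data.frame(
    parameter = c("kind", "k",
                  if (!is.null(logLik)) "logLik",
                  if (!is.null(model$gamma_alpha)) c("gamma_alpha", "n_categories"),
                  if (model$p_inv > 0) "p_inv",
                  paste0("freq_", seq_len(model$k))),
    value = c(model$kind, model$k,
              if (!is.null(logLik)) format(logLik, digits = 10),
              if (!is.null(model$gamma_alpha))
                c(format(model$gamma_alpha, digits = 6), model$n_categories),
              if (model$p_inv > 0) format(model$p_inv, digits = 6),
              format(model$freqs, digits = 6)),
    stringsAsFactors = FALSE
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PAML-style exchangeability table
#'
#' The format is the lower triangle of the symmetric exchangeability
#' matrix (k*(k-1)/2 numbers, row by row), optionally followed by k
#' equilibrium frequencies; whitespace and line breaks are free-form.
#'
#' @param path file path.
#' @param k state count (20 for protein-style tables).
#' @return list with `exchangeabilities` (symmetric k x k matrix, zero
#'   diagonal) and `frequencies` (length-k numeric or NULL).
#' @export
read_paml_exchangeability <- function(path, k = 20L) {
  txt <- readLines(path)
  txt <- txt[!startsWith(trimws(txt), "#")]
  nums <- suppressWarnings(as.numeric(unlist(strsplit(paste(txt, collapse = " "),
                                                      "[ \t]+"))))
  nums <- nums[!is.na(nums)]
  ntri <- k * (k - 1L) / 2L
  if (length(nums) < ntri)
    stop("expected at least ", ntri, " exchangeabilities, found ", length(nums))
  S <- matrix(0, k, k)
  S[upper.tri(S)] <- 0
  idx <- 1L
  for (i in 2:k) for (j in 1:(i - 1L)) {
    S[i, j] <- S[j, i] <- nums[idx]
    idx <- idx + 1L
  }
  freqs <- NULL
  if (length(nums) >= ntri + k) {
    freqs <- nums[ntri + seq_len(k)]
    freqs <- freqs / sum(freqs)
  }
  list(exchangeabilities = S, frequencies = freqs)
}
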