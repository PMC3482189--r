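#' Pipeline run configuration
#'
#' @param alignment nucleotide alignment: a file path (FASTA/relaxed
#'   PHYLIP) or a character matrix / named strings.
#' @param structure secondary-structure annotation of the ungapped
#'   reference sequence: a file path, annotation text, or a
#'   [pair_table()].
#' @param reference_taxon name of the taxon whose row carries the
#'   structure.
#' @param characters list of [morph_character()] (or paths readable by
#'   [read_character()]); defaults to [builtin_characters()] when the
#'   alignment taxa match, otherwise none.
#' @param arms which analysis arms to run: subset of
#'   `c("structure", "nucleotide")`.
#' @param profile `"test"` (reduced bootstrap counts: 20/20) or
#'   `"paper"` (100 ML / 1000 MP replicates).
#' @param structure_gamma,nucleotide_gamma use discrete-gamma rates in
#'   the respective arm's ML model.
#' @param exchangeability_file optional PAML-style table: when given,
#'   the structure arm's ML model uses these fixed exchangeabilities
#'   (e.g. LG) instead of the Poisson default.
#' @param support_threshold collapse threshold (percent, strict `<`)
#'   applied before ancestral-state reconstruction.
#' @param n_starts random-addition starts for the main searches.
#' @param bootstrap_ml,bootstrap_mp override the profile's replicate
#'   counts.
#' @param seed mandatory integer seed.
#' @param out_dir output directory.
#' @param drop_uncovered drop alignment columns not covered by the
#'   reference structure instead of coding them as unpaired bases.
#' @return list of class `run_config`.
#' @export
run_config <- function(alignment, structure, reference_taxon,
                       characters = NULL,
                       arms = c("structure", "nucleotide"),
                       profile = c("test", "paper"),
                       structure_gamma = TRUE,
                       nucleotide_gamma = TRUE,
                       exchangeability_file = NULL,
                       support_threshold = 50,
                       n_starts = 10L,
                       bootstrap_ml = NULL,
                       bootstrap_mp = NULL,
                       seed,
                       out_dir,
                       drop_uncovered = FALSE) {
  profile <- match.arg(profile)
  arms <- match.arg(arms, several.ok = TRUE)
  if (missing(seed)) stop("a seed is mandatory")
  if (support_threshold <= 0 || support_threshold > 100)
    stop("support_threshold must lie in (0, 100]")
  for (p in c(alignment, structure, exchangeability_file))
    if (is.character(p) && length(p) == 1L && !grepl("[\n(]", p) &&
        grepl("\\.[A-Za-z]+$", p) && !file.exists(p))
      stop("input file does not exist: ", p)
  if (is.null(bootstrap_ml))
    bootstrap_ml <- if (profile == "paper") 100L else 20L
  if (is.null(bootstrap_mp))
    bootstrap_mp <- if (profile == "paper") 1000L else 20L
  structure(list(alignment = alignment, structure = structure,
                 reference_taxon = reference_taxon, characters = characters,
                 arms = arms, profile = profile,
                 structure_gamma = structure_gamma,
                 nucleotide_gamma = nucleotide_gamma,
                 exchangeability_file = exchangeability_file,
                 support_threshold = support_threshold,
                 n_starts = as.integer(n_starts),
                 bootstrap_ml = as.integer(bootstrap_ml),
                 bootstrap_mp = as.integer(bootstrap_mp),
                 seed = as.integer(seed), out_dir = out_dir,
                 drop_uncovered = isTRUE(drop_uncovered)),
            class = "run_config")
}

#' Run the full structure-phylogenetics pipeline
#'
#' Recode -> infer (ML and MP) with bootstrap in each enabled arm ->
#' annotate supports -> collapse weak nodes -> ancestral-state
#' reconstruction -> reports.  Every output is written under
#' `cfg$out_dir` and listed, with its MD5 hash, in `manifest.json`;
#' rerunning the same configuration reproduces the hashes.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list with the main in-memory results:
#'   `recoded`, per-arm `ml`/`mp` fits and support trees, `collapsed`,
#'   and per-character `asr`; plus `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  outputs <- character(0)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s (%.1fs elapsed)", format(Sys.time(), "%H:%M:%S"),
                    stage, msg, as.numeric(difftime(Sys.time(), t0, units = "secs")))
    cat(line, "\n", file = log_path, append = TRUE)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(path) outputs <<- c(outputs, path)

  # ---- inputs ----
  aln <- stage("load_alignment",
               if (is.character(cfg$alignment) && length(cfg$alignment) == 1L &&
                   file.exists(cfg$alignment)) read_alignment(cfg$alignment)
               else .as_char_matrix(cfg$alignment))
  pt <- stage("load_structure", {
    s <- cfg$structure
    if (inherits(s, "pair_table")) s
    else if (is.character(s) && length(s) == 1L && file.exists(s))
      parse_structure(readLines(s))
    else parse_structure(s)
  })
  if (!cfg$reference_taxon %in% rownames(aln))
    stop("reference taxon '", cfg$reference_taxon, "' not in alignment")
  ann <- stage("project_structure",
               project_to_alignment(pt, aln[cfg$reference_taxon, ]))
  say("inputs", sprintf("%d taxa, %d columns, %d pairs",
                        nrow(aln), ncol(aln), nrow(pt$pairs)))

  results <- list(annotation = ann)
  seeds <- withr::with_seed(cfg$seed, sample.int(2^30, 8L))

  run_arm <- function(arm, data, model, k, seed_ml, seed_mp, sub) {
    dir.create(file.path(cfg$out_dir, sub), showWarnings = FALSE)
    out <- list()
    cfg_ml <- search_config("ml", n_starts = cfg$n_starts, seed = seed_ml,
                            bootstrap_replicates = cfg$bootstrap_ml)
    cfg_mp <- search_config("mp", n_starts = cfg$n_starts, seed = seed_mp,
                            bootstrap_replicates = cfg$bootstrap_mp)
    out$ml <- search_trees(data, model, cfg_ml, k = k)
    say(arm, sprintf("ML best lnL = %.3f", out$ml$score))
    out$mp <- search_trees(data, NULL, cfg_mp, k = k)
    say(arm, sprintf("MP best length = %d", as.integer(out$mp$score)))
    out$ml_boot <- bootstrap_trees(data, model, cfg_ml, k = k)
    out$mp_boot <- bootstrap_trees(data, NULL, cfg_mp, k = k)
    out$ml_support <- majority_consensus(out$ml_boot, annotate_onto = out$ml$tree)
    out$mp_support <- majority_consensus(out$mp_boot, annotate_onto = out$mp$tree)
    for (nm in c("ml", "mp")) {
      p <- file.path(cfg$out_dir, sub, paste0(nm, "_best.nwk"))
      ape::write.tree(out[[nm]]$tree, p); emit(p)
      p <- file.path(cfg$out_dir, sub, paste0(nm, "_bootstrap.nwk"))
      ape::write.tree(out[[paste0(nm, "_boot")]], p); emit(p)
      p <- file.path(cfg$out_dir, sub, paste0(nm, "_support.nwk"))
      ape::write.tree(out[[paste0(nm, "_support")]], p); emit(p)
    }
    out
  }

  if ("structure" %in% cfg$arms) {
    recoded <- stage("recode", recode_alignment(aln, ann, cfg$drop_uncovered))
    results$recoded <- recoded
    p <- file.path(cfg$out_dir, "structure"); dir.create(p, showWarnings = FALSE)
    f <- file.path(p, "recoded.fasta")
    write_alignment(to_protein_letters(recoded), f); emit(f)
    f <- file.path(p, "site_map.tsv"); write_site_map(recoded, f); emit(f)
    model <- stage("structure_model", build_model(
      if (is.null(cfg$exchangeability_file)) "poisson" else "fixed_exchangeability",
      k = 20L, frequencies = "empirical", data = recoded,
      exchangeabilities = cfg$exchangeability_file,
      gamma_alpha = if (cfg$structure_gamma) 1 else NULL))
    results$structure <- stage("structure_inference",
      run_arm("structure", recoded, model, 20L, seeds[1L], seeds[2L], "structure"))
    f <- file.path(cfg$out_dir, "structure", "ml_model.tsv")
    write_model_report(model, f, logLik = results$structure$ml$score); emit(f)
  }
  if ("nucleotide" %in% cfg$arms) {
    model <- stage("nucleotide_model", build_model(
      "gtr", k = 4L, frequencies = "empirical", data = aln,
      gamma_alpha = if (cfg$nucleotide_gamma) 1 else NULL, p_inv = 0.1))
    results$nucleotide <- stage("nucleotide_inference",
      run_arm("nucleotide", aln, model, 4L, seeds[3L], seeds[4L], "nucleotide"))
    f <- file.path(cfg$out_dir, "nucleotide", "ml_model.tsv")
    write_model_report(model, f, logLik = results$nucleotide$ml$score); emit(f)
  }

  # ---- ASR on the support-collapsed structure (or nucleotide) ML tree ----
  base_arm <- if ("structure" %in% cfg$arms) "structure" else "nucleotide"
  support_tree <- results[[base_arm]]$ml_support
  collapsed <- stage("collapse",
                     collapse_weak_nodes(support_tree, cfg$support_threshold,
                                         unsupported = "full"))
  results$collapsed <- collapsed
  p <- file.path(cfg$out_dir, "asr"); dir.create(p, showWarnings = FALSE)
  f <- file.path(p, "collapsed.nwk"); ape::write.tree(collapsed, f); emit(f)

  chars <- cfg$characters
  if (is.character(chars)) chars <- lapply(chars, read_character)
  if (!is.null(chars)) {
    results$asr <- list()
    for (ch in chars) {
      res <- stage(paste0("asr_", ch$name), {
        f <- file.path(p, paste0(ch$name, "_report.tsv"))
        r <- reconstruct_ancestral_states(collapsed, ch, report_path = f)
        emit(f)
        r
      })
      results$asr[[ch$name]] <- res
      say("asr", sprintf("%s: Mk rate %.4g, MP length %d", ch$name,
                         res$ml$rate, as.integer(res$mp$score)))
    }
  }

  manifest <- list(
    package = "strucphylo",
    version = as.character(utils::packageVersion("strucphylo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    profile = cfg$profile,
    arms = cfg$arms,
    parameters = list(support_threshold = cfg$support_threshold,
                      n_starts = cfg$n_starts,
                      bootstrap_ml = cfg$bootstrap_ml,
                      bootstrap_mp = cfg$bootstrap_mp,
                      structure_gamma = cfg$structure_gamma,
                      nucleotide_gamma = cfg$nucleotide_gamma,
                      drop_uncovered = cfg$drop_uncovered),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      list(path = sub(paste0("^", cfg$out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  say("done", paste(length(outputs), "artifacts written"))
  invisible(results)
}
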