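#' Simulation specification for structured alignments
#'
#' Bundles the settings of the synthetic-data generator: a Yule tree,
#' unpaired (loop) columns evolving independently under a 4-state model,
#' stem pairs evolving as single 16-state doublet characters (so
#' compensatory change is built in), and optional Mk-evolved tip
#' characters.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth Yule birth rate (default 5, which puts the mean
#'   root-to-tip depth of an 8-tip tree near 0.35 expected substitutions
#'   per site -- the divergence scale of phylum-level rRNA data).
#' @param n_loop_sites number of unpaired columns.
#' @param n_stem_pairs number of base pairs (each emits two nucleotide
#'   columns but is one doublet character).
#' @param loop_model `"jc"` or a 4-state `submodel` for loop sites.
#' @param stem_model `"poisson"` or a 16-state `submodel` for doublets.
#' @param char_k,char_rate state count and Mk rate for simulated tip
#'   characters (used by [simulate_character()]).
#' @param gap_fraction fraction of alignment cells masked to gaps after
#'   simulation (default 0; indels are not modelled, this only thins the
#'   data the way patchy sequencing does).
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_tips = 8L, birth = 5, n_loop_sites = 100L,
                     n_stem_pairs = 200L, loop_model = "jc",
                     stem_model = "poisson", char_k = 3L, char_rate = 0.5,
                     gap_fraction = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (n_loop_sites < 0L || n_stem_pairs < 0L) stop("site counts must be >= 0")
  if (birth <= 0 || char_rate <= 0) stop("rates must be > 0")
  if (gap_fraction < 0 || gap_fraction >= 1) stop("gap_fraction must be in [0, 1)")
  structure(list(n_tips = as.integer(n_tips), birth = birth,
                 n_loop_sites = as.integer(n_loop_sites),
                 n_stem_pairs = as.integer(n_stem_pairs),
                 loop_model = loop_model, stem_model = stem_model,
                 char_k = as.integer(char_k), char_rate = char_rate,
                 gap_fraction = gap_fraction, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a Yule (pure-birth) tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth birth rate.
#' @param seed integer seed.
#' @return `phylo` with tip labels `t1..tn` and branch lengths.
#' @export
simulate_tree <- function(n_tips, birth = 5, seed) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = birth, death = 0)
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
}

# simulate 1-based states for every node under a model; preorder walk
.simulate_states <- function(tree, model, n_sites, rate = 1) {
  k <- model$k
  nnode <- max(tree$edge)
  root <- ape::Ntip(tree) + 1L
  S <- matrix(NA_integer_, nnode, n_sites)
  S[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = model$freqs)
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  for (e in pre) {
    parent <- po$edge[e, 1L]; child <- po$edge[e, 2L]
    P <- transition_matrix(model, po$edge.length[e], rate)
    S[child, ] <- vapply(S[parent, ], function(s)
      sample.int(k, 1L, prob = P[s, ]), integer(1L))
  }
  S[seq_len(ape::Ntip(tree)), , drop = FALSE]
}

#' Simulate a structure-annotated nucleotide alignment
#'
#' Loop columns evolve independently under the 4-state loop model; each
#' stem pair evolves as one 16-state doublet character and is then
#' written out as its two nucleotide columns.  The emitted layout is a
#' single nested helix: `n_stem_pairs` 5' columns, the loop block, then
#' the matching 3' columns in reverse, i.e. dot-bracket
#' `(((...)))`-style.  The ground-truth structure is returned alongside.
#'
#' @param tree `phylo` with branch lengths.
#' @param spec a [sim_spec()] (its `n_tips` is ignored here).
#' @return list: `alignment` (character matrix of A/C/G/U), `pair_table`
#'   (true [pair_table()]), `annotation` (true `column_annotation`),
#'   `dotbracket` (annotation string), `doublet_states` (taxa x pairs,
#'   1-based 16-state truth), `loop_states` (taxa x loops, 1-based).
#' @export
simulate_alignment <- function(tree, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  L <- spec$n_loop_sites; P <- spec$n_stem_pairs
  if (L + P == 0L) stop("zero total sites")
  loop_model <- if (identical(spec$loop_model, "jc"))
    build_model("poisson", 4L) else spec$loop_model
  stem_model <- if (identical(spec$stem_model, "poisson"))
    build_model("poisson", 16L) else spec$stem_model
  ntip <- ape::Ntip(tree)
  withr::with_seed(spec$seed + 1L, {
    loops <- if (L > 0L) .simulate_states(tree, loop_model, L)
             else matrix(integer(0), ntip, 0L)
    stems <- if (P > 0L) .simulate_states(tree, stem_model, P)
             else matrix(integer(0), ntip, 0L)
  })
  bases <- .BASES
  ncol_total <- 2L * P + L
  aln <- matrix("", ntip, ncol_total,
                dimnames = list(tree$tip.label, NULL))
  if (P > 0L) {
    b5 <- matrix(bases[(stems - 1L) %/% 4L + 1L], ntip)
    b3 <- matrix(bases[(stems - 1L) %% 4L + 1L], ntip)
    aln[, seq_len(P)] <- b5
    aln[, ncol_total + 1L - seq_len(P)] <- b3
  }
  if (L > 0L)
    aln[, P + seq_len(L)] <- matrix(bases[loops], ntip)
  if (!is.null(spec$gap_fraction) && spec$gap_fraction > 0) {
    # mask cells everywhere except the reference (first) row, which must
    # stay ungapped to carry the structure annotation
    mask <- withr::with_seed(spec$seed + 2L,
      matrix(stats::runif(length(aln)) < spec$gap_fraction, ntip))
    mask[1L, ] <- FALSE
    aln[mask] <- "-"
  }
  pairs <- if (P > 0L)
    cbind(seq_len(P) - 1L, ncol_total - seq_len(P)) else NULL
  pt <- pair_table(ncol_total, pairs)
  ann <- project_to_alignment(pt, paste(aln[1L, ], collapse = ""))
  list(alignment = aln, pair_table = pt, annotation = ann,
       dotbracket = to_dotbracket(pt),
       doublet_states = stems, loop_states = loops)
}

#' Simulate a discrete tip character under the Mk model
#'
#' Uniform root state, symmetric k-state evolution at the given rate.
#'
#' @param tree `phylo` with branch lengths.
#' @param k number of states (>= 2).
#' @param rate Mk rate multiplier on the branch lengths (> 0).
#' @param seed integer seed.
#' @param name character name.
#' @return a [morph_character()] with every tip scored.
#' @export
simulate_character <- function(tree, k, rate, seed, name = "sim_char") {
  if (k < 2L) stop("k must be >= 2")
  if (rate <= 0) stop("rate must be > 0")
  model <- build_model("poisson", k)
  tips <- withr::with_seed(seed, .simulate_states(tree, model, 1L, rate))
  morph_character(name, paste0("s", seq_len(k) - 1L),
                  stats::setNames(as.integer(tips[, 1L]) - 1L, tree$tip.label))
}

#' Simulate several independent Mk characters at once
#'
#' @inheritParams simulate_character
#' @param n_chars number of characters.
#' @return integer matrix (taxa x characters) of 1-based states.
#' @export
simulate_characters_matrix <- function(tree, k, rate, n_chars, seed) {
  model <- build_model("poisson", k)
  withr::with_seed(seed, {
    X <- .simulate_states(tree, model, n_chars, rate)
  })
  rownames(X) <- tree$tip.label
  X
}

#' Write a simulated dataset into a run directory
#'
#' Emits FASTA alignment, dot-bracket structure, true Newick tree, and a
#' tip-character TSV, so downstream stages can be exercised file-to-file.
#'
#' @param tree,sim,char outputs of [simulate_tree()],
#'   [simulate_alignment()], [simulate_character()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(tree, sim, char, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$alignment, file.path(dir, "alignment.fasta"), "fasta")
  writeLines(sim$dotbracket, file.path(dir, "structure.db"))
  ape::write.tree(tree, file.path(dir, "true_tree.nwk"))
  if (!is.null(char)) {
    df <- data.frame(taxon = names(char$assignments),
                     state = char$states[char$assignments + 1L])
    utils::write.table(df, file.path(dir, "characters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
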