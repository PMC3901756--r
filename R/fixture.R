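# Fragment layout of the eight-marker concatenated matrix the package's
# test fixture emulates: fragment name, length (bp), genome/class, and
# whether the fragment is protein-coding (and therefore split into
# codon-position partitions).
fixture_fragments <- function() {
  data.frame(
    fragment = c("CAD", "COI_3p", "COII", "COI_5p", "28S", "Wnt", "16S", "H3"),
    length   = c(2008L,  821L,    684L,   671L,    670L,  466L,  447L,  328L),
    class    = c("nuc_pc", "mito_pc", "mito_pc", "mito_pc", "nuc_ribo",
                 "nuc_pc", "mito_ribo", "nuc_pc"),
    coding   = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

# Mean substitution rates (per site per Ma) for the eight rate classes.
# Chosen so that, on a 110 Ma tree: mitochondrial 3rd positions are
# deeply saturated (expected root-to-tip divergence > 2 subs/site),
# nuclear 3rd positions peak in informativeness in the 30-50 Ma window,
# ribosomal fragments are intermediate, and 1st/2nd positions stay far
# from saturation (< 0.2 subs/site root-to-tip). Adjacent classes are
# separated by at least a factor of two so the rate ordering is
# recoverable from data of this size.
fixture_rate_classes <- function() {
  c(mito_pos3 = 0.030,
    nuc_pos3  = 0.008,
    ribo_16S  = 0.004,
    ribo_28S  = 0.0018,
    mito_pos1 = 0.00085,
    nuc_pos1  = 0.0004,
    mito_pos2 = 0.0002,
    nuc_pos2  = 0.0001)
}

# Among-site gamma shapes and HKY parameters per fragment class.
fixture_model_params <- function() {
  list(
    mito_pc   = list(kappa = 6,   freq = c(0.35, 0.12, 0.10, 0.43)),
    nuc_pc    = list(kappa = 3,   freq = c(0.28, 0.22, 0.23, 0.27)),
    mito_ribo = list(kappa = 2.5, freq = c(0.33, 0.14, 0.12, 0.41)),
    nuc_ribo  = list(kappa = 2.5, freq = c(0.26, 0.22, 0.27, 0.25)))
}

#' Synthetic eight-marker reference dataset
#'
#' Generates a synthetic bundle emulating the structure of the
#' concatenated dataset the package is designed for: a 40-tip
#' ultrametric tree with a 110 Ma root; eight fragments with lengths
#' 2008 (CAD), 821 (COI 3'), 684 (COII), 671 (COI 5'), 670 (28S),
#' 466 (Wnt), 447 (16S) and 328 (H3) bp — 6095 columns in all; codon
#' substructure for the six protein-coding fragments (partitions are
#' gene-by-codon-position, in `\3` stride layout); strong
#' among-partition rate heterogeneity with saturating mitochondrial 3rd
#' positions and slow 1st/2nd positions; and 11% missing data at the
#' (taxon, fragment) level. All sequences are synthetic — simulated
#' under HKY + gamma with the rate regime of [fixture_config()] — not
#' real data.
#'
#' @param seed Integer seed; the same seed reproduces the bundle
#'   byte-for-byte.
#' @param n_tips Number of tips (default 40).
#' @param root_age Root age in Ma (default 110).
#' @param missing_rate Fragment-level missing-data probability
#'   (default 0.11).
#' @return A `"sim_bundle"` (see [simulate_alignment()]) whose
#'   `true_rates` carry an extra `rate_class` column, plus
#'   `fragment_scheme` (the 8 whole-fragment partitions) alongside the
#'   codon-level `scheme` (20 partitions).
#' @export
marker_fixture <- function(seed, n_tips = 40, root_age = 110,
                          missing_rate = 0.11) {
  frags <- fixture_fragments()
  rates <- fixture_rate_classes()
  models <- fixture_model_params()
  tree <- simulate_tree(n_tips, root_age, seed)

  # one simulator spec per (fragment, codon position) block; codon
  # columns are interleaved back into genomic order afterwards
  specs <- list(); owner <- list()
  for (i in seq_len(nrow(frags))) {
    fr <- frags$fragment[i]; L <- frags$length[i]; cl <- frags$class[i]
    mp <- models[[cl]]
    if (frags$coding[i]) {
      genome <- if (cl == "mito_pc") "mito" else "nuc"
      for (pos in 1:3) {
        cols_local <- seq(pos, L, by = 3)
        rc <- sprintf("%s_pos%d", genome, pos)
        nm <- sprintf("%s_pos%d", fr, pos)
        shape <- if (pos == 3) 2 else 4
        specs[[nm]] <- sim_partition_spec(nm, length(cols_local), rates[[rc]],
                                          gamma_shape = shape, model = "HKY",
                                          kappa = mp$kappa, freq = mp$freq)
        owner[[nm]] <- list(fragment = fr, local_cols = cols_local,
                            rate_class = rc)
      }
    } else {
      rc <- if (fr == "16S") "ribo_16S" else "ribo_28S"
      specs[[fr]] <- sim_partition_spec(fr, L, rates[[rc]], gamma_shape = 1,
                                        model = "HKY", kappa = mp$kappa,
                                        freq = mp$freq)
      owner[[fr]] <- list(fragment = fr, local_cols = seq_len(L),
                          rate_class = rc)
    }
  }

  sim <- simulate_alignment(tree, unname(specs),
                            seed = (seed + 1L) %% .Machine$integer.max)

  # reorder the block-wise simulated columns into genomic layout:
  # fragments in order, codon positions interleaved within fragments
  width <- sum(frags$length)
  offset <- setNames(cumsum(frags$length) - frags$length, frags$fragment)
  dest <- integer(width)
  src <- 0L
  for (nm in names(specs)) {
    ow <- owner[[nm]]
    n <- specs[[nm]]$length
    dest[offset[[ow$fragment]] + ow$local_cols] <- src + seq_len(n)
    src <- src + n
  }
  m <- sim$matrix[, dest, drop = FALSE]
  true_rates <- data.frame(
    site = seq_len(width),
    partition = sim$true_rates$partition[dest],
    rate_class = vapply(sim$true_rates$partition[dest],
                        function(p) owner[[p]]$rate_class, character(1)),
    lambda_true = sim$true_rates$lambda_true[dest],
    stringsAsFactors = FALSE)
  rownames(true_rates) <- NULL

  charset <- character(0)
  for (nm in names(specs)) {
    ow <- owner[[nm]]
    lc <- ow$local_cols
    glob <- offset[[ow$fragment]] + lc
    rng <- if (length(unique(diff(glob))) == 1 && length(glob) > 1 &&
               diff(glob)[1] > 1)
      sprintf("%d-%d\\%d", glob[1], offset[[ow$fragment]] +
                max(lc) , diff(glob)[1])
    else sprintf("%d-%d", glob[1], glob[length(glob)])
    charset <- c(charset, sprintf("%s = %s", nm, rng))
  }
  scheme <- resolve_partitions(paste(charset, collapse = "\n"), width)
  frag_charset <- sprintf("%s = %d-%d", frags$fragment,
                          offset + 1L, offset + frags$length)
  fragment_scheme <- resolve_partitions(paste(frag_charset, collapse = "\n"),
                                        width)

  m <- inject_missing(m, fragment_scheme, missing_rate,
                      seed = (seed + 2L) %% .Machine$integer.max)

  structure(list(tree = tree, matrix = m, true_rates = true_rates,
                 scheme = scheme, fragment_scheme = fragment_scheme,
                 specs = specs, seed = seed,
                 config = fixture_config(n_tips, root_age, missing_rate)),
            class = "sim_bundle")
}

#' Configuration constants of the simulated fixture
#'
#' @param n_tips,root_age,missing_rate As in [marker_fixture()].
#' @return Named list recording tree size, root age, missing-data rate,
#'   fragment table, rate classes and model parameters.
#' @export
fixture_config <- function(n_tips = 40, root_age = 110, missing_rate = 0.11) {
  list(n_tips = n_tips, root_age_ma = root_age,
       fragment_missing_rate = missing_rate,
       fragments = fixture_fragments(),
       rate_classes = as.list(fixture_rate_classes()),
       model_params = fixture_model_params())
}

#' Write a simulation bundle to a fixture directory
#'
#' Writes `alignment.fasta`, `tree.nwk`, `partitions.txt`,
#' `true_rates.tsv` and `config.yml` so the bundle can be consumed as
#' ordinary input files.
#'
#' @param bundle A `"sim_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$matrix, file.path(dir, "alignment.fasta"))
  writeLines(write_newick(bundle$tree), file.path(dir, "tree.nwk"))
  writeLines(format_partitions(bundle$scheme), file.path(dir, "partitions.txt"))
  tr <- bundle$true_rates
  names(tr)[names(tr) == "lambda_true"] <- "lambda"
  write_rate_table(tr, file.path(dir, "true_rates.tsv"),
                   provenance = c(generator = "phylopi simulator",
                                  seed = bundle$seed))
  cfg <- if (!is.null(bundle$config)) bundle$config else
    list(seed = bundle$seed)
  cfg$seed <- bundle$seed
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}
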