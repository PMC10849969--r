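#' End-to-end synthetic discovery pipeline
#'
#' Chains the full desk-scale workflow on a simulated repository:
#' simulate -> repository search (library reference spectra as queries)
#' -> presence matrix -> per-phenotype detection proportions ->
#' per-compound Wilcoxon / Benjamini-Hochberg association on abundances
#' gated by the *detected* presence matrix.  Used for parameter-recovery
#' validation: with planted group-differential occurrence, enriched
#' compounds should come out significant and null compounds should not.
#'
#' @param library A `compound_library`.
#' @param config A [sim_config()].
#' @param criteria A [match_criteria()].
#' @param pairs Group-label pairs for the association step (default: the
#'   config's group pair).
#' @param abundance_seed Seed for the abundance draw (default derived
#'   from the config seed).
#' @return List with `sim` (simulator output), `matches`, `presence`,
#'   `proportions`, `abundance`, `association`.
#' @export
run_discovery_pipeline <- function(library, config,
                                   criteria = match_criteria("qtof"),
                                   pairs = NULL,
                                   abundance_seed = NULL) {
  sim <- simulate_repository(library, config)
  queries <- library_reference_spectra(
    library[library$compound_id %in% rownames(config$occurrence), ,
            drop = FALSE])
  matches <- repository_search(queries, sim$corpus, criteria)
  presence <- build_presence_matrix(matches, sim$metadata,
                                    compounds = rownames(config$occurrence))
  proportions <- phenotype_proportions(presence, sim$metadata)
  if (is.null(abundance_seed)) {
    abundance_seed <- file_stream_seed(config$seed, 999983L)
  }
  set.seed(abundance_seed)
  abundance <- simulate_abundance_table(presence, sim$metadata)
  grp <- stats::setNames(sim$metadata$phenotype, sim$metadata$source_file)
  if (is.null(pairs)) {
    pairs <- utils::combn(config$groups, 2, simplify = FALSE)
  }
  association <- pairwise_wilcoxon_bh(abundance, grp, pairs = pairs)
  list(sim = sim, matches = matches, presence = presence,
       proportions = proportions, abundance = abundance,
       association = association)
}
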