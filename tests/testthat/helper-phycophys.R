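# Shared fixtures: scenarios with noise switched off for exact-recovery
# checks, and small builders used across test files.

study_scenario <- function() load_scenario("cpftsy_study")

noise_free <- function(sc) {
  sc$fluor$noise_cv <- 0
  sc$rlc$noise_cv <- 0
  sc$ecs$noise_sd <- 0
  sc$pigments$noise_cv <- 0
  sc$growth$noise_cv <- 0
  sc$photoinhibition$noise_cv <- 0
  sc
}

# Minimal protein_quant with explicit values; `values` is a proteins x
# samples matrix (NA allowed), groups a vector per sample.
toy_protein_quant <- function(values, groups, peptides = NULL) {
  n <- nrow(values)
  ids <- sprintf("prot%02d", seq_len(n))
  sample_ids <- paste0("s", seq_len(ncol(values)))
  colnames(values) <- sample_ids
  protein_quant(
    abundance = dplyr::bind_cols(tibble::tibble(protein_id = ids),
                                 tibble::as_tibble(values)),
    samples = tibble::tibble(sample_id = sample_ids, group = groups),
    proteins = tibble::tibble(
      protein_id = ids,
      peptides = peptides %||% rep(5L, n)
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
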