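# Ensembles of independent runs differing in their seeds (the published
# protocol uses 15 runs); the analysis module consumes the resulting list.

#' Run an ensemble of independent simulations
#'
#' @param runner function(seed, params) returning one run's outputs; @param
#'   seeds integer vector of distinct seeds; @param params parameters
#'   (optionally pre-modified with [case_variation()]).
#' @return list of runner outputs with attribute `seeds`.
#' @export
run_ensemble <- function(runner, seeds, params = default_parameters()) {
  if (!length(seeds)) stop("need at least one seed")
  if (anyDuplicated(seeds)) stop("seed collision in ensemble")
  out <- lapply(seeds, function(s) runner(s, params))
  attr(out, "seeds") <- seeds
  out
}
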