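# Shared fixtures: tiny GA configurations and ROI builders.

tiny_ms_cfg <- function(pop = 10, gens = 3, seed = 1,
                        quotas = c(selection = 2, crossover = 2, asexual = 2,
                                   mutation = 2, random = 2)) {
  ga_config(population_size = pop, generations = gens,
            quotas = quotas * (pop / sum(quotas)), seed = seed)
}

tiny_fs_cfg <- function(pop = 10, gens = 3, seed = 1,
                        quotas = c(selection = 2, crossover = 2, mutation = 2,
                                   random = 4)) {
  fs_config(population_size = pop, generations = gens,
            quotas = quotas * (pop / sum(quotas)), seed = seed)
}

const_roi <- function(n = 8, temp = 33, side = "left") {
  roi_matrix(matrix(temp, n, n), side = side)
}

noise_roi <- function(n = 16, seed = 1, side = "left", baseline = 33, sd = 0.5) {
  set.seed(seed)
  roi_matrix(matrix(baseline + rnorm(n * n, sd = sd), n, n), side = side)
}

# Cache for expensive acceptance-scale runs shared across test blocks.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}
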