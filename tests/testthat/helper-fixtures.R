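# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small desk-scale parameter set: 256 px slides, 32 px tiles (8x8 grid)
desk_params <- function(...) {
  args <- list(slide_px = 256L, tile_px = 32L, n_proteins = 8L,
               n_signal_proteins = 3L, noise_sd = 0.05, seed = 101L)
  args[names(list(...))] <- list(...)
  do.call(synthesis_params, args)
}

# 20-slide cohort reused by prep / contrastive / head tests
desk_cohort <- function() cached("desk_cohort", function() {
  man <- make_cohort(desk_params(), 20L, file.path(tempdir(), "fix_cohort"))
  bags <- cohort_bags(man, tile_px = 32L, min_tissue_frac = 0.5, downsample = 32L)
  list(man = man, bags = bags)
})

# lightly pretrained encoder on that cohort
desk_encoder <- function() cached("desk_encoder", function() {
  pretrain(desk_cohort()$bags, epochs = 2L, seed = 101L)
})

desk_features <- function() cached("desk_features", function() {
  lapply(desk_cohort()$bags, embed_tiles, encoder = desk_encoder())
})

# simulated survival data with a binary covariate and known hazard ratio
sim_surv <- function(n, theta = log(3), seed = 1L, base_rate = 0.1, cens_rate = 0.05) {
  set.seed(seed)
  x <- stats::rbinom(n, 1, 0.5)
  tev <- stats::rexp(n, base_rate * exp(theta * x))
  cen <- stats::rexp(n, cens_rate)
  survival_records(pmin(tev, cen), as.integer(tev <= cen), cbind(trt = x))
}
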