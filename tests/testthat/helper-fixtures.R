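# Shared fixtures, built lazily and cached for the whole test run so the
# expensive stages (packing, void filling, flow solves) are computed once
# and reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

fixture_add <- function() cached("add", function() calibrated_add())

# small packing for unit tests
small_pack <- function() cached("small_pack", function()
  advancing_front_pack(fixture_add(), 300, seed = 42))

# small filled / shrunk variants for the flow and homogenisation tests
small_fill <- function() cached("small_fill", function()
  fill_voids(small_pack(), fixture_add(), alpha_stop = 0.15, seed = 1))

small_shrunk <- function() cached("small_shrunk", function()
  shrink_to_porosity(small_fill(), 0.30))

# the six replicate packings of the study configuration
study_packs <- function() cached("study_packs", function()
  lapply(1:6, function(s) advancing_front_pack(fixture_add(), 2000, seed = s)))

# void-filled versions (the expensive stage)
study_fills <- function() cached("study_fills", function()
  lapply(seq_along(study_packs()), function(i)
    fill_voids(study_packs()[[i]], fixture_add(), alpha_stop = 0.15,
               seed = i)))

# filled geometries shrunk to the study ECS fraction
study_shrunk <- function() cached("study_shrunk", function()
  lapply(study_fills(), shrink_to_porosity, alpha_target = 0.30))

# solved sweep over the six replicates at the production resolution
study_sweep <- function() cached("study_sweep", function()
  rve_sweep(study_shrunk(), flow_bc(), resolution = 0.012,
            entrance_length = 1.5, exit_length = 1.5))

empty_channel_solution <- function(h = 0.25) cached(paste0("empty", h), function() {
  g <- geometry(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)),
                c(10, 10), check = FALSE)
  dom <- build_flow_domain(g, entrance_length = 10, exit_length = 10)
  solve_creeping_flow(dom, flow_bc(), resolution = h)
})
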