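# Memoised simulation fixtures shared across test files; built lazily so a
# single test file run only pays for what it uses.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# the study-condition excision scenario at a reduced size for unit tests
smallExcisionSim <- function(seed = 101) {
  fixture(paste0("excision_small_", seed), function()
    simulateGenomePair(simConfig(n_genes = 2000, n_chromosomes = 2,
                                 seed = seed)))
}

smallPseudoSim <- function(seed = 102) {
  fixture(paste0("pseudo_small_", seed), function()
    simulateGenomePair(simConfig(n_genes = 2000, n_chromosomes = 2,
                                 mechanism = "pseudogenization",
                                 seed = seed)))
}

runSmallPipeline <- function(sim, ...) {
  if (sim$mode == "self")
    runPipeline(sim$tableA, pairs = sim$pairs, sizesA = sim$sizesA,
                mode = "self", ...)
  else
    runPipeline(sim$tableA, sim$tableB, sim$pairs, sim$sizesA, sim$sizesB, ...)
}
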