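# Shared, lazily-built simulation fixtures (one backend call, reused
# across test files).

.fixtureCache <- new.env(parent = emptyenv())

fixtureLoci <- function() {
  if (is.null(.fixtureCache$loci)) {
    fx <- fixtureConfig()
    params <- sampleParameters(fx$priors, 1L, seed = 424243L, model = fx$model)
    .fixtureCache$design <- fx$design
    .fixtureCache$schema <- buildSchema(fx$design)
    .fixtureCache$loci <- simulateDataset(params[1L, ], fx$design,
                                          seed = 77001L)
  }
  .fixtureCache$loci
}

fixtureSchema <- function() {
  fixtureLoci()
  .fixtureCache$schema
}

fixtureDesign <- function() {
  fixtureLoci()
  .fixtureCache$design
}
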