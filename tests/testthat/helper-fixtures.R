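## Shared expensive fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## degree-10 surrogate of the two-parameter G-protein study, fit by least
## squares to 1000 uniform samples of the ODE model
fixtureM1Surrogate <- function() {
  memo("m1", function() {
    sp <- gproteinSpace2()
    ss <- makeGproteinSampleSet(sp, 1000, seed = 11)
    list(space = sp, samples = ss,
         fit = fitSurrogate(ss$Y, ss$Z, sp, 10, method = "ls"))
  })
}

## coarse-mesh sample set of the 15-parameter polarization subspace
fixturePdeSamples <- function() {
  memo("pde_samples", function() {
    sp <- polarizationSpace15()
    g <- circleGeometry(N = 100)
    ss <- makePdeSampleSet(sp, 300, seed = 101, geometry = g,
                           t_end = 1000, dt = 0.2)
    list(space = sp, geometry = g, samples = ss)
  })
}

## full-resolution baseline run of the polarization model to t = 1000 s
fixtureBaselineRun <- function() {
  memo("pde_baseline", function() {
    g <- circleGeometry()
    p <- polarizationParams()
    list(geometry = g, params = p,
         state = simulatePolarization(p, g, t_end = 1000, dt = 0.05))
  })
}
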