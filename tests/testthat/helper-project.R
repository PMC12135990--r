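# Build a complete synthetic project on disk: toy chain written as PDB,
# a seeded MC pool regenerated from the written file (so the pipeline's
# own pool is bit-identical), and a noiseless 60/40 two-conformer
# experiment drawn from the reduced pool.
make_demo_project <- function(dir, name = "demo", domains = c(10, 10),
                              linker = 8, trials = 500, stride = 5,
                              adjacentK = 2, seed = 19) {
  toy <- buildToyChain(domains[1], linker, domains[2])
  stf <- file.path(dir, "start.pdb")
  write_single_model(toy, stf)
  start <- readStructure(stf)
  regions <- detectFlexibleRegions(confidence(start), 60)
  align <- c(1, domains[1])
  pool <- runMC(start, regions,
                mcConfig(alignRange = align, trialAttempts = trials,
                         seed = seed))
  red <- reducePool(pool, stride, 0)
  rg <- poolRg(red)
  mods <- modelNumbers(red)[c(which.min(rg), which.max(rg))]
  q <- seq(0.005, 0.5, length.out = 201)
  expd <- makeSyntheticExperiment(pool, mods, c(0.6, 0.4), q,
                                  noiseFraction = 0, seed = seed)
  iqf <- file.path(dir, "iq.dat"); prf <- file.path(dir, "pr.dat")
  write.table(cbind(q, intensities(expd$iq)), iqf,
              row.names = FALSE, col.names = FALSE)
  write.table(cbind(rValues(expd$pr), pValues(expd$pr)), prf,
              row.names = FALSE, col.names = FALSE)
  cfg <- projectConfig(name, dir = dir, structureFile = stf,
                       iqFile = iqf, prFile = prf, alignRange = align,
                       trialAttempts = trials, stride = stride,
                       adjacentK = adjacentK, useSdWeighting = FALSE,
                       seed = seed)
  list(cfg = cfg, trueModels = mods, trueWeights = c(0.6, 0.4),
       pool = pool)
}
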