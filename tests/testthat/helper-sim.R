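## Shared fixture builders: small synthetic site tables with or without an
## injected event, built in code at test time.

noEvents <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             type = character(0), cell_fraction = numeric(0))
}

## One chromosome of hets with an optional whole/partial event.
eventSites <- function(type = "cnn_loh", f = 0.2, nSites = 2000,
                       start = 0, end = 248956422, bafSd = 0.03,
                       hetFraction = 1, switchRate = 0, seed = 1,
                       chrom = "chr1") {
  ev <- if (is.null(type)) noEvents()
        else data.frame(chrom = chrom, start = start, end = end,
                        type = type, cell_fraction = f)
  simulateArraySignals(ev, ArraySimConfig(nSites = nSites,
                                          hetFraction = hetFraction,
                                          bafSd = bafSd,
                                          phaseSwitchRate = switchRate,
                                          seed = seed), chroms = chrom)
}

## Noiseless step sequence of hets: d = 0 outside [i0, i1], +dbaf inside.
stepSites <- function(n = 300, i0 = 101, i1 = 200, dbaf = 0.25) {
  pos <- seq(1e6, by = 1e4, length.out = n)
  baf <- rep(0.5, n)
  baf[i0:i1] <- 0.5 + dbaf
  data.frame(chrom = "chr1", pos = pos, genotype = "AB", hap = 1L,
             baf = baf, lrr = 0)
}

tinyRegionLists <- function(emptyDriver = FALSE, emptyLymphoid = FALSE) {
  rl <- exampleRegionLists()
  if (emptyDriver)
    rl@driverCandidates <- rl@driverCandidates[0, , drop = FALSE]
  if (emptyLymphoid)
    rl@lymphoid <- rl@lymphoid[0, , drop = FALSE]
  rl
}
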