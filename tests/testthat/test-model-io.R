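test_that("tsv model round-trips entry by entry", {
  net <- makeRandomNetwork(2, 5, seed = 4)
  d <- withr::local_tempdir()
  p <- file.path(d, "model.tsv")
  writeModel(net, p)
  back <- readModel(p, format = "tsv")
  expect_identical(reactionIds(back), reactionIds(net))
  expect_identical(metaboliteIds(back), metaboliteIds(net))
  expect_equal(stoichiometry(back), stoichiometry(net))
  expect_equal(lowerBounds(back), lowerBounds(net))
  expect_equal(upperBounds(back), upperBounds(net))
})

test_that("invalid bounds are rejected with the offending reaction named", {
  d <- withr::local_tempdir()
  p <- file.path(d, "m.tsv")
  writeLines(c("metabolite_id\tR1\tR2", "M1\t1\t-1"), p)
  writeLines(c("reaction_id\tlb\tub", "R1\t5\t3", "R2\t0\t1"),
             file.path(d, "m_bounds.tsv"))
  expect_error(readModel(p, format = "tsv"), "R1")
})

test_that("cobra-style JSON models are read", {
  d <- withr::local_tempdir()
  p <- file.path(d, "m.json")
  writeLines('{"reactions": [
    {"id": "up", "lower_bound": 0, "upper_bound": 10, "metabolites": {"A": 1}},
    {"id": "down", "lower_bound": -5, "upper_bound": 5, "metabolites": {"A": -1}}
  ]}', p)
  m <- readModel(p)
  expect_equal(nReactions(m), 2)
  expect_equal(as.numeric(stoichiometry(m)["A", ]), c(1, -1))
  expect_equal(lowerBounds(m), c(0, -5))
})

test_that("SBML L3+FBC is read; missing bounds fall back with a warning", {
  d <- withr::local_tempdir()
  p <- file.path(d, "m.xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="toy">
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="ub10" value="10" constant="true"/>
  </listOfParameters>
  <listOfSpecies>
   <species id="A" boundaryCondition="false"/>
   <species id="X" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfReactants><speciesReference species="X" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="A" stoichiometry="1"/></listOfProducts>
   </reaction>
   <reaction id="R2">
    <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', p)
  expect_warning(m <- readModel(p), "R2")
  expect_equal(nReactions(m), 2)
  expect_identical(metaboliteIds(m), "A")   # boundary species excluded
  expect_equal(as.numeric(stoichiometry(m)), c(1, -1))
  expect_equal(lowerBounds(m), c(0, -1000))
  expect_equal(upperBounds(m), c(10, 1000))
})

test_that("dead-end and capped reactions are removed, others untouched", {
  pruned <- removeBlockedReactions(deadEndModel())
  expect_identical(attr(pruned, "removedReactions"), "R3")
  expect_identical(attr(pruned, "removedMetabolites"), "M2")
  expect_identical(reactionIds(pruned), c("R1", "R2"))

  # no blocked reactions: output identical to input
  box <- makeBox(5)
  same <- removeBlockedReactions(box)
  expect_equal(stoichiometry(same), stoichiometry(box))
  expect_identical(reactionIds(same), reactionIds(box))

  # a [0,0]-capped parallel branch is blocked by construction
  capped <- cappedParallelModel()
  pruned2 <- removeBlockedReactions(capped)
  expect_identical(attr(pruned2, "removedReactions"), "capped")
  expect_equal(nReactions(pruned2), nReactions(capped) - 1)
})

test_that("blocked-reaction removal is idempotent and flux-range preserving", {
  net <- makeRandomNetwork(3, 8, seed = 9)
  once <- removeBlockedReactions(net)
  twice <- removeBlockedReactions(once)
  expect_identical(reactionIds(twice), reactionIds(once))
  expect_equal(stoichiometry(twice), stoichiometry(once))

  before <- fluxVariability(net)
  after <- fluxVariability(once)
  survivors <- intersect(reactionIds(once), reactionIds(net))
  pick <- survivors[c(1, ceiling(length(survivors) / 2), length(survivors))]
  for (r in pick) {
    expect_equal(after$min[after$reaction_id == r],
                 before$min[before$reaction_id == r], tolerance = 1e-6)
    expect_equal(after$max[after$reaction_id == r],
                 before$max[before$reaction_id == r], tolerance = 1e-6)
  }
})

test_that("sample matrices round-trip through tsv with provenance", {
  sp <- boxSpace(3)
  s <- sampleOptGp(sp, 100, 2, 4, seed = 5)
  d <- withr::local_tempdir()
  p <- file.path(d, "samples.tsv")
  writeSamples(s, p)
  expect_identical(readLines(p, n = 1L),
                   paste(reactionIds(s), collapse = "\t"))
  back <- readSamples(p)
  expect_identical(reactionIds(back), reactionIds(s))
  expect_equal(samples(back), samples(s), tolerance = 1e-15)
  expect_equal(back@meta$seed, 5)
  expect_identical(back@meta$sampler, "optgp")
})

test_that("degenerate sample output is refused", {
  empty <- new("FluxSamples", samples = matrix(numeric(), 0, 2),
               reactionIds = c("a", "b"), meta = list())
  d <- withr::local_tempdir()
  expect_error(writeSamples(empty, file.path(d, "x.tsv")), "empty")
  sp <- boxSpace(2)
  s <- sampleHitAndRun(sp, 5, seed = 1)
  expect_error(writeSamples(s, file.path(d, "x.h5"), format = "hdf5"),
               "not supported")
})
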