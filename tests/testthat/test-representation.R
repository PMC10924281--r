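test_that("coarse-graining partitions segments with a remainder bead", {
  expect_equal(beadTable(coarseGrain(chainTop(100), 50))[, c("first", "last")],
               data.frame(first = c(1L, 51L), last = c(50L, 100L)))
  b <- beadTable(coarseGrain(chainTop(101), 50))
  expect_equal(b$first, c(1L, 51L, 101L))
  expect_equal(b$last, c(50L, 100L, 101L))
  expect_equal(b$nres, c(50L, 50L, 1L))
  m <- coarseGrain(chainTop(10), 1)
  expect_equal(nBeads(m), 10L)
  expect_true(all(beadTable(m)$nres == 1L))
})

test_that("invalid schemes and topologies are rejected", {
  expect_error(RepresentationScheme(0), "residuesPerBead")
  expect_error(coarseGrain(chainTop(20), RepresentationScheme(c(5, 10))),
               "one residuesPerBead value per topology segment")
  expect_error(ChainTopology(data.frame(chain_id = character(0),
                                        start = integer(0), end = integer(0),
                                        kind = character(0))),
               "no segments")
  expect_error(ChainTopology(data.frame(chain_id = "A", start = 5, end = 10,
                                        kind = "unstructured")),
               "start at residue 1")
  expect_error(ChainTopology(data.frame(chain_id = "A", start = c(1, 12),
                                        end = c(10, 20),
                                        kind = "unstructured")),
               "tile")
})

test_that("bead radius follows cube-root volume scaling", {
  expect_equal(beadRadius(1), (3 * 130 / (4 * pi))^(1 / 3))
  expect_equal(beadRadius(1), 3.14, tolerance = 1e-2)
  expect_equal(beadRadius(8) / beadRadius(1), 2)
  expect_true(all(diff(beadRadius(1:60)) > 0))
  expect_error(beadRadius(0), "nResidues")
})

test_that("free-parameter bound counts 3 per flexible bead, 6 per body", {
  m <- handModel(rep("A", 6), 2,
                 cbind(seq(0, 25, length.out = 6), 0, 0),
                 rigid = c(NA, NA, NA, NA, 1L, 1L))
  expect_equal(countFreeParameters(m), 3L * 4L + 6L * 1L)
  m1 <- handModel("A", 2, rbind(c(0, 0, 0)))
  expect_equal(countFreeParameters(m1), 3L)
  m2 <- handModel(c("A", "A"), 2, rbind(c(0, 0, 0), c(10, 0, 0)), rigid = 1L)
  expect_equal(countFreeParameters(m2), 6L)
})

test_that("residue coverage is conserved for every scheme", {
  tops <- list(chainTop(37),
               preset("globular")$topology,
               preset("mixed")$topology)
  for (top in tops) {
    lens <- chainLengths(top)
    seg <- segments(top)
    counts <- integer(0)
    for (rpb in c(1, 5, 10, 20, 30, 50)) {
      m <- coarseGrain(top, rpb)
      b <- beadTable(m)
      for (ch in names(lens)) {
        covered <- unlist(Map(seq.int, b$first[b$chain_id == ch],
                              b$last[b$chain_id == ch]))
        expect_identical(sort(covered), seq_len(lens[[ch]]))
      }
      seglen <- seg$end - seg$start + 1L
      expect_equal(nBeads(m), sum(ceiling(seglen / rpb)))
      counts <- c(counts, nBeads(m))
    }
    expect_true(all(diff(counts) <= 0))  # coarsening monotonicity
  }
})

test_that("structured beads inherit rigid bodies and reference centroids", {
  p <- preset("globular")
  m <- coarseGrain(p$topology, 10)
  b <- beadTable(m)
  str <- !is.na(b$rigid_body)
  expect_true(any(str))
  ref <- p$assembly@coords$A
  for (i in which(str)) {
    expect_equal(beadCoords(m)[i, ],
                 colMeans(ref[b$first[i]:b$last[i], , drop = FALSE]))
  }
})

test_that("randomizeModel is seed-deterministic and keeps bodies rigid", {
  m <- coarseGrain(preset("globular")$topology, 10)
  r1 <- randomizeModel(m, boxHalfSide = 100, seed = 4)
  r2 <- randomizeModel(m, boxHalfSide = 100, seed = 4)
  expect_identical(beadCoords(r1), beadCoords(r2))
  expect_true(max(abs(beadCoords(r1))) <= 100)
  idx <- which(!is.na(beadTable(m)$rigid_body))
  d0 <- dist(beadCoords(m)[idx, ])
  d1 <- dist(beadCoords(r1)[idx, ])
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
})
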