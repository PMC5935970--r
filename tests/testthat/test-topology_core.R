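test_that("residue contacts respect cutoff and sequence separation", {
  # CA-only chain: residues on a line, distances controlled exactly
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0), c(300, 0, 0),
               c(7.99, 0, 0), c(108.01, 0, 0), c(205, 0, 0))
  rs <- residue_contact_pairs(ca_chain(xyz))
  # residue 1-5: 7.99 A, separation 4 -> included
  expect_true(any(rs$pairs[, 1] == 1 & rs$pairs[, 2] == 5))
  # residue 2-6: 8.01 A -> excluded
  expect_false(any(rs$pairs[, 1] == 2 & rs$pairs[, 2] == 6))
  # residue 3-7: 5 A but separation below min_seq_sep
  rs2 <- residue_contact_pairs(ca_chain(xyz), min_seq_sep = 5)
  expect_false(any(rs2$pairs[, 1] == 3 & rs2$pairs[, 2] == 7))
  rs3 <- residue_contact_pairs(ca_chain(rbind(c(0, 0, 0), c(5, 0, 0))))
  expect_equal(nrow(rs3$pairs), 0)
})

test_that("contact counting matches a brute-force double loop", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 30
    xyz <- matrix(runif(3 * n, 0, 25), ncol = 3)
    ch <- ca_chain(xyz)
    rs <- residue_contact_pairs(ch, cutoff_A = 9, min_seq_sep = 3)
    brute <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (j - i >= 3 && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 9)
        brute[[length(brute) + 1]] <- c(i, j)
    brute <- do.call(rbind, brute)
    expect_equal(unname(rs$pairs), unname(brute))
    # SSE-level counting against the same brute-force set
    segs <- data.frame(sse_type = c("H", "E"), start_idx = c(1, 16),
                       end_idx = c(12, 30), length = c(12, 15),
                       ax = c(1, 0), ay = c(0, 1), az = c(0, 0),
                       cx = 0, cy = 0, cz = 0)
    cm <- build_contact_matrix(segs, rs, min_pairs = 1)
    cnt <- sum(brute[, 1] <= 12 & brute[, 2] >= 16)
    if (cnt >= 1) {
      expect_equal(cm$contacts$n_pairs, cnt)
    } else {
      expect_equal(nrow(cm$contacts), 0)
    }
  }
})

test_that("orientation classification is angular and symmetric", {
  expect_equal(classify_orientation(c(0, 0, 1), c(0, 0, 1)),
               list(orientation = "P", angle_deg = 0))
  r <- classify_orientation(c(0, 0, 1), c(0, 0, -1))
  expect_equal(r$orientation, "A")
  expect_equal(r$angle_deg, 180)
  r <- classify_orientation(c(0, 0, 1), c(0, 0.6, 0.8))
  expect_equal(r$orientation, "P")
  expect_equal(r$angle_deg, acos(0.8) * 180 / pi, tolerance = 1e-9)
  # the 90 degree boundary classifies as P
  r <- classify_orientation(c(0, 0, 1), c(1, 0, 0))
  expect_equal(r$orientation, "P")
  expect_equal(r$angle_deg, 90)
  # symmetry under argument swap
  set.seed(7)
  for (k in 1:20) {
    a <- topostrings:::unitv(rnorm(3)); b <- topostrings:::unitv(rnorm(3))
    expect_equal(classify_orientation(a, b), classify_orientation(b, a))
  }
  expect_error(classify_orientation(c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("SSE contacts require min_pairs supporting residue pairs", {
  segs <- data.frame(sse_type = c("E", "E"), start_idx = c(1, 10),
                     end_idx = c(5, 14), length = c(5, 5),
                     ax = c(0, 0), ay = c(1, -1), az = c(0, 0),
                     cx = 0, cy = 0, cz = 0)
  mk_rset <- function(pairs)
    structure(list(pairs = pairs, cutoff_A = 8, atom_rule = "CB",
                   min_seq_sep = 3L), class = "ResidueContactSet")
  cm <- build_contact_matrix(segs, mk_rset(cbind(c(1, 2, 3), c(10, 11, 12))))
  expect_equal(nrow(cm$contacts), 1)
  expect_equal(cm$contacts$orientation, "A")
  expect_equal(cm$contacts$n_pairs, 3)
  cm2 <- build_contact_matrix(segs, mk_rset(cbind(c(1, 2), c(10, 11))))
  expect_equal(nrow(cm2$contacts), 0)
})

test_that("topology strings encode canonically and parse back", {
  t <- topology("EEH", data.frame(i = c(1, 1), j = c(3, 2),
                                  orientation = c("P", "A")))
  expect_equal(encode_topology(t), "EEH|1-2A,1-3P")
  expect_equal(encode_topology(topology("HHH")), "HHH|")
  p <- parse_topology("EEH|1-2A,1-3P")
  expect_equal(p$composition, "EEH")
  expect_equal(p$contacts$i, c(1L, 1L))
  expect_equal(p$contacts$j, c(2L, 3L))
  expect_equal(p$contacts$orientation, c("A", "P"))
})

test_that("malformed topology strings are rejected with the offending token", {
  expect_error(parse_topology("EEH|1-4A"), "out of range")
  expect_error(parse_topology("EEH|1-2A,1-2P"), "duplicate")
  expect_error(parse_topology("EEH|2-1A"), "out of range")
  expect_error(parse_topology("EEH|1-2X"), "token")
  expect_error(parse_topology("EXH|1-2A"), "H/E")
  expect_error(parse_topology("EEH|1-3P,1-2A"), "sorted")
  expect_error(parse_topology("EEH"), "separator")
})

test_that("encode/parse round-trip on random topologies", {
  set.seed(11)
  for (k in 1:50) {
    t <- random_topology()
    s <- encode_topology(t)
    expect_identical(encode_topology(parse_topology(s)), s)
    expect_true(topologies_equal(t, parse_topology(s)))
  }
})

test_that("structure classes follow the composition", {
  expect_equal(structure_class(parse_topology("HHH|1-2A,2-3A")), "A")
  expect_equal(structure_class(parse_topology("EEEE|1-2A,2-3A,3-4A")), "B")
  expect_equal(structure_class(parse_topology("EEH|1-2A")), "AB")
  expect_error(structure_class(""), "non-empty")
})

test_that("topology equality is exact string equality", {
  expect_true(topologies_equal("EEH|1-2A", "EEH|1-2A"))
  expect_false(topologies_equal("EEH|1-2A", "EEH|1-2P"))
  expect_false(topologies_equal("EEH|", "EHE|"))
})

test_that("the pipeline recovers every fixture's ground truth exactly", {
  for (fx in built_fixtures()) {
    t <- chain_topology(fx$chain)
    expect_identical(encode_topology(t), fx$ground_truth)
    expect_equal(sum(t$sse_lengths), sum(attr(t, "segments")$length))
  }
})
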