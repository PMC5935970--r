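test_that("amide hydrogen placement follows the carbonyl construction", {
  # unit(C - O) = (0,0,-1): H sits 1 A below N
  h <- place_amide_hydrogen(c(1.33, 0, 0), c(0, 0, 0), c(0, 0, 1.23))
  expect_equal(h, c(1.33, 0, -1.0), tolerance = 1e-12)
  # no predecessor / degenerate carbonyl -> no-hydrogen marker
  expect_null(place_amide_hydrogen(c(0, 0, 0), NULL, NULL))
  expect_null(place_amide_hydrogen(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)))
  expect_null(place_amide_hydrogen(c(0, 0, 0), c(NA, 0, 0), c(0, 0, 1)))
})

test_that("hydrogen-bond energy matches the electrostatic model", {
  # C and O on the N-H bisector plane: r_ON = r_OH, r_CN = r_CH, E = 0
  n <- c(0, 0, 0); h <- c(0, 0, 1)
  expect_equal(ks_hbond_energy(n, h, c(3.5, 0, 0.5), c(2, 0, 0.5)), 0,
               tolerance = 1e-12)
  # direct evaluation at prescribed distances
  q <- 0.084 * 332
  e <- q * (1 / 2.9 + 1 / 3.9 - 1 / 1.9 - 1 / 3.8)
  expect_equal(e, -5.250, tolerance = 1e-3)
  # geometry realising those four distances: place atoms on a line
  # O at origin; N 2.9 away; H between N and O at 1.9 from O
  o <- c(0, 0, 0); n2 <- c(2.9, 0, 0); h2 <- c(1.9, 0, 0)
  # C placed to satisfy r_CH = 3.9 and r_CN = 3.8 (two-circle intersection)
  xc <- ((3.9^2 - 3.8^2) - (1.9^2 - 2.9^2)) / (2 * (2.9 - 1.9))
  yc <- sqrt(3.9^2 - (xc - 1.9)^2)
  cpos <- c(xc, yc, 0)
  expect_equal(ks_hbond_energy(n2, h2, cpos, o), e, tolerance = 1e-9)
  # long-range geometry is too weak to bond
  e_far <- q * (1 / 6.0 + 1 / 6.5 - 1 / 5.5 - 1 / 6.8)
  expect_lt(abs(e_far), 0.5)
  # clash sentinel
  expect_equal(ks_hbond_energy(n, h, c(0, 0, 1.2), c(0, 0, 0.9)), -9.9)
})

test_that("ideal helices and hairpins are labelled H and E", {
  h <- ideal_helix(12)
  ch <- structure_chain("A", 1:12, rep("", 12), rep("ALA", 12), h)
  lab <- assign_labels(ch)
  expect_gte(sum(lab == "H"), 8)
  expect_true(all(lab[3:10] == "H"))

  sp <- ideal_strand_pair(5, orientation = "A")
  lab <- assign_labels(sp)
  runs <- rle(lab)
  e_runs <- runs$lengths[runs$values == "E"]
  expect_length(e_runs, 2)
  expect_true(all(e_runs >= 3))
})

test_that("an isolated extended strand gets no E labels", {
  s <- topostrings:::ideal_strand(8)
  ch <- structure_chain("A", 1:8, rep("", 8), rep("VAL", 8), s)
  expect_false(any(assign_labels(ch) == "E"))
})

test_that("label runs segment with minimum lengths and the 3-10 flag", {
  lab <- strsplit("CCHHHHHCCEEECC", "")[[1]]
  segs <- segment_sses(lab)
  expect_equal(segs$sse_type, c("H", "E"))
  expect_equal(segs$start_idx, c(3, 10))
  expect_equal(segs$end_idx, c(7, 12))
  expect_equal(segs$length, c(5, 3))

  expect_equal(nrow(segment_sses(strsplit("CCHHHCC", "")[[1]])), 0)

  lab <- strsplit("GGGGHHHH", "")[[1]]
  off <- segment_sses(lab)
  expect_equal(off$length, 4)
  expect_equal(off$start_idx, 5)
  on <- segment_sses(lab, count_310 = TRUE)
  expect_equal(nrow(on), 1)
  expect_equal(on$length, 8)
})

test_that("segments never overlap and are sorted", {
  for (fx in built_fixtures()) {
    segs <- sse_segments(fx$chain)
    if (nrow(segs) < 2) next
    expect_true(all(diff(segs$start_idx) > 0))
    expect_true(all(segs$start_idx[-1] > segs$end_idx[-nrow(segs)]))
  }
})

test_that("fitted axes recover generator directions and the N-to-C sign", {
  h <- ideal_helix(12, direction = c(0, 0, 1))
  ch <- structure_chain("A", 1:12, rep("", 12), rep("ALA", 12), h)
  fit <- compute_axis(ch, 1, 12)
  expect_lt(topostrings:::vec_angle_deg(fit$axis, c(0, 0, 1)), 5)

  s <- topostrings:::ideal_strand(6)
  ch <- structure_chain("A", 1:6, rep("", 6), rep("VAL", 6), s)
  fit <- compute_axis(ch, 1, 6)
  expect_lt(topostrings:::vec_angle_deg(fit$axis, c(0, 1, 0)), 5)

  # reversing the residue order flips the axis (N-to-C sign convention)
  rev_coords <- lapply(h, function(m) m[12:1, ])
  chr <- structure_chain("A", 1:12, rep("", 12), rep("ALA", 12), rev_coords)
  fit_r <- compute_axis(chr, 1, 12)
  expect_lt(topostrings:::vec_angle_deg(fit_r$axis, c(0, 0, -1)), 5)

  # invariant: axis points along CA_end - CA_start for every fixture segment
  for (fx in built_fixtures()) {
    segs <- sse_segments(fx$chain)
    for (k in seq_len(nrow(segs))) {
      ca <- fx$chain$coords$CA
      d <- ca[segs$end_idx[k], ] - ca[segs$start_idx[k], ]
      expect_gt(sum(c(segs$ax[k], segs$ay[k], segs$az[k]) * d), 0)
    }
  }
})

test_that("assignment is deterministic", {
  fx <- built_fixtures()$reaction_centre_like
  expect_identical(assign_labels(fx$chain), assign_labels(fx$chain))
})

test_that("segment boundaries match generator ground truth within 2 residues", {
  for (fx in built_fixtures()) {
    span <- attr(fx$chain, "element_span")
    els <- fixture_bank()[[fx$name]]$elements
    types <- vapply(els, `[[`, "", "type")
    segs <- sse_segments(fx$chain)
    expected <- which(types != "G")
    expect_equal(nrow(segs), length(expected))
    for (k in seq_along(expected)) {
      e <- expected[k]
      expect_equal(segs$sse_type[k], types[e])
      expect_lte(abs(segs$start_idx[k] - span[e, 1]), 2)
      expect_lte(abs(segs$end_idx[k] - span[e, 2]), 2)
    }
  }
})
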