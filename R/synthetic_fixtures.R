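# Synthetic coordinate generators: chains of ideal alpha-helices and
# beta-strands at controlled positions and orientations, with known
# ground-truth topology strings. Every pipeline stage is testable against
# these without downloading structures.

# Ideal backbone dihedrals. Helices are grown residue-by-residue from
# internal coordinates (standard bond lengths/angles, trans peptide), which
# yields the textbook alpha-helix geometry (about 1.5 A rise and 100 degree
# twist per residue, CA radius about 2.3 A) and correct i -> i+4
# carbonyl-amide hydrogen bonds.
PHI_ALPHA <- -57; PSI_ALPHA <- -47
PHI_310 <- -49; PSI_310 <- -26

STRAND_RISE <- 3.3       # A per residue along the strand axis
STRAND_N_OFF <- 1.25     # N sits this far before the CA along the axis
STRAND_C_OFF <- 1.25     # C this far after
CARBONYL_LEN <- 1.23
# Carbonyl slant (sine of the tilt toward the C-terminus) used for parallel
# sheets, where hydrogen bonds are inclined; chosen so the flat strand model
# satisfies the parallel bridge geometry exactly.
PARALLEL_TILT <- 0.3587

# Grow an n-residue backbone with constant phi/psi; returns a list of n x 3
# coordinate matrices N, CA, C, O, CB.
build_backbone <- function(n, phi, psi) {
  stopifnot(n >= 2)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  a <- 111.2 * pi / 180
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(a), sin(a), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
    b <- CA[i, ] - N[i, ]; cc <- C[i, ] - CA[i, ]; ax <- cross3(b, cc)
    CB[i, ] <- -0.58273431 * ax + 0.56802827 * b - 0.54067466 * cc + CA[i, ]
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

# Center a coordinate set on its CA centroid and rotate its fitted CA axis
# onto `direction`, then optionally roll about that axis and translate to
# `centroid`.
orient_element <- function(coords, centroid, direction, roll = 0) {
  ca <- coords$CA
  mid <- colMeans(ca)
  centered <- sweep(ca, 2, mid)
  ax <- svd(centered, nu = 0, nv = 1)$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  R <- rotation_between(ax, direction)
  if (roll != 0) R <- rotation_axis_angle(direction, roll) %*% R
  out <- lapply(coords, function(m) transform_coords(sweep(m, 2, mid), R, centroid))
  attr(out, "rotation") <- R
  out
}

#' Generate an ideal alpha-helix
#'
#' Backbone (N, CA, C, O, CB) of an ideal alpha-helix built from standard
#' internal coordinates (phi = -57, psi = -47), centered on `centroid` with
#' its N-to-C axis along `direction`.
#'
#' @param n number of residues (>= 4).
#' @param centroid 3-vector position of the CA centroid.
#' @param direction unit 3-vector axis direction (N to C).
#' @return list of n x 3 coordinate matrices N, CA, C, O, CB.
#' @export
ideal_helix <- function(n, centroid = c(0, 0, 0), direction = c(0, 0, 1)) {
  stopifnot(n >= 4)
  orient_element(build_backbone(n, PHI_ALPHA, PSI_ALPHA), centroid, direction)
}

#' Generate an ideal 3-10 helix
#'
#' As [ideal_helix()] but with 3-10 dihedrals (phi = -49, psi = -26), whose
#' i -> i+3 hydrogen bonds the assigner labels G.
#'
#' @inheritParams ideal_helix
#' @return list of n x 3 coordinate matrices.
#' @export
ideal_310_helix <- function(n, centroid = c(0, 0, 0), direction = c(0, 0, 1)) {
  stopifnot(n >= 4)
  orient_element(build_backbone(n, PHI_310, PSI_310), centroid, direction)
}

# Flat idealised strand along +y, centered at the origin. `phase` selects
# which residue parity presents its N-H/C=O to the +x side; `tilt` slants
# the carbonyls toward the C-terminus (used for parallel pairing). CB atoms
# alternate above/below the sheet plane.
ideal_strand <- function(n, phase = 0, tilt = 0) {
  stopifnot(n >= 3)
  i <- seq_len(n) - 1L
  y <- STRAND_RISE * i - STRAND_RISE * (n - 1) / 2
  s <- ifelse((i + phase) %% 2 == 0, 1, -1)
  xo <- sqrt(1 - tilt^2)
  N <- cbind(0, y - STRAND_N_OFF, 0)
  C <- cbind(0, y + STRAND_C_OFF, 0)
  O <- C + CARBONYL_LEN * cbind(s * xo, tilt, 0)
  CA <- cbind(0, y, 0)
  CB <- cbind(0, y, 1.5 * s)
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

#' Describe one secondary-structure element of a synthetic chain
#'
#' @param type "H" (alpha-helix), "E" (strand) or "G" (3-10 helix).
#' @param n residue count (>= 4 for H/G, >= 3 for E).
#' @param centroid 3-vector CA centroid position.
#' @param direction unit 3-vector N-to-C axis.
#' @param roll rotation about the axis in degrees (after axis alignment).
#' @param phase strand side parity (0/1); strands only.
#' @param tilt strand carbonyl slant (sine); strands only.
#' @return a `fixture_element` list.
#' @export
fixture_element <- function(type = c("H", "E", "G"), n, centroid,
                            direction, roll = 0, phase = 0, tilt = 0) {
  type <- match.arg(type)
  stopifnot(n >= if (type == "E") 3 else 4,
            abs(vnorm(direction) - 1) < 1e-6)
  list(type = type, n = as.integer(n), centroid = centroid,
       direction = unitv(direction), roll = roll, phase = phase, tilt = tilt)
}

# Build one element's coordinates; returns coords plus, for strands, the
# direction in which the first residue's amide hydrogen must point when the
# strand geometry continues backwards (used to orient the preceding loop
# residue's carbonyl).
realise_element <- function(el) {
  coords <- switch(el$type,
    H = orient_element(build_backbone(el$n, PHI_ALPHA, PSI_ALPHA),
                       el$centroid, el$direction, el$roll),
    G = orient_element(build_backbone(el$n, PHI_310, PSI_310),
                       el$centroid, el$direction, el$roll),
    E = orient_element(ideal_strand(el$n, el$phase, el$tilt),
                       el$centroid, el$direction, el$roll))
  h_dir <- NULL
  if (el$type == "E") {
    R <- attr(coords, "rotation")
    s0 <- if (el$phase %% 2 == 0) 1 else -1
    xo <- sqrt(1 - el$tilt^2)
    h_dir <- as.vector(R %*% c(s0 * xo, -el$tilt, 0))
  }
  list(coords = coords, h_dir = h_dir,
       aa = switch(el$type, H = "ALA", G = "ALA", E = "VAL"))
}

# Assemble elements into a single chain, inserting short glycine loop
# residues (CA trace) between consecutive elements. The loop residue that
# precedes a strand carries a carbonyl oriented so the strand's first amide
# hydrogen is placed exactly as in a continuing sheet.
assemble_chain <- function(elements, chain_id = "A") {
  parts <- lapply(elements, realise_element)
  n_el <- length(parts)
  rows <- list()   # each: list(aa, N, CA, C, O, CB)
  el_span <- matrix(NA_integer_, n_el, 2)
  add_row <- function(aa, N = NULL, CA, C = NULL, O = NULL, CB = NULL)
    rows[[length(rows) + 1L]] <<- list(aa = aa, N = N, CA = CA, C = C,
                                       O = O, CB = CB)
  for (e in seq_len(n_el)) {
    if (e > 1) {
      prev_ca <- rows[[length(rows)]]$CA
      nxt <- parts[[e]]$coords
      start_ca <- nxt$CA[1, ]
      d <- vnorm(start_ca - prev_ca)
      n_loop <- min(4L, max(2L, as.integer(ceiling(d / 3.8)) - 1L))
      for (k in seq_len(n_loop)) {
        f <- k / (n_loop + 1)
        ca <- prev_ca + f * (start_ca - prev_ca)
        if (k == n_loop && !is.null(parts[[e]]$h_dir)) {
          cpos <- ca + 1.15 * unitv(nxt$N[1, ] - ca)
          opos <- cpos - CARBONYL_LEN * parts[[e]]$h_dir
          add_row("GLY", CA = ca, C = cpos, O = opos)
        } else {
          add_row("GLY", CA = ca)
        }
      }
    }
    co <- parts[[e]]$coords
    el_span[e, 1] <- length(rows) + 1L
    for (i in seq_len(nrow(co$CA)))
      add_row(parts[[e]]$aa, N = co$N[i, ], CA = co$CA[i, ], C = co$C[i, ],
              O = co$O[i, ], CB = co$CB[i, ])
    el_span[e, 2] <- length(rows)
  }
  n <- length(rows)
  coords <- lapply(setNames(BACKBONE_ATOMS, BACKBONE_ATOMS), function(at) {
    m <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) if (!is.null(rows[[i]][[at]])) m[i, ] <- rows[[i]][[at]]
    m
  })
  ch <- structure_chain(chain_id = chain_id, seq_num = seq_len(n),
                        icode = rep("", n),
                        aa = vapply(rows, `[[`, "", "aa"),
                        coords = coords)
  attr(ch, "element_span") <- el_span
  ch
}

#' Generate a hydrogen-bonded pair of ideal beta-strands
#'
#' Two idealised extended strands, joined by a short loop, placed so that
#' the Kabsch-Sander assigner labels both E and the contact matrix reports
#' exactly one inter-strand contact with the requested orientation.
#'
#' @param n residues per strand (>= 3; >= 5 recommended so the E runs
#'   survive the minimum strand length).
#' @param separation inter-strand axis distance in Angstrom.
#' @param orientation "A" (antiparallel) or "P" (parallel).
#' @return a `StructureChain`.
#' @export
ideal_strand_pair <- function(n, separation = 4.8, orientation = c("A", "P")) {
  orientation <- match.arg(orientation)
  assemble_chain(strand_pair_elements(n, separation, orientation,
                                      origin = c(0, 0, 0)))
}

# Element descriptions for a strand pair; `origin` is the centroid of the
# first strand.
strand_pair_elements <- function(n, separation, orientation, origin) {
  if (orientation == "A") {
    phase2 <- if (n %% 2 == 0) 1 else 0
    list(fixture_element("E", n, origin, c(0, 1, 0)),
         fixture_element("E", n, origin + c(separation, 0, 0), c(0, -1, 0),
                         phase = phase2))
  } else {
    list(fixture_element("E", n, origin, c(0, 1, 0), tilt = PARALLEL_TILT),
         fixture_element("E", n, origin + c(separation, STRAND_RISE, 0),
                         c(0, 1, 0), roll = 180, tilt = PARALLEL_TILT))
  }
}

#' Build a synthetic fixture chain and validate it against its ground truth
#'
#' Assembles the chain described by `spec`, runs the full topology pipeline
#' on it, and refuses (with a fixture-validation error) if the recovered
#' topology string differs from the declared ground truth -- a guard against
#' specs whose geometry creates ambiguous unintended contacts.
#'
#' @param spec list with `name`, `elements` (list of [fixture_element()]),
#'   and `ground_truth` (expected canonical topology string).
#' @param pdb_path optional path; when given the chain is also written as a
#'   PDB file.
#' @param validate logical; set `FALSE` to skip the pipeline check.
#' @return list with `chain` (a `StructureChain`), `ground_truth` (string),
#'   `topology` (the recovered `Topology`, when validated) and `path`.
#' @export
build_fixture <- function(spec, pdb_path = NULL, validate = TRUE) {
  stopifnot(is.list(spec), !is.null(spec$elements), !is.null(spec$ground_truth))
  chain <- assemble_chain(spec$elements,
                          chain_id = if (is.null(spec$chain_id)) "A" else spec$chain_id)
  topo <- NULL
  if (validate) {
    topo <- chain_topology(chain)
    got <- encode_topology(topo)
    if (!identical(got, spec$ground_truth))
      stop("fixture validation failed for '", spec$name, "': pipeline says ",
           got, " but ground truth is ", spec$ground_truth)
  }
  if (!is.null(pdb_path)) write_chain_pdb(chain, pdb_path)
  list(name = spec$name, chain = chain, ground_truth = spec$ground_truth,
       topology = topo, path = pdb_path)
}

#' The built-in bank of synthetic fixtures
#'
#' Eight chains of ideal secondary-structure elements spanning structure
#' classes A (all-alpha), B (all-beta) and AB (mixed), each with a declared
#' ground-truth topology string that the pipeline must recover exactly.
#' The "reaction_centre_like" entry mimics a photosynthetic reaction-centre
#' subunit architecture: an N-terminal antiparallel beta-hairpin followed by
#' seven alpha-helices, plus two 3-10 helices that are only counted as
#' helices under the 3-10-inclusive segmentation convention.
#'
#' @return named list of fixture specs for [build_fixture()].
#' @export
fixture_bank <- function() {
  z <- c(0, 0, 1); y <- c(0, 1, 0); my <- c(0, -1, 0); mz <- c(0, 0, -1)
  specs <- list(
    list(name = "hairpin_anti",
         elements = strand_pair_elements(5, 4.8, "A", c(0, 0, 0)),
         ground_truth = "EE|1-2A"),
    list(name = "sheet_parallel",
         elements = strand_pair_elements(5, 4.8, "P", c(0, 0, 0)),
         ground_truth = "EE|1-2P"),
    list(name = "sheet4_anti",
         elements = list(
           fixture_element("E", 5, c(0, 0, 0), y),
           fixture_element("E", 5, c(4.8, 0, 0), my),
           fixture_element("E", 5, c(9.6, 0, 0), y),
           fixture_element("E", 5, c(14.4, 0, 0), my)),
         ground_truth = "EEEE|1-2A,2-3A,3-4A"),
    list(name = "bundle3_anti",
         elements = list(
           fixture_element("H", 10, c(0, 0, 0), z),
           fixture_element("H", 10, c(9.5, 0, 0), mz),
           fixture_element("H", 10, c(19, 0, 0), z)),
         ground_truth = "HHH|1-2A,2-3A"),
    list(name = "bundle3_par",
         elements = list(
           fixture_element("H", 10, c(0, 0, 0), z),
           fixture_element("H", 10, c(9.5, 0, 0), z),
           fixture_element("H", 10, c(4.75, 8.23, 0), z)),
         ground_truth = "HHH|1-2P,1-3P,2-3P"),
    list(name = "pair_far",
         elements = list(
           fixture_element("H", 10, c(0, 0, 0), z),
           fixture_element("H", 10, c(40, 0, 0), z)),
         ground_truth = "HH|"),
    list(name = "hairpin_helix",
         elements = c(strand_pair_elements(5, 4.8, "A", c(0, 0, 0)),
                      list(fixture_element("H", 10, c(2.4, 0, 8), y))),
         ground_truth = "EEH|1-2A,1-3P,2-3A"),
    list(name = "reaction_centre_like",
         elements = c(
           strand_pair_elements(5, 4.8, "A", c(0, 0, 0)),
           list(fixture_element("G", 7, c(11, 0, 18), y)),
           lapply(seq_len(7), function(k)
             fixture_element("H", 10, c(18 + 9.5 * (k - 1), 0, 0),
                             if (k %% 2 == 1) z else mz)),
           list(fixture_element("G", 7, c(82, 0, 18), y))),
         ground_truth = paste0("EEHHHHHHH|1-2A,",
                               paste(sprintf("%d-%dA", 3:8, 4:9),
                                     collapse = ",")))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
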