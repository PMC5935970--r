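# Simplified Kabsch-Sander secondary-structure assignment.
#
# The assigner reproduces the hydrogen-bond patterns that define helices and
# sheets: an electrostatic model scores putative N-H...O=C bonds, n-turns and
# bridge patterns are detected from the bond table, and per-residue labels
# H/G/I/E/B/C are derived with the usual priority (alpha-helix, then sheet,
# then 3-10 and pi helices). Sheet-topology lettering, bulge merging and
# solvent accessibility are deliberately out of scope; a DSSP-file import
# path exists for exact-DSSP workflows.

KS_COUPLING <- 0.084 * 332      # kcal/mol * Angstrom, electrostatic prefactor
KS_HBOND_CUTOFF <- -0.5         # kcal/mol, bond threshold
KS_CLASH_DIST <- 0.5            # Angstrom
KS_MIN_ENERGY <- -9.9           # sentinel for clashing geometry
CHAIN_BREAK_CA_DIST <- 4.5      # Angstrom between consecutive CA atoms

#' Place the backbone amide hydrogen
#'
#' The amide hydrogen of residue i is placed 1 Angstrom from its nitrogen,
#' opposite the carbonyl C=O bond of the preceding residue (the standard
#' DSSP construction). Returns `NULL` (no-hydrogen marker) when the
#' predecessor's C/O or the residue's N is missing, or when the carbonyl
#' direction is degenerate.
#'
#' @param n_i N coordinate of the donor residue (3-vector).
#' @param c_prev,o_prev C and O coordinates of the preceding residue.
#' @return 3-vector H position, or `NULL`.
#' @export
place_amide_hydrogen <- function(n_i, c_prev, o_prev) {
  if (is.null(n_i) || is.null(c_prev) || is.null(o_prev)) return(NULL)
  if (anyNA(n_i) || anyNA(c_prev) || anyNA(o_prev)) return(NULL)
  d <- c_prev - o_prev
  if (vnorm(d) < 1e-6) return(NULL)
  n_i + unitv(d)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a putative hydrogen bond between an N-H donor and
#' a C=O acceptor: E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol
#' with distances in Angstrom. A bond is called when E < -0.5 kcal/mol. Any
#' pairwise distance below 0.5 Angstrom is treated as a clash and assigned
#' the minimum-energy sentinel (-9.9, bonded).
#'
#' @param n,h donor nitrogen and hydrogen coordinates.
#' @param c,o acceptor carbonyl carbon and oxygen coordinates.
#' @return energy in kcal/mol.
#' @export
ks_hbond_energy <- function(n, h, c, o) {
  r_on <- vnorm(o - n); r_ch <- vnorm(c - h)
  r_oh <- vnorm(o - h); r_cn <- vnorm(c - n)
  if (min(r_on, r_ch, r_oh, r_cn) < KS_CLASH_DIST) return(KS_MIN_ENERGY)
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# TRUE between residues i and i+1 when the backbone is continuous
# (CA-CA distance below the break cutoff and both CAs present).
chain_continuity <- function(chain) {
  n <- n_residues(chain)
  if (n < 2) return(logical(0))
  ca <- chain$coords$CA
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  d <= CHAIN_BREAK_CA_DIST
}

# Hydrogen-bond matrix: hb[i, j] TRUE when CO(i) accepts the N-H of j.
ks_hbond_matrix <- function(chain) {
  n <- n_residues(chain)
  cont <- chain_continuity(chain)
  co <- chain$coords
  # donor hydrogens (none for the first residue, after a break, for proline,
  # or with incomplete backbone)
  hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1 || !cont[i - 1] || chain$aa[i] == "PRO") next
    h <- place_amide_hydrogen(co$N[i, ], co$C[i - 1, ], co$O[i - 1, ])
    if (!is.null(h)) hpos[i, ] <- h
  }
  hb <- matrix(FALSE, n, n)
  ca <- co$CA
  for (i in seq_len(n)) {            # acceptor CO on i
    if (anyNA(co$C[i, ]) || anyNA(co$O[i, ])) next
    for (j in seq_len(n)) {          # donor NH on j
      if (abs(i - j) < 2) next
      if (anyNA(hpos[j, ]) || anyNA(co$N[j, ])) next
      if (vnorm(ca[i, ] - ca[j, ]) > 9) next
      e <- ks_hbond_energy(co$N[j, ], hpos[j, ], co$C[i, ], co$O[i, ])
      hb[i, j] <- e < KS_HBOND_CUTOFF
    }
  }
  hb
}

#' Assign per-residue secondary-structure labels
#'
#' Runs the built-in simplified Kabsch-Sander assigner on a chain: helices
#' from consecutive n-turns (H for 4-turns, G for 3-turns, I for 5-turns),
#' strands from parallel/antiparallel bridge ladders (E), isolated bridges
#' (B), everything else coil (C). Chain breaks (consecutive CA-CA distance
#' above 4.5 Angstrom) terminate all patterns.
#'
#' @param chain a `StructureChain` with backbone coordinates.
#' @return character vector of labels in H, G, I, E, B, C, aligned to the
#'   chain's residues.
#' @export
assign_labels <- function(chain) {
  n <- n_residues(chain)
  if (n < 5) {
    warning("chain too short for secondary-structure assignment; all coil")
    return(rep("C", n))
  }
  cont <- chain_continuity(chain)
  contiguous_span <- function(a, b) a >= 1 && b <= n && all(cont[a:(b - 1)])
  hb <- ks_hbond_matrix(chain)

  turn_at <- function(len) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - len))
      t[i] <- hb[i, i + len] && contiguous_span(i, i + len)
    t
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- turn_at(5)

  helix_mark <- function(t, len) {
    m <- rep(FALSE, n)
    for (i in 2:(n - len))
      if (t[i - 1] && t[i]) m[i:(i + len - 1)] <- TRUE
    m
  }
  is_h <- helix_mark(t4, 4)

  # bridge detection (|i - j| >= 3 so the two three-residue stretches do
  # not overlap)
  valid_mid <- function(i) i >= 2 && i <= n - 1 && cont[i - 1] && cont[i]
  bridges <- list()
  for (i in seq_len(n)) {
    if (!valid_mid(i)) next
    for (j in seq_len(n)) {
      if (j - i < 3 || !valid_mid(j)) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti)
        bridges[[length(bridges) + 1L]] <-
          c(i = i, j = j, type = if (anti) 1L else 2L)  # anti wins ties
    }
  }
  is_e <- rep(FALSE, n); is_b <- rep(FALSE, n)
  if (length(bridges)) {
    bdf <- do.call(rbind, bridges)
    # chain bridges into ladders: (i,j) connects to (i+1, j-1) antiparallel
    # or (i+1, j+1) parallel, same type
    nb <- nrow(bdf)
    parent <- seq_len(nb)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in seq_len(nb)) for (b in seq_len(nb)) {
      if (bdf[a, "type"] != bdf[b, "type"]) next
      step <- if (bdf[a, "type"] == 1L) -1L else 1L
      if (bdf[b, "i"] == bdf[a, "i"] + 1L && bdf[b, "j"] == bdf[a, "j"] + step) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    roots <- vapply(seq_len(nb), find, integer(1))
    for (r in unique(roots)) {
      members <- which(roots == r)
      res <- c(bdf[members, "i"], bdf[members, "j"])
      if (length(members) >= 2) is_e[res] <- TRUE else is_b[res] <- TRUE
    }
  }

  is_g <- helix_mark(t3, 3)
  is_i <- helix_mark(t5, 5)

  labels <- rep("C", n)
  labels[is_i] <- "I"
  labels[is_g] <- "G"
  labels[is_b & !is_e] <- "B"
  labels[is_e] <- "E"
  labels[is_h] <- "H"
  labels
}

#' Convert DSSP-file labels to the internal label track
#'
#' Aligns labels read with [read_dssp_file()] to a chain by residue number
#' and insertion code, mapping T/S and unmatched residues to coil.
#'
#' @param chain a `StructureChain`.
#' @param dssp data.frame from [read_dssp_file()].
#' @return character label vector aligned to the chain.
#' @export
dssp_label_track <- function(chain, dssp) {
  key <- paste(chain$seq_num, chain$icode, sep = "\r")
  dkey <- paste(dssp$seq_num, dssp$icode, sep = "\r")
  lab <- dssp$label[match(key, dkey)]
  lab[is.na(lab) | lab %in% c("T", "S")] <- "C"
  lab
}

#' Segment a label track into secondary-structure elements
#'
#' Maximal runs of H become helix segments and maximal runs of E become
#' strand segments; isolated bridges (B) are ignored. With `count_310` on,
#' runs of G count as helices too and G runs directly adjacent to H runs are
#' merged into a single helix (the convention some topology servers use,
#' which raises helix counts relative to the alpha-only default). Runs
#' shorter than the minima are discarded.
#'
#' @param labels character label track (H/G/I/E/B/C).
#' @param min_helix minimum helix length in residues.
#' @param min_strand minimum strand length in residues.
#' @param count_310 logical; include 3-10 helices as helix.
#' @return data.frame with columns `sse_type` ("H"/"E"), `start_idx`,
#'   `end_idx` (1-based inclusive residue indices) and `length`, ordered
#'   N to C.
#' @export
segment_sses <- function(labels, min_helix = 4L, min_strand = 3L,
                         count_310 = FALSE) {
  helix_set <- if (count_310) c("H", "G") else "H"
  eff <- ifelse(labels %in% helix_set, "H", ifelse(labels == "E", "E", "C"))
  r <- rle(eff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "H" & r$lengths >= min_helix) |
    (r$values == "E" & r$lengths >= min_strand)
  data.frame(sse_type = r$values[keep],
             start_idx = starts[keep],
             end_idx = ends[keep],
             length = r$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Fit the axis and centroid of a secondary-structure element
#'
#' The centroid is the mean CA position; the axis is the first principal
#' direction of the centered CA coordinates (leading singular vector),
#' sign-oriented so that it points N to C (positive projection on
#' CA_end - CA_start).
#'
#' @param chain a `StructureChain`.
#' @param start_idx,end_idx 1-based inclusive residue indices (span >= 3).
#' @return list with `axis` (unit 3-vector) and `centroid` (3-vector).
#' @export
compute_axis <- function(chain, start_idx, end_idx) {
  stopifnot(start_idx >= 1, end_idx <= n_residues(chain),
            end_idx - start_idx + 1 >= 3)
  ca <- chain$coords$CA[start_idx:end_idx, , drop = FALSE]
  centroid <- colMeans(ca)
  centered <- sweep(ca, 2, centroid)
  ax <- svd(centered, nu = 0, nv = 1)$v[, 1]
  direction <- ca[nrow(ca), ] - ca[1, ]
  if (sum(ax * direction) < 0) ax <- -ax
  list(axis = unitv(ax), centroid = centroid)
}

#' Assign, segment and orient a chain's secondary-structure elements
#'
#' Convenience wrapper: label the chain (built-in assigner or a supplied
#' label track), segment into SSEs and attach fitted axes and centroids.
#'
#' @param chain a `StructureChain`.
#' @param labels optional precomputed label track (e.g. from
#'   [dssp_label_track()]); defaults to [assign_labels()].
#' @inheritParams segment_sses
#' @return segment data.frame as from [segment_sses()] with additional
#'   columns `ax`, `ay`, `az` (axis) and `cx`, `cy`, `cz` (centroid).
#' @export
sse_segments <- function(chain, labels = NULL, min_helix = 4L,
                         min_strand = 3L, count_310 = FALSE) {
  if (is.null(labels)) labels <- assign_labels(chain)
  stopifnot(length(labels) == n_residues(chain))
  segs <- segment_sses(labels, min_helix = min_helix,
                       min_strand = min_strand, count_310 = count_310)
  axes <- matrix(NA_real_, nrow(segs), 6)
  for (k in seq_len(nrow(segs))) {
    fit <- compute_axis(chain, segs$start_idx[k], segs$end_idx[k])
    axes[k, ] <- c(fit$axis, fit$centroid)
  }
  segs$ax <- axes[, 1]; segs$ay <- axes[, 2]; segs$az <- axes[, 3]
  segs$cx <- axes[, 4]; segs$cy <- axes[, 5]; segs$cz <- axes[, 6]
  segs
}
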