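# Residue- and SSE-level contacts, the SSE contact adjacency matrix, and the
# canonical topology string.
#
# The topology string is the package's central data structure: a chain's SSE
# composition (H/E letters, N to C), followed by "|", followed by the sorted
# list of spatial SSE contacts "i-jO" where i < j are 1-based SSE indices and
# O is P (parallel, inter-axis angle <= 90 degrees) or A (antiparallel).
# Example: "EEH|1-2A,1-3P". It carries the three ingredients that define a
# topology: composition, contact, and relative arrangement.

#' Residue-level contact pairs
#'
#' Finds all residue pairs (i, j), i < j, whose selected atoms lie within
#' `cutoff_A` Angstrom and whose index separation is at least `min_seq_sep`
#' (sequence-local contacts are excluded). The default CB rule substitutes
#' CA for glycine or any residue lacking a CB; the "heavy" rule takes the
#' minimum distance over the stored backbone atoms.
#'
#' @param chain a `StructureChain`.
#' @param cutoff_A distance cutoff in Angstrom.
#' @param atom_rule one of "CB", "CA", "heavy".
#' @param min_seq_sep minimum residue index separation.
#' @return object of class `ResidueContactSet`: list with `pairs` (two-column
#'   integer matrix, i < j), `cutoff_A`, `atom_rule`, `min_seq_sep`.
#' @export
residue_contact_pairs <- function(chain, cutoff_A = 8.0,
                                  atom_rule = c("CB", "CA", "heavy"),
                                  min_seq_sep = 3L) {
  atom_rule <- match.arg(atom_rule)
  n <- n_residues(chain)
  stopifnot(n >= 1, cutoff_A > 0, min_seq_sep >= 1)
  if (atom_rule == "heavy") {
    d2 <- matrix(Inf, n, n)
    for (at in BACKBONE_ATOMS) {
      m <- chain$coords[[at]]
      ok <- !is.na(m[, 1])
      if (!any(ok)) next
      dd <- as.matrix(dist(m[ok, , drop = FALSE]))^2
      d2[ok, ok] <- pmin(d2[ok, ok], dd)
    }
  } else {
    m <- chain$coords[[atom_rule]]
    if (atom_rule == "CB") {
      miss <- is.na(m[, 1])
      m[miss, ] <- chain$coords$CA[miss, ]
    }
    d2 <- as.matrix(dist(m))^2
  }
  sep <- abs(row(d2) - col(d2))
  hit <- which(d2 <= cutoff_A^2 & sep >= min_seq_sep & upper.tri(d2),
               arr.ind = TRUE)
  pairs <- cbind(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  structure(list(pairs = pairs, cutoff_A = cutoff_A, atom_rule = atom_rule,
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "ResidueContactSet")
}

#' Classify the relative orientation of two SSE axes
#'
#' The inter-axis angle is arccos of the (clamped) dot product of the two
#' N-to-C unit axis vectors; the pair is parallel (P) when the angle is at
#' most `parallel_max_deg` degrees, antiparallel (A) otherwise. The boundary
#' angle itself classifies as P.
#'
#' @param axis_i,axis_j unit 3-vectors (norm within 1e-6 of 1).
#' @param parallel_max_deg P/A boundary angle in degrees.
#' @return list with `orientation` ("P" or "A") and `angle_deg`.
#' @export
classify_orientation <- function(axis_i, axis_j, parallel_max_deg = 90) {
  if (abs(vnorm(axis_i) - 1) > 1e-6 || abs(vnorm(axis_j) - 1) > 1e-6)
    stop("axis vectors must be unit length")
  ca <- max(-1, min(1, sum(axis_i * axis_j)))
  ang <- acos(ca) * 180 / pi
  list(orientation = if (ang <= parallel_max_deg) "P" else "A",
       angle_deg = ang)
}

#' Build the SSE contact adjacency matrix
#'
#' For every pair of SSEs (i < j, sequence order) counts the residue contact
#' pairs with one residue in each segment; pairs within one SSE are ignored.
#' Pairs supported by at least `min_pairs` residue contacts become an SSE
#' contact, with orientation classified from the two fitted axes.
#'
#' @param segments segment data.frame from [sse_segments()] (with axes).
#' @param rset a `ResidueContactSet`.
#' @param min_pairs minimum number of supporting residue pairs.
#' @param parallel_max_deg P/A boundary passed to [classify_orientation()].
#' @return object of class `ContactMatrix`: list with `n` (SSE count),
#'   `composition` and `contacts` data.frame (i, j, orientation, angle_deg,
#'   n_pairs).
#' @export
build_contact_matrix <- function(segments, rset, min_pairs = 3L,
                                 parallel_max_deg = 90) {
  n <- nrow(segments)
  if (n > 1 && any(diff(segments$start_idx) <= 0))
    stop("segments must be sorted N to C")
  member <- function(res, k)
    res >= segments$start_idx[k] & res <= segments$end_idx[k]
  p <- rset$pairs
  contacts <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- sum((member(p[, 1], i) & member(p[, 2], j)) |
                 (member(p[, 1], j) & member(p[, 2], i)))
    if (cnt >= min_pairs) {
      ori <- classify_orientation(
        c(segments$ax[i], segments$ay[i], segments$az[i]),
        c(segments$ax[j], segments$ay[j], segments$az[j]),
        parallel_max_deg)
      contacts[[length(contacts) + 1L]] <-
        data.frame(i = i, j = j, orientation = ori$orientation,
                   angle_deg = ori$angle_deg, n_pairs = cnt,
                   stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(contacts)) do.call(rbind, contacts)
  else data.frame(i = integer(0), j = integer(0),
                  orientation = character(0), angle_deg = numeric(0),
                  n_pairs = integer(0), stringsAsFactors = FALSE)
  structure(list(n = n, composition = paste(segments$sse_type, collapse = ""),
                 contacts = contacts),
            class = "ContactMatrix")
}

empty_contacts <- function() {
  data.frame(i = integer(0), j = integer(0), orientation = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a validated topology object
#'
#' @param composition string over the alphabet H (helix) and E (strand),
#'   N to C order.
#' @param contacts data.frame with columns `i`, `j` (1-based SSE indices,
#'   i < j) and `orientation` ("P"/"A"); may be empty.
#' @param sse_lengths optional integer residue counts per SSE.
#' @return object of class `Topology` with fields `composition`, `contacts`
#'   (canonically sorted), `sse_lengths` and `structure_class`.
#' @export
topology <- function(composition, contacts = empty_contacts(),
                     sse_lengths = NULL) {
  if (!is.character(composition) || length(composition) != 1 ||
      !nzchar(composition) || grepl("[^HE]", composition))
    stop("malformed topology: composition must be a non-empty string over H/E")
  n <- nchar(composition)
  contacts <- as.data.frame(contacts, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "orientation") %in% names(contacts)))
  contacts <- contacts[c("i", "j", "orientation")]
  contacts$i <- as.integer(contacts$i); contacts$j <- as.integer(contacts$j)
  if (nrow(contacts)) {
    bad <- contacts$i >= contacts$j | contacts$i < 1 | contacts$j > n
    if (any(bad))
      stop("malformed topology: contact ", contacts$i[bad][1], "-",
           contacts$j[bad][1], " out of range for ", n, " SSEs")
    if (!all(contacts$orientation %in% c("P", "A")))
      stop("malformed topology: orientation must be P or A")
    contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
    if (anyDuplicated(contacts[c("i", "j")]))
      stop("malformed topology: duplicate contact pair")
    rownames(contacts) <- NULL
  }
  if (!is.null(sse_lengths)) {
    sse_lengths <- as.integer(sse_lengths)
    stopifnot(length(sse_lengths) == n, all(sse_lengths >= 1))
  }
  structure(list(composition = composition, contacts = contacts,
                 sse_lengths = sse_lengths,
                 structure_class = composition_class(composition)),
            class = "Topology")
}

composition_class <- function(composition) {
  has_h <- grepl("H", composition); has_e <- grepl("E", composition)
  if (has_h && has_e) "AB" else if (has_h) "A" else "B"
}

#' Structure class of a topology
#'
#' "A" for all-helix compositions, "B" for all-strand, "AB" for mixed.
#'
#' @param t a `Topology`, a composition string, or a full topology string
#'   (the part after "|" is ignored).
#' @return "A", "B" or "AB".
#' @export
structure_class <- function(t) {
  comp <- if (inherits(t, "Topology")) t$composition
  else sub("\\|.*$", "", as.character(t))
  if (!nzchar(comp) || grepl("[^HE]", comp))
    stop("composition must be a non-empty string over H/E")
  composition_class(comp)
}

#' Encode a topology as its canonical string
#'
#' @param x a `Topology` or `ContactMatrix`.
#' @return canonical topology string, e.g. `"EEH|1-2A,1-3P"`; a topology
#'   with no contacts encodes as `"COMP|"`.
#' @export
encode_topology <- function(x) {
  if (inherits(x, "ContactMatrix"))
    x <- topology(x$composition, x$contacts[c("i", "j", "orientation")])
  stopifnot(inherits(x, "Topology"))
  co <- x$contacts
  paste0(x$composition, "|",
         paste(sprintf("%d-%d%s", co$i, co$j, co$orientation), collapse = ","))
}

#' Parse a canonical topology string
#'
#' Inverse of [encode_topology()]; rejects malformed strings (bad alphabet,
#' i >= j, out-of-range indices, duplicates, unsorted contact lists) with an
#' error naming the offending token.
#'
#' @param s topology string.
#' @return a `Topology`.
#' @export
parse_topology <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (!grepl("|", s, fixed = TRUE))
    stop("malformed topology string (no '|' separator): ", s)
  bar <- regexpr("|", s, fixed = TRUE)
  comp <- substr(s, 1, bar - 1)
  rest <- substr(s, bar + 1, nchar(s))
  contacts <- empty_contacts()
  if (nzchar(rest)) {
    toks <- strsplit(rest, ",", fixed = TRUE)[[1]]
    m <- regmatches(toks, regexec("^([0-9]+)-([0-9]+)([PA])$", toks))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad))
      stop("malformed topology contact token: '", toks[bad][1], "'")
    contacts <- data.frame(
      i = as.integer(vapply(m, `[`, "", 2)),
      j = as.integer(vapply(m, `[`, "", 3)),
      orientation = vapply(m, `[`, "", 4),
      stringsAsFactors = FALSE)
    ord <- order(contacts$i, contacts$j)
    if (any(ord != seq_len(nrow(contacts))))
      stop("malformed topology: contacts not sorted by (i, j) in: ", s)
  }
  topology(comp, contacts)
}

#' Test two topologies for equality
#'
#' True iff the canonical strings are identical (same composition, contact
#' pairs and orientations; SSE lengths are not compared).
#'
#' @param t1,t2 `Topology` objects or topology strings.
#' @return logical.
#' @export
topologies_equal <- function(t1, t2) {
  s1 <- if (inherits(t1, "Topology")) encode_topology(t1) else
    encode_topology(parse_topology(t1))
  s2 <- if (inherits(t2, "Topology")) encode_topology(t2) else
    encode_topology(parse_topology(t2))
  identical(s1, s2)
}

#' @export
print.Topology <- function(x, ...) {
  cat(encode_topology(x), "\n")
  invisible(x)
}

#' @export
format.Topology <- function(x, ...) encode_topology(x)

#' Compute the topology of a chain end to end
#'
#' Runs the full pipeline: secondary-structure assignment (built-in
#' Kabsch-Sander, or a supplied label track), SSE segmentation with axes,
#' residue contact detection, contact-matrix construction, and encoding.
#'
#' @param chain a `StructureChain`.
#' @param labels optional precomputed label track.
#' @inheritParams sse_segments
#' @inheritParams residue_contact_pairs
#' @inheritParams build_contact_matrix
#' @return a `Topology` with `sse_lengths` filled; the segment table and
#'   `ContactMatrix` are attached as attributes `segments` and
#'   `contact_matrix`.
#' @export
chain_topology <- function(chain, labels = NULL, min_helix = 4L,
                           min_strand = 3L, count_310 = FALSE,
                           cutoff_A = 8.0, atom_rule = "CB",
                           min_seq_sep = 3L, min_pairs = 3L,
                           parallel_max_deg = 90) {
  segs <- sse_segments(chain, labels = labels, min_helix = min_helix,
                       min_strand = min_strand, count_310 = count_310)
  if (nrow(segs) == 0)
    stop("no secondary-structure elements found in chain ", chain$chain_id)
  rset <- residue_contact_pairs(chain, cutoff_A = cutoff_A,
                                atom_rule = atom_rule,
                                min_seq_sep = min_seq_sep)
  cm <- build_contact_matrix(segs, rset, min_pairs = min_pairs,
                             parallel_max_deg = parallel_max_deg)
  t <- topology(cm$composition, cm$contacts[c("i", "j", "orientation")],
                sse_lengths = segs$length)
  attr(t, "segments") <- segs
  attr(t, "contact_matrix") <- cm
  t
}
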