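#' @importFrom stats setNames
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Construct a protein chain object
#'
#' A `StructureChain` holds one polymer chain as parallel vectors of residue
#' identifiers plus one n x 3 coordinate matrix per backbone atom type
#' (N, CA, C, O, CB). Rows of absent atoms are `NA`; the CA row is always
#' present. Residues are ordered N to C terminus.
#'
#' @param chain_id single chain identifier.
#' @param seq_num integer author residue numbers.
#' @param icode insertion codes ("" when absent).
#' @param aa three-letter residue names.
#' @param coords named list of n x 3 matrices for N, CA, C, O, CB.
#' @return an object of class `StructureChain`.
#' @export
structure_chain <- function(chain_id, seq_num, icode, aa, coords) {
  n <- length(seq_num)
  stopifnot(n >= 1, length(aa) == n, length(icode) == n)
  coords <- lapply(setNames(BACKBONE_ATOMS, BACKBONE_ATOMS), function(at) {
    m <- coords[[at]]
    if (is.null(m)) m <- matrix(NA_real_, n, 3)
    m <- as.matrix(m)
    stopifnot(nrow(m) == n, ncol(m) == 3)
    dimnames(m) <- NULL
    m
  })
  if (anyNA(coords$CA)) stop("every residue must have a CA coordinate")
  ord <- order(seq_num, icode)
  if (any(ord != seq_len(n))) stop("residues must be ordered by (seq_num, icode)")
  structure(list(chain_id = as.character(chain_id),
                 seq_num = as.integer(seq_num),
                 icode = as.character(icode),
                 aa = as.character(aa),
                 coords = coords),
            class = "StructureChain")
}

#' @export
print.StructureChain <- function(x, ...) {
  cat(sprintf("<StructureChain %s: %d residues (%d-%d)>\n",
              x$chain_id, n_residues(x), x$seq_num[1],
              x$seq_num[n_residues(x)]))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `StructureChain`.
#' @return integer residue count.
#' @export
n_residues <- function(chain) length(chain$seq_num)

#' Read a protein structure into chain objects
#'
#' Parses a PDB or mmCIF file (via bio3d) and returns one `StructureChain`
#' per polymer chain. Only the first model of multi-model entries is kept;
#' only standard amino acids are retained, with selenomethionine (MSE)
#' mapped to MET; alternate locations are resolved by highest occupancy,
#' ties broken by alphabetical altloc identifier; residues without a CA
#' atom are dropped. Other non-standard residues are skipped with a warning.
#'
#' @param path path to the structure file.
#' @param format_hint one of "auto", "pdb", "mmcif". "auto" detects by file
#'   extension, then by content sniffing.
#' @return list of `StructureChain`, named by chain ID.
#' @export
read_structure <- function(path, format_hint = c("auto", "pdb", "mmcif")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("structure file not found: ", path)
  fmt <- format_hint
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else {
      head_lines <- readLines(path, n = 20L, warn = FALSE)
      if (any(grepl("^data_|^_atom_site\\.", head_lines))) "mmcif" else "pdb"
    }
  }
  parsed <- tryCatch(
    if (fmt == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("could not parse ", path, " as ", fmt, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- parsed$atom
  # restrict to first model when the parser exposes model numbers
  if (!is.null(atoms$model)) atoms <- atoms[atoms$model == atoms$model[1], ]
  keep_res <- atoms$resid %in% STANDARD_AA3 | atoms$resid == "MSE"
  dropped <- unique(atoms$resid[!keep_res & atoms$type == "ATOM"])
  dropped <- setdiff(dropped, "HOH")
  if (length(dropped))
    warning("skipping non-standard residues: ", paste(dropped, collapse = ", "))
  atoms <- atoms[keep_res, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no protein chains found in ", path)
  atoms$resid[atoms$resid == "MSE"] <- "MET"
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$o[is.na(atoms$o)] <- 1

  chains <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch & atoms$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(a) == 0) next
    # resolve altlocs: per (residue, atom) keep highest occupancy then lowest altloc
    key <- paste(a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, a$alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    rkey <- paste(a$resno, a$insert, sep = "\r")
    res <- unique(data.frame(resno = a$resno, insert = a$insert, resid = a$resid,
                             key = rkey, stringsAsFactors = FALSE))
    res <- res[order(res$resno, res$insert), , drop = FALSE]
    n <- nrow(res)
    coords <- lapply(setNames(BACKBONE_ATOMS, BACKBONE_ATOMS),
                     function(at) matrix(NA_real_, n, 3))
    idx <- match(rkey, res$key)
    for (r in seq_len(nrow(a)))
      coords[[a$elety[r]]][idx[r], ] <- c(a$x[r], a$y[r], a$z[r])
    has_ca <- !is.na(coords$CA[, 1])
    if (!any(has_ca)) next
    coords <- lapply(coords, function(m) m[has_ca, , drop = FALSE])
    res <- res[has_ca, , drop = FALSE]
    chains[[as.character(ch)]] <- structure_chain(
      chain_id = ch, seq_num = res$resno, icode = res$insert,
      aa = res$resid, coords = coords)
  }
  if (length(chains) == 0) stop("no protein chains found in ", path)
  chains
}

#' Select one chain by identifier
#'
#' @param chains list of `StructureChain` as returned by [read_structure()].
#' @param chain_id chain identifier (case-sensitive exact match).
#' @return the matching `StructureChain`.
#' @export
select_chain <- function(chains, chain_id) {
  stopifnot(nzchar(chain_id))
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  hit <- which(ids == chain_id)
  if (length(hit) == 0)
    stop("chain '", chain_id, "' not found; available: ",
         paste(ids, collapse = ", "))
  chains[[hit[1]]]
}

#' Read per-residue secondary structure from a classic DSSP output file
#'
#' Parses the fixed-column residue table of classic DSSP text output and
#' returns the labels for one chain. Chain-break records ("!") are preserved
#' as gaps in the numbering, not as rows.
#'
#' @param path path to a DSSP output file.
#' @param chain_id chain to extract.
#' @return data.frame with columns `seq_num`, `icode`, `label`; labels are
#'   from H, G, I, E, B, T, S and "C" for blank/other.
#' @export
read_dssp_file <- function(path, chain_id) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0)
    stop("malformed DSSP file (no '  #  RESIDUE' header): ", path)
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 17]
  body <- body[substr(body, 14, 14) != "!"]
  if (length(body) == 0) stop("DSSP file has no residue records: ", path)
  ch <- substr(body, 12, 12)
  keep <- ch == chain_id
  if (!any(keep))
    stop("chain '", chain_id, "' not present in DSSP file; available: ",
         paste(sort(unique(trimws(ch))), collapse = ", "))
  body <- body[keep]
  seq_num <- as.integer(trimws(substr(body, 6, 10)))
  if (anyNA(seq_num)) stop("malformed DSSP residue record in ", path)
  icode <- trimws(substr(body, 11, 11))
  label <- substr(body, 17, 17)
  label[!label %in% c("H", "G", "I", "E", "B", "T", "S")] <- "C"
  data.frame(seq_num = seq_num, icode = icode, label = label,
             stringsAsFactors = FALSE)
}

#' Write a chain to a PDB file
#'
#' Used mainly to materialise synthetic fixtures on disk; output round-trips
#' through [read_structure()].
#'
#' @param chain a `StructureChain`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  n <- n_residues(chain)
  ele <- character(0); resno <- integer(0); resid <- character(0)
  xyz <- numeric(0); insert <- character(0)
  for (i in seq_len(n)) {
    for (at in BACKBONE_ATOMS) {
      p <- chain$coords[[at]][i, ]
      if (anyNA(p)) next
      ele <- c(ele, at); resno <- c(resno, chain$seq_num[i])
      resid <- c(resid, chain$aa[i]); insert <- c(insert, chain$icode[i])
      xyz <- c(xyz, p)
    }
  }
  insert[!nzchar(insert)] <- ""
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = ele, chain = chain$chain_id,
                   o = rep(1, length(ele)), b = rep(0, length(ele)))
  invisible(path)
}
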