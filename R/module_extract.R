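# Topological module extraction: the constituent sub-topologies of a chain,
# listed by growing an SSE window stepwise from the N terminus.

#' Induced sub-topology of a contiguous SSE window
#'
#' The composition is restricted to SSEs a..b and the contacts are exactly
#' the parent contacts with both endpoints inside the window, re-indexed to
#' start at 1.
#'
#' @param t a `Topology`.
#' @param window integer vector `c(a, b)` with 1 <= a < b <= n.
#' @return a `Topology`.
#' @export
induced_subtopology <- function(t, window) {
  stopifnot(inherits(t, "Topology"), length(window) == 2)
  a <- as.integer(window[1]); b <- as.integer(window[2])
  n <- nchar(t$composition)
  if (!(a >= 1 && a < b && b <= n))
    stop("invalid window (", a, ",", b, ") for ", n, " SSEs")
  co <- t$contacts
  keep <- co$i >= a & co$j <= b
  co <- co[keep, , drop = FALSE]
  co$i <- co$i - (a - 1L); co$j <- co$j - (a - 1L)
  topology(substr(t$composition, a, b), co,
           sse_lengths = if (!is.null(t$sse_lengths)) t$sse_lengths[a:b])
}

#' Extract a chain's constituent topological modules
#'
#' For a topology with n SSEs (n > 3 in the default mode), lists the n - 1
#' prefix windows (1,2), (1,3), ..., (1,n) in N-to-C order: each module is
#' the induced sub-topology of the chain's first k SSEs, and the last module
#' is the full topology itself. Topologies with n <= 3 return an empty list
#' unless `allow_small` is set. The exploratory `mode = "all-contiguous"`
#' emits every window (a, b) with b > a instead.
#'
#' @param t a `Topology`.
#' @param mode "prefix" (default) or "all-contiguous".
#' @param allow_small logical; emit prefix modules even for n <= 3.
#' @return list of modules, each a list with `window` (c(a, b)),
#'   `sub_topology` (a `Topology`) and `parent` (parent topology string).
#' @export
extract_modules <- function(t, mode = c("prefix", "all-contiguous"),
                            allow_small = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "Topology"))
  n <- nchar(t$composition)
  parent <- encode_topology(t)
  windows <- if (mode == "prefix") {
    if (n <= 3 && !allow_small) list()
    else lapply(2:n, function(b) c(1L, b))
  } else {
    out <- list()
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      out[[length(out) + 1L]] <- c(a, b)
    out
  }
  lapply(windows, function(w)
    list(window = w, sub_topology = induced_subtopology(t, w),
         parent = parent))
}

#' Match modules against a topology database
#'
#' Looks each module's canonical string up in a `TopologyDB` by exact
#' equality.
#'
#' @param modules list of modules from [extract_modules()].
#' @param db a `TopologyDB`.
#' @return data.frame with one row per module: `window_start`, `window_end`,
#'   `topology` (canonical string), `structure_class`, `matched` (logical),
#'   `protein_count` and `domain_count` (NA when unmatched).
#' @export
match_modules <- function(modules, db) {
  stopifnot(inherits(db, "TopologyDB"))
  if (length(modules) == 0)
    return(data.frame(window_start = integer(0), window_end = integer(0),
                      topology = character(0), structure_class = character(0),
                      matched = logical(0), protein_count = integer(0),
                      domain_count = integer(0), stringsAsFactors = FALSE))
  strs <- vapply(modules, function(m) encode_topology(m$sub_topology), "")
  hit <- match(strs, db$records$topology)
  data.frame(
    window_start = vapply(modules, function(m) m$window[1], integer(1)),
    window_end = vapply(modules, function(m) m$window[2], integer(1)),
    topology = strs,
    structure_class = vapply(strs, structure_class, "", USE.NAMES = FALSE),
    matched = !is.na(hit),
    protein_count = db$records$protein_count[hit],
    domain_count = db$records$domain_count[hit],
    stringsAsFactors = FALSE)
}
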