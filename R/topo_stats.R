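# Topology database: occurrence statistics over a set of chains/domains,
# binomial enrichment against a uniform null, FDR control, and the
# Prevalent / Non-prevalent split.
#
# The enrichment test is a declared modelling choice: each topology's
# protein count is compared with Binomial(N, 1/T) where N is the number of
# chains and T the number of distinct topologies -- the simplest null
# consistent with calling a topology group statistically significant. It is
# isolated in classify_prevalence() so an alternative null is a local swap.

#' Build a topology database from classified entries
#'
#' Groups entries by canonical topology string. Chain entries increment
#' `protein_count`, domain entries `domain_count`.
#'
#' @param entries data.frame with columns `source_id`, `topology` (canonical
#'   strings) and `kind` ("chain" or "domain"); or a list of such triples.
#' @return object of class `TopologyDB`: list with `records` (data.frame:
#'   topology, structure_class, protein_count, domain_count, p_value,
#'   q_value, prevalence, exemplars), `n_proteins`, `n_topologies`,
#'   `provenance`.
#' @export
build_db <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries))
    entries <- do.call(rbind, lapply(entries, function(e)
      data.frame(source_id = e[[1]],
                 topology = if (inherits(e[[2]], "Topology"))
                   encode_topology(e[[2]]) else e[[2]],
                 kind = e[[3]], stringsAsFactors = FALSE)))
  if (is.null(entries) || nrow(entries) == 0)
    stop("cannot build a topology database from zero entries")
  stopifnot(all(c("source_id", "topology", "kind") %in% names(entries)),
            all(entries$kind %in% c("chain", "domain")))
  # canonicalise (and validate) every string
  entries$topology <- vapply(entries$topology,
                             function(s) encode_topology(parse_topology(s)),
                             "", USE.NAMES = FALSE)
  keys <- sort(unique(entries$topology))
  recs <- data.frame(
    topology = keys,
    structure_class = vapply(keys, structure_class, "", USE.NAMES = FALSE),
    protein_count = vapply(keys, function(k)
      sum(entries$topology == k & entries$kind == "chain"), integer(1),
      USE.NAMES = FALSE),
    domain_count = vapply(keys, function(k)
      sum(entries$topology == k & entries$kind == "domain"), integer(1),
      USE.NAMES = FALSE),
    p_value = NA_real_, q_value = NA_real_, prevalence = NA_character_,
    stringsAsFactors = FALSE)
  recs$exemplars <- lapply(keys, function(k)
    unique(entries$source_id[entries$topology == k]))
  structure(list(records = recs,
                 n_proteins = sum(recs$protein_count),
                 n_topologies = nrow(recs),
                 provenance = list(
                   n_entries = nrow(entries),
                   built = format(Sys.time(), "%Y-%m-%d %H:%M:%S", tz = "UTC"))),
            class = "TopologyDB")
}

#' @export
print.TopologyDB <- function(x, ...) {
  cat(sprintf("<TopologyDB: %d topologies, %d chains, %d domains>\n",
              x$n_topologies, x$n_proteins, sum(x$records$domain_count)))
  invisible(x)
}

#' Upper binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(N, p0), evaluated with the stable complement
#' (`pbinom(k - 1, N, p0, lower.tail = FALSE)`).
#'
#' @param k observed count (0 <= k <= N).
#' @param N number of trials.
#' @param p0 null success probability in (0, 1).
#' @return tail probability in [0, 1].
#' @export
binom_tail <- function(k, N, p0) {
  stopifnot(all(k >= 0), all(k <= N), all(p0 > 0), all(p0 < 1))
  stats::pbinom(k - 1, N, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) * m / j, capped
#' at 1, returned in the input order (delegates to
#' `p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Classify topologies as Prevalent or Non-prevalent
#'
#' For each record, the p-value is the upper binomial tail of its protein
#' count against the uniform null p0 = 1 / n_topologies; q-values are BH
#' adjusted across all records. A topology is Prevalent (P) when p < alpha,
#' q < fdr_max and its count exceeds the uniform expectation
#' n_proteins / n_topologies; otherwise Non-prevalent (NP). The expectation
#' guard keeps depleted-but-significant topologies out of P.
#'
#' @param db a `TopologyDB`.
#' @param alpha significance threshold on the p-value.
#' @param fdr_max threshold on the BH q-value (FDR below 0.1\% by default).
#' @return the database with `p_value`, `q_value` and `prevalence` filled.
#' @export
classify_prevalence <- function(db, alpha = 0.001, fdr_max = 0.001) {
  stopifnot(inherits(db, "TopologyDB"))
  r <- db$records
  if (nrow(r) < 2) {
    warning("single-topology database: everything classified Prevalent")
    r$p_value <- binom_tail(r$protein_count, db$n_proteins, 0.5)
    r$q_value <- r$p_value
    r$prevalence <- "P"
    db$records <- r
    return(db)
  }
  p0 <- 1 / db$n_topologies
  r$p_value <- binom_tail(r$protein_count, db$n_proteins, p0)
  r$q_value <- bh_adjust(r$p_value)
  expected <- db$n_proteins / db$n_topologies
  r$prevalence <- ifelse(r$p_value < alpha & r$q_value < fdr_max &
                           r$protein_count > expected, "P", "NP")
  db$records <- r
  db
}

#' Coverage of the Prevalent class
#'
#' @param db a classified `TopologyDB`.
#' @return list with `topology_fraction_P` (share of distinct topologies
#'   that are Prevalent) and `protein_fraction_P` (share of proteins they
#'   cover).
#' @export
coverage_summary <- function(db) {
  stopifnot(inherits(db, "TopologyDB"))
  if (anyNA(db$records$prevalence))
    stop("database not classified; run classify_prevalence() first")
  p <- db$records$prevalence == "P"
  list(topology_fraction_P = sum(p) / db$n_topologies,
       protein_fraction_P = sum(db$records$protein_count[p]) / db$n_proteins)
}

#' Search a topology database by secondary-structure composition
#'
#' @param db a `TopologyDB`.
#' @param n_helix exact number of helices (H), or NULL for any.
#' @param n_strand exact number of strands (E), or NULL for any.
#' @param class_filter "A", "B", "AB" or "any".
#' @param max_q keep records with q_value <= max_q (requires a classified
#'   database); NULL for no significance filter.
#' @return the matching rows of `db$records`, sorted by descending
#'   `protein_count`, ties broken by topology string.
#' @export
search_composition <- function(db, n_helix = NULL, n_strand = NULL,
                               class_filter = c("any", "A", "B", "AB"),
                               max_q = NULL) {
  stopifnot(inherits(db, "TopologyDB"))
  class_filter <- match.arg(class_filter)
  r <- db$records
  comp <- sub("\\|.*$", "", r$topology)
  keep <- rep(TRUE, nrow(r))
  if (!is.null(n_helix))
    keep <- keep & nchar(gsub("[^H]", "", comp)) == n_helix
  if (!is.null(n_strand))
    keep <- keep & nchar(gsub("[^E]", "", comp)) == n_strand
  if (class_filter != "any") keep <- keep & r$structure_class == class_filter
  if (!is.null(max_q)) {
    if (anyNA(r$q_value))
      stop("significance filter requires a classified database")
    keep <- keep & r$q_value <= max_q
  }
  r <- r[keep, , drop = FALSE]
  r <- r[order(-r$protein_count, r$topology), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Write a topology database to a JSON file
#'
#' @param db a `TopologyDB`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_db <- function(db, path) {
  stopifnot(inherits(db, "TopologyDB"))
  out <- list(n_proteins = db$n_proteins, n_topologies = db$n_topologies,
              provenance = db$provenance, records = db$records)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a topology database from a JSON file written by [write_db()]
#'
#' @param path JSON file path.
#' @return a `TopologyDB`.
#' @export
read_db <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- as.data.frame(raw$records, stringsAsFactors = FALSE)
  if (is.null(recs$exemplars)) recs$exemplars <- vector("list", nrow(recs))
  recs$protein_count <- as.integer(recs$protein_count)
  recs$domain_count <- as.integer(recs$domain_count)
  for (col in c("p_value", "q_value"))
    recs[[col]] <- as.numeric(recs[[col]])
  if (is.null(recs$prevalence)) recs$prevalence <- NA_character_
  structure(list(records = recs,
                 n_proteins = as.integer(raw$n_proteins),
                 n_topologies = as.integer(raw$n_topologies),
                 provenance = raw$provenance),
            class = "TopologyDB")
}

#' Per-class database summary
#'
#' Counts of topologies, proteins and domains per structure class (A, B,
#' AB) plus a Total row -- the layout used for reporting a topology
#' database's composition.
#'
#' @param db a `TopologyDB`.
#' @return data.frame with columns `structure_class`, `topologies`,
#'   `proteins`, `domains`.
#' @export
db_class_summary <- function(db) {
  stopifnot(inherits(db, "TopologyDB"))
  r <- db$records
  rows <- lapply(c("A", "B", "AB"), function(cl) {
    sel <- r$structure_class == cl
    data.frame(structure_class = cl, topologies = sum(sel),
               proteins = sum(r$protein_count[sel]),
               domains = sum(r$domain_count[sel]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(structure_class = "Total", topologies = nrow(r),
                        proteins = sum(r$protein_count),
                        domains = sum(r$domain_count),
                        stringsAsFactors = FALSE))
}
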