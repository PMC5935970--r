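# Shared test scaffolding: built fixtures (cached per test run) and random
# generators for property-style tests.

built_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(fixture_bank(), build_fixture)
    cache
  }
})

# Random valid topology: composition over H/E, sorted unique contact pairs,
# random orientations.
random_topology <- function(n = sample(2:12, 1), p_contact = 0.35) {
  comp <- paste(sample(c("H", "E"), n, replace = TRUE), collapse = "")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_contact
  co <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                   orientation = sample(c("P", "A"), sum(keep),
                                        replace = TRUE),
                   stringsAsFactors = FALSE)
  co <- co[order(co$i, co$j), , drop = FALSE]
  topology(comp, co)
}

# Minimal chain with CA-only coordinates (CB absent -> CA substitution rule).
ca_chain <- function(xyz, aa = NULL) {
  n <- nrow(xyz)
  structure_chain("A", seq_len(n), rep("", n),
                  if (is.null(aa)) rep("GLY", n) else aa,
                  list(CA = xyz))
}
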