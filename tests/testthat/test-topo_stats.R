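# Brute-force reference implementations used as oracles.
binom_tail_oracle <- function(k, N, p0) {
  if (k == 0) return(1)
  x <- k:N
  sum(choose(N, x) * p0^x * (1 - p0)^(N - x))
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

toy_db <- function(counts = c(70, 10, 8, 7, 5)) {
  comps <- c("HHH|1-2A,2-3A", "EE|1-2A", "EEH|1-2A", "HH|1-2P",
             "EEEE|1-2A,2-3A,3-4A")[seq_along(counts)]
  build_db(data.frame(
    source_id = paste0("s", seq_len(sum(counts))),
    topology = rep(comps, counts),
    kind = "chain", stringsAsFactors = FALSE))
}

test_that("database building groups and counts by canonical string", {
  db <- build_db(data.frame(source_id = c("a", "b", "c", "d"),
                            topology = c("EE|1-2A", "EE|1-2A", "HH|",
                                         "EE|1-2A"),
                            kind = "chain", stringsAsFactors = FALSE))
  expect_equal(db$n_proteins, 4)
  expect_equal(db$n_topologies, 2)
  r <- db$records[db$records$topology == "EE|1-2A", ]
  expect_equal(r$protein_count, 3)
  expect_equal(sort(r$exemplars[[1]]), c("a", "b", "d"))

  one <- build_db(data.frame(source_id = "x", topology = "HH|1-2P",
                             kind = "chain", stringsAsFactors = FALSE))
  expect_equal(one$n_proteins, 1)
  expect_equal(one$records$protein_count, 1)

  mix <- build_db(data.frame(source_id = c("c1", "d1"),
                             topology = "EE|1-2A",
                             kind = c("chain", "domain"),
                             stringsAsFactors = FALSE))
  expect_equal(mix$records$protein_count, 1)
  expect_equal(mix$records$domain_count, 1)
  expect_error(build_db(list()), "zero entries")
})

test_that("binomial tails match exact summation", {
  expect_equal(binom_tail(0, 10, 0.3), 1.0)
  expect_equal(binom_tail(3, 3, 0.5), 0.125, tolerance = 1e-12)
  expect_equal(binom_tail(3, 10, 0.1), 0.0701908, tolerance = 1e-6)
  for (N in c(5, 17, 50)) for (p0 in c(0.01, 0.2, 0.5, 0.9))
    for (k in unique(c(0, 1, N %/% 2, N))) {
      expect_equal(binom_tail(k, N, p0), binom_tail_oracle(k, N, p0),
                   tolerance = 1e-12)
      # complement identity
      expect_equal(binom_tail(k, N, p0) + pbinom(k - 1, N, p0), 1,
                   tolerance = 1e-12)
    }
})

test_that("p-values decrease as counts grow (monotonicity)", {
  p <- binom_tail(0:50, 50, 0.2)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(5)
  for (k in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "p_values")
})

test_that("prevalence classification separates enriched topologies", {
  db <- classify_prevalence(toy_db())
  r <- db$records
  expect_equal(sum(r$prevalence == "P"), 1)
  expect_equal(r$topology[r$prevalence == "P"], "HHH|1-2A,2-3A")
  expect_lt(r$p_value[r$prevalence == "P"], 1e-10)
  # the count-5 topology sits below the expectation of 20 -> NP
  expect_equal(r$prevalence[r$protein_count == 5], "NP")
  cov <- coverage_summary(db)
  expect_equal(cov$topology_fraction_P, 0.2)
  expect_equal(cov$protein_fraction_P, 0.70)

  uniform <- classify_prevalence(toy_db(rep(10, 5)))
  expect_true(all(uniform$records$prevalence == "NP"))
  expect_equal(coverage_summary(uniform)$protein_fraction_P, 0)
})

test_that("classification is invariant to record order", {
  db <- toy_db()
  shuffled <- db
  set.seed(9)
  perm <- sample(nrow(db$records))
  shuffled$records <- db$records[perm, ]
  a <- classify_prevalence(db)$records
  b <- classify_prevalence(shuffled)$records
  b <- b[match(a$topology, b$topology), ]
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$prevalence, b$prevalence)
})

test_that("protein counts are conserved across build and classification", {
  db <- classify_prevalence(toy_db())
  expect_equal(sum(db$records$protein_count), db$n_proteins)
  expect_equal(db$n_topologies, nrow(db$records))
})

test_that("composition search filters and sorts records", {
  db <- classify_prevalence(toy_db())
  hits <- search_composition(db, n_helix = 3, n_strand = 0)
  expect_equal(hits$topology, "HHH|1-2A,2-3A")
  expect_equal(nrow(search_composition(db, class_filter = "B",
                                       n_helix = 2)), 0)
  all_hits <- search_composition(db)
  expect_equal(nrow(all_hits), 5)
  expect_true(all(diff(all_hits$protein_count) <= 0))
  sig <- search_composition(db, max_q = 1e-5)
  expect_true(all(sig$q_value <= 1e-5))
})

test_that("databases survive a JSON round trip", {
  db <- classify_prevalence(toy_db())
  path <- withr::local_tempfile(fileext = ".json")
  write_db(db, path)
  back <- read_db(path)
  expect_equal(back$n_proteins, db$n_proteins)
  expect_equal(back$records$topology, db$records$topology)
  expect_equal(back$records$p_value, db$records$p_value, tolerance = 1e-12)
  expect_equal(back$records$prevalence, db$records$prevalence)
  sm <- db_class_summary(back)
  expect_equal(sm$proteins[sm$structure_class == "Total"], 100)
  expect_equal(sum(sm$topologies[sm$structure_class != "Total"]),
               sm$topologies[sm$structure_class == "Total"])
})
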