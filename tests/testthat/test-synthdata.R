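# Cohort simulator: determinism, mutational process, cohort composition.

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_tips = 4L, true_tmrca_years = 20000, seed = 123L)
  s1 <- simulate_cohort(cfg, founder = "M42c")
  s2 <- simulate_cohort(cfg, founder = "M42c")
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth$branch_mutations, s2$truth$branch_mutations)
  s3 <- simulate_cohort(sim_config(n_tips = 4L, true_tmrca_years = 20000,
                                   seed = 124L), founder = "M42c")
  expect_false(identical(as.character(s1$sequences),
                         as.character(s3$sequences)))
})

test_that("zero elapsed time reproduces the founder haplotype", {
  cfg <- sim_config(n_tips = 1L, true_tmrca_years = 0, seed = 1L)
  sim <- simulate_cohort(cfg, founder = "M42c")
  founder_seq <- apply_variants(cumulative_expected(australia_tree(), "M42c"))
  expect_identical(as.character(sim$sequences[[1L]]), founder_seq)
  expect_equal(sum(sim$truth$genealogy$edge_length), 0)
})

test_that("founder motifs appear in every emitted sequence", {
  tr <- australia_tree()
  cfg <- sim_config(n_tips = 6L, true_tmrca_years = 30000, seed = 21L,
                    allow_homoplasy = FALSE)
  sim <- simulate_cohort(cfg, founder = "M42c")
  motif <- cumulative_expected(tr, "M42c")
  for (i in seq_len(6L)) {
    chars <- strsplit(as.character(sim$sequences[[i]]), "")[[1L]]
    expect_equal(chars[motif$position], motif$alt)
  }
  expect_error(simulate_cohort(cfg, founder = "NOPE"), "unknown founder")
})

test_that("per-lineage mutation counts match the Poisson expectation", {
  # E[mutations] = T / years-per-substitution; star, single tip, many reps
  T <- 36240; lambda <- T / 3624       # = 10
  set.seed(99)
  counts <- vapply(1:200, function(i) {
    cfg <- sim_config(topology = "star", n_tips = 1L, true_tmrca_years = T,
                      seed = NULL)
    sim <- simulate_cohort(cfg, founder = "S", emit_sequences = FALSE)
    sum(sim$truth$genealogy$edge_length)
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("yule genealogies respect the configured age", {
  cfg <- sim_config(topology = "yule", n_tips = 8L, true_tmrca_years = 40000,
                    seed = 8L)
  gen <- mitorho:::.simulate_genealogy(cfg)
  # every tip's root-to-tip duration equals the TMRCA (ultrametric)
  parent <- integer(max(gen$edge)); yrs <- numeric(max(gen$edge))
  parent[gen$edge[, 2]] <- gen$edge[, 1]
  yrs[gen$edge[, 2]] <- gen$years
  for (tip in 1:8) {
    d <- 0; cur <- tip
    while (cur != 9L) { d <- d + yrs[cur]; cur <- parent[cur] }
    expect_equal(d, 40000)
  }
})

test_that("repeat hits toggle a site back to the founder state", {
  ref <- mt_reference()
  # force every mutation onto one site: the second hit must revert it
  mut <- rep(0, ref$length); mut[5555] <- 1
  founder_seq <- apply_variants(cumulative_expected(australia_tree(), "S"))
  founder_base <- substr(founder_seq, 5555, 5555)
  for (seed in 40:49) {
    cfg <- sim_config(topology = "star", n_tips = 1L,
                      true_tmrca_years = 3624 * 4, mutability = mut,
                      seed = seed)
    sim <- simulate_cohort(cfg, founder = "S")
    toks <- sim$truth$branch_mutations[[1L]]
    expect_true(all(grepl("5555", toks)))
    got <- substr(as.character(sim$sequences[[1L]]), 5555, 5555)
    if (length(toks) %% 2 == 0) {
      expect_identical(got, founder_base)   # even hits toggle back
    } else {
      expect_false(identical(got, founder_base))
    }
  }
})

test_that("the default study cohort matches the sampled composition", {
  cohort <- default_study_cohort(seed = 7L)
  expect_equal(length(cohort$sequences), 127L)
  expect_equal(nrow(cohort$sample_sheet), 127L)
  counts <- table(cohort$sample_sheet$state)
  expect_equal(unname(counts["Queensland"]), 103L)
  expect_equal(unname(counts["New South Wales"]), 14L)
  expect_equal(unname(counts["Victoria"]), 6L)
  expect_equal(unname(counts["Tasmania"]), 2L)
  expect_equal(unname(counts["Western Australia"]), 2L)
  expect_true(all(cohort$sample_sheet$true_haplogroup %in% default_founders()))
  # determinism: byte-identical FASTA
  d1 <- tempfile(); d2 <- tempfile()
  default_study_cohort(seed = 7L, dir = d1)
  default_study_cohort(seed = 7L, dir = d2)
  expect_identical(readLines(file.path(d1, "cohort.fasta")),
                   readLines(file.path(d2, "cohort.fasta")))
  expect_true(file.exists(file.path(d1, "truth.json")))
})
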