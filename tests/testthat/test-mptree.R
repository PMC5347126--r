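# Maximum-parsimony haplotype trees within a clade.

test_that("a single sample with two privates is a single edge of length 2", {
  inst <- random_mp_instance(1L, 2L)
  st <- build_mp_tree(inst$profiles, inst$root)
  expect_equal(st$n_tips, 1L)
  expect_equal(parsimony_score(st), 2)
  expect_equal(sum(st$edge_length > 0), 1L)
})

test_that("nested carrier sets give the unique perfect phylogeny", {
  ref <- mt_reference()
  # tips: {a}, {a,b}, {a,c}, {}
  a <- paste0(ref$chars[5801], 5801, c(A="G",G="A",C="T",T="C")[ref$chars[5801]])
  b <- paste0(ref$chars[5802], 5802, c(A="G",G="A",C="T",T="C")[ref$chars[5802]])
  c <- paste0(ref$chars[5803], 5803, c(A="G",G="A",C="T",T="C")[ref$chars[5803]])
  profs <- list(mk_profile(a, "t1"), mk_profile(c(a, b), "t2"),
                mk_profile(c(a, c), "t3"), mk_profile(character(0), "t4"))
  st <- build_mp_tree(profs, mk_profile(character(0), "root"))
  expect_equal(parsimony_score(st), 3)
  # matches the exhaustive minimum
  carriers <- list(c(1L, 2L, 3L), 2L, 3L)
  expect_equal(parsimony_score(st), mp_oracle_score(carriers, 4L))
  # perfect phylogeny: score equals the number of distinct variants
  expect_equal(parsimony_score(st), 3)
  # the shared variant labels the internal edge above t1, t2, t3
  shared <- which(vapply(st$edge_tokens, function(tk) a %in% tk, logical(1)))
  expect_length(shared, 1L)
})

test_that("incompatible characters are resolved at the exhaustive minimum", {
  # {a,b}, {a,c}, {b,c}: a classic pairwise-incompatible trio
  inst <- local({
    set.seed(99)
    random_mp_instance(3L, 3L)
  })
  profs <- list(mk_profile(inst$tokens[c(1, 2)], "t1"),
                mk_profile(inst$tokens[c(1, 3)], "t2"),
                mk_profile(inst$tokens[c(2, 3)], "t3"))
  st <- build_mp_tree(profs, mk_profile(character(0), "root"))
  carriers <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  expect_equal(parsimony_score(st), mp_oracle_score(carriers, 3L))
})

test_that("parsimony score equals the oracle on random instances", {
  set.seed(2024)
  for (i in 1:20) {
    n <- sample(3:5, 1L); s <- sample(3:8, 1L)
    inst <- random_mp_instance(n, s)
    st <- build_mp_tree(inst$profiles, inst$root)
    expect_equal(parsimony_score(st), mp_oracle_score(inst$carriers, n),
                 label = paste("instance", i))
  }
})

test_that("weighted resolution duplicates the most mutable site", {
  set.seed(7)
  inst <- random_mp_instance(4L, 4L)
  pos <- as.integer(sub("^[ACGT]([0-9]+).*$", "\\1", inst$tokens))
  w <- site_weights(stats::setNames(c(0.1, rep(1, 3)), pos))
  st <- build_mp_tree(inst$profiles, inst$root, w = w)
  # weighted total changes match the exhaustive weighted minimum
  total_w <- sum(vapply(seq_len(nrow(st$edge)), function(e) {
    tks <- st$edge_tokens[[e]]
    if (length(tks) == 0) return(0)
    p <- as.integer(sub("^[ACGT]?([0-9]+).*$", "\\1", tks))
    sum(site_weight(w, p))
  }, numeric(1)))
  expect_equal(total_w, mp_oracle_score(inst$carriers, 4L,
                                        weights = site_weight(w, pos)))
})

test_that("tip path lengths match profile distances (exactly when compatible)", {
  pairwise_ok <- function(carriers) {
    nc <- length(carriers)
    if (nc < 2) return(TRUE)
    for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      ab <- length(intersect(carriers[[i]], carriers[[j]]))
      if (ab > 0 && ab < length(carriers[[i]]) && ab < length(carriers[[j]]))
        return(FALSE)
    }
    TRUE
  }
  set.seed(5)
  for (i in 1:8) {
    n <- sample(2:6, 1L)
    inst <- random_mp_instance(n, sample(3:10, 1L))
    compatible <- pairwise_ok(inst$carriers)
    st <- build_mp_tree(inst$profiles, inst$root)
    # recompute each tip's depth by walking the edge list
    parent <- integer(max(c(st$edge, st$root)))
    elen <- numeric(max(c(st$edge, st$root)))
    parent[st$edge[, 2]] <- st$edge[, 1]
    elen[st$edge[, 2]] <- st$edge_length
    for (tip in seq_len(n)) {
      d <- 0; cur <- tip
      while (cur != st$root) { d <- d + elen[cur]; cur <- parent[cur] }
      hamming <- nrow(inst$profiles[[tip]]$variants)
      if (compatible) expect_equal(d, hamming, label = paste("tip", tip))
      else expect_gte(d, hamming)
    }
  }
})

test_that("profiles conflicting with root back-mutations are rejected", {
  tr <- load_haplotree(write_tree_file(c(
    "ROOT\t-", "A\tROOT\tA9156G C64T", "B\tA\tA9156G!")))
  root_v <- tr$nodes$B$variants            # carries the A9156G! reversion
  rootp <- mt_profile("B", rbind(cumulative_expected(tr, "B"), root_v))
  expect_error(build_mp_tree(list(mk_profile(c("A9156G"), "t1")), rootp),
               "consistency")
  expect_error(build_mp_tree(list(), mk_profile(character(0))), "at least one")
})

test_that("a shared mutation joins lineages rather than geography", {
  # P11-like mainland and Tasmanian profiles share C11288T; the P4-like
  # profile does not carry it: the MP tree must join the two P11 lineages
  # through the shared mutation.
  tr <- australia_tree()
  root_profile <- mt_profile("P", cumulative_expected(tr, "P"))
  base <- cumulative_expected(tr, "P")$token
  mainland <- mk_profile(c(base, "C11288T", "A14927G"), "P11a_mainland")
  tasmanian <- mk_profile(c(base, "C11288T", "G15930A"), "P11b_tasmania")
  newguinea <- mk_profile(c(base, "T10586C"), "P4_newguinea")
  st <- build_mp_tree(list(mainland, tasmanian, newguinea), root_profile)
  e <- which(vapply(st$edge_tokens, function(tk) "C11288T" %in% tk, logical(1)))
  expect_length(e, 1L)
  joined <- st$edge[e, 2L]
  # the node below the C11288T edge is internal and ancestral to exactly the
  # two P11 lineages
  expect_gt(joined, st$n_tips)
  below <- st$edge[st$edge[, 1L] == joined, 2L]
  expect_setequal(st$tip_label[below], c("P11a_mainland", "P11b_tasmania"))
})

test_that("newick and TSV exports reflect the edge structure", {
  inst <- local({ set.seed(3); random_mp_instance(3L, 4L) })
  st <- build_mp_tree(inst$profiles, inst$root)
  nwk <- sample_tree_newick(st)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, st$tip_label)
  expect_equal(sum(ph$edge.length), parsimony_score(st))
  path <- tempfile(fileext = ".tsv")
  write_sample_tree_tsv(st, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), nrow(st$edge))
  expect_equal(sum(tab$length), parsimony_score(st))
})
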