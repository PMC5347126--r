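# Haplogroup tree loading, cumulative motifs, Newick export.

test_that("a minimal two-line definition loads", {
  ref <- mt_reference()
  tr <- load_haplotree(write_tree_file(c("ROOT\t-", "H1\tROOT\tA9156G")))
  expect_length(tr$nodes, 2L)
  expect_equal(tr$root, "ROOT")
  expect_equal(tr$nodes$H1$variants$token, "A9156G")
})

test_that("invalid definitions fail with line context", {
  expect_error(load_haplotree(write_tree_file(c("ROOT\t-", "H1\tNOPE\tA9156G"))),
               "unknown parent")
  expect_error(load_haplotree(write_tree_file(c(
    "ROOT\t-", "H1\tROOT\tA9156G", "H1\tROOT\tC64T"))), "duplicate")
  expect_error(load_haplotree(write_tree_file(c(
    "ROOT\t-", "H1\tROOT\tnotatoken"))), "line 2")
  expect_error(load_haplotree(write_tree_file(c("H1\tROOT\tA9156G"))), "root")
  # cyclic parents
  expect_error(load_haplotree(write_tree_file(c(
    "ROOT\t-", "A\tB\tC64T", "B\tA\tT195C"))), "cyclic|connected")
})

test_that("the packaged tree carries the main-text clade anchors", {
  tr <- australia_tree()
  expect_equal(tr$nodes$M42c$parent, "M42")
  expect_setequal(tr$nodes$M42c$variants$token, c("C64T", "T195C"))
  expect_true("A9156G" %in% tr$nodes$M42$variants$token)
  expect_true("G12771A" %in% tr$nodes$M42a$variants$token)
  expect_true("C11288T" %in% tr$nodes$P11$variants$token)
  # S is one mutation step from N
  expect_equal(tr$nodes$S$parent, "N")
  expect_equal(nrow(tr$nodes$S$variants), 1L)
  # every tree token is consistent with the packaged reference frame
  ref <- mt_reference()
  for (nm in names(tr$nodes)) {
    v <- tr$nodes[[nm]]$variants
    if (nrow(v) > 0)
      expect_equal(ref$chars[v$position], v$ref, label = nm)
  }
})

test_that("cumulative motifs accumulate along the root path", {
  tr <- australia_tree()
  expect_equal(nrow(cumulative_expected(tr, tr$root)), 0L)
  m42c <- cumulative_expected(tr, "M42c")$token
  expect_true(all(c("A9156G", "C64T", "T195C") %in% m42c))
  expect_false("G8251A" %in% m42c)
  expect_true("G8251A" %in% cumulative_expected(tr, "M42a")$token)
  expect_error(cumulative_expected(tr, "NOPE"), "unknown")
})

test_that("cumulative motif equals an independent naive path walk", {
  tr <- australia_tree()
  naive <- function(label) {
    toks <- character(0)
    for (nm in haplo_path(tr, label)) {
      v <- tr$nodes[[nm]]$variants
      for (i in seq_len(nrow(v))) {
        if (v$back[i]) toks <- setdiff(toks, sub("!$", "", v$token[i]))
        else toks <- union(toks, v$token[i])
      }
    }
    toks
  }
  for (nm in names(tr$nodes))
    expect_setequal(cumulative_expected(tr, nm)$token, naive(nm))
})

test_that("a back-mutation cancels its forward variant", {
  tr <- load_haplotree(write_tree_file(c(
    "ROOT\t-",
    "A\tROOT\tA9156G C64T",
    "B\tA\tA9156G!"
  )))
  expect_setequal(cumulative_expected(tr, "B")$token, "C64T")
  # monotone except at the explicit back-mutation
  expect_true(all(cumulative_expected(tr, "A")$token %in%
                  c(cumulative_expected(tr, "B")$token, "A9156G")))
  # a back-mutation without a forward occurrence is rejected at load
  expect_error(load_haplotree(write_tree_file(c(
    "ROOT\t-", "A\tROOT\tC64T", "B\tA\tA9156G!"))), "no forward")
})

test_that("Newick export has mutation-count branch lengths and round-trips", {
  tr <- australia_tree()
  nwk <- to_newick(tr)
  expect_match(nwk, "S:1[,)]")       # N -> S edge has length 1
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph) + ph$Nnode, length(tr$nodes))
  # topology preserved: parent of every node matches the definition
  labels <- c(ph$tip.label, ph$node.label)
  for (e in seq_len(nrow(ph$edge))) {
    child <- labels[ph$edge[e, 2L]]
    parent <- labels[ph$edge[e, 1L]]
    expect_equal(tr$nodes[[child]]$parent, parent)
    expect_equal(ph$edge.length[e], nrow(tr$nodes[[child]]$variants))
  }
  # leaves preserved
  kids <- unique(vapply(tr$nodes, function(n)
    ifelse(is.na(n$parent), "", n$parent), character(1)))
  leaves <- setdiff(names(tr$nodes), kids)
  expect_setequal(ph$tip.label, leaves)
})

test_that("motif JSON dump covers every node", {
  tr <- australia_tree()
  js <- jsonlite::fromJSON(motifs_json(tr))
  expect_setequal(names(js), names(tr$nodes))
  expect_setequal(js$M42c, cumulative_expected(tr, "M42c")$token)
})
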