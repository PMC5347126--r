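# Reference model, nomenclature parsing/formatting, variant calling.

test_that("packaged reference has the rCRS frame and anchored alleles", {
  ref <- mt_reference()
  expect_s3_class(ref, "mt_reference")
  expect_equal(ref$length, 16569L)
  expect_true(ref$circular)
  expect_equal(nchar(ref$sequence), 16569L)
  # main-text diagnostic alleles on the coordinate frame
  expect_equal(ref$chars[c(64, 195, 8251, 9156, 11288, 12771)],
               c("C", "T", "G", "A", "C", "G"))
  expect_true(all(ref$chars[c(303:309, 311:315)] == "C"))
})

test_that("nomenclature tokens parse into fully populated variants", {
  v <- parse_variant("A9156G")
  expect_equal(v$kind, "sub")
  expect_equal(v$position, 9156L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "G")
  expect_false(v$back)

  v <- parse_variant("C64T")
  expect_equal(unlist(v[, c("ref", "alt")], use.names = FALSE), c("C", "T"))
  expect_equal(v$position, 64L)

  v <- parse_variant("315.1C")
  expect_equal(v$kind, "ins")
  expect_equal(v$position, 315L)
  expect_equal(v$ins_index, 1L)
  expect_equal(v$alt, "C")

  v <- parse_variant("G8251A!")
  expect_true(v$back)
  expect_equal(v$token, "G8251A!")

  v <- parse_variant("249d")
  expect_equal(v$kind, "del")
  expect_equal(v$alt, "")

  # PosAlt dialect resolves the reference allele
  expect_equal(parse_variant("9156G")$token, "A9156G")
})

test_that("malformed or out-of-range tokens are rejected by name", {
  expect_error(parse_variant("xyz"), "xyz")
  expect_error(parse_variant("A9156A"), "ref equals alt")
  expect_error(parse_variant("A99999G"), "range")
  expect_error(parse_variant("315.0C"), "315.0C")
  expect_error(parse_variant(""), "empty")
  # wrong reference allele is caught against the frame
  expect_error(parse_variant("G9156A"), "reference allele")
})

test_that("format/parse round-trips canonical tokens", {
  toks <- c("A9156G", "C64T", "315.1C", "249d", "G8251A!", "T195C")
  v <- parse_variants(toks)
  expect_equal(format_variant(v), toks)
  expect_equal(parse_variants(format_variant(v))$token, v$token)
})

test_that("identity calling of the reference yields an empty profile", {
  ref <- mt_reference()
  p <- call_variants(ref$sequence)
  expect_equal(nrow(p$variants), 0L)
  expect_equal(sort(p$excluded_sites), sort(unique(default_mask())))
})

test_that("a single known substitution is called exactly", {
  ref <- mt_reference()
  seq <- apply_variants(parse_variants("A9156G"), ref)
  p <- call_variants(seq, sample_id = "one")
  expect_equal(p$variants$token, "A9156G")
})

test_that("injected random substitutions are recovered exactly", {
  ref <- mt_reference()
  set.seed(404)
  for (rep in 1:5) {
    pos <- sample(setdiff(500:16000, default_mask()), 10L)
    trs <- c(A = "G", G = "A", C = "T", T = "C")
    toks <- paste0(ref$chars[pos], pos, trs[ref$chars[pos]])
    seq <- apply_variants(parse_variants(toks), ref)
    p <- call_variants(seq)
    expect_setequal(p$variants$token, toks)
  }
})

test_that("N bases and masked positions yield no calls", {
  ref <- mt_reference()
  chars <- ref$chars
  chars[5000] <- "N"
  chars[16519] <- if (ref$chars[16519] == "A") "G" else "A"  # masked site
  p <- call_variants(paste0(chars, collapse = ""))
  expect_equal(nrow(p$variants), 0L)
  expect_true(16519L %in% p$excluded_sites)
})

test_that("indels are called and canonicalised at the 3'-most position", {
  ref <- mt_reference()
  # deletion via the alignment path
  del <- parse_variants("1500d")
  seq <- apply_variants(del, ref)
  p <- call_variants(seq)
  expect_equal(p$variants$kind, "del")
  # insertion round-trips through alignment
  ins <- parse_variants("1000.1A")
  seq <- apply_variants(ins, ref)
  p <- call_variants(seq)
  expect_equal(p$variants$kind, "ins")
  expect_equal(p$variants$alt, "A")
  # two alignments of the same homopolymer deletion give identical profiles
  run <- which(ref$chars[-c(1, ref$length)] == ref$chars[-c(1:2)] &
               ref$chars[-c(1, ref$length)] == ref$chars[-((ref$length - 1):ref$length)])
  run <- setdiff(run + 1L, c(default_mask(), default_mask() + 1L,
                             default_mask() - 1L))
  stopifnot(length(run) > 0)
  mid <- run[run > 2000][1L]           # centre of a >=3 homopolymer
  s1 <- paste0(ref$chars[-(mid - 1L)], collapse = "")
  s2 <- paste0(ref$chars[-(mid + 1L)], collapse = "")
  p1 <- call_variants(s1); p2 <- call_variants(s2)
  expect_equal(p1$variants$token, p2$variants$token)
  expect_equal(p1$variants$kind, "del")
})

test_that("length and alphabet violations raise clear errors", {
  ref <- mt_reference()
  expect_error(call_variants(substr(ref$sequence, 1, 16000)),
               "length .* tolerance")
  expect_error(call_variants(sub("A", "X", ref$sequence)), "alphabet")
})

test_that("apply/call round-trip holds for generated substitution profiles", {
  ref <- mt_reference()
  set.seed(11)
  trs <- c(A = "G", G = "A", C = "T", T = "C")
  for (rep in 1:10) {
    pos <- sample(setdiff(200:16100, default_mask()), sample(1:20, 1))
    toks <- paste0(ref$chars[pos], pos, trs[ref$chars[pos]])
    p <- call_variants(apply_variants(parse_variants(toks), ref))
    expect_setequal(p$variants$token, toks)
    expect_true(all(p$variants$position >= 1 & p$variants$position <= 16569))
  }
})

test_that("profiles export to TSV and VCF", {
  ref <- mt_reference()
  p1 <- call_variants(apply_variants(parse_variants("A9156G"), ref),
                      sample_id = "s1")
  p2 <- call_variants(apply_variants(parse_variants(c("C64T", "T195C")), ref),
                      sample_id = "s2")
  tsv <- tempfile(fileext = ".tsv")
  write_profiles_tsv(list(p1, p2), tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$sample_id, c("s1", "s2"))
  expect_equal(tab$variants[1], "A9156G")
  vcf <- tempfile(fileext = ".vcf")
  write_profiles_vcf(list(p1, p2), vcf)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##contig=<ID=chrM,length=16569>", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), 3L)
})
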