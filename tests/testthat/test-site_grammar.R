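test_that("miRNA construction validates its guide", {
  g <- let7a()
  expect_s3_class(g, "MiRNA")
  expect_equal(g$guide, "UGAGGUAGUAGGUUGUAUAGUU")
  expect_equal(mirna("x", "tgaggtagtaggttgtatagtt")$guide, g$guide)
  expect_error(mirna("x", "ACGU"), "18-26")
  expect_error(mirna("x", strrep("A", 30)), "18-26")
  expect_error(mirna("x", "UGAGGUAGUAGGUUGUAUAGNN"), "A/C/G/U")
})

test_that("pairing specifications are validated", {
  expect_error(pairing_spec(3, 8, t1 = "A"), "t1")
  expect_error(pairing_spec(2, 8, bulge = list(after = 5, nt = "G"),
                            deletion = 4L), "at most one")
  expect_error(pairing_spec(2, 6, wobbles = 8L), "outside")
  expect_error(pairing_spec(5, 3))
})

test_that("site motifs are the reverse complement of the guide span", {
  g <- let7a()
  expect_equal(site_motif(pairing_spec(2, 8, t1 = "A"), g), "CUACCUCA")
  expect_equal(site_motif(pairing_spec(2, 8), g), "CUACCUC")
  expect_equal(site_motif(pairing_spec(2, 7, t1 = "A"), g), "UACCUCA")
  expect_equal(site_motif(pairing_spec(2, 7), g), "UACCUC")
  expect_equal(site_motif(pairing_spec(2, 6, t1 = "A"), g), "ACCUCA")
  expect_equal(site_motif(pairing_spec(11, 21), g), "ACUAUACAACC")
  # wobble at g6 (guide U pairs target G)
  expect_equal(site_motif(pairing_spec(2, 8, t1 = "A", wobbles = 6L), g),
               "CUGCCUCA")
  expect_error(site_motif(pairing_spec(2, 8, t1 = "A", wobbles = 3L), g),
               "no wobble")   # g3 = A has no G:U partner
  # mismatch at g5: target position 4 replaced
  expect_equal(site_motif(pairing_spec(2, 8, t1 = "A",
                                       mismatches = c("5" = "G")), g),
               "CUAGCUCA")
  # bulged G between the nucleotides pairing g5 and g6
  expect_equal(site_motif(pairing_spec(2, 8, t1 = "A",
                                       bulge = list(after = 5, nt = "G")), g),
               "CUAGCCUCA")
  expect_error(site_motif(pairing_spec(2, 25), g), "exceeds")
})

test_that("canonical and decorated labels follow the nomenclature", {
  expect_equal(spec_label(pairing_spec(2, 8, t1 = "A")), "8mer")
  expect_equal(spec_label(pairing_spec(2, 8)), "7mer-m8")
  expect_equal(spec_label(pairing_spec(2, 7, t1 = "A")), "7mer-A1")
  expect_equal(spec_label(pairing_spec(2, 7)), "6mer")
  expect_equal(spec_label(pairing_spec(2, 6, t1 = "A")), "6mer-A1")
  expect_equal(spec_label(pairing_spec(2, 5, t1 = "A")), "5mer-A1")
  expect_equal(spec_label(pairing_spec(11, 21)), "11mer-m11.21")
  expect_equal(spec_label(pairing_spec(2, 8, t1 = "A", wobbles = 6L)),
               "8mer-w6")
  expect_equal(spec_label(pairing_spec(2, 8, t1 = "A",
                                       mismatches = c("5" = "G"))),
               "8mer-x5G")
  # seed-context bulge sites carry the standalone bX.YN name
  expect_equal(spec_label(pairing_spec(2, 8, t1 = "A",
                                       bulge = list(after = 5, nt = "G"))),
               "b5.6G")
  # non-seed-context bulges keep the suffix form
  expect_equal(spec_label(pairing_spec(2, 7, bulge = list(after = 4,
                                                          nt = "U"))),
               "6mer-b4.5U")
  # non-A t1 identities
  expect_equal(spec_label(pairing_spec(2, 7, t1 = "G")), "7mer-m2.7-G1")
  expect_equal(names(canonical_site_specs()),
               c("8mer", "7mer-m8", "7mer-A1", "6mer", "6mer-A1"))
})

test_that("classification reproduces hand-verified site assignments", {
  g <- let7a()
  cls <- function(m) classify_kmer(m, g)$label
  expect_equal(cls("CUACCUCA"), "8mer")
  expect_equal(cls("CUACCUC"), "7mer-m8")
  expect_equal(cls("UACCUCA"), "7mer-A1")
  expect_equal(cls("UACCUC"), "6mer")
  expect_equal(cls("ACCUCA"), "6mer-A1")
  expect_equal(cls("ACUAUACAACC"), "11mer-m11.21")
  expect_equal(cls("CUAGCCUCA"), "b5.6G")
  expect_equal(cls("CUGCCUCA"), "8mer-w6")
  expect_equal(cls("CUAGCUCA"), "8mer-x5G")
  # DNA input is accepted
  expect_equal(cls("CTACCTCA"), "8mer")
  # classification also reports the canonical motif of the matched site
  st <- classify_kmer("GUACCUCAC", g)
  expect_equal(st$label, "7mer-A1")
  expect_equal(st$motif, "UACCUCA")
  expect_equal(classify_kmer("CACCUCAG", g)$label, "6mer-A1")
})

test_that("boundary edits canonicalize to the shorter perfect site", {
  g <- let7a()
  # A|UACCUC: a full-length interpretation would need a terminal mismatch,
  # so the contained perfect 6mer wins
  expect_equal(classify_kmer("AUACCUC", g)$label, "6mer")
  expect_equal(classify_kmer("GUACCUCAC", g)$label, "7mer-A1")
})

test_that("classification rejects invalid input", {
  g <- let7a()
  expect_error(classify_kmer("ACG", g), "length")
  expect_error(classify_kmer(strrep("A", 13), g), "length")
  expect_error(classify_kmer("ACGUXACG", g), "alphabet")
})

test_that("motif enumeration merges equivalent deletions and flags clashes", {
  g <- let7a()
  # g4 and g5 are both G: deleting either yields the same motif
  specs <- list(pairing_spec(2, 8, t1 = "A", deletion = 4L),
                pairing_spec(2, 8, t1 = "A", deletion = 5L))
  out <- enumerate_site_motifs(g, specs)
  expect_equal(length(out), 1L)
  expect_equal(names(out), "8mer-d4/5")
  expect_equal(unname(out), "CUACUCA")
  expect_error(enumerate_site_motifs(g, list(pairing_spec(2, 7),
                                             pairing_spec(2, 7))),
               "ambiguous")
  canon <- enumerate_site_motifs(g, canonical_site_specs())
  expect_equal(unname(canon["8mer"]), "CUACCUCA")
  path <- tempfile(fileext = ".tsv")
  write_site_table(canon, path)
  df <- read.delim(path)
  expect_equal(df$label, names(canon))
  expect_equal(df$motif, unname(canon))
})
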